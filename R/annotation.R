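#' Transcript container
#'
#' A light container for one transcript's features of a single kind (exon or
#' CDS), as read from a GFF3/GTF file. Coordinates are 1-based inclusive
#' genomic positions; features of one kind must not overlap.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome/scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param features data.frame with columns `kind` (`"exon"`/`"CDS"`),
#'   `start`, `stop` (1-based inclusive).
#' @return an object of class `transcript`.
#' @export
new_transcript <- function(transcript_id, gene_id, chrom, strand, features) {
  stopifnot(strand %in% c("+", "-"),
            all(c("kind", "start", "stop") %in% names(features)))
  features <- features[order(features$start), , drop = FALSE]
  if (any(features$stop < features$start)) {
    stop("transcript ", transcript_id, ": feature with stop < start")
  }
  for (k in unique(features$kind)) {
    f <- features[features$kind == k, ]
    if (nrow(f) > 1L && any(f$start[-1L] <= f$stop[-nrow(f)])) {
      stop("transcript ", transcript_id, ": overlapping ", k, " features")
    }
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, features = features),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("transcript %s (gene %s) %s%s, %d %s feature(s)\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$features), paste(unique(x$features$kind),
                                      collapse = "/")))
  invisible(x)
}

strip_id_prefix <- function(x) sub("^(transcript:|gene:|mRNA:)", "", x)

#' Parse a GFF3 or GTF annotation into transcripts
#'
#' Reads the annotation with [rtracklayer::import()] and returns one
#' [new_transcript()] per annotated transcript, holding only features of the
#' requested kind sorted by start. Both GFF3 (`Parent` attributes) and GTF
#' (`transcript_id`/`gene_id` attributes) dialects are supported; features
#' without transcript attribution are skipped with a warning; a line with the
#' wrong number of tab-separated fields raises an error naming the line.
#'
#' @param path annotation file.
#' @param feature_kind `"exon"` or `"CDS"`.
#' @param format `"auto"` (by extension), `"gff3"` or `"gtf"`.
#' @return named list of [new_transcript()] objects.
#' @export
parse_annotation <- function(path, feature_kind = c("exon", "CDS"),
                             format = c("auto", "gff3", "gtf")) {
  feature_kind <- match.arg(feature_kind)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "gff3"
  }
  raw <- readLines(path)
  body <- !grepl("^\\s*(#|$)", raw)
  nfield <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop("malformed annotation line ", bad, " in ", path,
         " (expected 9 tab-separated fields)")
  }
  gr <- rtracklayer::import(path, format = format)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)

  feat <- which(type == feature_kind)
  if (format == "gff3") {
    parents <- as.list(mc$Parent[feat])
    tx_of_feat <- lapply(parents, strip_id_prefix)
    # transcript -> gene map from container features carrying ID + Parent
    has_id <- !is.na(mc$ID) & lengths(mc$Parent) > 0L & type != feature_kind
    gene_map <- stats::setNames(
      strip_id_prefix(vapply(as.list(mc$Parent[has_id]), `[`, "", 1L)),
      strip_id_prefix(mc$ID[has_id]))
  } else {
    tx <- mc$transcript_id[feat]
    tx_of_feat <- lapply(tx, function(t) if (is.na(t)) character() else t)
    ok <- !is.na(mc$transcript_id) & !is.na(mc$gene_id)
    gene_map <- stats::setNames(mc$gene_id[ok], mc$transcript_id[ok])
    gene_map <- gene_map[!duplicated(names(gene_map))]
  }

  orphan <- lengths(tx_of_feat) == 0L
  if (any(orphan)) {
    warning(sum(orphan), " ", feature_kind,
            " feature(s) without transcript attribution skipped")
  }

  rows <- data.frame(
    idx = rep(feat, lengths(tx_of_feat)),
    tx = unlist(tx_of_feat),
    stringsAsFactors = FALSE
  )
  out <- list()
  for (t in unique(rows$tx)) {
    idx <- rows$idx[rows$tx == t]
    gene <- if (t %in% names(gene_map)) unname(gene_map[[t]]) else t
    out[[t]] <- new_transcript(
      transcript_id = t, gene_id = gene,
      chrom = as.character(GenomicRanges::seqnames(gr))[idx[1L]],
      strand = as.character(GenomicRanges::strand(gr))[idx[1L]],
      features = data.frame(
        kind = feature_kind,
        start = GenomicRanges::start(gr)[idx],
        stop = GenomicRanges::end(gr)[idx],
        stringsAsFactors = FALSE))
  }
  out
}

#' Pick the longest isoform of a gene
#'
#' Returns the transcript maximising the summed length of its features (of
#' the kind the run was parsed with); ties broken toward the
#' lexicographically smallest transcript id.
#'
#' @param transcripts nonempty list of [new_transcript()] sharing a gene.
#' @return a single [new_transcript()].
#' @export
select_longest_isoform <- function(transcripts) {
  if (length(transcripts) == 0L) stop("select_longest_isoform: empty list")
  genes <- unique(vapply(transcripts, `[[`, "", "gene_id"))
  if (length(genes) != 1L) {
    stop("select_longest_isoform: transcripts from multiple genes: ",
         paste(genes, collapse = ", "))
  }
  totals <- vapply(transcripts, function(t) {
    sum(t$features$stop - t$features$start + 1)
  }, numeric(1))
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  best <- which(totals == max(totals))
  transcripts[[best[order(ids[best])][1L]]]
}

# --- genome sequence helpers -----------------------------------------------

chrom_string <- function(genome, chrom) {
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) stop("chromosome ", chrom,
                                        " absent from genome")
    return(genome[[chrom]])
  }
  nm <- sub("\\s.*$", "", names(genome))
  i <- match(chrom, nm)
  if (is.na(i)) stop("chromosome ", chrom, " absent from genome")
  as.character(genome[[i]])
}

# substring with N-padding outside 1..nchar(x)
slice_padded <- function(x, from, to) {
  n <- nchar(x)
  left <- max(0L, 1L - from)
  right <- max(0L, to - n)
  core <- if (min(to, n) >= max(from, 1L))
    substr(x, max(from, 1L), min(to, n)) else ""
  paste0(strrep("N", left), core, strrep("N", right))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

make_intron_id <- function(assembly, chrom, start, stop, strand) {
  paste(assembly, chrom, start, stop, strand, sep = ":")
}

#' Intron phase from CDS structure
#'
#' Phase of the intron following the `intron_index`-th CDS feature in
#' transcript orientation: the summed length of CDS sequence 5' of the
#' intron, modulo 3 (0 = between codons). Exon-defined transcripts have
#' undefined phase (`NA`).
#'
#' @param transcript a CDS-parsed [new_transcript()].
#' @param intron_index which inter-feature gap, 1 = 5'-most.
#' @return integer 0, 1 or 2, or `NA` for exon-defined transcripts.
#' @export
compute_phase <- function(transcript, intron_index) {
  f <- transcript$features
  if (!all(f$kind == "CDS")) return(NA_integer_)
  n <- nrow(f)
  if (intron_index < 1L || intron_index > n - 1L) {
    stop("intron_index ", intron_index, " out of range for ", n, " features")
  }
  if (transcript$strand == "-") f <- f[rev(seq_len(n)), , drop = FALSE]
  upstream <- sum(f$stop[seq_len(intron_index)] -
                  f$start[seq_len(intron_index)] + 1)
  as.integer(upstream %% 3)
}

MIN_CLASSIFIABLE_LENGTH <- 30L

#' Extract introns from one transcript
#'
#' Introns are the gaps between adjacent same-kind features: genomic start =
#' upstream feature stop + 1, stop = downstream feature start - 1. Ranks are
#' numbered 5' to 3' in transcript orientation and minus-strand sequences are
#' reverse-complemented. Motif windows use signed positions that skip zero
#' (+1 = first intron base, -1 = last): the 5' splice-site window spans
#' -3..+9 (12 nt, N-padded at chromosome edges) and the branch-point search
#' region spans -55..-5, truncated so it neither crosses the 5' splice site
#' nor the intron boundary. Introns shorter than 30 nt are flagged
#' `too_short` and carry no motif windows.
#'
#' @param transcript a [new_transcript()].
#' @param genome named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param assembly assembly label used in intron ids.
#' @param flank exonic flank length recorded on each side (default 50 nt).
#' @return data.frame with one row per intron (the intron table).
#' @export
extract_introns <- function(transcript, genome, assembly = "asm",
                            flank = 50L) {
  f <- transcript$features
  if (nrow(f) == 0L) stop("extract_introns: transcript has no features")
  chrom <- chrom_string(genome, transcript$chrom)
  n <- nrow(f)
  if (n >= 2L && any(f$start[-1L] <= f$stop[-n])) {
    stop("extract_introns: overlapping features in ",
         transcript$transcript_id)
  }
  gaps <- data.frame(start = f$stop[-n] + 1L, stop = f$start[-1L] - 1L,
                     feat = seq_len(max(n - 1L, 0L)))
  gaps <- gaps[gaps$stop >= gaps$start, , drop = FALSE]  # drop abutting pairs
  if (nrow(gaps) == 0L) return(empty_intron_table())
  minus <- transcript$strand == "-"
  k <- nrow(gaps)
  # junction index between features in transcript orientation (drives phase);
  # rank renumbers the extracted introns 5'->3' in transcript orientation
  junction <- if (minus) n - gaps$feat else gaps$feat
  rank <- rank(junction)
  cds_defined <- all(f$kind == "CDS")

  rows <- vector("list", k)
  for (i in seq_len(k)) {
    s <- gaps$start[i]; e <- gaps$stop[i]
    len <- e - s + 1L
    if (minus) {
      full <- revcomp(substr(chrom, s, e))
      up <- revcomp(slice_padded(chrom, e + 1L, e + flank))
      down <- revcomp(slice_padded(chrom, s - flank, s - 1L))
    } else {
      full <- substr(chrom, s, e)
      up <- slice_padded(chrom, s - flank, s - 1L)
      down <- slice_padded(chrom, e + 1L, e + flank)
    }
    too_short <- len < MIN_CLASSIFIABLE_LENGTH
    if (!too_short) {
      seq_5ss <- paste0(substr(up, flank - 2L, flank), substr(full, 1L, 9L))
      rs <- max(10L, len - 54L)
      re <- len - 4L
      bps_region <- substr(full, rs, re)
      bps_region_start <- rs
    } else {
      seq_5ss <- NA_character_
      bps_region <- NA_character_
      bps_region_start <- NA_integer_
    }
    phase <- if (cds_defined) compute_phase(transcript, junction[i]) else
      NA_integer_
    rows[[i]] <- data.frame(
      intron_id = make_intron_id(assembly, transcript$chrom, s, e,
                                 transcript$strand),
      gene_id = transcript$gene_id,
      transcript_id = transcript$transcript_id,
      chrom = transcript$chrom, start = s, stop = e,
      strand = transcript$strand, length = len, rank = rank[i],
      phase = phase,
      dnt_5 = substr(full, 1L, 2L),
      dnt_3 = substr(full, len - 1L, len),
      seq_5ss = seq_5ss, seq_bps_region = bps_region,
      bps_region_start = bps_region_start,
      upstream_flank = up, downstream_flank = down, full_seq = full,
      defined_by = if (cds_defined) "CDS" else "exon",
      too_short = too_short,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_intron_table <- function() {
  data.frame(intron_id = character(), gene_id = character(),
             transcript_id = character(), chrom = character(),
             start = integer(), stop = integer(), strand = character(),
             length = integer(), rank = integer(), phase = integer(),
             dnt_5 = character(), dnt_3 = character(),
             seq_5ss = character(), seq_bps_region = character(),
             bps_region_start = integer(), upstream_flank = character(),
             downstream_flank = character(), full_seq = character(),
             defined_by = character(), too_short = logical(),
             stringsAsFactors = FALSE)
}

#' Terminal-dinucleotide label
#'
#' Maps first/last intron dinucleotides to the conventional categories
#' `GT-AG`, `GC-AG`, `AT-AC` or `other`.
#'
#' @param dnt_5,dnt_3 character vectors of first and last dinucleotides.
#' @return character vector of labels.
#' @export
dnt_label <- function(dnt_5, dnt_3) {
  out <- rep("other", length(dnt_5))
  out[dnt_5 == "GT" & dnt_3 == "AG"] <- "GT-AG"
  out[dnt_5 == "GC" & dnt_3 == "AG"] <- "GC-AG"
  out[dnt_5 == "AT" & dnt_3 == "AC"] <- "AT-AC"
  out
}

#' Merge CDS-defined and exon-defined intron runs
#'
#' Union keyed by (chrom, start, stop, strand). When an intron occurs in
#' both runs the CDS-defined record wins (it carries a defined phase);
#' exon-only introns — those in untranslated regions or non-coding
#' transcripts — are retained with undefined phase.
#'
#' @param cds_introns,exon_introns intron tables from [extract_introns()].
#' @return merged intron table sorted by position.
#' @export
merge_runs <- function(cds_introns, exon_introns) {
  key <- function(d) paste(d$chrom, d$start, d$stop, d$strand, sep = "\r")
  extra <- exon_introns[!key(exon_introns) %in% key(cds_introns), ,
                        drop = FALSE]
  out <- rbind(cds_introns, extra)
  out <- out[order(out$chrom, out$start, out$stop, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

ELLIPSIS <- "…"

#' Abbreviated intron display string
#'
#' Renders an intron as
#' `UUUUUU|DDDDDDDDDD...BBBBBBBBBBBB...EEEEE|XXXXXX`: 6 nt of upstream exon,
#' a bar at the 5' splice site, the first 10 intron nt, an ellipsis, the
#' best-scoring branch-point 12-mer, an ellipsis, the last 5 intron nt, a bar
#' at the 3' splice site and 6 nt of downstream exon, all in transcript
#' orientation. Introns too short for distinct segments fall back to the
#' full sequence between bars.
#'
#' @param intron one row of an intron table.
#' @param best_bps result of [best_bps()] for that intron (or `NULL`).
#' @return display string.
#' @export
format_abbreviated <- function(intron, best_bps = NULL) {
  up6 <- substr(intron$upstream_flank, nchar(intron$upstream_flank) - 5L,
                nchar(intron$upstream_flank))
  down6 <- substr(intron$downstream_flank, 1L, 6L)
  L <- intron$length
  if (is.null(best_bps) || L < 27L || isTRUE(intron$too_short)) {
    return(paste0(up6, "|", intron$full_seq, "|", down6))
  }
  paste0(up6, "|", substr(intron$full_seq, 1L, 10L), ELLIPSIS,
         best_bps$motif_seq, ELLIPSIS,
         substr(intron$full_seq, L - 4L, L), "|", down6)
}

#' Parse an abbreviated intron display string
#'
#' Inverse of [format_abbreviated()] for the segmented form; returns the
#' segments plus the terminal dinucleotides they imply.
#'
#' @param x display string.
#' @return list with `upstream_exon`, `intron_5p`, `bps`, `intron_3p`,
#'   `downstream_exon`, `dnt_5`, `dnt_3`, `dnt` (the [dnt_label()]).
#' @export
parse_abbreviated <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stop("expected two '|' separators in ", x)
  mid <- strsplit(parts[2], ELLIPSIS, fixed = TRUE)[[1]]
  if (length(mid) == 1L) {  # fallback form: full intron between bars
    intron5 <- mid[1]; bps <- NA_character_; intron3 <- mid[1]
  } else if (length(mid) == 3L) {
    intron5 <- mid[1]; bps <- mid[2]; intron3 <- mid[3]
  } else stop("expected 0 or 2 ellipses in ", x)
  d5 <- substr(intron5, 1L, 2L)
  d3 <- substr(intron3, nchar(intron3) - 1L, nchar(intron3))
  list(upstream_exon = parts[1], intron_5p = intron5, bps = bps,
       intron_3p = intron3, downstream_exon = parts[3],
       dnt_5 = d5, dnt_3 = d3, dnt = dnt_label(d5, d3))
}

# Last 40 nt of the intron with the branch-point motif bracketed, as stored
# in the output table's 3'-terminus column.
bracket_3p <- function(full_seq, bps_start, motif_len = 12L, width = 40L) {
  L <- nchar(full_seq)
  from <- max(1L, L - width + 1L)
  if (is.na(bps_start)) return(substr(full_seq, from, L))
  bs <- bps_start; be <- bps_start + motif_len - 1L
  if (bs < from || be > L) return(substr(full_seq, from, L))
  paste0(substr(full_seq, from, bs - 1L), "[", substr(full_seq, bs, be), "]",
         substr(full_seq, be + 1L, L))
}

#' Write the intron annotation table
#'
#' Tab-separated output with one row per intron: id, probability score and
#' class call (when supplied), coordinates, length, strand, rank, phase,
#' terminal dinucleotides, 50-nt exonic flanks, the bracketed 3' terminus,
#' the full intron sequence and gene/transcript ids.
#'
#' @param introns intron table.
#' @param path output file.
#' @param results optional data.frame from [classify_introns()] with
#'   `intron_id`, `p_u12`, `call`.
#' @param scores optional data.frame from [score_genome()] (used for the
#'   bracketed branch-point position).
#' @return `path`, invisibly.
#' @export
write_intron_table <- function(introns, path, results = NULL,
                               scores = NULL) {
  tab <- introns
  tab$terminal_dinucleotides <- paste(tab$dnt_5, tab$dnt_3, sep = "-")
  tab$score <- NA_real_
  tab$class <- NA_character_
  if (!is.null(results)) {
    i <- match(tab$intron_id, results$intron_id)
    tab$score <- round(100 * results$p_u12[i], 3)
    tab$class <- results$call[i]
  }
  bpos <- rep(NA_integer_, nrow(tab))
  if (!is.null(scores)) {
    i <- match(tab$intron_id, scores$intron_id)
    bpos <- tab$bps_region_start + scores$bps_position[i] - 1L
  }
  tab$terminus_3p <- vapply(seq_len(nrow(tab)), function(r) {
    bracket_3p(tab$full_seq[r], bpos[r])
  }, character(1))
  cols <- c("intron_id", "score", "class", "chrom", "start", "stop",
            "length", "strand", "rank", "phase", "terminal_dinucleotides",
            "upstream_flank", "terminus_3p", "downstream_flank", "full_seq",
            "gene_id", "transcript_id")
  utils::write.table(tab[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
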