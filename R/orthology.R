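#' Pairwise protein alignment container
#'
#' Two equal-length gapped protein strings from a global alignment of
#' orthologous transcripts (reciprocal-best-hit search and alignment are
#' consumed as inputs, not executed here).
#'
#' @param id_a,id_b transcript identifiers.
#' @param row_a,row_b gapped protein strings (gap character `-`).
#' @return an object of class `pairwise_alignment`.
#' @export
new_pairwise_alignment <- function(id_a, id_b, row_a, row_b) {
  if (nchar(row_a) != nchar(row_b)) {
    stop("alignment rows have unequal lengths (", nchar(row_a), " vs ",
         nchar(row_b), ")")
  }
  structure(list(id_a = id_a, id_b = id_b, row_a = row_a, row_b = row_b),
            class = "pairwise_alignment")
}

#' Read aligned-FASTA pairwise alignments
#'
#' Reads an aligned FASTA file containing exactly two records and returns a
#' [new_pairwise_alignment()].
#'
#' @param path aligned-FASTA file.
#' @return a `pairwise_alignment`.
#' @export
read_pairwise_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) != 2L) {
    stop("expected exactly 2 records in ", path, ", found ", length(aa))
  }
  ids <- sub("\\s.*$", "", names(aa))
  new_pairwise_alignment(ids[1], ids[2], as.character(aa[[1]]),
                         as.character(aa[[2]]))
}

#' Anchor introns to protein residue coordinates
#'
#' For each CDS-defined intron of a transcript, records the 1-based codon
#' (residue) position of its splice junction —
#' `floor(upstream CDS nt / 3) + 1` — and carries its phase through.
#' Exon-defined introns have no protein coordinate and are skipped with a
#' warning.
#'
#' @param transcript a CDS-parsed [new_transcript()].
#' @param introns intron table for that transcript (from
#'   [extract_introns()]).
#' @return data.frame: intron_id, transcript_id, residue_index, phase.
#' @export
anchor_introns <- function(transcript, introns) {
  f <- transcript$features
  if (!all(f$kind == "CDS")) {
    warning("anchor_introns: exon-defined transcript ",
            transcript$transcript_id, " skipped (no protein coordinates)")
    return(data.frame(intron_id = character(), transcript_id = character(),
                      residue_index = integer(), phase = integer(),
                      stringsAsFactors = FALSE))
  }
  introns <- introns[order(introns$rank), , drop = FALSE]
  # CDS nucleotides 5' of each intron in transcript orientation
  upstream <- vapply(seq_len(nrow(introns)), function(i) {
    if (transcript$strand == "+") {
      up <- f$stop < introns$start[i]
    } else {
      up <- f$start > introns$stop[i]
    }
    sum(f$stop[up] - f$start[up] + 1L)
  }, numeric(1))
  data.frame(intron_id = introns$intron_id,
             transcript_id = transcript$transcript_id,
             residue_index = as.integer(upstream %/% 3L + 1L),
             phase = as.integer(upstream %% 3L),
             stringsAsFactors = FALSE)
}

residue_to_column <- function(gapped_row, residue_index) {
  chars <- strsplit(gapped_row, "", fixed = TRUE)[[1]]
  resno <- cumsum(chars != "-")
  col <- which(chars != "-" & resno == residue_index)
  if (length(col) == 0L) return(NA_integer_)
  col[1L]
}

#' Local alignment quality around a column
#'
#' Fraction of identical residue pairs (both non-gap and equal) among the
#' columns within `window` of `column`, truncated at the alignment ends;
#' the denominator is the number of columns examined.
#'
#' @param aln a [new_pairwise_alignment()].
#' @param column alignment column (1-based).
#' @param window half-width in columns (default 10).
#' @return fraction in `[0, 1]`.
#' @export
alignment_quality <- function(aln, column, window = 10L) {
  L <- nchar(aln$row_a)
  stopifnot(column >= 1L, column <= L)
  cols <- max(1L, column - window):min(L, column + window)
  a <- substring(aln$row_a, cols, cols)
  b <- substring(aln$row_b, cols, cols)
  sum(a == b & a != "-" & b != "-") / length(cols)
}

#' Pairwise orthologous-intron links
#'
#' Two anchored introns link as orthologs when they map to the same
#' alignment column, have equal phase, and the local alignment quality at
#' that column is at least `min_quality` (the >= 40% identity within +-10
#' residues filter).
#'
#' @param aln a [new_pairwise_alignment()].
#' @param anchors_a,anchors_b [anchor_introns()] tables for the two
#'   transcripts.
#' @param min_quality minimum [alignment_quality()] (default 0.40).
#' @param window quality window half-width.
#' @return data.frame: intron_id_a, intron_id_b, column, phase, quality.
#' @export
link_orthologous_introns <- function(aln, anchors_a, anchors_b,
                                     min_quality = 0.40, window = 10L) {
  map_cols <- function(anchors, row, who) {
    n_res <- sum(strsplit(row, "", fixed = TRUE)[[1]] != "-")
    vapply(seq_len(nrow(anchors)), function(i) {
      ri <- anchors$residue_index[i]
      if (ri > n_res) {
        stop("anchor ", anchors$intron_id[i], " beyond protein length of ",
             who, " (residue ", ri, " > ", n_res, ")")
      }
      residue_to_column(row, ri)
    }, integer(1))
  }
  col_a <- map_cols(anchors_a, aln$row_a, aln$id_a)
  col_b <- map_cols(anchors_b, aln$row_b, aln$id_b)
  out <- list()
  for (i in seq_along(col_a)) {
    j <- which(col_b == col_a[i] & anchors_b$phase == anchors_a$phase[i])
    for (jj in j) {
      q <- alignment_quality(aln, col_a[i], window = window)
      if (q >= min_quality) {
        out[[length(out) + 1L]] <- data.frame(
          intron_id_a = anchors_a$intron_id[i],
          intron_id_b = anchors_b$intron_id[jj],
          column = col_a[i], phase = anchors_a$phase[i], quality = q,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(intron_id_a = character(), intron_id_b = character(),
                      column = integer(), phase = integer(),
                      quality = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group orthologous introns by maximal-clique listing
#'
#' Treats pairwise orthologous-intron links as an undirected graph and
#' lists every maximal clique of size >= 2 — each group is a set of introns
#' in which every pair is a recorded ortholog, and no group can be extended
#' (links A-B, A-C, B-C, B-D yield groups \{A,B,C\} and \{B,D\}; a node may
#' appear in several groups). Members are sorted within groups and groups
#' ordered deterministically.
#'
#' @param links two-column data.frame (or matrix) of unordered intron-id
#'   pairs.
#' @param max_nodes guard against accidental dense inputs (maximal-clique
#'   listing is exponential in the worst case).
#' @return list of character vectors (sorted member ids).
#' @export
clique_groups <- function(links, max_nodes = 100000L) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (nrow(links) == 0L) return(list())
  a <- as.character(links[[1]]); b <- as.character(links[[2]])
  if (any(a == b)) {
    stop("clique_groups: self-link rejected: ", a[which(a == b)[1L]])
  }
  nodes <- unique(c(a, b))
  if (length(nodes) > max_nodes) {
    stop("clique_groups: ", length(nodes), " nodes exceed the ceiling of ",
         max_nodes)
  }
  g <- igraph::simplify(
    igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE))
  cl <- igraph::max_cliques(g, min = 2L)
  groups <- lapply(cl, function(v) sort(names(v)))
  groups[order(vapply(groups, paste, "", collapse = "\r"))]
}

#' Write an ortholog group table
#'
#' Tab-separated table with a numeric group id and the comma-joined member
#' intron ids of each group.
#'
#' @param groups list from [clique_groups()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_group_table <- function(groups, path) {
  df <- data.frame(group_id = seq_along(groups),
                   members = vapply(groups, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
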