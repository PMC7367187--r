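#' Simulation configuration
#'
#' Parameters of the synthetic-genome generator. Each planted intron draws
#' its 5' splice-site 12-mer (-3..+9), its acceptor dinucleotide and — for
#' U12-type introns — a branch-point 12-mer from the class consensus, with
#' each position kept at the consensus base with probability
#' `motif_fidelity` and otherwise replaced by a uniformly chosen different
#' base. Intron and exon lengths are log-normal with a floor; genes are
#' laid on one chromosome separated by random intergenic padding, and a
#' configurable fraction of genes is placed on the minus strand.
#'
#' @param seed RNG seed; all outputs are deterministic per seed.
#' @param n_genes number of single-transcript genes.
#' @param introns_per_gene integer range `c(min, max)` sampled uniformly.
#' @param u12_fraction fraction of introns planted as U12-type (the planted
#'   count is `round(u12_fraction * total introns)`).
#' @param u2_consensus_5ss,u12_consensus_5ss 12-nt 5'SS consensus strings
#'   (-3..+9; positions 1-3 are exonic).
#' @param u12_consensus_bps 12-nt branch-point consensus (carries the
#'   branch A at position 9).
#' @param u2_acceptor,u12_acceptor terminal acceptor dinucleotides.
#' @param motif_fidelity per-position probability of the consensus base.
#' @param intron_length,exon_length lists `(meanlog, sdlog, min)` of the
#'   log-normal length distributions (nt).
#' @param genome_padding intergenic padding (nt).
#' @param minus_strand_fraction fraction of genes on the minus strand.
#' @param assembly,chrom labels used in coordinates and intron ids.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 42L, n_genes = 60L,
                              introns_per_gene = c(1L, 6L),
                              u12_fraction = 0.01,
                              u2_consensus_5ss = "CAGGTAAGTATC",
                              u12_consensus_5ss = "ATAGTATCCTTT",
                              u12_consensus_bps = "TTTCCTTAACTT",
                              u2_acceptor = "AG", u12_acceptor = "AG",
                              motif_fidelity = 0.95,
                              intron_length = list(meanlog = log(120),
                                                   sdlog = 0.35, min = 70L),
                              exon_length = list(meanlog = log(150),
                                                 sdlog = 0.3, min = 60L),
                              genome_padding = 200L,
                              minus_strand_fraction = 0.3,
                              assembly = "sim1", chrom = "chr1") {
  stopifnot(u12_fraction >= 0, u12_fraction <= 1,
            motif_fidelity >= 0, motif_fidelity <= 1,
            minus_strand_fraction >= 0, minus_strand_fraction <= 1,
            nchar(u2_consensus_5ss) == 12L, nchar(u12_consensus_5ss) == 12L,
            nchar(u12_consensus_bps) == 12L,
            introns_per_gene[1] >= 1L,
            introns_per_gene[2] >= introns_per_gene[1])
  if (intron_length$min < 70L) {
    stop("intron_length$min must be >= 70 nt so the branch-point window ",
         "clears the 5' splice site")
  }
  structure(as.list(environment()), class = "simulation_config")
}

rand_seq <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

sample_motif <- function(consensus, fidelity) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  mutate <- stats::runif(length(bases)) >= fidelity
  if (any(mutate)) {
    bases[mutate] <- vapply(bases[mutate], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1))
  }
  paste(bases, collapse = "")
}

splice_in <- function(seq, at, replacement) {
  paste0(substr(seq, 1L, at - 1L), replacement,
         substr(seq, at + nchar(replacement), nchar(seq)))
}

#' Simulate a genome with planted U2- and U12-type introns
#'
#' Generates a FASTA genome, a GFF3 annotation (gene/mRNA/exon/CDS; every
#' transcript fully coding) and a truth table recording each planted
#' intron's coordinates, class, phase, rank, realized terminal
#' dinucleotides, realized 5'SS 12-mer and (for U12-type) the planted
#' branch-point motif and its position within the intron. Deterministic per
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, `genome.fa`,
#'   `annotation.gff3` and `truth.tsv` are written there.
#' @return list with `genome` (named character), `gff` (character lines),
#'   `truth` (data.frame), `config`, and file `paths` when `out_dir` is
#'   given.
#' @export
simulate_genome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ipg <- config$introns_per_gene
  choices <- seq(ipg[1], ipg[2])  # length-1 safe: sample() from the vector
  n_int <- choices[sample.int(length(choices), config$n_genes,
                              replace = TRUE)]
  total <- sum(n_int)
  n_u12 <- round(config$u12_fraction * total)
  u12_global <- if (n_u12 > 0L) sort(sample(total, n_u12)) else integer()
  minus <- stats::runif(config$n_genes) < config$minus_strand_fraction

  draw_len <- function(n, spec) {
    pmax(as.integer(round(stats::rlnorm(n, spec$meanlog, spec$sdlog))),
         as.integer(spec$min))
  }

  chrom_parts <- list(rand_seq(config$genome_padding))
  offset <- config$genome_padding
  gff <- c("##gff-version 3")
  truth <- list()
  counter <- 0L

  for (g in seq_len(config$n_genes)) {
    k <- n_int[g]
    exon_lens <- draw_len(k + 1L, config$exon_length)
    intron_lens <- draw_len(k, config$intron_length)
    classes <- ifelse((counter + seq_len(k)) %in% u12_global, "U12", "U2")
    counter <- counter + k
    exons <- vapply(exon_lens, rand_seq, character(1))
    introns <- character(k)
    planted <- vector("list", k)
    for (i in seq_len(k)) {
      L <- intron_lens[i]
      s <- rand_seq(L)
      cons <- if (classes[i] == "U12") config$u12_consensus_5ss else
        config$u2_consensus_5ss
      motif12 <- sample_motif(cons, config$motif_fidelity)
      exons[i] <- splice_in(exons[i], exon_lens[i] - 2L,
                            substr(motif12, 1L, 3L))
      s <- splice_in(s, 1L, substr(motif12, 4L, 12L))
      acc <- if (classes[i] == "U12") config$u12_acceptor else
        config$u2_acceptor
      s <- splice_in(s, L - 1L, sample_motif(acc, config$motif_fidelity))
      bps_motif <- NA_character_
      bps_start <- NA_integer_
      if (classes[i] == "U12") {
        bps_motif <- sample_motif(config$u12_consensus_bps,
                                  config$motif_fidelity)
        delta <- sample(0:35, 1L)
        bps_start <- L - 15L - delta
        s <- splice_in(s, bps_start, bps_motif)
      }
      introns[i] <- s
      planted[[i]] <- list(class = classes[i],
                           five_ss = paste0(substr(exons[i],
                                                   exon_lens[i] - 2L,
                                                   exon_lens[i]),
                                            substr(s, 1L, 9L)),
                           bps_motif = bps_motif, bps_start = bps_start)
    }
    # transcript-local layout (1-based, transcript orientation)
    tx_seq <- character(2L * k + 1L)
    tx_seq[seq(1L, 2L * k + 1L, 2L)] <- exons
    tx_seq[seq(2L, 2L * k, 2L)] <- introns
    tx_seq <- paste(tx_seq, collapse = "")
    lens <- integer(2L * k + 1L)
    lens[seq(1L, 2L * k + 1L, 2L)] <- exon_lens
    lens[seq(2L, 2L * k, 2L)] <- intron_lens
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    gene_len <- ends[length(ends)]
    strand <- if (minus[g]) "-" else "+"
    gene_id <- sprintf("gene%03d", g)
    tx_id <- sprintf("tx%03d", g)
    gstart <- offset + 1L

    loc2gen <- function(s, e) {
      if (strand == "+") c(gstart + s - 1L, gstart + e - 1L) else
        c(gstart + gene_len - e, gstart + gene_len - s)
    }
    gseq <- if (strand == "+") tx_seq else revcomp(tx_seq)
    chrom_parts[[length(chrom_parts) + 1L]] <- gseq
    chrom_parts[[length(chrom_parts) + 1L]] <-
      rand_seq(config$genome_padding)
    offset <- offset + gene_len + config$genome_padding

    attr_line <- function(type, s, e, frame, attrs) {
      paste(config$chrom, "introntype_sim", type, s, e, ".", strand, frame,
            attrs, sep = "\t")
    }
    span <- loc2gen(1L, gene_len)
    gff <- c(gff,
             attr_line("gene", span[1], span[2], ".",
                       paste0("ID=", gene_id)),
             attr_line("mRNA", span[1], span[2], ".",
                       paste0("ID=", tx_id, ";Parent=", gene_id)))
    cum_cds <- 0L
    for (e in seq_len(k + 1L)) {
      idx <- 2L * e - 1L
      pos <- loc2gen(starts[idx], ends[idx])
      frame <- (3L - cum_cds %% 3L) %% 3L
      gff <- c(gff,
               attr_line("exon", pos[1], pos[2], ".",
                         paste0("Parent=", tx_id)),
               attr_line("CDS", pos[1], pos[2], frame,
                         paste0("ID=", tx_id, ".cds;Parent=", tx_id)))
      cum_cds <- cum_cds + lens[idx]
    }
    cum_exon <- cumsum(exon_lens)
    for (i in seq_len(k)) {
      idx <- 2L * i
      pos <- loc2gen(starts[idx], ends[idx])
      iseq <- introns[i]
      truth[[length(truth) + 1L]] <- data.frame(
        intron_id = make_intron_id(config$assembly, config$chrom, pos[1],
                                   pos[2], strand),
        gene_id = gene_id, transcript_id = tx_id, chrom = config$chrom,
        start = pos[1], stop = pos[2], strand = strand,
        length = intron_lens[i], rank = i,
        phase = as.integer(cum_exon[i] %% 3L),
        class = planted[[i]]$class,
        dnt_5 = substr(iseq, 1L, 2L),
        dnt_3 = substr(iseq, intron_lens[i] - 1L, intron_lens[i]),
        five_ss = planted[[i]]$five_ss,
        bps_motif = planted[[i]]$bps_motif,
        bps_start = planted[[i]]$bps_start,
        stringsAsFactors = FALSE)
    }
  }

  genome <- stats::setNames(paste(unlist(chrom_parts), collapse = ""),
                            config$chrom)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  out <- list(genome = genome, gff = gff, truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genome.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome), fa, width = 80L)
    gf <- file.path(out_dir, "annotation.gff3")
    writeLines(gff, gf)
    tt <- file.path(out_dir, "truth.tsv")
    utils::write.table(truth, tt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- c(genome = fa, annotation = gf, truth = tt)
  }
  out
}

#' Simulate a labeled training set
#'
#' Emits per-class 5' splice-site 12-mers and branch-point region sequences
#' in the classifier's training format. U12-type rows draw both motifs from
#' the U12 consensus (the branch-point 12-mer is planted at a random
#' position of a 51-nt region); U2-type rows draw the 5'SS from the U2
#' consensus over a random branch-point region, since U2-type introns carry
#' no extended branch-point motif. Class separation is controlled by
#' `config$motif_fidelity`.
#'
#' @param n_u2,n_u12 per-class counts (an imbalanced U2 >> U12 regime
#'   matches real training data).
#' @param config a [simulation_config()].
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @param region_length branch-point region length (default 51).
#' @return data.frame: class, five_ss, bps_region.
#' @export
simulate_training_set <- function(n_u2, n_u12, config,
                                  seed = config$seed + 1L,
                                  region_length = 51L) {
  stopifnot(n_u2 >= 1L, n_u12 >= 1L)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_u2)) {
    rows[[length(rows) + 1L]] <- data.frame(
      class = "U2",
      five_ss = sample_motif(config$u2_consensus_5ss,
                             config$motif_fidelity),
      bps_region = rand_seq(region_length), stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_u12)) {
    region <- rand_seq(region_length)
    pos <- sample(region_length - 11L, 1L)
    region <- splice_in(region, pos,
                        sample_motif(config$u12_consensus_bps,
                                     config$motif_fidelity))
    rows[[length(rows) + 1L]] <- data.frame(
      class = "U12",
      five_ss = sample_motif(config$u12_consensus_5ss,
                             config$motif_fidelity),
      bps_region = region, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write training-sequence files
#'
#' Plain-text, one intron per line: the 12-nt 5' splice-site window and the
#' branch-point region sequence, tab-separated. One file per class.
#'
#' @param training single-class subset of a training data.frame.
#' @param path file path.
#' @return `write_training_file()` returns `path` invisibly;
#'   `read_training_file()` returns a data.frame with `class`, `five_ss`,
#'   `bps_region`.
#' @export
write_training_file <- function(training, path) {
  stopifnot(length(unique(training$class)) == 1L)
  writeLines(paste(training$five_ss, training$bps_region, sep = "\t"), path)
  invisible(path)
}

#' @param class class label to attach on read (`"U2"` or `"U12"`).
#' @rdname write_training_file
#' @export
read_training_file <- function(path, class) {
  parts <- strsplit(readLines(path), "\t", fixed = TRUE)
  data.frame(class = class,
             five_ss = vapply(parts, `[`, "", 1L),
             bps_region = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' PWM set matching a simulation's consensus motifs
#'
#' Materialises the scoring matrices implied by a [simulation_config()]:
#' U2 and U12 5'SS matrices (offset -3) and the U12 branch-point matrix,
#' each a [consensus_pwm()] at the configured fidelity. Subtype is read
#' from the +1/+2 dinucleotide of each 5'SS consensus.
#'
#' @param config a [simulation_config()].
#' @return named list of [new_pwm()] objects.
#' @export
simulate_pwm_set <- function(config) {
  st <- function(cons) {
    if (substr(cons, 4L, 5L) == "AT") "AT-AC" else "GT-AG"
  }
  list(
    u2_5ss = consensus_pwm(config$u2_consensus_5ss, config$motif_fidelity,
                           offset = -3L, name = "u2_5ss",
                           intron_class = "U2", motif = "5SS",
                           subtype = st(config$u2_consensus_5ss)),
    u12_5ss = consensus_pwm(config$u12_consensus_5ss,
                            config$motif_fidelity, offset = -3L,
                            name = "u12_5ss", intron_class = "U12",
                            motif = "5SS",
                            subtype = st(config$u12_consensus_5ss)),
    u12_bps = consensus_pwm(config$u12_consensus_bps,
                            config$motif_fidelity, offset = 1L,
                            name = "u12_bps", intron_class = "U12",
                            motif = "BPS", subtype = "GT-AG"))
}

#' Simulate a pairwise ortholog alignment with planted shared introns
#'
#' Generates two gapless aligned proteins whose per-position identity is
#' `conservation` (identity indicators share underlying uniform draws
#' across calls with the same seed, so sweeping `conservation` upward only
#' adds identical positions), plants `planted_shared_introns` introns at
#' common residue positions and phases in both transcripts, and records the
#' true links.
#'
#' @param conservation fraction of identical residue positions.
#' @param planted_shared_introns number of shared intron positions.
#' @param seed RNG seed.
#' @param protein_length alignment length in residues.
#' @return list: `alignment` ([new_pairwise_alignment()]), `anchors_a`,
#'   `anchors_b`, `truth_links` (data.frame `intron_id_a`, `intron_id_b`).
#' @export
simulate_ortholog_pair <- function(conservation, planted_shared_introns = 3L,
                                   seed = 42L, protein_length = 200L) {
  stopifnot(conservation >= 0, conservation <= 1,
            protein_length >= planted_shared_introns + 20L)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  set.seed(seed)
  prot_a <- sample(aa, protein_length, replace = TRUE)
  u <- stats::runif(protein_length)
  alt <- vapply(prot_a, function(x) sample(setdiff(aa, x), 1L),
                character(1), USE.NAMES = FALSE)
  pos <- sort(sample(seq(11L, protein_length - 10L),
                     planted_shared_introns))
  phase <- sample(0:2, planted_shared_introns, replace = TRUE)
  prot_b <- ifelse(u < conservation, prot_a, alt)
  aln <- new_pairwise_alignment("txA", "txB",
                                paste(prot_a, collapse = ""),
                                paste(prot_b, collapse = ""))
  mk <- function(who) data.frame(
    intron_id = sprintf("%s_intron%02d", who,
                        seq_len(planted_shared_introns)),
    transcript_id = paste0("tx", who), residue_index = pos, phase = phase,
    stringsAsFactors = FALSE)
  list(alignment = aln, anchors_a = mk("A"), anchors_b = mk("B"),
       truth_links = data.frame(
         intron_id_a = sprintf("A_intron%02d",
                               seq_len(planted_shared_introns)),
         intron_id_b = sprintf("B_intron%02d",
                               seq_len(planted_shared_introns)),
         stringsAsFactors = FALSE))
}
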