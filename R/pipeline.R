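#' Full genome classification pipeline
#'
#' Runs the whole method end to end: parse the annotation twice (CDS-defined
#' and exon-defined runs), keep the longest isoform of each gene per run,
#' extract and merge introns (CDS-defined records win on coordinate
#' collisions), score every intron's 5' splice site, derive the empirical
#' species-specific U2 branch-point matrix from the background, score
#' branch points, score the labeled training sequences on the same scale,
#' train the linear SVM, and call U12-type at the probability threshold.
#'
#' @param genome path to a FASTA file, or a named character vector /
#'   [Biostrings::DNAStringSet] of chromosomes.
#' @param annotation path to a GFF3/GTF file.
#' @param pwm_set list of [new_pwm()] objects (U2/U12 5'SS, U12 BPS).
#' @param training data.frame with `class`, `five_ss`, `bps_region` (e.g.
#'   from [read_training_file()] or [simulate_training_set()]).
#' @param feature `"both"` (merge CDS- and exon-defined runs), `"cds"` or
#'   `"exon"`.
#' @param threshold U12-type probability threshold (default 0.90).
#' @param C SVM penalty; `NULL` to optimise by cross-validation.
#' @param seed RNG seed for fold assignment.
#' @param assembly assembly label for intron ids.
#' @param format annotation format passed to [parse_annotation()].
#' @return list: `introns` (merged intron table), `scores`, `u2_bps`
#'   (empirical matrix), `training_scores`, `model`, `results`
#'   (classification calls).
#' @export
classify_genome <- function(genome, annotation, pwm_set, training,
                            feature = c("both", "cds", "exon"),
                            threshold = 0.90, C = NULL, seed = 42L,
                            assembly = "asm", format = "auto") {
  feature <- match.arg(feature)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
    genome <- stats::setNames(as.character(gs),
                              sub("\\s.*$", "", names(gs)))
  }
  run <- function(kind) {
    txs <- parse_annotation(annotation, feature_kind = kind,
                            format = format)
    genes <- split(txs, vapply(txs, `[[`, "", "gene_id"))
    tabs <- lapply(genes, function(g) {
      extract_introns(select_longest_isoform(g), genome,
                      assembly = assembly)
    })
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    out
  }
  introns <- switch(feature,
    cds = run("CDS"),
    exon = run("exon"),
    both = merge_runs(run("CDS"), run("exon")))
  scored <- score_genome(introns, pwm_set)
  training_scores <- score_training_set(training, pwm_set, scored$u2_bps)
  model <- train_classifier(training_scores, C = C, seed = seed)
  results <- classify_introns(scored$scores, model, threshold = threshold)
  list(introns = introns, scores = scored$scores, u2_bps = scored$u2_bps,
       training_scores = training_scores, model = model, results = results)
}
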