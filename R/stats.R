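#' Phase-distribution bias test
#'
#' Per intron class, a chi-squared goodness-of-fit test of the phase
#' (0/1/2) counts against a null of equal expected fractions (1/3 each by
#' default, overridable). Classes without phased introns are omitted with a
#' message.
#'
#' @param introns classified intron table with columns `phase` and `call`
#'   (or `class`).
#' @param expected null phase fractions, length 3 summing to 1.
#' @return data.frame: class, n0, n1, n2, chi2, df, p_value.
#' @export
phase_bias_test <- function(introns, expected = rep(1 / 3, 3)) {
  stopifnot(length(expected) == 3L, abs(sum(expected) - 1) < 1e-9)
  cls <- class_column(introns)
  out <- list()
  for (cl in unique(cls[!is.na(cls)])) {
    ph <- introns$phase[cls == cl]
    ph <- ph[!is.na(ph)]
    if (length(ph) == 0L) {
      message("phase_bias_test: class ", cl,
              " has no phased introns; omitted")
      next
    }
    counts <- as.numeric(table(factor(ph, levels = 0:2)))
    ct <- suppressWarnings(stats::chisq.test(counts, p = expected))
    out[[cl]] <- data.frame(class = cl, n0 = counts[1], n1 = counts[2],
                            n2 = counts[3],
                            chi2 = unname(ct$statistic),
                            df = unname(ct$parameter),
                            p_value = ct$p.value,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

class_column <- function(introns) {
  cls <- if ("call" %in% names(introns)) introns$call else introns$class
  sub("-type$", "", cls)
}

#' Nucleotide composition at the -1 exonic position
#'
#' For each intron class and group (phase or terminal-dinucleotide
#' category), the fraction of introns carrying each base immediately
#' upstream of the 5' splice site (the last base of the upstream exonic
#' flank, transcript orientation). `N` bases are excluded; rows sum to 1.
#'
#' @param introns classified intron table with `upstream_flank`.
#' @param grouping `"phase"` or `"terminal_dinucleotides"`.
#' @return data.frame: class, group, A, C, G, T, n.
#' @export
minus1_table <- function(introns,
                         grouping = c("phase", "terminal_dinucleotides")) {
  grouping <- match.arg(grouping)
  cls <- class_column(introns)
  base <- substr(introns$upstream_flank, nchar(introns$upstream_flank),
                 nchar(introns$upstream_flank))
  grp <- if (grouping == "phase") as.character(introns$phase) else
    dnt_label(introns$dnt_5, introns$dnt_3)
  keep <- !is.na(cls) & !is.na(grp) & base %in% DNA_BASES
  out <- list()
  for (cl in unique(cls[keep])) {
    for (g in sort(unique(grp[keep & cls == cl]))) {
      b <- base[keep & cls == cl & grp == g]
      if (length(b) == 0L) next
      tab <- table(factor(b, levels = DNA_BASES)) / length(b)
      out[[paste(cl, g)]] <- data.frame(
        class = cl, group = g, A = tab[["A"]], C = tab[["C"]],
        G = tab[["G"]], T = tab[["T"]], n = length(b),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Terminal-dinucleotide percentages per class
#'
#' Percentage of introns in each class whose boundaries fall in each of the
#' conventional categories GT-AG, GC-AG, AT-AC or other; rows sum to 100 up
#' to rounding.
#'
#' @param introns classified intron table.
#' @return data.frame: class, `GT-AG`, `GC-AG`, `AT-AC`, other, n.
#' @export
terminal_dinucleotide_table <- function(introns) {
  cls <- class_column(introns)
  lab <- dnt_label(introns$dnt_5, introns$dnt_3)
  cats <- c("GT-AG", "GC-AG", "AT-AC", "other")
  out <- list()
  for (cl in unique(cls[!is.na(cls)])) {
    l <- lab[!is.na(cls) & cls == cl]
    pct <- 100 * as.numeric(table(factor(l, levels = cats))) / length(l)
    row <- as.data.frame(as.list(stats::setNames(pct, cats)),
                         check.names = FALSE)
    row <- cbind(data.frame(class = cl, stringsAsFactors = FALSE), row,
                 n = length(l))
    out[[cl]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deduplicate alternative splice variants of the same intron
#'
#' Builds a graph with one node per distinct genomic coordinate
#' (assembly + chromosome + position) and one edge per annotated intron row
#' joining its start and stop. Introns sharing a splice site (alternative
#' donors/acceptors) merge into one connected component, so the number of
#' unique introns is the number of components. One representative row per
#' component is returned: the lexicographically smallest (start, stop).
#'
#' @param rows data.frame with `assembly`, `chrom`, `start`, `stop`.
#' @return list with `unique_intron_count` and `representatives`
#'   (a data.frame of one row per component).
#' @export
dedup_splice_variants <- function(rows) {
  if (nrow(rows) == 0L) {
    return(list(unique_intron_count = 0L, representatives = rows))
  }
  a <- paste(rows$assembly, rows$chrom, rows$start, sep = ":")
  b <- paste(rows$assembly, rows$chrom, rows$stop, sep = ":")
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  comp <- igraph::components(g)$membership
  edge_comp <- comp[a]
  reps <- do.call(rbind, lapply(split(seq_len(nrow(rows)), edge_comp),
    function(idx) {
      r <- rows[idx, , drop = FALSE]
      r[order(r$start, r$stop)[1L], , drop = FALSE]
    }))
  rownames(reps) <- NULL
  list(unique_intron_count = max(comp), representatives = reps)
}

#' Binomial test for clustering of U12-type introns within genes
#'
#' Under random placement, the number of genes carrying more than one
#' U12-type intron — among the n genes carrying at least one — is binomial
#' with success probability `p_multi = 1 - (1 - x)^(m - 1)`, where x is the
#' genome-wide proportion of U12-type introns and m the average number of
#' introns per (intron-containing) gene. Both the binomial point mass
#' `P(X = k)` and the upper tail `P(X >= k)` are reported for k = observed
#' count of genes with two or more U12-type introns; the tail is labelled
#' as the p-value.
#'
#' @param genes data.frame with columns `gene_id`, `n_introns`, `n_u12`.
#' @return list: `n_genes_with_u12`, `x_u12_fraction`, `m_mean_introns`,
#'   `p_multi`, `observed_multi`, `p_point`, `p_value`, `degenerate`.
#' @export
u12_clustering_test <- function(genes) {
  stopifnot(all(c("n_introns", "n_u12") %in% names(genes)))
  with_introns <- genes$n_introns >= 1L
  x <- sum(genes$n_u12) / sum(genes$n_introns)
  m <- mean(genes$n_introns[with_introns])
  p_multi <- 1 - (1 - x)^(m - 1)
  n <- sum(genes$n_u12 >= 1L)
  k <- sum(genes$n_u12 >= 2L)
  degenerate <- x == 0
  if (degenerate) {
    warning("u12_clustering_test: no U12-type introns (x = 0); ",
            "test degenerate")
  }
  list(n_genes_with_u12 = n, x_u12_fraction = x, m_mean_introns = m,
       p_multi = p_multi, observed_multi = k,
       p_point = stats::dbinom(k, n, p_multi),
       p_value = stats::pbinom(k - 1L, n, p_multi, lower.tail = FALSE),
       degenerate = degenerate)
}

#' Codon families that permit a wobble G
#'
#' Groups the 61 sense codons of the standard genetic code into 20 families
#' by encoded amino acid and counts the families containing at least one
#' codon ending in G. The -1 exonic nucleotide of a phase 0 intron is a
#' codon's wobble position, so this count bounds how many codon families
#' can present a -1 G without changing the protein.
#'
#' @return integer count of families (13 under the standard code).
#' @export
wobble_g_families <- function() {
  code <- Biostrings::GENETIC_CODE
  sense <- code[code != "*"]
  fams <- split(names(sense), unname(sense))
  sum(vapply(fams, function(codons) {
    any(substr(codons, 3L, 3L) == "G")
  }, logical(1)))
}

#' Per-class intron length summary
#'
#' Mean intron length and intron count per class, with the genome size
#' attached for cross-species correlation.
#'
#' @param introns classified intron table with `length`.
#' @param genome_size genome size in bp (optional).
#' @param species species label (optional).
#' @return data.frame: species, class, mean_length, mean_log10_length,
#'   count, genome_size.
#' @export
length_summary <- function(introns, genome_size = NA_real_,
                           species = NA_character_) {
  cls <- class_column(introns)
  out <- list()
  for (cl in unique(cls[!is.na(cls)])) {
    len <- introns$length[!is.na(cls) & cls == cl]
    out[[cl]] <- data.frame(species = species, class = cl,
                            mean_length = mean(len),
                            mean_log10_length = mean(log10(len)),
                            count = length(len),
                            genome_size = genome_size,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-species correlation of mean intron length with genome size
#'
#' Pearson correlation of per-species mean intron length against genome
#' size, per class, over species where both are available. Zero-variance
#' input yields `NA` with a warning.
#'
#' @param summaries row-bound [length_summary()] results across species.
#' @return data.frame: class, r, n_species.
#' @export
length_genome_correlation <- function(summaries) {
  out <- list()
  for (cl in unique(summaries$class)) {
    s <- summaries[summaries$class == cl &
                   !is.na(summaries$genome_size) &
                   !is.na(summaries$mean_length), , drop = FALSE]
    if (nrow(s) < 2L) {
      out[[cl]] <- data.frame(class = cl, r = NA_real_,
                              n_species = nrow(s))
      next
    }
    if (stats::sd(s$mean_length) == 0 || stats::sd(s$genome_size) == 0) {
      warning("length_genome_correlation: zero variance for class ", cl,
              "; correlation undefined")
      r <- NA_real_
    } else {
      r <- stats::cor(s$mean_length, s$genome_size)
    }
    out[[cl]] <- data.frame(class = cl, r = r, n_species = nrow(s),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
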