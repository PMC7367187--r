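# Independent oracles and small fixture builders shared across tests.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# random PWM with Dirichlet-ish columns
random_pwm <- function(width, ...) {
  m <- matrix(stats::runif(4L * width) + 0.01, nrow = 4L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- sweep(m, 2L, colSums(m), "/")
  new_pwm(m, name = "rand", ...)
}

# product-then-log oracle for the binary log-ratio score
oracle_log_ratio <- function(u12, u2, seq) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  pc <- u12$pseudo_count
  p12 <- 1; p2 <- 1
  for (j in seq_along(bases)) {
    if (bases[j] == "N") next
    p12 <- p12 * (u12$mat[bases[j], j] + pc)
    p2 <- p2 * (u2$mat[bases[j], j] + pc)
  }
  unname(log2(p12) - log2(p2))
}

# exhaustive 12-mer scan oracle (substr loop, independent of scan_windows)
oracle_best_bps <- function(region, u12, u2) {
  w <- ncol(u12$mat)
  best <- NULL
  for (i in seq_len(nchar(region) - w + 1L)) {
    cand <- substr(region, i, i + w - 1L)
    s <- oracle_log_ratio(u12, u2, cand)
    if (is.null(best) || s >= best$log_ratio - 1e-12) {
      best <- list(log_ratio = s, motif_seq = cand, position = i)
    }
  }
  best
}

# union-find component counter over intron coordinate rows
oracle_union_find <- function(rows) {
  keys <- unique(c(paste(rows$assembly, rows$chrom, rows$start, sep = ":"),
                   paste(rows$assembly, rows$chrom, rows$stop, sep = ":")))
  parent <- stats::setNames(seq_along(keys), keys)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (r in seq_len(nrow(rows))) {
    a <- find(match(paste(rows$assembly[r], rows$chrom[r], rows$start[r],
                          sep = ":"), keys))
    b <- find(match(paste(rows$assembly[r], rows$chrom[r], rows$stop[r],
                          sep = ":"), keys))
    parent[a] <- b
  }
  length(unique(vapply(seq_along(keys), find, numeric(1))))
}

# brute-force maximal clique listing by subset enumeration (<= 20 nodes)
oracle_cliques <- function(links) {
  nodes <- sort(unique(c(links[[1]], links[[2]])))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(links))) {
    adj[links[[1]][r], links[[2]][r]] <- TRUE
    adj[links[[2]][r], links[[1]][r]] <- TRUE
  }
  is_clique <- function(idx) {
    all(adj[idx, idx][upper.tri(diag(length(idx)))])
  }
  cliques <- list()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < 2L || !is_clique(idx)) next
    extendable <- any(vapply(setdiff(seq_len(n), idx), function(v) {
      all(adj[v, idx])
    }, logical(1)))
    if (!extendable) cliques[[length(cliques) + 1L]] <- nodes[idx]
  }
  cliques[order(vapply(cliques, paste, "", collapse = "\r"))]
}

# standard genetic code written out independently of Biostrings: codons in
# T/C/A/G nested order paired with the canonical one-letter translation
oracle_codon_table <- function() {
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
}

# test-local consensus noising (mirrors the generator's planting model)
sample_motif_for_test <- function(consensus, fidelity) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  mutate <- stats::runif(length(bases)) >= fidelity
  bases[mutate] <- vapply(bases[mutate], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1))
  paste(bases, collapse = "")
}

# quick transcript builder
tx <- function(id, gene, strand, kind, starts, stops, chrom = "chr1") {
  new_transcript(id, gene, chrom, strand,
                 data.frame(kind = kind, start = starts, stop = stops,
                            stringsAsFactors = FALSE))
}

# fixture PWM set with clearly separated U2/U12 consensus motifs
fixture_pwms <- function(fidelity = 0.95) {
  simulate_pwm_set(simulation_config(motif_fidelity = fidelity))
}

fixture_intron <- function(seq_5ss = NULL, bps_region = NULL,
                           dnt_5 = "GT", dnt_3 = "AG") {
  list(seq_5ss = seq_5ss, seq_bps_region = bps_region, dnt_5 = dnt_5,
       dnt_3 = dnt_3, too_short = FALSE)
}
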