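test_that("5'SS scores are positive for U12 consensus and negative for U2", {
  cfg <- simulation_config()
  pw <- simulate_pwm_set(cfg)
  u12_like <- fixture_intron(seq_5ss = cfg$u12_consensus_5ss)
  u2_like <- fixture_intron(seq_5ss = cfg$u2_consensus_5ss)
  expect_gt(score_five_prime(u12_like, pw), 0)
  expect_lt(score_five_prime(u2_like, pw), 0)
  expect_true(is.na(score_five_prime(
    fixture_intron(seq_5ss = NA_character_), pw)))
})

test_that("subtype dispatch selects AT-AC and GC-AG matrices when present", {
  cfg <- simulation_config()
  pw <- simulate_pwm_set(cfg)
  pw$u12_5ss_atac <- consensus_pwm("ATAATATCCTTT", 0.99, offset = -3L,
                                   name = "u12_5ss_atac",
                                   intron_class = "U12", motif = "5SS",
                                   subtype = "AT-AC")
  pw$u2_5ss_gcag <- consensus_pwm("CAGGCAAGTATC", 0.99, offset = -3L,
                                  name = "u2_5ss_gcag", intron_class = "U2",
                                  motif = "5SS", subtype = "GC-AG")
  seq <- "ATAATATCCTTT"
  atac <- fixture_intron(seq_5ss = seq, dnt_5 = "AT", dnt_3 = "AC")
  expect_equal(score_five_prime(atac, pw),
               score_log_ratio(pw$u12_5ss_atac, pw$u2_5ss, seq))
  gcag <- fixture_intron(seq_5ss = seq, dnt_5 = "GC", dnt_3 = "AG")
  expect_equal(score_five_prime(gcag, pw),
               score_log_ratio(pw$u12_5ss, pw$u2_5ss_gcag, seq))
  # unknown termini fall back to GT-AG matrices of both classes
  other <- fixture_intron(seq_5ss = seq, dnt_5 = "CT", dnt_3 = "TG")
  expect_equal(score_five_prime(other, pw),
               score_log_ratio(pw$u12_5ss, pw$u2_5ss, seq))
})

test_that("best_bps scans every 12-mer, ties resolved 3'-most", {
  set.seed(9)
  u12 <- random_pwm(12, intron_class = "U12", motif = "BPS")
  u2 <- random_pwm(12, intron_class = "U2", motif = "BPS")
  region <- rand_dna(51)
  b <- best_bps(fixture_intron(bps_region = region), u12, u2)
  o <- oracle_best_bps(region, u12, u2)
  expect_equal(b$position, o$position)
  expect_lte(b$position, 40L)  # 51-nt region has exactly 40 candidates
  expect_equal(b$log_ratio, o$log_ratio, tolerance = 1e-9)

  # planted motif in uniform background is found
  cfg <- simulation_config()
  pwm_u12 <- consensus_pwm(cfg$u12_consensus_bps, 0.95,
                           intron_class = "U12", motif = "BPS")
  pwm_u2 <- consensus_pwm("ACGTACGTACGT", 0.25, intron_class = "U2",
                          motif = "BPS")
  for (rep in 1:10) {
    region <- rand_dna(51)
    pos <- sample(40, 1)
    substr(region, pos, pos + 11) <- cfg$u12_consensus_bps
    b <- best_bps(fixture_intron(bps_region = region), pwm_u12, pwm_u2)
    expect_equal(b$position, pos)
  }

  # identical planted motifs: the 3'-most wins
  region <- paste0(cfg$u12_consensus_bps, strrep("G", 10),
                   cfg$u12_consensus_bps, strrep("G", 17))
  b <- best_bps(fixture_intron(bps_region = region), pwm_u12, pwm_u2)
  expect_equal(b$position, 23L)

  # region shorter than the motif yields NULL (too_short)
  expect_null(best_bps(fixture_intron(bps_region = "ACGTACGTACG"),
                       u12, u2))
})

test_that("best_bps equals the exhaustive-scan oracle on random regions", {
  set.seed(10)
  u12 <- random_pwm(12, intron_class = "U12", motif = "BPS")
  u2 <- random_pwm(12, intron_class = "U2", motif = "BPS")
  for (rep in 1:50) {
    region <- rand_dna(sample(12:60, 1))
    b <- best_bps(fixture_intron(bps_region = region), u12, u2)
    o <- oracle_best_bps(region, u12, u2)
    expect_equal(b$position, o$position)
    expect_equal(b$log_ratio, o$log_ratio, tolerance = 1e-9)
  }
})

test_that("empirical U2 BPS derivation filters at the 95th percentile", {
  set.seed(13)
  cfg <- simulation_config()
  u12_bps <- consensus_pwm(cfg$u12_consensus_bps, 0.95,
                           intron_class = "U12", motif = "BPS")
  n <- 200
  introns <- data.frame(
    seq_bps_region = vapply(1:n, function(i) rand_dna(51), character(1)),
    stringsAsFactors = FALSE)
  scores <- stats::rnorm(n)
  pwm <- derive_empirical_u2_bps(introns, scores, u12_bps)
  expect_s3_class(pwm, "pwm")
  expect_equal(pwm$intron_class, "U2")
  # quantile-then-filter oracle: which introns contributed
  cut <- stats::quantile(scores, 0.95, names = FALSE)
  contributed <- which(scores < cut)
  expect_equal(length(contributed), 190L)
  motifs <- vapply(contributed, function(i) {
    best <- NULL
    region <- introns$seq_bps_region[i]
    for (p in 1:40) {
      cand <- substr(region, p, p + 11)
      bases <- match(strsplit(cand, "")[[1]], c("A", "C", "G", "T"))
      s <- sum(log2(u12_bps$mat[cbind(bases, 1:12)] + u12_bps$pseudo_count))
      if (is.null(best) || s >= best$s - 1e-12) best <- list(s = s, m = cand)
    }
    best$m
  }, character(1))
  expect_equal(pwm$mat, build_pwm(motifs)$mat)

  # homogeneous scores: percentile equals the value, below-set empty
  expect_error(derive_empirical_u2_bps(introns, rep(1, n), u12_bps),
               "strictly below")
  expect_error(derive_empirical_u2_bps(introns[1:10, , drop = FALSE],
                                       scores[1:10], u12_bps), ">= 20")
})

test_that("empirical U2 BPS approaches uniform columns on random regions", {
  set.seed(14)
  cfg <- simulation_config()
  u12_bps <- consensus_pwm(cfg$u12_consensus_bps, 0.95,
                           intron_class = "U12", motif = "BPS")
  n <- 5000
  introns <- data.frame(
    seq_bps_region = vapply(1:n, function(i) rand_dna(51), character(1)),
    stringsAsFactors = FALSE)
  pwm <- derive_empirical_u2_bps(introns, stats::rnorm(n), u12_bps)
  # best-of-40 selection biases toward the scanned consensus, but each
  # column stays within 0.05-ish of the 0.25 background at this n except
  # for the strongly selected consensus base
  off_consensus <- function(j) {
    cons <- substr(cfg$u12_consensus_bps, j, j)
    pwm$mat[setdiff(rownames(pwm$mat), cons), j]
  }
  for (j in c(1, 6, 12)) {
    expect_true(all(off_consensus(j) > 0.05))
    expect_true(all(off_consensus(j) < 0.45))
  }
})

test_that("score_genome composes 5'SS scoring, the empirical matrix and best_bps", {
  set.seed(15)
  cfg <- simulation_config(seed = 100, n_genes = 30,
                           introns_per_gene = c(2, 3), u12_fraction = 0.1)
  sim <- simulate_genome(cfg)
  ann <- tempfile(fileext = ".gff3")
  writeLines(sim$gff, ann)
  txs <- parse_annotation(ann, "CDS")
  introns <- do.call(rbind, lapply(txs, extract_introns, sim$genome,
                                   assembly = cfg$assembly))
  rownames(introns) <- NULL
  pw <- simulate_pwm_set(cfg)
  scored <- score_genome(introns, pw)
  expect_equal(nrow(scored$scores), nrow(introns))  # nothing dropped
  truth <- sim$truth[match(scored$scores$intron_id, sim$truth$intron_id), ]
  u12 <- truth$class == "U12"
  expect_true(all(scored$scores$five_ss[u12] > 0))
  expect_true(all(scored$scores$bps[u12] > 0))
  expect_gt(min(scored$scores$five_ss[u12]),
            max(scored$scores$five_ss[!u12]))

  # single-intron composition oracle
  one <- introns[5, , drop = FALSE]
  manual_five <- score_five_prime(one, pw)
  manual_bps <- best_bps(one, pw$u12_bps, scored$u2_bps)
  i <- match(one$intron_id, scored$scores$intron_id)
  expect_equal(scored$scores$five_ss[i], manual_five)
  expect_equal(scored$scores$bps[i], manual_bps$log_ratio)
  expect_equal(scored$scores$bps_motif[i], manual_bps$motif_seq)

  # empty input
  empty <- score_genome(introns[0, ], pw)
  expect_equal(nrow(empty$scores), 0L)
})

test_that("antisymmetry: swapping U12 and U2 matrices negates every score", {
  set.seed(16)
  u12 <- random_pwm(12, intron_class = "U12")
  u2 <- random_pwm(12, intron_class = "U2")
  for (rep in 1:10) {
    s <- rand_dna(12)
    expect_equal(score_log_ratio(u2, u12, s), -score_log_ratio(u12, u2, s))
  }
  region <- rand_dna(51)
  scores <- vapply(1:40, function(i) {
    oracle_log_ratio(u12, u2, substr(region, i, i + 11))
  }, numeric(1))
  b <- best_bps(fixture_intron(bps_region = region), u2, u12)
  expect_equal(b$log_ratio, max(-scores), tolerance = 1e-9)
})

test_that("refine_bps_pwm recovers a planted branch-point consensus", {
  set.seed(17)
  cfg <- simulation_config()
  regions <- vapply(1:200, function(i) {
    r <- rand_dna(51)
    pos <- sample(40, 1)
    substr(r, pos, pos + 11) <- sample_motif_for_test(
      cfg$u12_consensus_bps, 0.9)
    r
  }, character(1))
  seed_pwm <- consensus_pwm(cfg$u12_consensus_bps, 0.6,
                            intron_class = "U12", motif = "BPS")
  refined <- refine_bps_pwm(regions, seed_pwm)
  cons <- strsplit(cfg$u12_consensus_bps, "")[[1]]
  recovered <- rownames(refined$mat)[apply(refined$mat, 2, which.max)]
  expect_gte(sum(recovered == cons), 10)
  expect_true(all(refined$mat["A", 9] > 0.5 | refined$mat["A", 10] > 0.5))
})
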