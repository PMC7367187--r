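#' 5' splice-site log-ratio score of one intron
#'
#' Scores the 12-nt window spanning -3..+9 around the first intron base with
#' the U12 and U2 5'SS matrices matching the intron's subtype (AT-AC termini
#' use AT-AC U12 matrices, GC-AG introns the GC-AG U2 matrix, everything
#' else GT-AG) and returns the binary log-ratio: positive = U12-like.
#'
#' @param intron one row of an intron table.
#' @param pwm_set list of [new_pwm()] objects.
#' @return numeric score in bits, or `NA` for `too_short` introns.
#' @export
score_five_prime <- function(intron, pwm_set) {
  if (isTRUE(intron$too_short) || is.na(intron$seq_5ss)) return(NA_real_)
  st <- subtype_of(intron$dnt_5, intron$dnt_3)
  u12 <- find_pwm(pwm_set, "U12", "5SS", st)
  u2 <- find_pwm(pwm_set, "U2", "5SS", st)
  score_log_ratio(u12, u2, intron$seq_5ss)
}

#' Best branch-point 12-mer of an intron
#'
#' Scores every 12-mer in the branch-point search region (-55..-5 from the
#' last intron base, truncated for short introns) as a U12/U2 log-ratio and
#' returns the highest-scoring one; ties are broken toward the 3'-most
#' (most branch-point-proximal) position.
#'
#' @param intron one row of an intron table (or any object with
#'   `seq_bps_region`).
#' @param u12_bps,u2_bps branch-point [new_pwm()] objects.
#' @return list with `log_ratio`, `motif_seq` and `position` (1-based start
#'   of the motif within the search region), or `NULL` when the region is
#'   shorter than 12 nt (`too_short`).
#' @export
best_bps <- function(intron, u12_bps, u2_bps) {
  region <- intron$seq_bps_region
  if (is.null(region) || is.na(region)) return(NULL)
  w <- ncol(u12_bps$mat)
  n <- nchar(region)
  if (n < w) return(NULL)
  pc <- u12_bps$pseudo_count
  logmat <- rbind(log2((u12_bps$mat + pc) / (u2_bps$mat + pc)), 0)  # N row
  scores <- scan_windows(region, logmat)
  i <- max(which(scores >= max(scores) - 1e-12))  # ties go 3'-most
  list(log_ratio = scores[i], motif_seq = substr(region, i, i + w - 1L),
       position = i)
}

# scores of every length-w window of `region` under a 5 x w contribution
# matrix (rows A, C, G, T, N)
scan_windows <- function(region, logmat) {
  idx <- seq_to_rows(region)
  w <- ncol(logmat)
  starts <- seq_len(length(idx) - w + 1L)
  scores <- numeric(length(starts))
  for (j in seq_len(w)) {
    scores <- scores + logmat[cbind(idx[starts + j - 1L], j)]
  }
  scores
}

# Highest-probability 12-mer under a single PWM (used before the empirical
# U2 BPS matrix exists); ties 3'-most.
best_bps_single <- function(region, pwm) {
  if (is.null(region) || is.na(region)) return(NULL)
  w <- ncol(pwm$mat)
  n <- nchar(region)
  if (n < w) return(NULL)
  pc <- pwm$pseudo_count
  logmat <- rbind(log2(pwm$mat + pc), log2(pc))  # N row: bare pseudo-count
  scores <- scan_windows(region, logmat)
  i <- max(which(scores >= max(scores) - 1e-12))
  list(log_prob = scores[i], motif_seq = substr(region, i, i + w - 1L),
       position = i)
}

#' Empirical species-specific U2 branch-point PWM
#'
#' U2-type introns carry no extended branch-point motif, so the U2 BPS
#' matrix is derived from the data: the 95th percentile of the 5'SS scores
#' is computed over the input set, every intron strictly below it (i.e.
#' introns unlikely to be U12-type) contributes its best U12-scored
#' branch-point 12-mer, and a PWM is built from those 12-mers. This makes
#' branch-point scoring conservative: the U2 matrix is defined by the most
#' U12-like motifs found in the background.
#'
#' @param introns intron table.
#' @param five_ss_scores numeric vector of 5'SS log-ratio scores, aligned
#'   with `introns` rows (`NA` for unscorable introns).
#' @param u12_bps the U12 branch-point [new_pwm()] (subtype-matched lookup
#'   happens in [score_genome()]; a single matrix is accepted here).
#' @param percentile filter quantile (default 0.95; linear-interpolation
#'   estimator).
#' @return a U2-class BPS [new_pwm()].
#' @export
derive_empirical_u2_bps <- function(introns, five_ss_scores, u12_bps,
                                    percentile = 0.95) {
  ok <- !is.na(five_ss_scores) & !is.na(introns$seq_bps_region)
  if (sum(ok) < 20L) {
    stop("derive_empirical_u2_bps: need >= 20 scored introns, got ",
         sum(ok))
  }
  cut <- stats::quantile(five_ss_scores[ok], percentile, names = FALSE,
                         type = 7)
  below <- ok & five_ss_scores < cut
  if (!any(below)) {
    stop("derive_empirical_u2_bps: no introns strictly below the ",
         percentile * 100, "th percentile (homogeneous scores?)")
  }
  motifs <- vapply(which(below), function(i) {
    best_bps_single(introns$seq_bps_region[i], u12_bps)$motif_seq
  }, character(1))
  build_pwm(motifs, offset = 1L, pseudo_count = u12_bps$pseudo_count,
            name = "u2_bps_empirical", intron_class = "U2", motif = "BPS",
            subtype = "GT-AG")
}

#' Score all introns of a genome
#'
#' Two-pass contract: pass 1 scores every intron's 5' splice site; the
#' empirical U2 branch-point matrix is then derived from the background
#' (see [derive_empirical_u2_bps()]); pass 2 scores every intron's best
#' branch-point 12-mer as a U12/U2 log-ratio against that matrix. Introns
#' flagged `too_short` are carried through with `NA` scores, never dropped.
#'
#' @param introns intron table from [extract_introns()]/[merge_runs()].
#' @param pwm_set list of [new_pwm()] objects containing U12 and U2 5'SS
#'   matrices and a U12 BPS matrix (per subtype where available).
#' @param percentile passed to [derive_empirical_u2_bps()].
#' @return list with `scores` (data.frame: intron_id, five_ss, bps,
#'   bps_motif, bps_position, too_short) and `u2_bps` (the empirical PWM).
#' @export
score_genome <- function(introns, pwm_set, percentile = 0.95) {
  if (nrow(introns) == 0L) {
    return(list(scores = data.frame(intron_id = character(),
                                    five_ss = numeric(), bps = numeric(),
                                    bps_motif = character(),
                                    bps_position = integer(),
                                    too_short = logical(),
                                    stringsAsFactors = FALSE),
                u2_bps = NULL))
  }
  five <- vapply(seq_len(nrow(introns)), function(i) {
    score_five_prime(introns[i, ], pwm_set)
  }, numeric(1))
  u12_bps <- find_pwm(pwm_set, "U12", "BPS", "GT-AG")
  u2_bps <- derive_empirical_u2_bps(introns, five, u12_bps,
                                    percentile = percentile)
  st <- subtype_of(introns$dnt_5, introns$dnt_3)
  bps <- rep(NA_real_, nrow(introns))
  bmotif <- rep(NA_character_, nrow(introns))
  bpos <- rep(NA_integer_, nrow(introns))
  for (i in seq_len(nrow(introns))) {
    if (is.na(five[i])) next
    u12_i <- find_pwm(pwm_set, "U12", "BPS", st[i])
    b <- best_bps(introns[i, ], u12_i, u2_bps)
    if (is.null(b)) next
    bps[i] <- b$log_ratio
    bmotif[i] <- b$motif_seq
    bpos[i] <- b$position
  }
  list(scores = data.frame(intron_id = introns$intron_id, five_ss = five,
                           bps = bps, bps_motif = bmotif,
                           bps_position = bpos,
                           too_short = introns$too_short,
                           stringsAsFactors = FALSE),
       u2_bps = u2_bps)
}

#' Score a labeled training set
#'
#' Computes (5'SS, BPS) log-ratio vectors for training sequences using the
#' same matrices and the same empirical U2 branch-point matrix as the
#' genome being classified, so training and genome scores share one scale.
#' Subtype dispatch reads the +1/+2 dinucleotide of each training 5'SS
#' window (positions 4-5 of the 12-mer).
#'
#' @param training data.frame with columns `class` (`"U2"`/`"U12"`),
#'   `five_ss` (12-nt windows) and `bps_region`.
#' @param pwm_set list of [new_pwm()] objects.
#' @param u2_bps empirical U2 BPS PWM from [score_genome()].
#' @return data.frame with `five_ss`, `bps` score columns and `label`.
#' @export
score_training_set <- function(training, pwm_set, u2_bps) {
  first2 <- substr(training$five_ss, 4L, 5L)
  st <- ifelse(first2 == "AT", "AT-AC",
               ifelse(first2 == "GC", "GC-AG", "GT-AG"))
  n <- nrow(training)
  five <- numeric(n); bps <- numeric(n)
  for (i in seq_len(n)) {
    u12_5 <- find_pwm(pwm_set, "U12", "5SS", st[i])
    u2_5 <- find_pwm(pwm_set, "U2", "5SS", st[i])
    five[i] <- score_log_ratio(u12_5, u2_5, training$five_ss[i])
    u12_b <- find_pwm(pwm_set, "U12", "BPS", st[i])
    b <- best_bps(list(seq_bps_region = training$bps_region[i]), u12_b,
                  u2_bps)
    bps[i] <- if (is.null(b)) NA_real_ else b$log_ratio
  }
  data.frame(five_ss = five, bps = bps, label = training$class,
             stringsAsFactors = FALSE)
}

#' Refine a U12 branch-point PWM from training regions
#'
#' Builds a U12 BPS matrix from branch-point regions by iterating: scan each
#' region for its best 12-mer under the current matrix, keep motifs with an
#' adenosine at position +9 or +10 (the branch-A constraint used when
#' assembling U12 branch-point training matrices), rebuild the matrix from
#' the kept motifs, repeat.
#'
#' @param regions character vector of branch-point region sequences.
#' @param seed_pwm starting [new_pwm()] (e.g. a [consensus_pwm()]).
#' @param anchor_a positions of the 12-mer where an A is required
#'   (default 9 and 10).
#' @param iterations scan/rebuild rounds.
#' @return a U12-class BPS [new_pwm()].
#' @export
refine_bps_pwm <- function(regions, seed_pwm, anchor_a = c(9L, 10L),
                           iterations = 2L) {
  pwm <- seed_pwm
  for (it in seq_len(iterations)) {
    motifs <- vapply(regions, function(r) {
      b <- best_bps_single(r, pwm)
      if (is.null(b)) NA_character_ else b$motif_seq
    }, character(1), USE.NAMES = FALSE)
    motifs <- motifs[!is.na(motifs)]
    keep <- vapply(motifs, function(m) {
      any(substring(m, anchor_a, anchor_a) == "A")
    }, logical(1))
    if (!any(keep)) {
      stop("refine_bps_pwm: no candidate motif satisfies the branch-A ",
           "constraint")
    }
    pwm <- build_pwm(motifs[keep], offset = 1L,
                     pseudo_count = seed_pwm$pseudo_count,
                     name = "u12_bps_refined", intron_class = "U12",
                     motif = "BPS", subtype = seed_pwm$subtype)
  }
  pwm
}
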