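#' Balanced accuracy
#'
#' Mean of sensitivity and specificity with U12 as the positive class; the
#' metric used for model selection because U2-type introns vastly outnumber
#' U12-type introns in any training set.
#'
#' @param truth,predicted equal-length label vectors over `{"U2","U12"}`.
#' @return numeric in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  if (length(truth) == 0L || length(truth) != length(predicted)) {
    stop("balanced_accuracy: need equal-length nonempty label vectors")
  }
  if (length(unique(truth)) < 2L) {
    stop("balanced_accuracy: truth contains a single class")
  }
  tp <- sum(truth == "U12" & predicted == "U12")
  fn <- sum(truth == "U12" & predicted != "U12")
  tn <- sum(truth == "U2" & predicted == "U2")
  fp <- sum(truth == "U2" & predicted != "U2")
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' F1 score
#'
#' Harmonic mean of precision and recall with U12 as the positive class.
#'
#' @inheritParams balanced_accuracy
#' @return numeric in `[0, 1]` (0 when no positive predictions or truths).
#' @export
f1_score <- function(truth, predicted) {
  tp <- sum(truth == "U12" & predicted == "U12")
  fp <- sum(truth != "U12" & predicted == "U12")
  fn <- sum(truth == "U12" & predicted != "U12")
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# stratified fold assignment preserving class ratios
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stop("stratified_folds: class ", cl, " has fewer members (",
             length(idx), ") than folds (", k, ")")
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# linear SVM on standardized features; returns weights on the standardized
# scale oriented so that U12 decisions are positive
fit_linear_svm <- function(x, y, C) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- scale(x, center = center, scale = scale)
  fit <- e1071::svm(x = xs, y = factor(y, levels = c("U2", "U12")),
                    kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  d <- drop(xs %*% w) + b
  if (mean(d[y == "U12"]) < mean(d[y == "U2"])) {
    w <- -w; b <- -b
  }
  list(weights = w, bias = b, center = center, scale = scale, C = C)
}

svm_decision <- function(model, x) {
  xs <- scale(as.matrix(x), center = model$center, scale = model$scale)
  drop(xs %*% model$weights) + model$bias
}

cv_balanced_accuracy <- function(x, y, C, fold_id) {
  bas <- c()
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    if (length(unique(y[!tr])) < 2L) next
    m <- fit_linear_svm(x[tr, , drop = FALSE], y[tr], C)
    pred <- ifelse(svm_decision(m, x[!tr, , drop = FALSE]) > 0, "U12", "U2")
    bas <- c(bas, balanced_accuracy(y[!tr], pred))
  }
  mean(bas)
}

#' Optimise the SVM penalty C by iterative cross-validation
#'
#' Round 1 evaluates a logarithmically spaced grid of C values by stratified
#' k-fold cross-validation on balanced accuracy; each subsequent round
#' re-grids between the grid neighbours of the best-performing C. After the
#' final round the arithmetic mean of the surviving range's endpoints is
#' returned. When several C values tie for best, the largest is taken as the
#' round's centre, preferring a more conservative (larger-C) margin.
#'
#' @param training data.frame with columns `five_ss`, `bps`, `label`.
#' @param folds cross-validation folds (default 5).
#' @param rounds grid-narrowing rounds (default 3).
#' @param seed RNG seed for fold assignment.
#' @param grid range of the initial grid (default `c(1e-3, 1e3)`).
#' @param points grid points per round (default 13).
#' @return the chosen C, with a `trace` attribute recording every
#'   (round, C, balanced accuracy) evaluated.
#' @export
optimize_C <- function(training, folds = 5L, rounds = 3L, seed = 42L,
                       grid = c(1e-3, 1e3), points = 13L) {
  x <- as.matrix(training[, c("five_ss", "bps")])
  y <- training$label
  lo <- grid[1]; hi <- grid[2]
  trace <- list()
  for (r in seq_len(rounds)) {
    cs <- 10^seq(log10(lo), log10(hi), length.out = points)
    fold_id <- stratified_folds(y, folds, seed + r)
    ba <- vapply(cs, function(C) cv_balanced_accuracy(x, y, C, fold_id),
                 numeric(1))
    trace[[r]] <- data.frame(round = r, C = cs, balanced_accuracy = ba)
    best <- max(which(ba >= max(ba) - 1e-12))  # ties -> largest C
    lo <- cs[max(best - 1L, 1L)]
    hi <- cs[min(best + 1L, points)]
  }
  out <- mean(c(lo, hi))
  attr(out, "trace") <- do.call(rbind, trace)
  out
}

# slope-only sigmoid calibration: p = plogis(a * d), a > 0 fitted by
# maximum likelihood on out-of-fold decision values. The missing intercept
# pins the class boundary (d = 0) to probability 0.5.
fit_calibration_slope <- function(decisions, labels, bounds = c(1e-4, 200)) {
  z <- ifelse(labels == "U12", 1, -1)
  nll <- function(a) -sum(stats::plogis(a * z * decisions, log.p = TRUE))
  stats::optimize(nll, interval = bounds)$minimum
}

#' Train the intron-class SVM
#'
#' Fits a maximal-margin linear separator with penalty `C` on standardized
#' (5'SS, BPS) score vectors, then fits a monotone sigmoid calibration on
#' out-of-fold decision values so that decision 0 maps to probability 0.5.
#'
#' @param training data.frame with columns `five_ss`, `bps`, `label`
#'   (`"U2"`/`"U12"`).
#' @param C penalty; when `NULL`, chosen by [optimize_C()].
#' @param seed RNG seed (fold assignment); recorded on the model.
#' @param folds,rounds passed to [optimize_C()] and used for calibration
#'   folds.
#' @return an object of class `intron_svm`.
#' @export
train_classifier <- function(training, C = NULL, seed = 42L, folds = 5L,
                             rounds = 3L) {
  y <- training$label
  if (length(unique(y)) < 2L) {
    stop("train_classifier: training data contains a single class")
  }
  x <- as.matrix(training[, c("five_ss", "bps")])
  if (is.null(C)) {
    C <- as.numeric(optimize_C(training, folds = folds, rounds = rounds,
                               seed = seed))
  }
  fit <- fit_linear_svm(x, y, C)
  # out-of-fold decision values for calibration
  fold_id <- stratified_folds(y, folds, seed + 1000L)
  oof <- numeric(length(y))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    m <- fit_linear_svm(x[tr, , drop = FALSE], y[tr], C)
    oof[!tr] <- svm_decision(m, x[!tr, , drop = FALSE])
  }
  slope <- fit_calibration_slope(oof, y)
  structure(list(weights = fit$weights, bias = fit$bias, C = C,
                 center = fit$center, scale = fit$scale,
                 calibration_slope = slope, seed = seed),
            class = "intron_svm")
}

#' @export
print.intron_svm <- function(x, ...) {
  cat(sprintf(paste0("linear intron-class SVM: w = (%.4f, %.4f), b = %.4f, ",
                     "C = %.4g, calibration slope = %.4g, seed = %d\n"),
              x$weights[1], x$weights[2], x$bias, x$C, x$calibration_slope,
              x$seed))
  invisible(x)
}

#' Assign intron class from score vectors
#'
#' Maps each (5'SS, BPS) score vector through the trained SVM and sigmoid
#' calibration to a probability of being U12-type, and calls `U12-type`
#' when that probability reaches the threshold (default 90%). Unscorable
#' (`too_short`) introns are carried through with `NA` probability and call.
#'
#' @param scores data.frame with `intron_id`, `five_ss`, `bps`.
#' @param model an `intron_svm` from [train_classifier()].
#' @param threshold probability threshold for a U12-type call
#'   (default 0.90).
#' @return data.frame `intron_id`, `five_ss`, `bps`, `p_u12`, `call`,
#'   ordered as the input.
#' @export
classify_introns <- function(scores, model, threshold = 0.90) {
  ok <- !is.na(scores$five_ss) & !is.na(scores$bps)
  p <- rep(NA_real_, nrow(scores))
  if (any(ok)) {
    d <- svm_decision(model, scores[ok, c("five_ss", "bps")])
    p[ok] <- stats::plogis(model$calibration_slope * d)
  }
  call <- ifelse(is.na(p), NA_character_,
                 ifelse(p >= threshold, "U12-type", "U2-type"))
  data.frame(intron_id = scores$intron_id, five_ss = scores$five_ss,
             bps = scores$bps, p_u12 = p, call = call,
             stringsAsFactors = FALSE)
}

#' Read and write classifier model files
#'
#' Versioned plain-text serialization of an `intron_svm` (weights, bias, C,
#' standardization, calibration slope, seed).
#'
#' @param model an `intron_svm`.
#' @param path file path.
#' @return `write_svm_model()` returns `path` invisibly;
#'   `read_svm_model()` returns the model.
#' @export
write_svm_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "introntype_svm\t1",
    paste0("weights\t", num(model$weights[1]), "\t", num(model$weights[2])),
    paste0("bias\t", num(model$bias)),
    paste0("C\t", num(model$C)),
    paste0("center\t", num(model$center[1]), "\t", num(model$center[2])),
    paste0("scale\t", num(model$scale[1]), "\t", num(model$scale[2])),
    paste0("calibration_slope\t", num(model$calibration_slope)),
    paste0("seed\t", model$seed))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  if (!identical(lines[[1]], c("introntype_svm", "1"))) {
    stop("not an introntype model file (or unsupported version): ", path)
  }
  kv <- stats::setNames(lapply(lines[-1], `[`, -1L),
                        vapply(lines[-1], `[`, "", 1L))
  nm <- c("five_ss", "bps")
  structure(list(
    weights = stats::setNames(as.numeric(kv$weights), nm),
    bias = as.numeric(kv$bias),
    C = as.numeric(kv$C),
    center = stats::setNames(as.numeric(kv$center), nm),
    scale = stats::setNames(as.numeric(kv$scale), nm),
    calibration_slope = as.numeric(kv$calibration_slope),
    seed = as.integer(kv$seed)), class = "intron_svm")
}
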