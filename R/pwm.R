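#' Position weight matrices for splice-site motifs
#'
#' A `pwm` object stores per-position base frequencies for a splice-site or
#' branch-point motif of one intron class (U2 or U12) and subtype (GT-AG,
#' GC-AG or AT-AC), together with the signed position label of its first
#' column and the pseudo-count frequency added at scoring time. Position
#' labels skip zero: +1 is the first intron base and -1 the last, so the
#' 12-column 5' splice-site matrix spans -3..+9 and branch-point matrices
#' span 12 columns.
#'
#' @param mat numeric matrix, 4 rows named A, C, G, T; columns are motif
#'   positions and each column sums to 1.
#' @param name identifier for the matrix.
#' @param intron_class `"U2"` or `"U12"`.
#' @param motif `"5SS"` or `"BPS"`.
#' @param subtype `"GT-AG"`, `"GC-AG"` or `"AT-AC"`.
#' @param offset signed position label of the first column (zero skipped).
#' @param pseudo_count frequency added to every cell at scoring time;
#'   default 0.001.
#' @return an object of class `pwm`.
#' @export
new_pwm <- function(mat, name, intron_class = c("U2", "U12"),
                    motif = c("5SS", "BPS"),
                    subtype = c("GT-AG", "GC-AG", "AT-AC"),
                    offset = 1L, pseudo_count = 0.001) {
  intron_class <- match.arg(intron_class)
  motif <- match.arg(motif)
  subtype <- match.arg(subtype)
  stopifnot(is.matrix(mat), nrow(mat) == 4L)
  if (!identical(rownames(mat), DNA_BASES)) {
    stop("PWM rows must be named A, C, G, T (in that order)")
  }
  sums <- colSums(mat)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("every PWM column must sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")")
  }
  structure(
    list(name = name, intron_class = intron_class, motif = motif,
         subtype = subtype, offset = as.integer(offset), mat = mat,
         pseudo_count = pseudo_count),
    class = "pwm"
  )
}

DNA_BASES <- c("A", "C", "G", "T")

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' [%s %s %s] %d columns, offset %+d, pseudo-count %g\n",
              x$name, x$intron_class, x$motif, x$subtype,
              ncol(x$mat), x$offset, x$pseudo_count))
  print(round(x$mat, 3))
  invisible(x)
}

#' Build a position weight matrix from aligned sequences
#'
#' Column frequencies are base counts divided by the column total; `N`
#' characters are excluded from both counts and totals. The pseudo-count is
#' recorded on the object and applied at scoring time, not folded into the
#' frequencies.
#'
#' @param sequences character vector of equal-length sequences over
#'   `A,C,G,T,N`.
#' @param offset signed position label of the first column.
#' @param pseudo_count scoring-time pseudo-count frequency.
#' @inheritParams new_pwm
#' @return a [new_pwm()] object.
#' @export
build_pwm <- function(sequences, offset = 1L, pseudo_count = 0.001,
                      name = "pwm", intron_class = "U2", motif = "5SS",
                      subtype = "GT-AG") {
  if (length(sequences) == 0L) stop("build_pwm: no input sequences")
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L) {
    stop("build_pwm: sequences have unequal lengths: ",
         paste(lens, collapse = ", "))
  }
  chars <- matrix(unlist(strsplit(toupper(sequences), "", fixed = TRUE)),
                  nrow = length(sequences), byrow = TRUE)
  bad <- setdiff(unique(as.vector(chars)), c(DNA_BASES, "N"))
  if (length(bad)) stop("build_pwm: invalid characters: ",
                        paste(bad, collapse = ", "))
  mat <- vapply(seq_len(lens), function(j) {
    col <- chars[, j]
    col <- col[col != "N"]
    if (length(col) == 0L) return(rep(0.25, 4L))
    tab <- table(factor(col, levels = DNA_BASES))
    as.numeric(tab) / length(col)
  }, numeric(4L))
  rownames(mat) <- DNA_BASES
  new_pwm(mat, name = name, intron_class = intron_class, motif = motif,
          subtype = subtype, offset = offset, pseudo_count = pseudo_count)
}

#' Build a PWM around a consensus sequence
#'
#' Each column assigns probability `fidelity` to the consensus base and
#' `(1 - fidelity)/3` to the other three bases; used by the simulator to
#' materialise matrices consistent with its planted motifs.
#'
#' @param consensus motif consensus string.
#' @param fidelity probability mass on the consensus base per column.
#' @inheritParams new_pwm
#' @return a [new_pwm()] object.
#' @export
consensus_pwm <- function(consensus, fidelity = 0.95, offset = 1L,
                          name = consensus, intron_class = "U2",
                          motif = "5SS", subtype = "GT-AG",
                          pseudo_count = 0.001) {
  stopifnot(fidelity >= 0, fidelity <= 1)
  bases <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  stopifnot(all(bases %in% DNA_BASES))
  mat <- matrix((1 - fidelity) / 3, nrow = 4L, ncol = length(bases),
                dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(bases)) mat[bases[j], j] <- fidelity
  new_pwm(mat, name = name, intron_class = intron_class, motif = motif,
          subtype = subtype, offset = offset, pseudo_count = pseudo_count)
}

seq_to_rows <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], c(DNA_BASES, "N"))
}

#' U12/U2 binary log-ratio score of a motif
#'
#' Scores `seq` as `sum_i log2((u12[i, b_i] + pc) / (u2[i, b_i] + pc))` where
#' `pc` is the pseudo-count; an `N` at any position contributes
#' `log2(pc/pc) = 0`. Positive scores indicate U12-like motifs, negative
#' scores U2-like motifs.
#'
#' @param u12,u2 [new_pwm()] objects with equal column counts.
#' @param seq motif string whose length equals the column count.
#' @return log-ratio score in bits.
#' @export
score_log_ratio <- function(u12, u2, seq) {
  stopifnot(inherits(u12, "pwm"), inherits(u2, "pwm"))
  n <- ncol(u12$mat)
  if (ncol(u2$mat) != n) stop("score_log_ratio: PWM column counts differ")
  if (nchar(seq) != n) {
    stop("score_log_ratio: sequence length ", nchar(seq),
         " does not match PWM width ", n)
  }
  idx <- seq_to_rows(seq)
  if (anyNA(idx)) stop("score_log_ratio: invalid characters in sequence")
  pc <- u12$pseudo_count
  total <- 0
  for (j in seq_len(n)) {
    b <- idx[j]
    if (b == 5L) next  # N: pc/pc cancels
    total <- total + log2((u12$mat[b, j] + pc) / (u2$mat[b, j] + pc))
  }
  unname(total)
}

# log2 probability of a motif under one PWM (pseudo-count applied; N
# contributes log2(pc)). Used to rank candidate branch-point 12-mers when
# only the U12 matrix exists yet.
pwm_log_prob <- function(pwm, seq) {
  idx <- seq_to_rows(seq)
  pc <- pwm$pseudo_count
  total <- 0
  for (j in seq_along(idx)) {
    b <- idx[j]
    total <- total + if (b == 5L) log2(pc) else log2(pwm$mat[b, j] + pc)
  }
  unname(total)
}

#' Read and write PWM files
#'
#' Plain-text, tab-separated format: each matrix begins with a header line
#' `>name<TAB>class<TAB>motif<TAB>subtype<TAB>offset<TAB>pseudo_count`
#' followed by one line per position with the A, C, G, T frequencies.
#'
#' @param path file path.
#' @return `read_pwm_file()` returns a named list of [new_pwm()] objects;
#'   `write_pwm_file()` returns `path` invisibly.
#' @export
read_pwm_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no PWM headers ('>') found in ", path)
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    hdr <- strsplit(sub("^>", "", lines[heads[i]]), "\t", fixed = TRUE)[[1]]
    if (length(hdr) != 6L) {
      stop("malformed PWM header at line ", heads[i], " of ", path)
    }
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE),
                                  as.numeric))
    mat <- t(rows)
    rownames(mat) <- DNA_BASES
    out[[hdr[1]]] <- new_pwm(mat, name = hdr[1], intron_class = hdr[2],
                             motif = hdr[3], subtype = hdr[4],
                             offset = as.integer(hdr[5]),
                             pseudo_count = as.numeric(hdr[6]))
  }
  out
}

#' @param pwms a list of [new_pwm()] objects.
#' @rdname read_pwm_file
#' @export
write_pwm_file <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste(paste0(">", p$name), p$intron_class, p$motif, p$subtype,
                     p$offset, format(p$pseudo_count, digits = 15),
                     sep = "\t"), con)
    apply(p$mat, 2, function(col) {
      writeLines(paste(format(col, digits = 15), collapse = "\t"), con)
    })
  }
  invisible(path)
}

# Select the class/motif matrix for an intron's subtype, falling back to
# GT-AG matrices when no subtype-specific matrix is supplied. Dispatch rule:
# AT-AC termini use AT-AC U12 matrices; GC-AG introns use the GC-AG U2 5'SS
# matrix; everything else (including non-canonical termini) uses GT-AG.
find_pwm <- function(pwm_set, intron_class, motif, subtype = "GT-AG") {
  pick <- function(st) {
    for (p in pwm_set) {
      if (p$intron_class == intron_class && p$motif == motif &&
          p$subtype == st) return(p)
    }
    NULL
  }
  wanted <- subtype
  if (intron_class == "U12" && subtype == "GC-AG") wanted <- "GT-AG"
  if (intron_class == "U2" && subtype == "AT-AC") wanted <- "GT-AG"
  p <- pick(wanted)
  if (is.null(p) && wanted != "GT-AG") p <- pick("GT-AG")
  if (is.null(p)) {
    stop("no ", intron_class, " ", motif, " PWM (subtype ", subtype,
         " or GT-AG fallback) in the PWM set")
  }
  p
}

# Map terminal dinucleotides to the PWM subtype used for scoring.
subtype_of <- function(dnt5, dnt3) {
  ifelse(dnt5 == "AT" & dnt3 == "AC", "AT-AC",
         ifelse(dnt5 == "GC" & dnt3 == "AG", "GC-AG", "GT-AG"))
}
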