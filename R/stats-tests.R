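# Self-contained implementations of the hypothesis tests used throughout the
# pipeline. Exact small-sample branches enumerate the permutation null; large
# samples fall back on tie-corrected normal approximations with continuity
# correction. All p-values are two-sided unless stated otherwise.

# cache of exact null distributions for the tie-free rank tests, keyed by
# sample sizes; avoids re-enumerating C(n+m, n) labelings on repeated calls
.nullCache <- new.env(parent = emptyenv())

newTestResult <- function(statistic, df = NA_real_, p, method, n) {
  structure(
    list(statistic = unname(statistic), df = unname(df),
         p.value = max(0, min(1, unname(p))),
         sidedness = "two.sided", method = method, n = n),
    class = "ublTest")
}

#' @export
print.ublTest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, two-sided p = %.6g (n = %s)\n",
              x$method, x$statistic,
              if (is.na(x$df)) "NA" else format(x$df),
              x$p.value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' t tests: Welch two-sample, one-sample, and paired
#'
#' Implements the three t-test variants used by the pipeline. The Welch mode
#' uses the unequal-variance statistic with Welch-Satterthwaite degrees of
#' freedom; the paired mode reduces to a one-sample test on differences.
#' Degenerate zero-variance inputs follow a fixed convention: equal means give
#' p = 1, unequal means p = 0.
#'
#' @param x Numeric sample.
#' @param y Second sample (`welch_two_sample`, `paired`) or the scalar null
#'   mean `mu` (`one_sample`; default 0).
#' @param mode One of `"welch_two_sample"`, `"one_sample"`, `"paired"`.
#' @return A `ublTest` list: `statistic`, `df`, `p.value`, `sidedness`,
#'   `method`, `n`.
#' @export
#' @examples
#' tTest(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' tTest(c(0.5, 1.2, 0.8), 0, mode = "one_sample")
tTest <- function(x, y = 0,
                  mode = c("welch_two_sample", "one_sample", "paired")) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  if (anyNA(x)) x <- x[!is.na(x)]
  if (mode == "paired") {
    y <- as.numeric(y)
    if (length(x) != length(y))
      stopf("paired t test needs equal-length samples (%d vs %d)",
            length(x), length(y))
    ok <- !(is.na(x) | is.na(y))
    return(withMethodTag(tTest(x[ok] - y[ok], 0, mode = "one_sample"),
                         "paired t test"))
  }
  if (mode == "one_sample") {
    mu <- as.numeric(y)[1L]
    n <- length(x)
    if (n < 2L) stopf("one-sample t test needs at least 2 observations")
    se <- sqrt(var(x) / n)
    if (se == 0) {
      eq <- isTRUE(all.equal(mean(x), mu))
      return(newTestResult(if (eq) 0 else sign(mean(x) - mu) * Inf,
                           n - 1, if (eq) 1 else 0, "one-sample t test", n))
    }
    stat <- (mean(x) - mu) / se
    return(newTestResult(stat, n - 1, 2 * pt(-abs(stat), n - 1),
                         "one-sample t test", n))
  }
  y <- as.numeric(y)
  if (anyNA(y)) y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stopf("Welch test needs at least 2 observations per group (got %d, %d)",
          nx, ny)
  vx <- var(x); vy <- var(y)
  sepool <- vx / nx + vy / ny
  if (sepool == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(newTestResult(if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                         nx + ny - 2, if (eq) 1 else 0,
                         "Welch two-sample t test", c(nx, ny)))
  }
  stat <- (mean(x) - mean(y)) / sqrt(sepool)
  df <- sepool^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  newTestResult(stat, df, 2 * pt(-abs(stat), df),
                "Welch two-sample t test", c(nx, ny))
}

withMethodTag <- function(res, tag) { res$method <- tag; res }

# exact null distribution of the Mann-Whitney U statistic for tie-free data
# with group sizes n, m: table over all C(n+m, n) labelings
.exactUNull <- function(n, m) {
  key <- sprintf("U_%d_%d", n, m)
  if (!is.null(.nullCache[[key]])) return(.nullCache[[key]])
  N <- n + m
  idx <- combn(N, n)
  # ranks are 1..N (no ties); U = sum of x-ranks - n(n+1)/2
  u <- colSums(matrix(idx, nrow = n)) - n * (n + 1) / 2
  tab <- table(u) / ncol(idx)
  out <- list(values = as.numeric(names(tab)), probs = as.numeric(tab))
  .nullCache[[key]] <- out
  out
}

twoSidedFromNull <- function(values, probs, observed) {
  lower <- sum(probs[values <= observed + 1e-9])
  upper <- sum(probs[values >= observed - 1e-9])
  min(1, 2 * min(lower, upper))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided test of location difference between two independent samples.
#' For tie-free data with `n + m <= exactMax` the p-value is exact, from
#' enumeration of all `choose(n + m, n)` group labelings of the pooled ranks;
#' otherwise a tie-corrected normal approximation with continuity correction
#' is used.
#'
#' @param x,y Numeric samples.
#' @param exactMax Largest pooled size for the exact branch (default 16).
#' @return A `ublTest` list; `statistic` is U computed for `x`.
#' @export
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
mannWhitneyU <- function(x, y, exactMax = 16L) {
  x <- as.numeric(x); x <- x[!is.na(x)]
  y <- as.numeric(y); y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n < 1L || m < 1L) stopf("mannWhitneyU() needs non-empty samples")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  hasTies <- anyDuplicated(pooled) > 0L
  if (!hasTies && (n + m) <= exactMax) {
    null <- .exactUNull(n, m)
    # null is symmetric about nm/2
    p <- twoSidedFromNull(null$values, null$probs, u)
    return(newTestResult(u, NA_real_, p,
                         "Wilcoxon-Mann-Whitney (exact)", c(n, m)))
  }
  N <- n + m
  tieTab <- table(pooled)
  tieCorr <- sum(tieTab^3 - tieTab) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tieCorr)
  if (sigma2 <= 0) return(newTestResult(u, NA_real_, 1,
                                        "Wilcoxon-Mann-Whitney (approx)",
                                        c(n, m)))
  mu <- n * m / 2
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  if (u == mu) z <- 0
  newTestResult(u, NA_real_, 2 * pnorm(-abs(z)),
                "Wilcoxon-Mann-Whitney (approx)", c(n, m))
}

# exact null of the signed-rank statistic W+ for a given rank vector
# (ties allowed: enumeration is conditional on the observed |d| ranks);
# distribution built by convolution over the 2^n sign patterns
.signedRankNull <- function(ranks) {
  # work in half-rank units so midranks stay integral
  r2 <- as.integer(round(2 * ranks))
  key <- paste0("W_", paste(sort(r2), collapse = "_"))
  if (!is.null(.nullCache[[key]])) return(.nullCache[[key]])
  maxW <- sum(r2)
  probs <- numeric(maxW + 1L)  # index = W*2 + 1
  probs[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), probs[seq_len(maxW + 1L - r)])
    probs <- (probs + shifted) / 2
  }
  out <- list(values = (0:maxW) / 2, probs = probs)
  .nullCache[[key]] <- out
  out
}

#' Wilcoxon signed-rank test
#'
#' Two-sided one-sample test of symmetry about `mu`. Observations equal to
#' `mu` are dropped before ranking (Wilcoxon's original convention). With at
#' most `exactMax` remaining observations the p-value is exact, from the
#' distribution of the signed-rank sum over all `2^n` sign patterns of the
#' observed ranks (so midranks from ties are honoured); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param values Numeric sample.
#' @param mu Null centre (default 0).
#' @param exactMax Largest n for the exact branch (default 20).
#' @return A `ublTest` list; `statistic` is the positive-rank sum W+.
#' @export
#' @examples
#' wilcoxonSignedRank(c(1.2, 0.8, 2.1, 1.4, 0.6))  # exact p = 0.0625
wilcoxonSignedRank <- function(values, mu = 0, exactMax = 20L) {
  d <- as.numeric(values) - mu
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L)
    return(newTestResult(0, NA_real_, 1, "Wilcoxon signed-rank", 0L))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exactMax) {
    null <- .signedRankNull(r)
    p <- twoSidedFromNull(null$values, null$probs, w)
    return(newTestResult(w, NA_real_, p, "Wilcoxon signed-rank (exact)", n))
  }
  muW <- n * (n + 1) / 4
  tieTab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tieTab^3 - tieTab) / 48
  if (sigma2 <= 0)
    return(newTestResult(w, NA_real_, 1, "Wilcoxon signed-rank (approx)", n))
  z <- (w - muW - sign(w - muW) * 0.5) / sqrt(sigma2)
  if (w == muW) z <- 0
  newTestResult(w, NA_real_, 2 * pnorm(-abs(z)),
                "Wilcoxon signed-rank (approx)", n)
}
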