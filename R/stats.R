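# Statistical primitives of the comparison protocol.  The computations are
# delegated to the standard stats implementations; these wrappers pin down
# the conventions used throughout the package (difference orientation,
# zero-difference handling, exactness regime, capping) and give uniform
# return values.

#' Paired two-tailed t-test
#'
#' Tests the mean of the per-subject differences \code{d = y - x} against
#' zero: \eqn{t = \bar d / (s_d/\sqrt n)}, two-tailed p from Student's t
#' with n-1 degrees of freedom.
#'
#' Degenerate inputs: if all differences are identical, the test statistic
#' is undefined through the usual formula; a zero mean yields
#' \code{t = 0, p = 1} and a nonzero mean yields \code{p = 0} with a
#' warning (the difference is deterministic at the observed resolution).
#'
#' @param x,y paired numeric vectors (equal length, n >= 2).
#' @return list with \code{t}, \code{p}, \code{df}, \code{n},
#'   \code{mean_diff}, \code{sd_diff}.
#' @examples
#' pairedTTest(c(0, 0, 0), c(1, 2, 3))  # t = 2*sqrt(3), p ~= 0.0742
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values", call. = FALSE)
  d <- y - x
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) {
      return(list(t = 0, p = 1, df = n - 1L, n = n, mean_diff = 0, sd_diff = 0))
    }
    warning("all paired differences identical and nonzero; p set to 0", call. = FALSE)
    return(list(t = sign(m) * Inf, p = 0, df = n - 1L, n = n,
                mean_diff = m, sd_diff = 0))
  }
  ht <- stats::t.test(y, x, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       n = n, mean_diff = m, sd_diff = s)
}

#' Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped before ranking (Wilcoxon's original
#' treatment) and ties receive midranks.  The exact null distribution is
#' used for n <= 25 nonzero, tie-free differences; otherwise the normal
#' approximation with continuity correction.
#'
#' @param x,y paired numeric vectors.
#' @return list with \code{W} (sum of positive ranks), \code{p},
#'   \code{n_nonzero}, \code{exact} (logical).
#' @examples
#' wilcoxonSignedRank(rep(0, 6), 1:6)  # all-positive, exact p = 2/64
#' @export
wilcoxonSignedRank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)", call. = FALSE)
  d <- y - x
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero", call. = FALSE)
  n <- length(d)
  exact <- n <= 25L && !anyDuplicated(abs(d))
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE,
                       alternative = "two.sided")
  )
  list(W = unname(res$statistic), p = res$p.value, n_nonzero = n, exact = exact)
}

#' Shapiro-Wilk normality test
#'
#' Standard Shapiro-Wilk W and p-value (Royston's approximation), for
#' 3 <= n <= 5000.  Constant vectors are rejected with an error.
#'
#' @param values numeric vector.
#' @return list with \code{W}, \code{p}, \code{n}.
#' @export
shapiroWilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (stats::sd(values) == 0) stop("constant vector: normality test undefined", call. = FALSE)
  res <- stats::shapiro.test(values)
  list(W = unname(res$statistic), p = res$p.value, n = n)
}

#' Holm-Bonferroni step-down correction
#'
#' Orders the raw p-values ascending, multiplies the i-th smallest of m by
#' (m - i + 1), enforces monotonicity by running maxima, caps at 1 and
#' returns the corrected values in the original order.
#'
#' @param raw_ps numeric vector of p-values in [0, 1].
#' @return corrected p-values, same order as the input.
#' @examples
#' holmBonferroni(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holmBonferroni <- function(raw_ps) {
  if (!is.numeric(raw_ps) || anyNA(raw_ps) ||
      any(raw_ps < 0) || any(raw_ps > 1)) {
    stop("raw p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(raw_ps, method = "holm")
}

#' Cohen's d for paired designs
#'
#' Two denominator conventions are exposed: \code{"diff_sd"} standardizes
#' the mean difference by the SD of the per-subject differences;
#' \code{"pooled_sd"} standardizes by \eqn{\sqrt{(var(x)+var(y))/2}}.  The
#' convention must be stated when reporting paired effect sizes, since the
#' two can differ by an order of magnitude when x and y are highly
#' correlated.
#'
#' @param x,y paired numeric vectors.
#' @param mode denominator convention.
#' @return list with \code{d}, \code{mode}, \code{n}.
#' @export
cohensDPaired <- function(x, y, mode = c("pooled_sd", "diff_sd")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- y - x
  denom <- switch(mode,
    diff_sd = stats::sd(d),
    pooled_sd = sqrt((stats::var(x) + stats::var(y)) / 2)
  )
  if (!is.finite(denom) || denom == 0) {
    stop("zero denominator in Cohen's d (", mode, ")", call. = FALSE)
  }
  list(d = mean(d) / denom, mode = mode, n = n)
}
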