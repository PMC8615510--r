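# Group comparison statistics used across modules: ECDFs, two-sample
# Kolmogorov-Smirnov and Mann-Whitney U, thin wrappers over the stats
# package with the conventions fixed (U statistic, exact-p policy).

#' Empirical cumulative distribution function
#'
#' Right-continuous step function of a sample; F(max) = 1.
#'
#' @param values numeric vector (>= 1 finite value).
#' @return a \code{stats::ecdf} step function.
#' @export
ecdfStep <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1L) stop("at least one finite value is required")
  stats::ecdf(values)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |F_x - F_y| between the two sample ECDFs.  The p-value is the
#' exact small-sample computation when n*m < 10000 (and no ties are
#' present), and the asymptotic Kolmogorov distribution otherwise.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with D, p, and the method used.
#' @export
ksTwoSample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- length(x) * length(y) < 10000 && !any(duplicated(c(x, y)))
  res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(res$statistic), p = res$p.value,
       method = if (exact) "exact" else "asymptotic")
}

#' Two-sample Mann-Whitney U test
#'
#' Rank-sum U statistic with tie correction; the p-value is exact for
#' small samples without ties (both n and m below 50) and uses the
#' normal approximation with continuity correction otherwise.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return list with U, p, and the method used.
#' @export
mannWhitney <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- length(x) < 50 && length(y) < 50 && !any(duplicated(c(x, y)))
  res <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE))
  list(U = unname(res$statistic), p = res$p.value,
       method = if (exact) "exact" else "normal-approximation")
}
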