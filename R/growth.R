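# Logistic growth modelling of viability time courses and the 2D-vs-3D
# growth-rate comparison.

#' Logistic growth law
#'
#' N(t) = C0 * Cmax / (C0 + (Cmax - C0) * exp(-d * t)).  At t = 0 the
#' value is C0; for d > 0 and t -> Inf it approaches Cmax; at d = 0 the
#' population stays at C0.
#'
#' @param t time in days (vector).
#' @param C0 population-proportional value at t = 0 (> 0).
#' @param Cmax carrying capacity (> 0).
#' @param d growth rate in 1/day.
#' @return N(t), same length as t.
#' @export
logisticGrowth <- function(t, C0, Cmax, d) {
  if (C0 <= 0 || Cmax <= 0) stop("C0 and Cmax must be > 0")
  if (d == 0) return(rep(C0, length(t)))
  # exp underflow at large d*t correctly yields Cmax
  C0 * Cmax / (C0 + (Cmax - C0) * exp(-d * t))
}

seriesMeans <- function(series) {
  agg <- aggregate(value ~ time_days, series, mean)
  agg[order(agg$time_days), ]
}

validateSeries <- function(series) {
  need <- c("time_days", "value")
  if (!all(need %in% names(series)))
    stop("series must have columns: ", paste(need, collapse = ", "))
  if (length(unique(series$time_days)) < 3L)
    stop("at least 3 distinct time points are required for fitting")
  if (any(!is.finite(series$time_days)) || any(!is.finite(series$value)))
    stop("times and values must be finite")
  invisible(series)
}

#' Fit the logistic growth model
#'
#' Nonlinear least squares over all replicate points (or per-time means),
#' with positivity of C0, Cmax and d enforced by log-parameterisation of
#' the smooth unconstrained objective.  A constant series makes d
#' unidentifiable: the fit short-circuits to d = 0 with a degenerate
#' flag and NA standard errors.
#'
#' @param series data.frame with columns time_days, value (replicate
#'   rows allowed).
#' @param init optional named list/vector with starting values C0, Cmax,
#'   d; defaults are the first time point's mean, the overall maximum,
#'   and 0.5 per day.
#' @param onMeans if TRUE fit the per-time means instead of all
#'   replicate points (default FALSE: joint fit).
#' @return a \code{\link{LogisticFit-class}} object.
#' @export
fitLogistic <- function(series, init = NULL, onMeans = FALSE) {
  validateSeries(series)
  if (onMeans) series <- seriesMeans(series)
  mu <- seriesMeans(series)
  if (diff(range(mu$value)) <= 1e-9 * max(abs(mu$value), 1e-12)) {
    lev <- max(mean(series$value), .Machine$double.eps)
    return(new("LogisticFit", C0 = lev, Cmax = lev, d = 0,
               rss = sum((series$value - lev)^2),
               se = c(C0 = NA_real_, Cmax = NA_real_, d = NA_real_),
               converged = TRUE, degenerate = TRUE,
               message = paste("constant series: d is unidentifiable and",
                               "reported as 0 with undefined uncertainty")))
  }
  # initialisation: logit-linearisation of the logistic law
  # log(N / (Cmax - N)) is linear in t with slope d
  cmax0 <- 1.05 * max(mu$value)
  logit <- log(pmax(mu$value, 1e-12) / pmax(cmax0 - mu$value, 1e-12))
  ll <- lm(logit ~ mu$time_days)
  d0 <- max(unname(coef(ll)[2L]), 1e-3)
  c00 <- cmax0 / (1 + exp(-unname(coef(ll)[1L])))
  starts <- list(list(
    lC0 = log(max(if (!is.null(init)) init[["C0"]] else c00,
                  .Machine$double.eps)),
    lCmax = log(max(if (!is.null(init)) init[["Cmax"]] else cmax0,
                    .Machine$double.eps)),
    ld = log(max(if (!is.null(init)) init[["d"]] else d0, 1e-8))))
  # fallback heuristic starts in case the linearised start fails
  for (dTry in c(0.5, 0.1, 2))
    starts[[length(starts) + 1L]] <-
      list(lC0 = log(max(mu$value[1L], .Machine$double.eps)),
           lCmax = log(max(series$value)), ld = log(dTry))
  model <- function(p)
    exp(p[1L]) * exp(p[2L]) /
      (exp(p[1L]) + (exp(p[2L]) - exp(p[1L])) *
         exp(-exp(p[3L]) * series$time_days))
  residFun <- function(p) series$value - model(p)
  best <- NULL
  for (start in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = unlist(start), fn = residFun,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(out) || !(out$info %in% 1:4)) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best)) {
    lev <- max(mu$value[1L], .Machine$double.eps)
    return(new("LogisticFit", C0 = lev, Cmax = max(series$value),
               d = 0, rss = NA_real_,
               se = c(C0 = NA_real_, Cmax = NA_real_, d = NA_real_),
               converged = FALSE, degenerate = FALSE,
               message = "fit failed: no start converged"))
  }
  est <- c(C0 = unname(exp(best$par[1L])),
           Cmax = unname(exp(best$par[2L])),
           d = unname(exp(best$par[3L])))
  se <- tryCatch({
    dof <- max(nrow(series) - 3L, 1L)
    covLog <- best$deviance / dof * solve(best$hessian / 2)
    s <- sqrt(pmax(diag(covLog), 0))
    # delta method through the exp transform
    c(C0 = est[["C0"]] * s[1L], Cmax = est[["Cmax"]] * s[2L],
      d = est[["d"]] * s[3L])
  }, error = function(e) c(C0 = NA_real_, Cmax = NA_real_, d = NA_real_))
  new("LogisticFit", C0 = est[["C0"]], Cmax = est[["Cmax"]], d = est[["d"]],
      rss = best$deviance, se = se, converged = TRUE,
      degenerate = FALSE, message = "converged")
}

#' Ordinary linear fit of a viability series
#'
#' Least squares of value on time; the near-surface cell subpopulation of
#' a 3D construct grows linearly rather than logistically, and this fit
#' quantifies that regime.
#'
#' @param series data.frame with columns time_days, value (>= 2 distinct
#'   time points).
#' @return list with slope (units/day), intercept, r.squared.
#' @export
fitLinearGrowth <- function(series) {
  if (length(unique(series$time_days)) < 2L)
    stop("at least 2 distinct time points are required")
  m <- lm(value ~ time_days, data = series)
  s <- suppressWarnings(summary(m))  # exact fits are legitimate here
  list(slope = unname(coef(m)["time_days"]),
       intercept = unname(coef(m)["(Intercept)"]),
       r.squared = s$r.squared)
}

#' Compare 2D and 3D growth fits
#'
#' Growth-rate ratio d_2D / d_3D, plus per-time-point Mann-Whitney tests
#' of the replicate viability values when the raw series are supplied.
#'
#' @param fit2d,fit3d converged \code{\link{LogisticFit-class}} objects.
#' @param series2d,series3d optional replicate-level series for the
#'   per-time-point tests.
#' @return list with dRatio and (optionally) perTime, a data.frame of
#'   time_days, U, p.
#' @export
compareGrowth <- function(fit2d, fit3d, series2d = NULL, series3d = NULL) {
  if (!fit2d@converged || !fit3d@converged)
    stop("both fits must have converged")
  out <- list(dRatio = fit2d@d / fit3d@d,
              d2d = fit2d@d, d3d = fit3d@d)
  if (!is.null(series2d) && !is.null(series3d)) {
    times <- sort(intersect(unique(series2d$time_days),
                            unique(series3d$time_days)))
    out$perTime <- do.call(rbind, lapply(times, function(tt) {
      mw <- mannWhitney(series2d$value[series2d$time_days == tt],
                        series3d$value[series3d$time_days == tt])
      data.frame(time_days = tt, U = mw$U, p = mw$p)
    }))
  }
  out
}
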