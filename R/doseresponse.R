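# Dose-response pharmacodynamics: absorbance-to-dead-fraction conversion
# with error propagation, the weighted Hill fit on the log10-dose axis,
# IC50 extraction and the 2D/3D resistance report.

#' Dead fraction from absorbances with error propagation
#'
#' E = (1 - A/A0) * 100 percent, with the uncertainty propagated as
#' sigmaE = (100 / A0) * sigmaA.  Values above the control (E < 0,
#' growth) are reported unclipped and flagged.
#'
#' @param A mean absorbance of the treated group (>= 0).
#' @param A0 mean absorbance of the matching control (> 0).
#' @param sigmaA standard deviation of the treated group's absorbance.
#' @return list with E (percent), sigmaE (percent), negative (flag).
#' @export
deadFraction <- function(A, A0, sigmaA = 0) {
  if (any(A0 <= 0)) stop("control absorbance A0 must be > 0")
  if (any(A < 0)) stop("absorbance must be >= 0")
  E <- (1 - A / A0) * 100
  list(E = E, sigmaE = (100 / A0) * sigmaA, negative = E < 0)
}

#' Hill sigmoid on the log10-dose axis
#'
#' E(dose) = Emax / (1 + 10^((EC50 - dose) * h)), with dose and EC50 both
#' in log10 micrograms per millilitre.  At dose = EC50 the effect is
#' Emax/2; for h > 0 it increases monotonically to the Emax asymptote.
#'
#' @param doseLog10 dose on the log10 ug/mL scale.
#' @param Emax maximum effect in percent.
#' @param EC50 half-maximal effective concentration, log10 ug/mL.
#' @param h Hill coefficient.
#' @return effect in percent.
#' @export
hillCurve <- function(doseLog10, Emax, EC50, h) {
  Emax / (1 + 10^((EC50 - doseLog10) * h))
}

validateDoseTable <- function(table) {
  need <- c("dose_ug_ml", "E_mean")
  if (!all(need %in% names(table)))
    stop("dose-response table must have columns: ",
         paste(need, collapse = ", "))
  if (any(table$dose_ug_ml < 0)) stop("doses must be >= 0")
  if (any(!is.finite(table$E_mean))) stop("effects must be finite")
  invisible(table)
}

#' Fit the Hill dose-response model
#'
#' Weighted nonlinear least squares on log10-transformed doses with the
#' inverse error (1/sigmaE) as the weight.  Weights are capped at their
#' 95th percentile so near-zero-sigma points cannot dominate; when all
#' sigmaE are zero or missing, unit weights are used with a warning.
#' The zero-dose control cannot be log-transformed and is anchored at a
#' pseudo-dose two decades below the smallest nonzero dose with its
#' weight multiplied (default x10), reflecting that the data are
#' normalised to the control.  By default the fit is constrained to
#' 0 < Emax <= 100 and h > 0 for robustness; set
#' \code{constrain = FALSE} for the fully unconstrained fit.
#'
#' @param table data.frame with columns dose_ug_ml, E_mean and optionally
#'   E_sd, n; one zero-dose control row expected.
#' @param constrain constrain Emax to (0, 100] and h > 0 (default TRUE).
#' @param controlWeightMult weight multiplier of the control anchor.
#' @param anchorDecades decades below the minimum nonzero dose at which
#'   the control anchor is placed.
#' @param weightCapQuantile quantile at which 1/sigmaE weights are
#'   capped.
#' @param start optional named starting values (Emax, EC50, h).
#' @return a \code{\link{HillFit-class}} object; IC50 is extracted via
#'   \code{\link{ic50}} against the tested dose range.
#' @export
fitHill <- function(table, constrain = TRUE, controlWeightMult = 10,
                    anchorDecades = 2, weightCapQuantile = 0.95,
                    start = NULL) {
  validateDoseTable(table)
  nz <- table[table$dose_ug_ml > 0, ]
  if (length(unique(nz$dose_ug_ml)) < 4L)
    stop("at least 4 distinct nonzero doses are required")
  ctrl <- table[table$dose_ug_ml == 0, ]
  x <- log10(nz$dose_ug_ml)
  y <- nz$E_mean
  sdE <- if ("E_sd" %in% names(nz)) nz$E_sd else rep(0, nrow(nz))
  sdE[is.na(sdE)] <- 0
  doseRange <- range(nz$dose_ug_ml)

  if (all(sdE == 0)) {
    warning("all sigma_E are zero or missing; using unit weights")
    w <- rep(1, length(y))
  } else {
    w <- 1 / pmax(sdE, .Machine$double.eps)
    cap <- quantile(w[sdE > 0], weightCapQuantile, names = FALSE)
    w <- pmin(w, cap)
  }
  if (nrow(ctrl)) {
    x <- c(log10(min(nz$dose_ug_ml)) - anchorDecades, x)
    y <- c(0, y)
    w <- c(controlWeightMult * max(w), w)
  }
  dat <- data.frame(x = x, y = y)

  # effectively-null table: Emax at the zero boundary, IC50 not reached
  if (all(abs(y) < 1e-9)) {
    return(new("HillFit", Emax = 0, EC50 = mean(x), h = 1,
               EC50Linear = 10^mean(x), IC50 = NA_real_,
               IC50Reached = FALSE, rss = 0,
               se = c(Emax = NA_real_, EC50 = NA_real_, h = NA_real_),
               converged = TRUE, constrained = constrain,
               doseRange = doseRange,
               message = "null effect: Emax at the 0 boundary"))
  }

  if (is.null(start)) {
    eTop <- max(y)
    start <- list(Emax = if (constrain) min(max(eTop, 1), 100) else
      max(eTop, 1),
      EC50 = x[which.min(abs(y - max(y) / 2))], h = 1)
  }
  lower <- if (constrain) c(Emax = 1e-6, EC50 = -Inf, h = 1e-6) else
    c(Emax = -Inf, EC50 = -Inf, h = -Inf)
  upper <- if (constrain) c(Emax = 100, EC50 = Inf, h = Inf) else
    c(Emax = Inf, EC50 = Inf, h = Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Emax / (1 + 10^((EC50 - x) * h)), data = dat,
                      start = start, weights = w,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-12, ptol = 1e-12, maxiter = 1000)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new("HillFit", Emax = start$Emax, EC50 = start$EC50,
               h = start$h, EC50Linear = 10^start$EC50, IC50 = NA_real_,
               IC50Reached = FALSE, rss = NA_real_,
               se = c(Emax = NA_real_, EC50 = NA_real_, h = NA_real_),
               converged = FALSE, constrained = constrain,
               doseRange = doseRange,
               message = paste("fit failed:", conditionMessage(fit))))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))),
                 error = function(e)
                   c(Emax = NA_real_, EC50 = NA_real_, h = NA_real_))
  out <- new("HillFit", Emax = unname(cf["Emax"]),
             EC50 = unname(cf["EC50"]), h = unname(cf["h"]),
             EC50Linear = 10^unname(cf["EC50"]), IC50 = NA_real_,
             IC50Reached = FALSE, rss = sum(w * residuals(fit)^2),
             se = se, converged = TRUE, constrained = constrain,
             doseRange = doseRange, message = "converged")
   icRes <- tryCatch(ic50(out), error = function(e) list(ic50 = NA_real_,
                                                        reached = FALSE))
  out@IC50 <- icRes$ic50
  out@IC50Reached <- icRes$reached
  validObject(out)
  out
}

#' Half-maximal inhibitory concentration from a Hill fit
#'
#' Inverts the fitted curve at 50% cell death:
#' dose_log10 = EC50 - log10(Emax/50 - 1) / h, defined only when
#' Emax > 50.  The IC50 is "not reached" when the asymptote stays at or
#' below 50% or the crossing lies above the tested dose range.
#'
#' @param fit a converged \code{\link{HillFit-class}}.
#' @param doseRange tested dose range in ug/mL (default the fit's own).
#' @return list with ic50 (ug/mL, NA when not reached) and reached
#'   (logical).
#' @export
ic50 <- function(fit, doseRange = fit@doseRange) {
  if (!fit@converged) stop("fit has not converged")
  if (fit@h == 0) stop("flat curve (h = 0): IC50 undefined")
  if (fit@Emax <= 50)
    return(list(ic50 = NA_real_, reached = FALSE))
  doseLog <- fit@EC50 - log10(fit@Emax / 50 - 1) / fit@h
  doseLin <- 10^doseLog
  if (length(doseRange) == 2L && is.finite(doseRange[2]) &&
      doseLin > doseRange[2])
    return(list(ic50 = NA_real_, reached = FALSE))
  list(ic50 = doseLin, reached = TRUE)
}

#' Resistance report across culture formats and formulations
#'
#' Ratios of linear-scale EC50 (3D over 2D) per formulation, plus
#' per-dose Mann-Whitney comparisons of replicate dead fractions when
#' replicate-level tables are supplied.
#'
#' @param fits named list of converged \code{\link{HillFit-class}}
#'   objects; names combine culture and formulation as
#'   "2D_free", "3D_free", "2D_nano", "3D_nano" (any subset with at
#'   least one complete 2D/3D pair).
#' @param replicates optional named list (same names) of replicate
#'   tables with columns dose_ug_ml, E.
#' @return list with \code{ratios} (data.frame formulation,
#'   EC50_2D_ug_ml, EC50_3D_ug_ml, ratio) and optionally \code{perDose}
#'   (formulation, dose_ug_ml, U, p).  Missing groups yield a partial
#'   report with a warning.
#' @export
resistanceReport <- function(fits, replicates = NULL) {
  if (length(fits) < 2L) stop("at least 2 converged fits are required")
  forms <- unique(sub("^(2D|3D)_", "", names(fits)))
  ratios <- list(); perDose <- list()
  for (f in forms) {
    k2 <- paste0("2D_", f); k3 <- paste0("3D_", f)
    if (!(k2 %in% names(fits)) || !(k3 %in% names(fits))) {
      warning("missing group for formulation '", f,
              "'; partial report")
      next
    }
    if (!fits[[k2]]@converged || !fits[[k3]]@converged)
      stop("fits must have converged")
    ratios[[f]] <- data.frame(
      formulation = f,
      EC50_2D_ug_ml = fits[[k2]]@EC50Linear,
      EC50_3D_ug_ml = fits[[k3]]@EC50Linear,
      ratio = fits[[k3]]@EC50Linear / fits[[k2]]@EC50Linear)
    if (!is.null(replicates) && k2 %in% names(replicates) &&
        k3 %in% names(replicates)) {
      r2 <- replicates[[k2]]; r3 <- replicates[[k3]]
      doses <- sort(intersect(unique(r2$dose_ug_ml),
                              unique(r3$dose_ug_ml)))
      doses <- doses[doses > 0]
      perDose[[f]] <- do.call(rbind, lapply(doses, function(dd) {
        mw <- mannWhitney(r2$E[r2$dose_ug_ml == dd],
                          r3$E[r3$dose_ug_ml == dd])
        data.frame(formulation = f, dose_ug_ml = dd, U = mw$U, p = mw$p)
      }))
    }
  }
  if (!length(ratios)) stop("no complete 2D/3D pair found")
  out <- list(ratios = do.call(rbind, ratios))
  rownames(out$ratios) <- NULL
  if (length(perDose)) out$perDose <- do.call(rbind, perDose)
  out
}
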