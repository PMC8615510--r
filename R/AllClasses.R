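#' @import methods
NULL

#' Stain separation of an RGB micrograph
#'
#' Result of colour deconvolution: three same-shaped scalar channels in
#' optical-density units (cell stain, matrix stain, residual/background),
#' together with the 3x3 stain matrix used, the root-mean-square
#' reconstruction residual and the total negative-concentration mass that
#' was clipped to zero.
#'
#' @slot cells matrix, optical density attributed to the cell stain.
#' @slot matrixChannel matrix, optical density attributed to the matrix stain.
#' @slot background matrix, residual third channel.
#' @slot stainMatrix 3x3 numeric matrix; rows are unit OD stain vectors.
#' @slot residualNorm numeric(1), RMS of the remix residual in OD units.
#' @slot clippedMass numeric(1), summed negative mass clipped to zero.
#' @exportClass StainSeparation
setClass("StainSeparation",
  representation(cells = "matrix", matrixChannel = "matrix",
                 background = "matrix", stainMatrix = "matrix",
                 residualNorm = "numeric", clippedMass = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@cells) == dim(object@matrixChannel)) ||
        !all(dim(object@cells) == dim(object@background)))
      msg <- c(msg, "channels must share dimensions")
    if (!all(dim(object@stainMatrix) == c(3L, 3L)))
      msg <- c(msg, "stainMatrix must be 3x3")
    if (any(!is.finite(object@cells)) || any(object@cells < 0))
      msg <- c(msg, "cell channel must be finite and >= 0")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "StainSeparation", function(object) {
  cat("StainSeparation:", nrow(object@cells), "x", ncol(object@cells),
      "px\n  remix residual (RMS OD):",
      format(object@residualNorm, digits = 4),
      "\n  clipped negative mass:", format(object@clippedMass, digits = 4),
      "\n")
})

#' Centerline graph of a vascular network
#'
#' Pixel-resolution skeleton of a vessel image together with its graph
#' decomposition: nodes are skeleton pixels with a number of 8-connected
#' skeleton neighbours different from two (endpoints and junctions), edges
#' are the pixel chains connecting them.  Edge lengths use the 8-connected
#' step metric (1 per axial step, sqrt(2) per diagonal step, plus one pixel
#' for the chain's own extent).
#'
#' @slot skeleton logical matrix marking skeleton pixels.
#' @slot nodes data.frame with columns id, row, col, degree, type
#'   ("endpoint" or "junction").
#' @slot edges data.frame with columns id, from, to, nPixels, lengthPx,
#'   lengthUm.
#' @slot chains list of 2-column (row, col) matrices, one pixel chain per edge.
#' @slot pixelSizeUm numeric(1), microns per pixel.
#' @slot provenance character, free-form description of the source image.
#' @exportClass VesselSkeleton
setClass("VesselSkeleton",
  representation(skeleton = "matrix", nodes = "data.frame",
                 edges = "data.frame", chains = "list",
                 pixelSizeUm = "numeric", provenance = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
      msg <- c(msg, "pixelSizeUm must be a single positive number")
    if (nrow(object@edges) != length(object@chains))
      msg <- c(msg, "one pixel chain per edge required")
    if (nrow(object@edges) > 0) {
      straight <- vapply(object@chains, function(ch) {
        if (nrow(ch) < 2L) 0 else
          sqrt(sum((ch[nrow(ch), ] - ch[1L, ])^2))
      }, numeric(1))
      if (any(object@edges$lengthPx + 1e-9 < straight))
        msg <- c(msg, "edge length must be >= endpoint distance")
    }
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "VesselSkeleton", function(object) {
  cat("VesselSkeleton:", sum(object@skeleton), "skeleton px,",
      nrow(object@edges), "segments,",
      junctionCount(object), "junctions\n",
      " total length:", format(totalLengthUm(object), digits = 6), "um\n")
})

#' Logistic growth fit
#'
#' Parameter estimates of the logistic growth law
#' N(t) = C0*Cmax / (C0 + (Cmax - C0) * exp(-d t)) fitted to a viability
#' time course by nonlinear least squares.
#'
#' @slot C0 numeric(1), viability-proportional population at t = 0.
#' @slot Cmax numeric(1), carrying capacity in the same units.
#' @slot d numeric(1), growth rate in 1/day.
#' @slot rss numeric(1), residual sum of squares.
#' @slot se named numeric, approximate standard errors (delta method from
#'   the log-parameterised fit); NA when unidentifiable.
#' @slot converged logical(1).
#' @slot degenerate logical(1), TRUE for a constant series where d is
#'   unidentifiable and reported as 0.
#' @slot message character, fitting diagnostics.
#' @exportClass LogisticFit
setClass("LogisticFit",
  representation(C0 = "numeric", Cmax = "numeric", d = "numeric",
                 rss = "numeric", se = "numeric", converged = "logical",
                 degenerate = "logical", message = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@C0 <= 0) msg <- c(msg, "C0 must be > 0")
    if (object@Cmax <= 0) msg <- c(msg, "Cmax must be > 0")
    if (object@d < 0) msg <- c(msg, "d must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "LogisticFit", function(object) {
  cat("LogisticFit: C0 =", format(object@C0, digits = 4),
      " Cmax =", format(object@Cmax, digits = 4),
      " d =", format(object@d, digits = 4), "1/day\n",
      " RSS =", format(object@rss, digits = 4),
      if (object@degenerate) " [degenerate: constant series]" else "",
      if (!object@converged) " [NOT CONVERGED]" else "", "\n")
})

#' @describeIn LogisticFit-class named coefficient vector (C0, Cmax, d).
#' @param object a \code{LogisticFit}.
#' @param ... ignored.
#' @export
setMethod("coef", "LogisticFit", function(object, ...)
  c(C0 = object@C0, Cmax = object@Cmax, d = object@d))

#' Hill dose-response fit
#'
#' Parameters of the sigmoid effect-dose law
#' E(dose) = Emax / (1 + 10^((EC50 - dose) * h)) with dose and EC50 on the
#' log10 microgram-per-millilitre axis, plus the linear-scale EC50 and the
#' IC50 (dose giving 50% cell death) when the curve reaches it.
#'
#' @slot Emax numeric(1), maximum effect in percent dead cells.
#' @slot EC50 numeric(1), log10 ug/mL.
#' @slot h numeric(1), Hill coefficient.
#' @slot EC50Linear numeric(1), 10^EC50 in ug/mL.
#' @slot IC50 numeric(1), ug/mL, NA when not reached.
#' @slot IC50Reached logical(1).
#' @slot rss numeric(1), weighted residual sum of squares.
#' @slot se named numeric, approximate standard errors.
#' @slot converged logical(1).
#' @slot constrained logical(1), TRUE when fitted under 0 < Emax <= 100,
#'   h > 0.
#' @slot doseRange numeric(2), min/max nonzero tested dose (ug/mL).
#' @slot message character.
#' @exportClass HillFit
setClass("HillFit",
  representation(Emax = "numeric", EC50 = "numeric", h = "numeric",
                 EC50Linear = "numeric", IC50 = "numeric",
                 IC50Reached = "logical", rss = "numeric", se = "numeric",
                 converged = "logical", constrained = "logical",
                 doseRange = "numeric", message = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@constrained &&
        (object@Emax < 0 || object@Emax > 100 + 1e-6))
      msg <- c(msg, "constrained Emax must lie in (0, 100]")
    if (!isTRUE(all.equal(object@EC50Linear, 10^object@EC50,
                          tolerance = 1e-8)))
      msg <- c(msg, "EC50Linear must equal 10^EC50")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "HillFit", function(object) {
  cat("HillFit: Emax =", format(object@Emax, digits = 4), "%",
      " EC50 =", format(object@EC50Linear, digits = 4), "ug/mL",
      " h =", format(object@h, digits = 4), "\n  IC50:",
      if (object@IC50Reached) paste(format(object@IC50, digits = 4), "ug/mL")
      else "not reached",
      if (!object@converged) " [NOT CONVERGED]" else "", "\n")
})

#' @describeIn HillFit-class named coefficient vector (Emax, EC50 in log10
#'   ug/mL, h).
#' @param object a \code{HillFit}.
#' @param ... ignored.
#' @export
setMethod("coef", "HillFit", function(object, ...)
  c(Emax = object@Emax, EC50 = object@EC50, h = object@h))

#' Total skeleton length in microns
#'
#' @param object a \code{VesselSkeleton}.
#' @return numeric(1), summed edge lengths in microns.
#' @export
setGeneric("totalLengthUm", function(object) standardGeneric("totalLengthUm"))

#' @rdname totalLengthUm
#' @export
setMethod("totalLengthUm", "VesselSkeleton", function(object)
  sum(object@edges$lengthUm))

#' Number of junctions of a skeleton
#'
#' Junction nodes (three or more skeleton neighbours) closer to each
#' other than a merge radius are counted once: a physical bifurcation has
#' the spatial extent of the vessel width and thinning can split it into
#' adjacent degree-3 pixels.
#'
#' @param object a \code{VesselSkeleton}.
#' @param mergeRadiusPx junction nodes within this distance collapse to
#'   one (default 3; 0 counts raw junction nodes).
#' @return integer(1), number of merged junctions.
#' @export
setGeneric("junctionCount", function(object, mergeRadiusPx = 3)
  standardGeneric("junctionCount"))

#' @rdname junctionCount
#' @export
setMethod("junctionCount", "VesselSkeleton",
          function(object, mergeRadiusPx = 3) {
  j <- object@nodes[object@nodes$type == "junction", , drop = FALSE]
  n <- nrow(j)
  if (n <= 1L || mergeRadiusPx <= 0) return(n)
  # single-linkage clustering at the merge radius
  dd <- as.matrix(dist(j[, c("row", "col")]))
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
      if (dd[i, k] <= mergeRadiusPx && lab[i] != lab[k]) {
        lab[lab == lab[k]] <- lab[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(lab))
})
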