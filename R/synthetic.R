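# Ground-truthed synthetic data: stained two-compartment sections populated
# by elliptical cells, branching dark-vessel trees on a bright membrane,
# logistic viability curves and sigmoid dose-response tables.  Every
# generator returns the rendered artifact together with the analytic truth
# used to render it, so downstream quantification can be validated without
# external data.

#' Default H&E-style stain matrix
#'
#' Rows are unit optical-density vectors for the cell stain (hematoxylin),
#' the matrix stain (eosin) and an orthogonal residual channel, following
#' the standard two-stain convention for H&E colour deconvolution.
#'
#' @return 3x3 numeric matrix with unit-norm rows.
#' @export
defaultStainMatrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  m <- rbind(cells = h / sqrt(sum(h^2)),
             matrix = e / sqrt(sum(e^2)),
             background = r / sqrt(sum(r^2)))
  colnames(m) <- c("R", "G", "B")
  m
}

checkStainMatrix <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)))
    stop("stain matrix must be 3x3")
  nrm <- sqrt(rowSums(m^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("stain vectors must be unit norm")
  for (i in 1:2) for (j in (i + 1):3) {
    if (abs(sum(m[i, ] * m[j, ])) > 1 - 1e-6)
      stop("stain vectors must be pairwise non-collinear")
  }
  invisible(m)
}

#' Specification of a synthetic stained section
#'
#' Describes a two-compartment H&E-like section populated by elliptical
#' cells of controlled convex-hull circularity.  The compartment layout is
#' a vertical split: label 1 (parenchymal) on the left, label 2 (stromal)
#' on the right, with an optional unstained background margin (label 0).
#'
#' @param rows,cols image size in pixels.
#' @param pixelSizeUm microns per pixel.
#' @param cellCount integer(2), cells per compartment
#'   (parenchymal, stromal).
#' @param axisRatio numeric(2), target ellipse major/minor axis ratio per
#'   compartment; 1 gives circles.
#' @param axisRatioSd lognormal spread of individual axis ratios around the
#'   target (s.d. of log ratio).
#' @param cellRadiusUm equivalent (equal-area) cell radius in microns.
#' @param stainMatrix 3x3 unit-row stain matrix
#'   (default \code{\link{defaultStainMatrix}}).
#' @param cellOD,matrixOD peak optical densities of the cell and matrix
#'   stains.
#' @param noiseSd additive Gaussian intensity noise s.d. (clipped to [0,1]).
#' @param marginPx width of the label-0 background border framing the
#'   section.
#' @param allowOverlap if TRUE, cells may touch/overlap (stress mode for
#'   segmentation splitting); default FALSE renders non-touching cells.
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return a validated list of class \code{SyntheticHistologySpec}.
#' @export
histologySpec <- function(rows = 256L, cols = 256L, pixelSizeUm = 1,
                          cellCount = c(parenchymal = 30L, stromal = 30L),
                          axisRatio = c(parenchymal = 1.1, stromal = 4),
                          axisRatioSd = 0.05, cellRadiusUm = 6,
                          stainMatrix = defaultStainMatrix(),
                          cellOD = 0.9, matrixOD = 0.25, noiseSd = 0.01,
                          marginPx = 8L, allowOverlap = FALSE, seed = 1L) {
  if (any(cellCount < 0)) stop("cell counts must be >= 0")
  if (pixelSizeUm <= 0) stop("pixel size must be > 0")
  if (noiseSd < 0) stop("noise s.d. must be >= 0")
  if (any(axisRatio < 1)) stop("axis ratios must be >= 1")
  checkStainMatrix(stainMatrix)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pixelSizeUm = pixelSizeUm,
                 cellCount = setNames(as.integer(cellCount),
                                      c("parenchymal", "stromal")),
                 axisRatio = setNames(as.numeric(axisRatio),
                                      c("parenchymal", "stromal")),
                 axisRatioSd = axisRatioSd, cellRadiusUm = cellRadiusUm,
                 stainMatrix = stainMatrix, cellOD = cellOD,
                 matrixOD = matrixOD, noiseSd = noiseSd,
                 marginPx = as.integer(marginPx),
                 allowOverlap = isTRUE(allowOverlap),
                 seed = as.integer(seed)),
            class = "SyntheticHistologySpec")
}

# Fractional pixel coverage of a rotated ellipse over a bounding box,
# 2x2 supersampled.
ellipseCoverage <- function(r0, c0, a, b, theta, rowIdx, colIdx) {
  cov <- matrix(0, length(rowIdx), length(colIdx))
  ct <- cos(theta); st <- sin(theta)
  for (dr in c(-0.25, 0.25)) for (dc in c(-0.25, 0.25)) {
    rr <- rowIdx + dr - r0
    cc <- colIdx + dc - c0
    # rotated coordinates
    u <- outer(rr * ct, rep(1, length(cc))) + outer(rep(1, length(rr)), cc * st)
    v <- outer(rr * -st, rep(1, length(cc))) + outer(rep(1, length(rr)), cc * ct)
    cov <- cov + ((u / a)^2 + (v / b)^2 <= 1)
  }
  cov / 4
}

#' Render a synthetic two-compartment stained section
#'
#' Cells are rendered as elliptical optical-density blobs in the cell-stain
#' colour, mixed with a textured matrix stain through the Beer-Lambert
#' model I = 10^(-OD), over a white background.  The returned truth lists
#' every cell with its analytic convex-hull circularity (the hull of an
#' ellipse is the ellipse itself) and compartment label.
#'
#' @param spec a \code{\link{histologySpec}}.
#' @param centers optional data.frame (row, col, compartment) fixing cell
#'   centres instead of random placement; one row per cell.
#' @param maxAttemptsPerCell rejection-sampling budget for non-touching
#'   placement before the generator gives up.
#' @return list with elements \code{image} (rows x cols x 3 array in
#'   [0,1]), \code{compartmentMask} (integer matrix, 0 = background,
#'   1 = parenchymal, 2 = stromal), \code{sectionMask} (logical),
#'   and \code{truth} (cell table, label image, analytic cell-area
#'   fraction, seed).
#' @export
synthHistology <- function(spec, centers = NULL, maxAttemptsPerCell = 500L) {
  stopifnot(inherits(spec, "SyntheticHistologySpec"))
  withSeed(spec$seed, {
    nr <- spec$rows; nc <- spec$cols; m <- spec$marginPx
    comp <- matrix(0L, nr, nc)
    inR <- (m + 1L):(nr - m); inC <- (m + 1L):(nc - m)
    split <- m + round((nc - 2 * m) / 2)
    comp[inR, inC[inC <= split]] <- 1L
    comp[inR, inC[inC > split]] <- 2L
    section <- comp > 0L

    # textured matrix stain density
    tex <- convolveSep(matrix(runif(nr * nc), nr, nc), gaussKernel1d(6))
    tex <- 0.7 + 0.3 * (tex - min(tex)) / max(diff(range(tex)), 1e-12)
    matrixDensity <- tex * section

    compNames <- c("parenchymal", "stromal")
    cells <- list(); id <- 0L
    placed <- matrix(numeric(0), 0, 5)  # row, col, aPx, bPx, theta
    # extent of an ellipse along the unit direction at angle phi
    supportRadius <- function(a, b, theta, phi)
      sqrt((a * cos(phi - theta))^2 + (b * sin(phi - theta))^2)
    rEq <- spec$cellRadiusUm / spec$pixelSizeUm
    for (k in 1:2) {
      nk <- if (is.null(centers)) spec$cellCount[k] else
        sum(centers$compartment == compNames[k])
      if (nk == 0L) next
      ratios <- pmax(1, exp(rnorm(nk, log(spec$axisRatio[k]),
                                  spec$axisRatioSd)))
      ctrs <- if (!is.null(centers))
        as.matrix(centers[centers$compartment == compNames[k],
                          c("row", "col")])
      else NULL
      for (i in seq_len(nk)) {
        a <- rEq * sqrt(ratios[i]); b <- rEq / sqrt(ratios[i])
        theta <- runif(1, 0, pi)
        if (!is.null(ctrs)) {
          r0 <- ctrs[i, 1]; c0 <- ctrs[i, 2]
        } else {
          ok <- FALSE
          for (att in seq_len(maxAttemptsPerCell)) {
            r0 <- runif(1, m + a + 1, nr - m - a - 1)
            cLo <- if (k == 1L) m + 1 else split + 1
            cHi <- if (k == 1L) split else nc - m
            c0 <- runif(1, max(cLo, a + 1), min(cHi, nc - a - 1))
            if (comp[round(r0), round(c0)] != k) next
            if (!spec$allowOverlap && nrow(placed) > 0) {
              dd <- sqrt((placed[, 1] - r0)^2 + (placed[, 2] - c0)^2)
              phi <- atan2(c0 - placed[, 2], r0 - placed[, 1])
              req <- supportRadius(placed[, 3], placed[, 4], placed[, 5],
                                   phi) +
                supportRadius(a, b, theta, phi) + 2
              if (any(dd < req)) next
            }
            ok <- TRUE; break
          }
          if (!ok)
            stop("could not place non-touching cells in the '",
                 compNames[k], "' compartment: too crowded")
        }
        id <- id + 1L
        placed <- rbind(placed, c(r0, c0, a, b, theta))
        cells[[id]] <- data.frame(
          id = id, compartment = compNames[k], row = r0, col = c0,
          aPx = a, bPx = b, thetaRad = theta,
          circularity = ellipseCircularity(a, b),
          areaUm2 = pi * a * b * spec$pixelSizeUm^2)
      }
    }
    cellTable <- if (id > 0L) do.call(rbind, cells) else
      data.frame(id = integer(0), compartment = character(0),
                 row = numeric(0), col = numeric(0), aPx = numeric(0),
                 bPx = numeric(0), thetaRad = numeric(0),
                 circularity = numeric(0), areaUm2 = numeric(0))

    cellDensity <- matrix(0, nr, nc)
    labelImage <- matrix(0L, nr, nc)
    for (i in seq_len(id)) {
      ci <- cellTable[i, ]
      rIdx <- max(1L, floor(ci$row - ci$aPx - 1)):min(nr, ceiling(ci$row + ci$aPx + 1))
      cIdx <- max(1L, floor(ci$col - ci$aPx - 1)):min(nc, ceiling(ci$col + ci$aPx + 1))
      cov <- ellipseCoverage(ci$row, ci$col, ci$aPx, ci$bPx, ci$thetaRad,
                             rIdx, cIdx)
      cellDensity[rIdx, cIdx] <- pmin(1, cellDensity[rIdx, cIdx] + cov)
      lab <- labelImage[rIdx, cIdx]
      lab[cov > 0.5] <- ci$id
      labelImage[rIdx, cIdx] <- lab
    }

    od1 <- cellDensity * spec$cellOD
    od2 <- matrixDensity * spec$matrixOD
    img <- array(0, c(nr, nc, 3))
    for (ch in 1:3)
      img[, , ch] <- 10^(-(od1 * spec$stainMatrix[1, ch] +
                           od2 * spec$stainMatrix[2, ch]))
    if (spec$noiseSd > 0)
      img <- img + array(rnorm(length(img), 0, spec$noiseSd), dim(img))
    img <- clip01(img)

    sectionArea <- sum(section)
    truth <- list(cells = cellTable, labelImage = labelImage,
                  cellMask = labelImage > 0L,
                  cellAreaFraction = if (sectionArea > 0)
                    sum(pi * cellTable$aPx * cellTable$bPx) / sectionArea
                  else 0,
                  seed = spec$seed)
    list(image = img, compartmentMask = comp, sectionMask = section,
         truth = truth)
  })
}

#' Specification of a synthetic vessel-tree image
#'
#' Describes a branching tree of dark curvilinear strokes on a bright
#' membrane-like background, emulating the appearance of CAM vasculature
#' in the green channel of a brightfield stereomicrograph.
#'
#' @param rows,cols image size in pixels.
#' @param pixelSizeUm microns per pixel.
#' @param nRoots number of tree roots entering from the image border.
#' @param branchProb probability of spawning a side branch per growth step.
#' @param stepUm mean advance per growth step, in microns.
#' @param maxSteps growth steps per branch before termination.
#' @param widthPx rendered vessel width in pixels (>= 1).
#' @param curvatureSd direction jitter per step (radians).
#' @param branchAngle mean angle between parent and child branch (radians).
#' @param fg,bg foreground (vessel) and background gray levels; vessels
#'   must be darker than the background (dark-line polarity).
#' @param noiseSd additive Gaussian intensity noise s.d.
#' @param maxBranches cap on the total number of branches.
#' @param seed integer RNG seed.
#' @return a validated list of class \code{SyntheticVesselSpec}.
#' @export
vesselSpec <- function(rows = 256L, cols = 256L, pixelSizeUm = 2,
                       nRoots = 2L, branchProb = 0.04, stepUm = 6,
                       maxSteps = 80L, widthPx = 3, curvatureSd = 0.05,
                       branchAngle = 0.7, fg = 0.25, bg = 0.9,
                       noiseSd = 0.01, maxBranches = 16L, seed = 1L) {
  if (widthPx < 1) stop("vessel width must be >= 1 px")
  if (fg >= bg) stop("vessels must be darker than the background")
  if (pixelSizeUm <= 0) stop("pixel size must be > 0")
  if (branchProb < 0 || branchProb > 1) stop("branchProb must be in [0,1]")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pixelSizeUm = pixelSizeUm, nRoots = as.integer(nRoots),
                 branchProb = branchProb, stepUm = stepUm,
                 maxSteps = as.integer(maxSteps), widthPx = widthPx,
                 curvatureSd = curvatureSd, branchAngle = branchAngle,
                 fg = fg, bg = bg, noiseSd = noiseSd,
                 maxBranches = as.integer(maxBranches),
                 seed = as.integer(seed)),
            class = "SyntheticVesselSpec")
}

# Count pairwise crossings between segments of a polyline set (used for the
# truth junction count of explicitly supplied polylines).
countCrossings <- function(polylines) {
  segs <- list()
  for (pi in seq_along(polylines)) {
    p <- polylines[[pi]]
    if (nrow(p) < 2L) next
    for (i in seq_len(nrow(p) - 1L))
      segs[[length(segs) + 1L]] <- c(p[i, ], p[i + 1L, ], pi, i)
  }
  cross <- 0L
  n <- length(segs)
  if (n < 2L) return(0L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- segs[[i]]; b <- segs[[j]]
    if (a[5] == b[5] && abs(a[6] - b[6]) <= 1) next  # adjacent in chain
    d1 <- c(a[3] - a[1], a[4] - a[2]); d2 <- c(b[3] - b[1], b[4] - b[2])
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) next
    t <- ((b[1] - a[1]) * d2[2] - (b[2] - a[2]) * d2[1]) / den
    u <- ((b[1] - a[1]) * d1[2] - (b[2] - a[2]) * d1[1]) / den
    if (t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9)
      cross <- cross + 1L
  }
  cross
}

#' Render a synthetic vascular tree image
#'
#' Grows a random branching tree of smooth polylines (or renders explicitly
#' supplied polylines) and paints them as dark anti-aliased strokes of
#' constant width on a bright background, strongest in contrast in the
#' green channel.  The truth records the centerline polylines, their total
#' arc length in microns and the junction count.
#'
#' @param spec a \code{\link{vesselSpec}}.
#' @param polylines optional list of 2-column (row, col) pixel-coordinate
#'   matrices to render instead of growing a random tree; truth junctions
#'   are then the pairwise polyline crossings.
#' @return list with \code{image} (rows x cols x 3 array) and \code{truth}
#'   (polylines, totalLengthUm, junctionCount, green plane, seed).
#' @export
synthVessels <- function(spec, polylines = NULL) {
  stopifnot(inherits(spec, "SyntheticVesselSpec"))
  withSeed(spec$seed, {
    nr <- spec$rows; nc <- spec$cols
    clipped <- FALSE
    junctions <- 0L
    if (is.null(polylines)) {
      stepPx <- spec$stepUm / spec$pixelSizeUm
      polylines <- list()
      tips <- list()
      for (r in seq_len(spec$nRoots)) {
        side <- sample(4L, 1L)
        pos <- switch(side,
                      c(2, runif(1, 2, nc - 1)),
                      c(nr - 1, runif(1, 2, nc - 1)),
                      c(runif(1, 2, nr - 1), 2),
                      c(runif(1, 2, nr - 1), nc - 1))
        dir <- atan2(nc / 2 - pos[2], nr / 2 - pos[1]) + rnorm(1, 0, 0.3)
        tips[[r]] <- list(pos = pos, dir = dir, steps = spec$maxSteps,
                          pts = matrix(pos, 1))
      }
      nBranches <- length(tips)
      while (length(tips) > 0L) {
        tip <- tips[[1L]]; tips[[1L]] <- NULL
        repeat {
          if (tip$steps <= 0L) break
          tip$dir <- tip$dir + rnorm(1, 0, spec$curvatureSd)
          nxt <- tip$pos + stepPx * c(cos(tip$dir), sin(tip$dir))
          if (nxt[1] < 1 || nxt[1] > nr || nxt[2] < 1 || nxt[2] > nc) {
            # clip the final step at the canvas border
            tt <- min(ifelse(abs(nxt[1] - tip$pos[1]) > 1e-12,
                             pmax((c(1, nr) - tip$pos[1]) /
                                  (nxt[1] - tip$pos[1]), 0), Inf),
                      ifelse(abs(nxt[2] - tip$pos[2]) > 1e-12,
                             pmax((c(1, nc) - tip$pos[2]) /
                                  (nxt[2] - tip$pos[2]), 0), Inf))
            tt <- suppressWarnings(min(tt[tt <= 1 & tt > 0], 1))
            if (is.finite(tt) && tt > 1e-6) {
              edge <- tip$pos + tt * (nxt - tip$pos)
              tip$pts <- rbind(tip$pts, edge)
            }
            clipped <- TRUE
            break
          }
          tip$pts <- rbind(tip$pts, nxt)
          tip$pos <- nxt
          tip$steps <- tip$steps - 1L
          if (runif(1) < spec$branchProb && nBranches < spec$maxBranches) {
            junctions <- junctions + 1L
            nBranches <- nBranches + 1L
            childDir <- tip$dir + sample(c(-1, 1), 1) *
              (spec$branchAngle + rnorm(1, 0, 0.1))
            tips[[length(tips) + 1L]] <-
              list(pos = nxt, dir = childDir,
                   steps = max(8L, round(tip$steps * 0.7)),
                   pts = matrix(nxt, 1))
          }
        }
        if (nrow(tip$pts) >= 2L)
          polylines[[length(polylines) + 1L]] <- unname(tip$pts)
      }
      if (clipped)
        warning("vessel tree clipped at the canvas border; ",
                "truth length recomputed on the clipped tree")
    } else {
      polylines <- lapply(polylines, function(p) {
        p <- as.matrix(p)
        if (any(p[, 1] < 1 | p[, 1] > nr | p[, 2] < 1 | p[, 2] > nc))
          warning("polyline clipped to canvas")
        p[, 1] <- pmin(pmax(p[, 1], 1), nr)
        p[, 2] <- pmin(pmax(p[, 2], 1), nc)
        p
      })
      junctions <- countCrossings(polylines)
    }

    totalLengthPx <- sum(vapply(polylines, polylineLength, numeric(1)))

    # rasterise centerlines, then paint constant-width anti-aliased tubes
    # using the distance to the nearest centerline pixel
    mask <- matrix(0, nr, nc)
    for (p in polylines) {
      if (nrow(p) < 2L) next
      for (i in seq_len(nrow(p) - 1L)) {
        len <- sqrt(sum((p[i + 1L, ] - p[i, ])^2))
        ns <- max(2L, ceiling(len / 0.25))
        tt <- seq(0, 1, length.out = ns)
        rr <- round(p[i, 1] + tt * (p[i + 1L, 1] - p[i, 1]))
        cc <- round(p[i, 2] + tt * (p[i + 1L, 2] - p[i, 2]))
        mask[cbind(pmin(pmax(rr, 1L), nr), pmin(pmax(cc, 1L), nc))] <- 1
      }
    }
    dist <- if (any(mask > 0)) EBImage::distmap(1 - mask) else
      matrix(Inf, nr, nc)
    alpha <- clip01(spec$widthPx / 2 + 0.5 - dist)
    green <- spec$bg - (spec$bg - spec$fg) * alpha
    red <- 0.92 - 0.2 * alpha
    blue <- 0.88 - 0.35 * alpha * (spec$bg - spec$fg)
    img <- array(0, c(nr, nc, 3))
    img[, , 1] <- red; img[, , 2] <- green; img[, , 3] <- blue
    if (spec$noiseSd > 0)
      img <- img + array(rnorm(length(img), 0, spec$noiseSd), dim(img))
    img <- clip01(img)

    truth <- list(polylines = polylines,
                  totalLengthPx = totalLengthPx,
                  totalLengthUm = totalLengthPx * spec$pixelSizeUm,
                  junctionCount = junctions,
                  green = img[, , 2],
                  clipped = clipped,
                  seed = spec$seed)
    list(image = img, truth = truth)
  })
}

#' Generate a synthetic viability time course
#'
#' Draws replicate MTT-style viability values from the logistic growth law
#' N(t) = C0*Cmax / (C0 + (Cmax - C0) e^(-d t)) plus i.i.d. Gaussian noise.
#'
#' @param C0 viability-proportional population at t = 0 (> 0).
#' @param Cmax carrying capacity (>= C0).
#' @param d growth rate in 1/day (>= 0); d = 0 gives the constant C0.
#' @param times time points in days (default the 28-day assay grid:
#'   days 1, 7, 14, 21, 28).
#' @param nReplicates replicates per time point.
#' @param noiseSd Gaussian noise s.d. in viability units.
#' @param seed integer RNG seed.
#' @param culture label attached to the series ("2D" or "3D").
#' @return list with \code{series} (data.frame time_days, value, replicate,
#'   culture) and \code{truth} (C0, Cmax, d, noiseSd, seed).
#' @export
synthViability <- function(C0, Cmax, d, times = c(1, 7, 14, 21, 28),
                           nReplicates = 6L, noiseSd = 0, seed = 1L,
                           culture = "2D") {
  if (C0 <= 0) stop("C0 must be > 0")
  if (Cmax < C0) stop("Cmax must be >= C0")
  if (d < 0) stop("d must be >= 0")
  if (noiseSd < 0) stop("noise s.d. must be >= 0")
  if (any(!is.finite(times))) stop("times must be finite")
  withSeed(seed, {
    grid <- expand.grid(replicate = seq_len(nReplicates), time_days = times)
    mu <- logisticGrowth(grid$time_days, C0, Cmax, d)
    val <- mu + if (noiseSd > 0) rnorm(nrow(grid), 0, noiseSd) else 0
    series <- data.frame(time_days = grid$time_days, value = val,
                         replicate = grid$replicate, culture = culture)
    list(series = series[order(series$time_days, series$replicate), ],
         truth = list(C0 = C0, Cmax = Cmax, d = d, noiseSd = noiseSd,
                      seed = seed))
  })
}

#' Generate a synthetic dose-response table
#'
#' Draws replicate dead-fraction values from the sigmoid law
#' E(dose) = Emax / (1 + 10^((EC50 - dose) h)) on the log10-dose axis,
#' plus Gaussian noise, and summarises them per dose as mean, s.d. and n.
#' The zero-dose control is generated at E = 0.
#'
#' @param Emax maximum effect in percent (0 < Emax <= 100).
#' @param EC50 half-maximal effective concentration on the log10 ug/mL
#'   scale.
#' @param h Hill coefficient.
#' @param doses dose grid in ug/mL; must include the zero-dose control
#'   (default the 0.1-10 ug/mL assay grid).
#' @param nReplicates replicates per dose.
#' @param noiseSd Gaussian noise s.d. in percent dead cells.
#' @param seed integer RNG seed.
#' @param culture,formulation labels attached to the table.
#' @return list with \code{table} (data.frame dose_ug_ml, E_mean, E_sd, n,
#'   culture, formulation), \code{replicates} (per-replicate values) and
#'   \code{truth}.
#' @export
synthDoseResponse <- function(Emax, EC50, h,
                              doses = c(0, 0.1, 0.25, 0.5, 1, 2.5, 5, 10),
                              nReplicates = 8L, noiseSd = 0, seed = 1L,
                              culture = "2D", formulation = "free") {
  if (Emax <= 0 || Emax > 100) stop("Emax must be in (0, 100]")
  if (any(doses < 0)) stop("doses must be >= 0")
  if (!any(doses == 0)) stop("the zero-dose control must be included")
  if (noiseSd < 0) stop("noise s.d. must be >= 0")
  withSeed(seed, {
    grid <- expand.grid(replicate = seq_len(nReplicates), dose = doses)
    mu <- ifelse(grid$dose > 0, hillCurve(log10(grid$dose), Emax, EC50, h), 0)
    val <- mu + if (noiseSd > 0) rnorm(nrow(grid), 0, noiseSd) else 0
    reps <- data.frame(dose_ug_ml = grid$dose, E = val,
                       replicate = grid$replicate, culture = culture,
                       formulation = formulation)
    agg <- do.call(rbind, lapply(split(reps, reps$dose_ug_ml), function(g)
      data.frame(dose_ug_ml = g$dose_ug_ml[1], E_mean = mean(g$E),
                 E_sd = sd(g$E), n = nrow(g), culture = culture,
                 formulation = formulation)))
    agg <- agg[order(agg$dose_ug_ml), ]
    rownames(agg) <- NULL
    list(table = agg, replicates = reps,
         truth = list(Emax = Emax, EC50 = EC50, h = h, noiseSd = noiseSd,
                      seed = seed))
  })
}
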