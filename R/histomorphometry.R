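# Quantification of cancer-cell colonization on stained sections:
# Gaussian pre-blur, colour deconvolution into cell/matrix/background
# optical-density channels, thresholding + watershed segmentation,
# convex-hull circularity morphotyping, compartment-resolved cellularity
# and invasion depth.

#' Gaussian pre-blur in micron units
#'
#' Per-channel Gaussian smoothing with the physical scale expressed in
#' microns; the pixel-space s.d. is sigmaUm / pixelSizeUm.  Borders are
#' handled by reflection.
#'
#' @param image matrix or rows x cols x channels array in [0,1].
#' @param sigmaUm smoothing s.d. in microns (0 returns the input
#'   unchanged); the default 0.65 um suppresses high-frequency texture
#'   before deconvolution.
#' @param pixelSizeUm microns per pixel (> 0).
#' @return blurred image of the same shape.
#' @export
preblur <- function(image, sigmaUm = 0.65, pixelSizeUm = 1) {
  if (sigmaUm < 0) stop("sigmaUm must be >= 0")
  if (pixelSizeUm <= 0) stop("pixel size must be > 0")
  if (sigmaUm == 0) return(image)
  sigmaPx <- sigmaUm / pixelSizeUm
  dims <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  if (sigmaPx > min(dims) / 4)
    stop("blur kernel (sigma = ", format(sigmaPx, digits = 3),
         " px) exceeds a quarter of the image size")
  k <- gaussKernel1d(sigmaPx)
  if (is.matrix(image)) return(convolveSep(image, k))
  out <- image
  for (ch in seq_len(dim(image)[3]))
    out[, , ch] <- convolveSep(image[, , ch], k)
  out
}

#' Colour deconvolution into stain channels
#'
#' Converts an RGB image to optical density OD = -log10((I + eps) / I0)
#' and unmixes it through the inverse of the stain matrix into three
#' scalar concentration channels (cell stain, matrix stain, residual
#' background).  Negative concentrations are clipped to zero and the
#' clipped mass is reported.
#'
#' @param image rows x cols x 3 array in [0,1] (8-bit input is rescaled).
#' @param stainMatrix 3x3 matrix with unit-norm stain OD vectors as rows
#'   (default \code{\link{defaultStainMatrix}}).
#' @param maxCondition reject stain matrices with a condition number above
#'   this threshold as effectively singular.
#' @param eps intensity floor avoiding log of zero.
#' @return a \code{\link{StainSeparation-class}} object.
#' @export
deconvolveStains <- function(image, stainMatrix = defaultStainMatrix(),
                             maxCondition = 1e4, eps = 1e-6) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an RGB image (rows x cols x 3)")
  if (max(image) > 1) image <- image / 255
  if (kappa(stainMatrix, exact = TRUE) > maxCondition)
    stop("stain matrix is near-singular (condition number above ",
         maxCondition, ")")
  nr <- dim(image)[1]; nc <- dim(image)[2]
  od <- -log10((matrix(image, nr * nc, 3) + eps) / 1)
  conc <- od %*% solve(stainMatrix)
  clipped <- sum(pmax(-conc, 0))
  concClip <- pmax(conc, 0)
  resid <- sqrt(mean((concClip %*% stainMatrix - od)^2))
  new("StainSeparation",
      cells = matrix(concClip[, 1], nr, nc),
      matrixChannel = matrix(concClip[, 2], nr, nc),
      background = matrix(concClip[, 3], nr, nc),
      stainMatrix = stainMatrix,
      residualNorm = resid, clippedMass = clipped)
}

#' Segment cells on a stain concentration channel
#'
#' Thresholds the cell optical-density channel (Otsu by default, fixed
#' value on request), labels connected components, optionally splits
#' touching regions by a distance-transform watershed, and removes
#' regions below a minimum physical area.
#'
#' @param channel non-negative matrix (cell OD concentrations).
#' @param pixelSizeUm microns per pixel.
#' @param threshold "otsu" or a fixed numeric threshold in channel units.
#' @param minAreaUm2 minimum object area kept, in square microns.
#' @param splitTouching if TRUE (default), watershed-split touching
#'   regions seeded at distance-transform maxima.
#' @param watershedTolerance minimum depth between distance-transform
#'   maxima for a split (px); larger values split less.
#' @return integer label matrix; 0 is background.  An empty foreground
#'   yields an all-zero matrix; an all-foreground threshold is an error
#'   suggesting a threshold override.
#' @export
segmentCells <- function(channel, pixelSizeUm = 1, threshold = "otsu",
                         minAreaUm2 = 20, splitTouching = TRUE,
                         watershedTolerance = 1) {
  if (any(channel < 0)) stop("channel must be non-negative")
  if (pixelSizeUm <= 0) stop("pixel size must be > 0")
  rng <- range(channel)
  if (diff(rng) == 0)
    return(matrix(0L, nrow(channel), ncol(channel)))
  thr <- if (identical(threshold, "otsu")) {
    scaled <- (channel - rng[1]) / diff(rng)
    rng[1] + EBImage::otsu(EBImage::Image(scaled)) * diff(rng)
  } else as.numeric(threshold)
  mask <- channel > thr
  if (!any(mask)) return(matrix(0L, nrow(channel), ncol(channel)))
  if (all(mask))
    stop("threshold left no background; override 'threshold' with a ",
         "fixed value")
  labels <- if (splitTouching) {
    dm <- EBImage::distmap(mask)
    EBImage::imageData(EBImage::watershed(dm, tolerance = watershedTolerance,
                                          ext = 1))
  } else {
    EBImage::imageData(EBImage::bwlabel(mask))
  }
  labels <- matrix(as.integer(labels), nrow(channel), ncol(channel))
  minPx <- minAreaUm2 / pixelSizeUm^2
  tab <- tabulate(labels[labels > 0L])
  keep <- which(tab >= minPx)
  if (length(keep) == 0L) return(matrix(0L, nrow(channel), ncol(channel)))
  remap <- integer(max(labels))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(channel), ncol(channel))
  pos <- labels > 0L
  out[pos] <- remap[labels[pos]]
  out
}

# Boundary pixels of one labelled region (pixels with a 4-neighbour of a
# different label), as a (row, col) matrix of pixel centres.
regionBoundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(mask & !inner, arr.ind = TRUE)
}

#' Convex-hull circularity of a region
#'
#' Circularity = 4 * pi * hullArea / hullPerimeter^2, computed on the
#' convex hull polygon of the region's boundary pixel centres.  The hull
#' approximation of the cell boundary damps pixel-level roughness; a disk
#' scores ~1, elongated shapes score lower.  Values are clipped at 1 on
#' report (small discretization overshoot).
#'
#' @param region logical matrix (TRUE = region pixels) or a 2-column
#'   (row, col) matrix of pixel coordinates.
#' @return circularity in [0, 1]; degenerate (collinear) regions return 0
#'   with a warning.
#' @export
hullCircularity <- function(region) {
  coords <- if (is.matrix(region) && ncol(region) == 2L && !is.logical(region))
    region else regionBoundary(region)
  if (nrow(coords) < 3L) {
    warning("degenerate region (< 3 boundary pixels); circularity 0")
    return(0)
  }
  hullIdx <- grDevices::chull(coords[, 1], coords[, 2])
  hull <- coords[hullIdx, , drop = FALSE]
  hm <- hullMetrics(hull)
  if (hm$per == 0 || hm$area == 0) {
    warning("degenerate (collinear) region; circularity 0")
    return(0)
  }
  min(4 * pi * hm$area / hm$per^2, 1)
}

# Area and perimeter of the convex hull of pixel centres, dilated by half
# a pixel to account for the pixels' own footprint (Minkowski sum of a
# convex polygon with a disk of radius 1/2):
# A' = A + P/2 + pi/4, P' = P + pi.
hullMetrics <- function(hull) {
  a <- polygonArea(hull)
  p <- polygonPerimeter(hull)
  if (p == 0 || a == 0) return(list(area = a, per = p))
  list(area = a + p / 2 + pi / 4, per = p + pi)
}

#' Classify cell morphotype from circularity
#'
#' Epithelioid (round) versus mesenchymal-like (elongated) morphotypes
#' split at a circularity cutoff; values exactly at the cutoff are
#' classified epithelioid.
#'
#' @param circularity numeric vector in [0, 1].
#' @param cutoff circularity cutoff in (0, 1); default 0.7.
#' @return character vector: "epithelioid" or "mesenchymal-like".
#' @export
classifyMorphotype <- function(circularity, cutoff = 0.7) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  if (any(circularity < 0 | circularity > 1, na.rm = TRUE))
    stop("circularity must lie in [0, 1]")
  ifelse(circularity >= cutoff, "epithelioid", "mesenchymal-like")
}

#' Data-driven circularity cutoff
#'
#' Otsu split of a circularity sample, for separating a bimodal
#' round/elongated population without a fixed cutoff.
#'
#' @param circularity numeric vector.
#' @return numeric(1), the split point.
#' @export
circularityCutoff <- function(circularity) otsuBreak(circularity)

#' Measure segmented cells
#'
#' Extracts one record per labelled region: centroid, pixel area, convex
#' hull area/perimeter and circularity, all geometry in microns.
#'
#' @param labels integer label matrix from \code{\link{segmentCells}}.
#' @param pixelSizeUm microns per pixel.
#' @return data.frame with columns label, row, col, areaUm2, hullAreaUm2,
#'   hullPerimeterUm, circularity.
#' @export
measureCells <- function(labels, pixelSizeUm = 1) {
  ids <- sort(unique(labels[labels > 0L]))
  rows <- lapply(ids, function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    bnd <- regionBoundary(labels == id)
    circ <- if (nrow(bnd) >= 3L) {
      hull <- bnd[grDevices::chull(bnd[, 1], bnd[, 2]), , drop = FALSE]
      hm <- hullMetrics(hull)
      list(circ = if (hm$per > 0 && hm$area > 0)
        min(4 * pi * hm$area / hm$per^2, 1) else 0,
        area = hm$area, per = hm$per)
    } else list(circ = 0, area = 0, per = 0)
    data.frame(label = id,
               row = mean(px[, 1]), col = mean(px[, 2]),
               areaUm2 = nrow(px) * pixelSizeUm^2,
               hullAreaUm2 = circ$area * pixelSizeUm^2,
               hullPerimeterUm = circ$per * pixelSizeUm,
               circularity = circ$circ)
  })
  if (length(rows) == 0L)
    return(data.frame(label = integer(0), row = numeric(0),
                      col = numeric(0), areaUm2 = numeric(0),
                      hullAreaUm2 = numeric(0),
                      hullPerimeterUm = numeric(0),
                      circularity = numeric(0)))
  do.call(rbind, rows)
}

#' Relative cellularity of a section
#'
#' Percentage of the section area occupied by segmented cells.
#'
#' @param labels integer label matrix (0 = background).
#' @param sectionMask logical matrix marking the section.
#' @return percentage in [0, 100].
#' @export
relativeCellularity <- function(labels, sectionMask) {
  if (!any(sectionMask)) stop("section mask is empty")
  100 * sum(labels > 0L & sectionMask) / sum(sectionMask)
}

#' Invasion depth of cells below the section surface
#'
#' Depth of each cell centroid measured as the Euclidean distance
#' transform of the section mask (distance to the nearest point outside
#' the section, i.e. to the scaffold surface), in microns.  A centroid on
#' the surface has depth 0; centroids outside the section are flagged
#' with NA.
#'
#' @param cells data.frame with columns row, col
#'   (from \code{\link{measureCells}}).
#' @param sectionMask logical matrix; its boundary is the tissue surface.
#' @param pixelSizeUm microns per pixel.
#' @param frontPercentile percentile reported as the invasion front
#'   (default 0.95, robust to outliers).
#' @return list with \code{depthsUm} (per cell, NA outside the section)
#'   and \code{summary} (mean, sd, front, nOutside).
#' @export
invasionDepths <- function(cells, sectionMask, pixelSizeUm = 1,
                           frontPercentile = 0.95) {
  dm <- EBImage::imageData(EBImage::distmap(sectionMask))
  idx <- cbind(pmin(pmax(round(cells$row), 1L), nrow(sectionMask)),
               pmin(pmax(round(cells$col), 1L), ncol(sectionMask)))
  d <- dm[idx]
  depths <- ifelse(d > 0, pmax(d - 1, 0) * pixelSizeUm, NA_real_)
  ok <- !is.na(depths)
  list(depthsUm = depths,
       summary = list(meanUm = if (any(ok)) mean(depths[ok]) else NA_real_,
                      sdUm = if (sum(ok) > 1) sd(depths[ok]) else NA_real_,
                      frontUm = if (any(ok))
                        unname(quantile(depths[ok], frontPercentile))
                      else NA_real_,
                      frontPercentile = frontPercentile,
                      nOutside = sum(!ok)))
}

#' Assign cells to tissue compartments
#'
#' A cell's compartment is the label of the compartment mask at its
#' centroid; cells whose region spans several labels with less than the
#' majority fraction in any one are labelled "mixed", and centroids on
#' label 0 give "none".
#'
#' @param cells data.frame from \code{\link{measureCells}}.
#' @param labels integer cell label matrix (needed for the majority rule).
#' @param compartmentMask integer matrix (0 = background,
#'   1 = parenchymal, 2 = stromal), aligned to the image.
#' @param majority minimum fraction of the cell's pixels in a single
#'   compartment before it is called "mixed" (default 0.8).
#' @return the cells data.frame with a \code{compartment} column added.
#' @export
assignCompartments <- function(cells, labels, compartmentMask,
                               majority = 0.8) {
  if (!all(dim(labels) == dim(compartmentMask)))
    stop("compartment mask shape does not match the label image")
  nm <- c("none", "parenchymal", "stromal")
  comp <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    id <- cells$label[i]
    centroidLab <- compartmentMask[pmin(pmax(round(cells$row[i]), 1L),
                                        nrow(labels)),
                                   pmin(pmax(round(cells$col[i]), 1L),
                                        ncol(labels))]
    if (centroidLab == 0L) { comp[i] <- "none"; next }
    labs <- compartmentMask[labels == id]
    frac <- max(tabulate(labs + 1L, nbins = 3L)) / length(labs)
    comp[i] <- if (frac < majority) "mixed" else nm[centroidLab + 1L]
  }
  cells$compartment <- comp
  cells
}

#' Morphometry summary of a section
#'
#' Aggregates per-cell records into the section-level report: relative
#' cellularity, per-compartment counts and morphotype fractions, invasion
#' depth statistics and the invasion-front percentile.  Also reports cell
#' count density as a secondary output.
#'
#' @param cells data.frame with columns compartment, morphotype, depthUm.
#' @param labels integer label matrix.
#' @param sectionMask logical section mask.
#' @param pixelSizeUm microns per pixel.
#' @return list: relativeCellularityPct, countPerMm2, perCompartment
#'   (count, epithelioid/mesenchymal fractions in percent, depth
#'   mean/sd/front).
#' @export
morphometrySummary <- function(cells, labels, sectionMask, pixelSizeUm = 1) {
  sectionAreaMm2 <- sum(sectionMask) * pixelSizeUm^2 / 1e6
  perComp <- lapply(split(cells, cells$compartment), function(g) {
    cls <- g$morphotype[g$morphotype %in%
                          c("epithelioid", "mesenchymal-like")]
    fr <- if (length(cls)) 100 * table(factor(
      cls, levels = c("epithelioid", "mesenchymal-like"))) / length(cls)
    else c(epithelioid = NA_real_, `mesenchymal-like` = NA_real_)
    ok <- !is.na(g$depthUm)
    list(count = nrow(g),
         epithelioidPct = unname(fr["epithelioid"]),
         mesenchymalPct = unname(fr["mesenchymal-like"]),
         depthMeanUm = if (any(ok)) mean(g$depthUm[ok]) else NA_real_,
         depthSdUm = if (sum(ok) > 1) sd(g$depthUm[ok]) else NA_real_)
  })
  list(relativeCellularityPct = relativeCellularity(labels, sectionMask),
       countPerMm2 = nrow(cells) / max(sectionAreaMm2, .Machine$double.eps),
       nCells = nrow(cells),
       perCompartment = perComp)
}

#' End-to-end histomorphometry of a stained section
#'
#' Runs the full pipeline: Gaussian pre-blur, colour deconvolution,
#' segmentation of the cell channel, hull-circularity morphotyping,
#' compartment assignment, invasion depth and the section summary.
#'
#' @param image RGB array in [0,1].
#' @param pixelSizeUm microns per pixel.
#' @param sectionMask logical matrix; defaults to the whole image.
#' @param compartmentMask optional integer compartment mask.
#' @param sigmaUm pre-blur scale in microns.
#' @param stainMatrix stain matrix for deconvolution.
#' @param circularityCutoff morphotype cutoff, or "otsu" for the
#'   data-driven split.
#' @param ... passed to \code{\link{segmentCells}}.
#' @return list: cells (per-cell table), labels, separation
#'   (StainSeparation), summary.
#' @export
analyzeHistology <- function(image, pixelSizeUm,
                             sectionMask = NULL, compartmentMask = NULL,
                             sigmaUm = 0.65,
                             stainMatrix = defaultStainMatrix(),
                             circularityCutoff = 0.7, ...) {
  if (is.null(sectionMask))
    sectionMask <- matrix(TRUE, dim(image)[1], dim(image)[2])
  blurred <- preblur(image, sigmaUm, pixelSizeUm)
  sep <- deconvolveStains(blurred, stainMatrix)
  labels <- segmentCells(sep@cells, pixelSizeUm, ...)
  cells <- measureCells(labels, pixelSizeUm)
  cutoff <- if (identical(circularityCutoff, "otsu"))
    otsuBreak(cells$circularity) else circularityCutoff
  cells$morphotype <- if (nrow(cells)) classifyMorphotype(
    cells$circularity, cutoff) else character(0)
  dep <- invasionDepths(cells, sectionMask, pixelSizeUm)
  cells$depthUm <- dep$depthsUm
  cells$compartment <- if (!is.null(compartmentMask) && nrow(cells))
    assignCompartments(cells, labels, compartmentMask)$compartment
  else rep("none", nrow(cells))
  list(cells = cells, labels = labels, separation = sep,
       summary = c(morphometrySummary(cells, labels, sectionMask,
                                      pixelSizeUm),
                   list(invasion = dep$summary,
                        circularityCutoff = cutoff)))
}
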