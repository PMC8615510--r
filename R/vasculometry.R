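# CAM vessel quantification: green-channel extraction, histogram
# stretching, Steger-style ridge detection (Gaussian-derivative Hessian,
# sub-pixel line-point test, hysteresis linking), morphological thinning
# to a unit-width skeleton, graph decomposition and per-ROI branch-length
# density.

#' Extract the green channel
#'
#' Vessels have the highest contrast in the green channel of brightfield
#' CAM images; returns that plane unchanged.
#'
#' @param image rows x cols x 3 RGB array.
#' @return matrix, the green plane.
#' @export
greenChannel <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected a 3-channel RGB image")
  image[, , 2]
}

#' Percentile histogram stretching
#'
#' Linear rescale mapping the low/high intensity percentiles to [0, 1],
#' clipping outside.  A constant image is returned unchanged with a
#' warning.
#'
#' @param image gray-level matrix.
#' @param lowPct,highPct percentiles (0-100) mapped to 0 and 1.
#' @return stretched matrix in [0, 1].
#' @export
stretchContrast <- function(image, lowPct = 0, highPct = 100) {
  q <- quantile(image, c(lowPct, highPct) / 100, names = FALSE)
  if (diff(q) == 0) {
    warning("constant image; contrast stretch is a no-op")
    return(image)
  }
  clip01((image - q[1]) / (q[2] - q[1]))
}

#' Ridge detection parameters
#'
#' The Gaussian scale should match the expected vessel half-width; by
#' Steger's width relation a line of full width w is optimally detected
#' at sigma = w / (2 * sqrt(3)).  Response thresholds act on the
#' scale-normalised principal second derivative (sigma^2 * max Hessian
#' eigenvalue) and were calibrated on synthetic vessel images of contrast
#' ~0.65.
#'
#' @param sigma Gaussian scale in pixels; derived from
#'   \code{vesselWidthPx} when NULL.
#' @param vesselWidthPx expected vessel width in pixels (default 3).
#' @param upper,lower hysteresis thresholds on the normalised ridge
#'   response (upper >= lower >= 0).
#' @param minLengthPx minimum accepted line/spur length in pixels.
#' @param polarity "dark" for dark lines on a bright background (CAM
#'   vessels in the green channel) or "bright".
#' @return list of class \code{RidgeParams}.
#' @export
ridgeParams <- function(sigma = NULL, vesselWidthPx = 3,
                        upper = 0.08, lower = 0.02,
                        minLengthPx = 5, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (is.null(sigma)) sigma <- vesselWidthPx / (2 * sqrt(3))
  if (sigma <= 0) stop("sigma must be > 0")
  if (lower < 0 || upper < lower)
    stop("thresholds must satisfy upper >= lower >= 0")
  structure(list(sigma = sigma, upper = upper, lower = lower,
                 minLengthPx = minLengthPx, polarity = polarity),
            class = "RidgeParams")
}

# Shift a matrix by (dr, dc) with zero fill.
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen thinning of a logical matrix to an 8-connected unit-width
# skeleton.
thinSkeleton <- function(mask, maxIter = 500L) {
  m <- mask * 1
  offs <- list(P2 = c(-1, 0), P3 = c(-1, 1), P4 = c(0, 1), P5 = c(1, 1),
               P6 = c(1, 0), P7 = c(1, -1), P8 = c(0, -1), P9 = c(-1, -1))
  for (it in seq_len(maxIter)) {
    changed <- FALSE
    for (pass in 1:2) {
      p <- lapply(offs, function(o) shiftMat(m, o[1], o[2]))
      B <- Reduce(`+`, p)
      seqp <- p[c("P2", "P3", "P4", "P5", "P6", "P7", "P8", "P9", "P2")]
      A <- 0
      for (i in 1:8) A <- A + (seqp[[i]] == 0) * (seqp[[i + 1]] == 1)
      if (pass == 1) {
        c1 <- p$P2 * p$P4 * p$P6 == 0
        c2 <- p$P4 * p$P6 * p$P8 == 0
      } else {
        c1 <- p$P2 * p$P4 * p$P8 == 0
        c2 <- p$P2 * p$P6 * p$P8 == 0
      }
      del <- m == 1 & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) { m[del] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}

# 8-connected flood labelling of a sparse logical mask (used for node
# clusters; small sets only).
labelSparse <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  lab <- integer(n)
  if (n == 0L) return(list(idx = idx, lab = lab))
  key <- idx[, 1] * (ncol(mask) + 2L) + idx[, 2]
  lookup <- new.env(hash = TRUE)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        k <- (idx[j, 1] + dr) * (ncol(mask) + 2L) + (idx[j, 2] + dc)
        hit <- mget(as.character(k), envir = lookup,
                    ifnotfound = list(NULL))[[1L]]
        if (!is.null(hit) && lab[hit] == 0L) {
          lab[hit] <- cur
          queue <- c(queue, hit)
        }
      }
    }
  }
  list(idx = idx, lab = lab)
}

# Geometric length of a pixel chain: Euclidean arc length of the
# moving-average-smoothed chain coordinates (window 5), plus one pixel
# for the chain's own extent.  Smoothing removes the digitization jitter
# that makes raw 8-connected step sums overestimate oblique curves;
# straight axial and diagonal chains are measured exactly.
smoothChain <- function(chain, window = 5L) {
  n <- nrow(chain)
  if (n < 3L || window < 3L) return(chain)
  half <- window %/% 2L
  out <- chain
  for (j in 1:2) {
    cs <- cumsum(c(0, chain[, j]))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    # symmetric shrinking window keeps the endpoints exact
    shrink <- pmin(seq_len(n) - lo, hi - seq_len(n))
    lo <- seq_len(n) - shrink; hi <- seq_len(n) + shrink
    out[, j] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

# freeEnds: number of chain ends (0..2) that terminate the network
# (endpoint nodes / dead ends); each contributes its half-pixel extent.
# Ends shared with a junction cluster contribute nothing (the junction
# carries that extent).
chainLengthPx <- function(chain, window = 5L, freeEnds = 2L) {
  if (nrow(chain) == 0L) return(0)
  if (nrow(chain) == 1L) return(0.5 * freeEnds)
  base <- if (nrow(chain) == 2L)
    sqrt(sum((chain[2L, ] - chain[1L, ])^2))
  else polylineLength(smoothChain(chain, window))
  base + 0.5 * freeEnds
}

# Decompose a unit-width skeleton into a node/edge graph.  Pixel
# adjacency is the reduced 8-adjacency: a diagonal link is dropped when
# the two pixels share an axial skeleton neighbour (this resolves the
# staircase ambiguities left by thinning).  Nodes are 8-connected
# clusters of pixels whose reduced degree differs from two; edges are
# the pixel chains between them.
buildSkeletonGraph <- function(skel, pixelSizeUm, provenance = "") {
  nr <- nrow(skel); nc <- ncol(skel)

  inBounds <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  # reduced-adjacency neighbours of one pixel
  neighbours <- function(r, c) {
    res <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (!inBounds(rr, cc) || !skel[rr, cc]) next
      if (dr != 0 && dc != 0 &&
          ((inBounds(r + dr, c) && skel[r + dr, c]) ||
           (inBounds(r, c + dc) && skel[r, c + dc]))) next
      res <- rbind(res, c(rr, cc))
    }
    res
  }

  # reduced degree of every skeleton pixel, vectorised via shifts
  s <- skel * 1
  deg <- matrix(0, nr, nc)
  for (dc in c(-1, 1)) deg <- deg + shiftMat(s, 0, dc)
  for (dr in c(-1, 1)) deg <- deg + shiftMat(s, dr, 0)
  for (dr in c(-1, 1)) for (dc in c(-1, 1)) {
    diagOk <- shiftMat(s, dr, dc) *
      (1 - pmax(shiftMat(s, dr, 0), shiftMat(s, 0, dc)))
    deg <- deg + diagOk
  }
  nodeMask <- skel & deg != 2
  nodes <- labelSparse(nodeMask)
  nodeId <- matrix(0L, nr, nc)
  if (nrow(nodes$idx)) nodeId[nodes$idx] <- nodes$lab
  nNodes <- if (length(nodes$lab)) max(nodes$lab) else 0L

  visited <- matrix(FALSE, nr, nc)
  chains <- list(); from <- integer(0); to <- integer(0)
  isLoop <- logical(0)
  seenPair <- new.env(hash = TRUE)  # dedupe node-node contact edges

  # trace from every node pixel into each neighbour
  if (nNodes > 0L) for (i in seq_len(nrow(nodes$idx))) {
    r0 <- nodes$idx[i, 1]; c0 <- nodes$idx[i, 2]
    nbrs <- neighbours(r0, c0)
    if (is.null(nbrs)) next
    for (k in seq_len(nrow(nbrs))) {
      r <- nbrs[k, 1]; c <- nbrs[k, 2]
      if (nodeId[r, c] > 0L) {
        # direct node-node contact: record each pixel pair once
        if (nodeId[r, c] == nodes$lab[i]) next
        key <- paste(min(r0 * nc + c0, r * nc + c),
                     max(r0 * nc + c0, r * nc + c))
        if (!is.null(seenPair[[key]])) next
        seenPair[[key]] <- TRUE
        chains[[length(chains) + 1L]] <- rbind(c(r0, c0), c(r, c))
        from <- c(from, nodes$lab[i]); to <- c(to, nodeId[r, c])
        isLoop <- c(isLoop, FALSE)
        next
      }
      if (visited[r, c]) next
      chain <- rbind(c(r0, c0), c(r, c))
      visited[r, c] <- TRUE
      prevR <- r0; prevC <- c0
      repeat {
        nxt <- neighbours(r, c)
        nxt <- nxt[!(nxt[, 1] == prevR & nxt[, 2] == prevC), ,
                   drop = FALSE]
        if (is.null(nxt) || nrow(nxt) == 0L) break  # dead end
        prevR <- r; prevC <- c
        r <- nxt[1L, 1L]; c <- nxt[1L, 2L]
        chain <- rbind(chain, c(r, c))
        if (nodeId[r, c] > 0L) break
        visited[r, c] <- TRUE
      }
      endNode <- nodeId[r, c]
      chains[[length(chains) + 1L]] <- chain
      from <- c(from, nodes$lab[i])
      to <- c(to, if (endNode > 0L) endNode else NA_integer_)
      isLoop <- c(isLoop, FALSE)
    }
  }

  # closed loops with no nodes
  loopStarts <- which(skel & !visited & nodeId == 0L, arr.ind = TRUE)
  while (nrow(loopStarts)) {
    r0 <- loopStarts[1, 1]; c0 <- loopStarts[1, 2]
    chain <- matrix(c(r0, c0), 1)
    visited[r0, c0] <- TRUE
    prevR <- -1L; prevC <- -1L; r <- r0; c <- c0
    repeat {
      nxt <- neighbours(r, c)
      nxt <- nxt[!(nxt[, 1] == prevR & nxt[, 2] == prevC), , drop = FALSE]
      if (!is.null(nxt) && nrow(nxt))
        nxt <- nxt[!visited[nxt] |
                     (nxt[, 1] == r0 & nxt[, 2] == c0), , drop = FALSE]
      if (is.null(nxt) || nrow(nxt) == 0L) break
      prevR <- r; prevC <- c
      r <- nxt[1L, 1L]; c <- nxt[1L, 2L]
      if (r == r0 && c == c0) break
      visited[r, c] <- TRUE
      chain <- rbind(chain, c(r, c))
    }
    chains[[length(chains) + 1L]] <- chain
    from <- c(from, NA_integer_); to <- c(to, NA_integer_)
    isLoop <- c(isLoop, TRUE)
    loopStarts <- which(skel & !visited & nodeId == 0L, arr.ind = TRUE)
  }

  lens <- vapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    if (isLoop[i]) {
      # closed cycle: include the closing step, no free ends
      cl <- if (nrow(ch) > 1L)
        sqrt(sum((ch[1L, ] - ch[nrow(ch), ])^2)) else 0
      return(chainLengthPx(ch, freeEnds = 0L) + cl)
    }
    fs <- deg[ch[1L, 1L], ch[1L, 2L]] <= 1
    fe <- if (is.na(to[i])) TRUE else
      deg[ch[nrow(ch), 1L], ch[nrow(ch), 2L]] <= 1
    chainLengthPx(ch, freeEnds = sum(fs, fe))
  }, numeric(1))
  edges <- data.frame(id = seq_along(chains), from = from, to = to,
                      nPixels = vapply(chains, nrow, integer(1)),
                      loop = isLoop,
                      lengthPx = lens, lengthUm = lens * pixelSizeUm)

  deg <- integer(nNodes)
  for (i in seq_along(from)) {
    if (!is.na(from[i])) deg[from[i]] <- deg[from[i]] + 1L
    if (!is.na(to[i])) deg[to[i]] <- deg[to[i]] + 1L
  }
  nodeTab <- if (nNodes > 0L) {
    cent <- do.call(rbind, lapply(seq_len(nNodes), function(l)
      colMeans(nodes$idx[nodes$lab == l, , drop = FALSE])))
    data.frame(id = seq_len(nNodes), row = cent[, 1], col = cent[, 2],
               degree = deg,
               type = ifelse(deg >= 3L, "junction", "endpoint"))
  } else data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                    degree = integer(0), type = character(0))

  new("VesselSkeleton", skeleton = skel, nodes = nodeTab, edges = edges,
      chains = chains, pixelSizeUm = pixelSizeUm,
      provenance = as.character(provenance))
}

# Remove terminal segments shorter than minLengthPx, then rebuild the
# graph; stabilises junction counts against thinning spurs.
pruneSpurs <- function(graph, minLengthPx, maxRounds = 3L) {
  for (round in seq_len(maxRounds)) {
    e <- graph@edges
    if (nrow(e) == 0L) return(graph)
    endNodes <- graph@nodes$id[graph@nodes$type == "endpoint"]
    isSpur <- (e$from %in% endNodes | e$to %in% endNodes |
                 is.na(e$from) | is.na(e$to)) & e$lengthPx < minLengthPx
    # never remove an isolated full component's only long edge
    if (!any(isSpur)) return(graph)
    skel <- graph@skeleton
    for (i in which(isSpur)) {
      ch <- graph@chains[[i]]
      keepEnd <- function(nid) !is.na(nid) &&
        graph@nodes$type[graph@nodes$id == nid] == "junction"
      drop <- rep(TRUE, nrow(ch))
      if (keepEnd(e$from[i])) drop[1L] <- FALSE
      if (keepEnd(e$to[i])) drop[nrow(ch)] <- FALSE
      skel[ch[drop, , drop = FALSE]] <- FALSE
    }
    graph <- buildSkeletonGraph(thinSkeleton(skel), graph@pixelSizeUm,
                                graph@provenance)
  }
  graph
}

#' Detect curvilinear vessels and extract their skeleton
#'
#' Steger-style line extraction: the image is convolved with first and
#' second derivatives of a Gaussian kernel; at each pixel the principal
#' curvature (largest Hessian eigenvalue for dark lines) and its
#' direction are computed, and pixels whose sub-pixel response maximum
#' falls inside the pixel (line-point test) seed hysteresis linking at
#' the upper/lower response thresholds.  The linked mask is thinned to an
#' 8-connected unit-width skeleton, spurs shorter than the minimum length
#' are pruned, and the skeleton is decomposed into a node/edge graph.
#'
#' @param image gray-level matrix in [0, 1] (green channel after
#'   \code{\link{stretchContrast}}).
#' @param params a \code{\link{ridgeParams}} object.
#' @param pixelSizeUm microns per pixel.
#' @return a \code{\link{VesselSkeleton-class}} object.
#' @export
detectRidges <- function(image, params = ridgeParams(), pixelSizeUm = 1) {
  stopifnot(inherits(params, "RidgeParams"))
  if (params$sigma > min(dim(image)) / 8)
    stop("sigma exceeds image size / 8")
  if (params$polarity == "bright") image <- 1 - image
  s <- params$sigma
  g0 <- gaussKernel1d(s, 0L); g1 <- gaussKernel1d(s, 1L)
  g2 <- gaussKernel1d(s, 2L)
  gx <- convolveSep(image, g0, g1)   # d/dcol
  gy <- convolveSep(image, g1, g0)   # d/drow
  hxx <- convolveSep(image, g0, g2)
  hyy <- convolveSep(image, g2, g0)
  hxy <- convolveSep(image, g1, g1)
  # principal (most positive) Hessian eigenvalue: dark line -> positive
  half <- (hyy + hxx) / 2
  tmp <- sqrt(((hyy - hxx) / 2)^2 + hxy^2)
  l1 <- half + tmp
  resp <- s^2 * pmax(l1, 0)
  # eigenvector of l1 in (row, col) coordinates
  ny <- hxy
  nx <- l1 - hyy
  nrm <- sqrt(nx^2 + ny^2)
  flat <- nrm < 1e-12
  ny[flat] <- ifelse(hyy[flat] >= hxx[flat], 1, 0)
  nx[flat] <- ifelse(hyy[flat] >= hxx[flat], 0, 1)
  nrm[flat] <- 1
  ny <- ny / nrm; nx <- nx / nrm
  # sub-pixel offset of the response maximum along the line normal
  tNum <- -(gy * ny + gx * nx)
  t <- ifelse(l1 > 1e-12, tNum / l1, Inf)
  linePoint <- abs(t * ny) <= 0.5 & abs(t * nx) <= 0.5

  strong <- linePoint & resp >= params$upper
  weak <- resp >= params$lower
  mask <- matrix(FALSE, nrow(image), ncol(image))
  if (any(strong)) {
    lab <- EBImage::imageData(EBImage::bwlabel(weak))
    keep <- unique(lab[strong])
    keep <- keep[keep > 0]
    mask <- matrix(lab %in% keep, nrow(image), ncol(image))
  }
  skel <- thinSkeleton(mask)
  graph <- buildSkeletonGraph(skel, pixelSizeUm, provenance = "detectRidges")
  graph <- pruneSpurs(graph, params$minLengthPx)
  # drop whole components shorter than the minimum accepted line length
  shortIso <- with(graph@edges, !is.na(from) & !is.na(to) &
                     lengthPx < params$minLengthPx &
                     from %in% graph@nodes$id[graph@nodes$degree == 1] &
                     to %in% graph@nodes$id[graph@nodes$degree == 1])
  if (any(shortIso)) {
    skel <- graph@skeleton
    for (i in which(shortIso)) skel[graph@chains[[i]]] <- FALSE
    graph <- buildSkeletonGraph(skel, pixelSizeUm,
                                provenance = "detectRidges")
  }
  graph
}

# TRUE for points inside a rectangular or polygonal ROI.
roiContains <- function(roi, r, c) {
  if (is.list(roi) && !is.null(roi$row0)) {
    r >= roi$row0 & r < roi$row0 + roi$height &
      c >= roi$col0 & c < roi$col0 + roi$width
  } else {
    p <- as.matrix(roi)
    n <- nrow(p)
    inside <- rep(FALSE, length(r))
    j <- n
    for (i in seq_len(n)) {
      crosses <- ((p[i, 1] > r) != (p[j, 1] > r)) &
        (c < (p[j, 2] - p[i, 2]) * (r - p[i, 1]) /
           (p[j, 1] - p[i, 1]) + p[i, 2])
      inside <- xor(inside, crosses)
      j <- i
    }
    inside
  }
}

roiAreaPx <- function(roi) {
  if (is.list(roi) && !is.null(roi$row0)) roi$height * roi$width
  else polygonArea(as.matrix(roi))
}

#' Rectangular region of interest
#'
#' @param row0,col0 top-left corner (pixel coordinates).
#' @param height,width extent in pixels.
#' @return ROI list usable in \code{\link{branchLengthDensity}}.
#' @export
rectRoi <- function(row0, col0, height, width) {
  if (height <= 0 || width <= 0) stop("ROI must have positive area")
  list(row0 = row0, col0 = col0, height = height, width = width)
}

#' Seeded random rectangular ROI sampler
#'
#' Draws axis-aligned ROIs uniformly inside an image, for synthetic
#' studies where the manual ROI choice of a real assay is emulated.
#'
#' @param dims image dimensions c(rows, cols).
#' @param n number of ROIs.
#' @param sizePx ROI side length in pixels.
#' @param seed RNG seed.
#' @return list of ROIs.
#' @export
sampleRois <- function(dims, n = 10L, sizePx = 64L, seed = 1L) {
  withSeed(seed, {
    lapply(seq_len(n), function(i)
      rectRoi(runif(1, 1, dims[1] - sizePx),
              runif(1, 1, dims[2] - sizePx), sizePx, sizePx))
  })
}

#' Branch length density within a region of interest
#'
#' Total skeleton branch length inside the ROI (8-connected step metric,
#' in microns) divided by the ROI area in square microns; also reports
#' the junction density and mean segment length.
#'
#' @param skeleton a \code{\link{VesselSkeleton-class}}.
#' @param roi a \code{\link{rectRoi}} or a polygon as a 2-column
#'   (row, col) matrix.
#' @param pixelSizeUm microns per pixel; defaults to the skeleton's.
#' @return list of class \code{RoiMetrics}: roiAreaUm2, totalLengthUm,
#'   densityUmPerUm2, junctionsPerUm2, nJunctions, meanSegmentLengthUm.
#' @export
branchLengthDensity <- function(skeleton, roi,
                                pixelSizeUm = skeleton@pixelSizeUm) {
  if (pixelSizeUm <= 0) stop("pixel size must be > 0")
  areaPx <- roiAreaPx(roi)
  if (areaPx <= 0) stop("ROI has zero area")
  dims <- dim(skeleton@skeleton)
  if (is.list(roi) && !is.null(roi$row0) &&
      (roi$row0 < 0 || roi$col0 < 0 ||
       roi$row0 + roi$height > dims[1] + 1 ||
       roi$col0 + roi$width > dims[2] + 1))
    stop("ROI exceeds image bounds")
  totalPx <- 0
  segLens <- numeric(0)
  for (ch in skeleton@chains) {
    inside <- roiContains(roi, ch[, 1], ch[, 2])
    if (!any(inside)) next
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    segTotal <- 0
    for (k in which(runs$values)) {
      seg <- ch[starts[k]:ends[k], , drop = FALSE]
      segTotal <- segTotal + chainLengthPx(seg)
    }
    totalPx <- totalPx + segTotal
    segLens <- c(segLens, segTotal)
  }
  nJ <- if (nrow(skeleton@nodes))
    sum(skeleton@nodes$type == "junction" &
          roiContains(roi, skeleton@nodes$row, skeleton@nodes$col))
  else 0L
  areaUm2 <- areaPx * pixelSizeUm^2
  totalUm <- totalPx * pixelSizeUm
  structure(list(roiAreaUm2 = areaUm2, totalLengthUm = totalUm,
                 densityUmPerUm2 = totalUm / areaUm2,
                 junctionsPerUm2 = nJ / areaUm2, nJunctions = nJ,
                 meanSegmentLengthUm = if (length(segLens))
                   mean(segLens) * pixelSizeUm else 0),
            class = "RoiMetrics")
}

#' Per-egg summary of ROI metrics
#'
#' Arithmetic mean vascular density across the egg's ROIs; branching
#' points per area are pooled as total junctions over total area.
#'
#' @param roiMetrics list of \code{RoiMetrics} from
#'   \code{\link{branchLengthDensity}}.
#' @param eggId,group optional identifiers carried into the output.
#' @return one-row data.frame: eggId, group, nRois, meanDensityUmPerUm2,
#'   junctionsPerUm2, meanSegmentLengthUm.
#' @export
eggSummary <- function(roiMetrics, eggId = NA, group = NA) {
  if (length(roiMetrics) < 1L) stop("at least one ROI is required")
  dens <- vapply(roiMetrics, `[[`, numeric(1), "densityUmPerUm2")
  nJ <- vapply(roiMetrics, `[[`, numeric(1), "nJunctions")
  area <- vapply(roiMetrics, `[[`, numeric(1), "roiAreaUm2")
  segL <- vapply(roiMetrics, `[[`, numeric(1), "meanSegmentLengthUm")
  data.frame(eggId = eggId, group = group, nRois = length(roiMetrics),
             meanDensityUmPerUm2 = mean(dens),
             junctionsPerUm2 = sum(nJ) / sum(area),
             meanSegmentLengthUm = mean(segL))
}
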