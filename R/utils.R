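# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Sampled 1D Gaussian and its first/second derivatives on integer offsets.
# The smoothing kernel is normalised to unit sum; the derivative kernels are
# the analytic derivatives of the same (normalised) Gaussian.
gaussKernel1d <- function(sigma, order = 0L, radius = NULL) {
  stopifnot(sigma > 0)
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = g * (-x / sigma^2),
         "2" = g * ((x^2 - sigma^2) / sigma^4),
         stop("order must be 0, 1 or 2"))
}

# Reflective padding of a matrix by (top/bottom, left/right) margins.
padReflect <- function(m, ry, rx) {
  nr <- nrow(m); nc <- ncol(m)
  if (ry >= nr || rx >= nc)
    stop("padding exceeds image size")
  ri <- c(rev(seq_len(ry) + 1L), seq_len(nr), nr - seq_len(ry))
  ci <- c(rev(seq_len(rx) + 1L), seq_len(nc), nc - seq_len(rx))
  m[ri, ci, drop = FALSE]
}

# Separable convolution with reflective borders; ky runs down rows, kx along
# columns.  Kernels must have odd length.
convolveSep <- function(m, ky, kx = ky) {
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  p <- padReflect(m, ry, rx)
  nr <- nrow(m); nc <- ncol(m)
  # rows pass
  tmp <- matrix(0, nr, ncol(p))
  for (j in seq_along(ky))
    tmp <- tmp + ky[j] * p[(j - 1L) + seq_len(nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_along(kx))
    out <- out + kx[j] * tmp[, (j - 1L) + seq_len(nc), drop = FALSE]
  out
}

# Shoelace area of a polygon given as a 2-column (row, col) matrix.
polygonArea <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  x <- p[, 1L]; y <- p[, 2L]
  i2 <- c(2:n, 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

polygonPerimeter <- function(p) {
  n <- nrow(p)
  if (n < 2L) return(0)
  i2 <- c(2:n, 1L)
  sum(sqrt((p[, 1L] - p[i2, 1L])^2 + (p[, 2L] - p[i2, 2L])^2))
}

# Analytic circularity 4*pi*A/P^2 of an ellipse with semi-axes a >= b,
# using the complete elliptic integral of the second kind for the perimeter.
# The convex hull of an ellipse is the ellipse itself.
ellipseCircularity <- function(a, b) {
  hi <- pmax(a, b); lo <- pmin(a, b)
  m <- 1 - (lo / hi)^2
  e2 <- vapply(m, function(mi) pracma::ellipke(mi)$e, numeric(1))
  per <- 4 * hi * e2
  area <- pi * hi * lo
  4 * pi * area / per^2
}

# Otsu threshold of a numeric vector (histogram-based, 256 bins).
otsuBreak <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0) return(mean(range(x)))
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[length(mu)]
  sb <- (muT * w1 - mu)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# Arc length of a polyline given as a 2-column matrix of coordinates.
polylineLength <- function(p) {
  if (nrow(p) < 2L) return(0)
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
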