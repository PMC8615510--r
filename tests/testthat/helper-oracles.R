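# Shared fixtures and independent oracles used across the suite.

# Binary disk mask of radius r centred in a square canvas.
digitalDisk <- function(r, pad = 10L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  idx <- expand.grid(row = seq_len(n), col = seq_len(n))
  matrix((idx$row - ctr)^2 + (idx$col - ctr)^2 <= r^2, n, n)
}

# Polygonal brute-force circularity of an a:b ellipse: dense perimeter
# sampling, shoelace area and summed chord lengths.  Independent of the
# elliptic-integral implementation used by the generator.
ellipseCircPolygon <- function(a, b, n = 20000L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(th); y <- b * sin(th)
  i2 <- c(2:n, 1L)
  area <- abs(sum(x * y[i2] - x[i2] * y)) / 2
  per <- sum(sqrt((x - x[i2])^2 + (y - y[i2])^2))
  4 * pi * area / per^2
}

# Exhaustive-enumeration null distribution of the two-sample KS statistic
# (no ties): all C(n+m, n) assignments of the pooled sample.
ksEnumP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); m <- length(y)
  ksD <- function(a, b) {
    s <- sort(unique(c(a, b)))
    max(abs(stats::ecdf(a)(s) - stats::ecdf(b)(s)))
  }
  dObs <- ksD(x, y)
  combos <- utils::combn(n + m, n)
  ds <- apply(combos, 2, function(ix) ksD(pooled[ix], pooled[-ix]))
  mean(ds >= dObs - 1e-12)
}

# Exhaustive-enumeration two-sided Mann-Whitney p (no ties), using the
# same two-sided rule as the exact distribution: 2 * min(P(U <= u),
# P(U >= u)) capped at 1.
mwEnumP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); m <- length(y)
  uStat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  uObs <- uStat(x, y)
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(ix) uStat(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(us <= uObs + 1e-12), mean(us >= uObs - 1e-12)))
}

# Independent scalar evaluation of the logistic growth law in its
# reciprocal form 1 / (1/Cmax + (1/C0 - 1/Cmax) exp(-d t)).
logisticOracle <- function(t, C0, Cmax, d)
  1 / (1 / Cmax + (1 / C0 - 1 / Cmax) * exp(-d * t))

# Independent scalar Hill evaluation (linear-dose form):
# E = Emax * dose^h / (EC50lin^h + dose^h).
hillOracle <- function(doseLin, Emax, EC50lin, h)
  Emax * doseLin^h / (EC50lin^h + doseLin^h)

# Default sparse random-tree spec used in vessel recovery tests.
treeSpec <- function(seed, ...) vesselSpec(seed = seed, ...)
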