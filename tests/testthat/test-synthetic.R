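# Ground-truth generators: empty/degenerate cases, analytic truth
# consistency, determinism.

test_that("histology generator handles empty and single-cell specs", {
  spec0 <- histologySpec(cellCount = c(0, 0), noiseSd = 0, seed = 1)
  h0 <- synthHistology(spec0)
  expect_equal(nrow(h0$truth$cells), 0L)
  expect_true(all(h0$truth$labelImage == 0L))
  # pure matrix/background: no cell-stain mass anywhere
  expect_true(all(h0$image >= 0 & h0$image <= 1))

  spec1 <- histologySpec(cellCount = c(1, 0), axisRatio = c(1, 1),
                         axisRatioSd = 0, noiseSd = 0, seed = 2)
  h1 <- synthHistology(spec1)
  expect_equal(nrow(h1$truth$cells), 1L)
  expect_equal(h1$truth$cells$circularity, 1.0, tolerance = 1e-9)
})

test_that("analytic truth circularity matches the polygonal hull oracle", {
  spec <- histologySpec(rows = 512, cols = 512,
                        cellCount = c(0, 50), axisRatio = c(1, 4),
                        axisRatioSd = 0, noiseSd = 0, seed = 3)
  h <- synthHistology(spec)
  expect_equal(nrow(h$truth$cells), 50L)
  oracle <- ellipseCircPolygon(4, 1)
  expect_equal(mean(h$truth$cells$circularity), oracle, tolerance = 1e-6)
})

test_that("histology truth cell count equals rendered labels and output is deterministic", {
  spec <- histologySpec(seed = 11)
  h1 <- synthHistology(spec)
  h2 <- synthHistology(spec)
  expect_identical(h1$image, h2$image)
  expect_identical(h1$truth$cells, h2$truth$cells)
  rendered <- sort(unique(h1$truth$labelImage[h1$truth$labelImage > 0]))
  expect_equal(rendered, h1$truth$cells$id)
})

test_that("overcrowded placement fails naming the compartment", {
  spec <- histologySpec(rows = 64, cols = 64, cellCount = c(0, 400),
                        seed = 1)
  expect_error(synthHistology(spec), "stromal")
})

test_that("vessel generator renders explicit polylines with exact truth", {
  # one straight 200 um segment: 100 px at 2 um/px
  sp <- vesselSpec(noiseSd = 0, seed = 1)
  v <- synthVessels(sp, polylines = list(cbind(128, c(50, 150))))
  expect_equal(v$truth$totalLengthUm, 200)
  expect_equal(v$truth$junctionCount, 0L)

  # two crossing straight segments: one junction by construction
  v2 <- synthVessels(sp, polylines = list(cbind(c(50, 200), c(50, 200)),
                                          cbind(c(200, 50), c(50, 200))))
  expect_equal(v2$truth$junctionCount, 1L)
})

test_that("random tree truth length equals re-integration of its polylines", {
  v <- suppressWarnings(synthVessels(treeSpec(seed = 5)))
  reint <- sum(vapply(v$truth$polylines, function(p) {
    # refine each segment before integrating: piecewise-linear arc length
    tot <- 0
    for (i in seq_len(nrow(p) - 1L)) {
      tt <- seq(0, 1, length.out = 50L)
      xs <- p[i, 1] + tt * (p[i + 1L, 1] - p[i, 1])
      ys <- p[i, 2] + tt * (p[i + 1L, 2] - p[i, 2])
      tot <- tot + sum(sqrt(diff(xs)^2 + diff(ys)^2))
    }
    tot
  }, numeric(1)))
  expect_equal(v$truth$totalLengthPx, reint, tolerance = 1e-3)
})

test_that("vessel truth length is invariant under 90-degree rotation", {
  sp <- vesselSpec(noiseSd = 0, seed = 1)
  pls <- list(cbind(c(40, 90, 150), c(30, 80, 100)),
              cbind(c(200, 120), c(200, 60)))
  rot <- lapply(pls, function(p) cbind(p[, 2], 257 - p[, 1]))
  v1 <- synthVessels(sp, polylines = pls)
  v2 <- synthVessels(sp, polylines = rot)
  expect_equal(v1$truth$totalLengthUm, v2$truth$totalLengthUm)
})

test_that("vessel images are deterministic and dark-on-bright", {
  sp <- treeSpec(seed = 9)
  v1 <- suppressWarnings(synthVessels(sp))
  v2 <- suppressWarnings(synthVessels(sp))
  expect_identical(v1$image, v2$image)
  g <- v1$truth$green
  expect_lt(min(g), 0.5)           # vessels dark
  expect_gt(median(g), 0.7)        # membrane bright
  expect_error(vesselSpec(fg = 0.9, bg = 0.3), "darker")
  expect_error(vesselSpec(widthPx = 0.5), "width")
})

test_that("viability generator matches the growth law", {
  # d = 0: constant C0
  s0 <- synthViability(0.2, 1, 0, times = c(0, 3, 9), noiseSd = 0)
  expect_true(all(s0$series$value == 0.2))
  # t = 0 gives C0 for any d
  s1 <- synthViability(0.2, 1, 1.7, times = c(0, 5), noiseSd = 0)
  expect_equal(unique(s1$series$value[s1$series$time_days == 0]), 0.2)
  # independent scalar re-evaluation at the 28-day point
  s2 <- synthViability(0.1, 1, 0.63, times = c(1, 28), noiseSd = 0)
  expect_equal(unique(s2$series$value[s2$series$time_days == 28]),
               logisticOracle(28, 0.1, 1, 0.63), tolerance = 1e-12)
  expect_error(synthViability(-1, 1, 0.5), "C0")
  expect_error(synthViability(0.5, 0.2, 0.5), "Cmax")
})

test_that("dose-response generator matches the sigmoid law", {
  ec50 <- log10(0.8)
  d <- synthDoseResponse(80, ec50, 1.3,
                         doses = c(0, 0.1, 0.8, 2, 5, 10), noiseSd = 0)
  # dose = EC50 gives Emax / 2
  expect_equal(d$table$E_mean[d$table$dose_ug_ml == 0.8], 40,
               tolerance = 1e-9)
  # asymptote: within 0.1% of Emax at EC50 + 3/h decades
  far <- 10^(ec50 + 3 / 1.3)
  d2 <- synthDoseResponse(80, ec50, 1.3, doses = c(0, 0.1, 0.5, 1, far),
                          noiseSd = 0)
  expect_equal(d2$table$E_mean[d2$table$dose_ug_ml == far] / 80, 1,
               tolerance = 1e-3)
  expect_error(synthDoseResponse(80, ec50, 1.3, doses = c(0, -1, 2)),
               ">= 0")
  expect_error(synthDoseResponse(80, ec50, 1.3, doses = c(0.5, 1, 2, 5, 10)),
               "control")
  expect_error(synthDoseResponse(120, ec50, 1.3), "Emax")
})

test_that("the generated 50%-death crossing sits at the calibrated dose", {
  # calibrate EC50 so the curve crosses 50% exactly at 0.43 ug/mL
  ic <- 0.43; Emax <- 100; h <- 1
  ec50 <- log10(ic) + log10(Emax / 50 - 1 + 1e-300) / h  # = log10(ic)
  tab <- synthDoseResponse(Emax, ec50, h, noiseSd = 0)$table
  # root-finding oracle on an independent linear-dose Hill form
  root <- uniroot(function(dd) hillOracle(dd, Emax, 10^ec50, h) - 50,
                  c(1e-4, 100), tol = 1e-12)$root
  expect_equal(root, ic, tolerance = 1e-8)
  # and the tabulated means bracket 50% around that dose
  below <- max(tab$dose_ug_ml[tab$E_mean < 50])
  above <- min(tab$dose_ug_ml[tab$E_mean > 50])
  expect_true(below <= ic && ic <= above)
})

test_that("generated dead-fraction means respect the noise envelope", {
  for (seed in 1:5) {
    d <- synthDoseResponse(70, log10(1), 1.5, noiseSd = 4, seed = seed,
                           nReplicates = 6)
    expect_true(all(d$table$E_mean >= -3 * 4))
    expect_true(all(d$table$E_mean <= 70 + 3 * 4))
  }
})
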