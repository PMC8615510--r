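# Vessel quantification: channel handling, contrast stretch, ridge
# detection and skeleton graph, ROI densities, group statistics.

test_that("green channel extraction is exact", {
  g <- matrix(runif(100), 10, 10)
  rgb <- array(0, c(10, 10, 3))
  rgb[, , 1] <- g; rgb[, , 2] <- g; rgb[, , 3] <- g
  expect_identical(greenChannel(rgb), g)
  red <- array(0, c(5, 5, 3)); red[, , 1] <- 1
  expect_true(all(greenChannel(red) == 0))
  expect_error(greenChannel(matrix(0, 5, 5)), "3-channel")
  v <- suppressWarnings(synthVessels(treeSpec(seed = 3)))
  expect_identical(greenChannel(v$image), v$truth$green)
})

test_that("histogram stretching maps the range to [0,1] and is idempotent", {
  img <- matrix(seq(0.2, 0.7, length.out = 64), 8, 8)
  s <- stretchContrast(img)
  expect_equal(range(s), c(0, 1))
  expect_equal(stretchContrast(s), s, tolerance = 1e-12)
  expect_warning(out <- stretchContrast(matrix(0.5, 5, 5)), "constant")
  expect_identical(out, matrix(0.5, 5, 5))
})

test_that("ridge detection on a blank image yields an empty skeleton", {
  sk <- detectRidges(matrix(0.9, 64, 64), ridgeParams(), 1)
  expect_equal(sum(sk@skeleton), 0)
  expect_equal(nrow(sk@edges), 0L)
  expect_error(detectRidges(matrix(0.5, 32, 32),
                            ridgeParams(sigma = 10)), "sigma")
})

test_that("a straight dark line is recovered as one accurate segment", {
  sp <- vesselSpec(rows = 64, cols = 340, noiseSd = 0, seed = 1)
  v <- synthVessels(sp, polylines = list(cbind(32, c(20, 319))))
  sk <- detectRidges(stretchContrast(greenChannel(v$image)), ridgeParams(),
                     pixelSizeUm = 1)
  expect_equal(junctionCount(sk), 0L)
  expect_equal(sum(sk@edges$lengthPx), 300, tolerance = 0.02)
  # skeleton length is invariant to brightness/contrast changes
  dim1 <- 0.3 + 0.5 * greenChannel(v$image)
  sk2 <- detectRidges(stretchContrast(dim1), ridgeParams(), 1)
  expect_equal(sum(sk2@edges$lengthPx), sum(sk@edges$lengthPx),
               tolerance = 0.01)
})

test_that("a crossing-free branched tree recovers length and junctions", {
  sp <- vesselSpec(noiseSd = 0, seed = 1)
  # explicit Y-shaped tree with 3 branch points, no crossings
  pls <- list(cbind(c(20, 120), c(128, 128)),
              cbind(c(120, 200), c(128, 60)),
              cbind(c(120, 200), c(128, 196)),
              cbind(c(160, 160), c(94, 30)),
              cbind(c(160, 160), c(162, 230)))
  # force shared branch points into the truth count via crossings at the
  # attachment pixels: branches start exactly on the parent polyline
  v <- synthVessels(sp, polylines = pls)
  sk <- detectRidges(stretchContrast(greenChannel(v$image)), ridgeParams(),
                     pixelSizeUm = sp$pixelSizeUm)
  truthLen <- sum(vapply(pls, tecquant:::polylineLength, numeric(1))) *
    sp$pixelSizeUm
  expect_equal(totalLengthUm(sk), truthLen, tolerance = 0.05)
  expect_lte(abs(junctionCount(sk) - 3), 1)
})

test_that("random-tree skeleton length recovers analytic truth", {
  ratios <- vapply(1:5, function(seed) {
    v <- suppressWarnings(synthVessels(treeSpec(seed = seed)))
    sk <- detectRidges(stretchContrast(greenChannel(v$image)),
                       ridgeParams(), pixelSizeUm = 2)
    totalLengthUm(sk) / v$truth$totalLengthUm
  }, numeric(1))
  expect_lte(median(abs(ratios - 1)), 0.05)
})

test_that("branch length density follows its closed form and units", {
  sp <- vesselSpec(rows = 64, cols = 340, noiseSd = 0, seed = 1)
  v <- synthVessels(sp, polylines = list(cbind(32, c(20, 319))))
  sk <- detectRidges(stretchContrast(greenChannel(v$image)), ridgeParams(),
                     pixelSizeUm = 1)
  # empty skeleton: zero density
  blank <- detectRidges(matrix(0.9, 64, 64), ridgeParams(), 1)
  expect_equal(branchLengthDensity(blank, rectRoi(1, 1, 60, 60),
                                   1)$densityUmPerUm2, 0)
  # closed form L*s / (W*H*s^2) for a fully-contained axial line
  roi <- rectRoi(1, 1, 64, 340)
  m1 <- branchLengthDensity(sk, roi, 1)
  expect_equal(m1$densityUmPerUm2, sum(sk@edges$lengthPx) / (64 * 340))
  # density scales as 1/s when the pixel size doubles
  m2 <- branchLengthDensity(sk, roi, 2)
  expect_equal(m2$densityUmPerUm2, m1$densityUmPerUm2 / 2)
  expect_error(branchLengthDensity(sk, rectRoi(1, 1, 0, 10), 1), "area")
  expect_error(branchLengthDensity(sk, rectRoi(1, 1, 640, 10), 1),
               "bounds")
})

test_that("density is rotation-invariant within discretization error", {
  v <- suppressWarnings(synthVessels(treeSpec(seed = 7)))
  g <- stretchContrast(greenChannel(v$image))
  gRot <- t(g)[ncol(g):1, ]    # 90-degree rotation
  sk <- detectRidges(g, ridgeParams(), 2)
  skRot <- detectRidges(gRot, ridgeParams(), 2)
  roi <- rectRoi(60, 40, 120, 160)
  roiRot <- rectRoi(nrow(gRot) - (40 + 160) + 1, 60, 160, 120)
  d1 <- branchLengthDensity(sk, roi)$densityUmPerUm2
  d2 <- branchLengthDensity(skRot, roiRot)$densityUmPerUm2
  expect_equal(d2, d1, tolerance = 0.03)
})

test_that("egg summaries average ROI densities and pool junctions", {
  v <- suppressWarnings(synthVessels(treeSpec(seed = 2)))
  sk <- detectRidges(stretchContrast(greenChannel(v$image)), ridgeParams(),
                     2)
  rois <- sampleRois(dim(sk@skeleton), n = 10, sizePx = 64, seed = 21)
  ms <- lapply(rois, function(r) branchLengthDensity(sk, r))
  one <- eggSummary(ms[1], eggId = "e1", group = "TEC")
  expect_equal(one$meanDensityUmPerUm2, ms[[1]]$densityUmPerUm2)
  s <- eggSummary(ms, eggId = "e1", group = "TEC")
  expect_equal(s$meanDensityUmPerUm2,
               mean(vapply(ms, `[[`, numeric(1), "densityUmPerUm2")))
  expect_equal(s$junctionsPerUm2,
               sum(vapply(ms, `[[`, numeric(1), "nJunctions")) /
                 sum(vapply(ms, `[[`, numeric(1), "roiAreaUm2")))
  expect_error(eggSummary(list()), "ROI")
})

test_that("group mean densities preserve a constructed density ordering", {
  groups <- list(intact = 1, scaffold = 2, TEC = 3)
  means <- vapply(names(groups), function(gname) {
    dens <- vapply(1:2, function(i) {
      sp <- vesselSpec(seed = 100 * groups[[gname]] + i,
                       nRoots = groups[[gname]],
                       branchProb = 0.02 * groups[[gname]])
      v <- suppressWarnings(synthVessels(sp))
      sk <- detectRidges(stretchContrast(greenChannel(v$image)),
                         ridgeParams(), 2)
      branchLengthDensity(sk, rectRoi(1, 1, 256, 256))$densityUmPerUm2
    }, numeric(1))
    mean(dens)
  }, numeric(1))
  expect_true(means[["intact"]] < means[["scaffold"]])
  expect_true(means[["scaffold"]] < means[["TEC"]])
})

test_that("ECDFs match brute-force counting", {
  f1 <- ecdfStep(5)
  expect_equal(f1(4.999), 0); expect_equal(f1(5), 1)
  fdup <- ecdfStep(c(1, 2, 2, 3))
  expect_equal(fdup(2) - fdup(1.999), 0.5)   # jump of 2/n at the tie
  x <- c(3.2, -1, 7, 0.5, 3.2)
  f <- ecdfStep(x)
  for (v in sort(unique(x)))
    expect_equal(f(v), mean(x <= v))
  # monotone, ends at 1
  grid <- seq(-2, 8, by = 0.25)
  expect_true(all(diff(f(grid)) >= 0))
  expect_equal(f(max(x)), 1)
  expect_error(ecdfStep(numeric(0)), "value")
})

test_that("KS statistic and p-value match exhaustive enumeration", {
  expect_equal(ksTwoSample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ksTwoSample(c(1, 2), c(3, 4))$D, 1)
  withr::with_seed(42, {
    for (i in 1:4) {
      x <- round(rnorm(sample(3:5, 1)), 6)
      y <- round(rnorm(sample(3:5, 1)) + 0.5, 6)
      res <- ksTwoSample(x, y)
      expect_equal(res$p, ksEnumP(x, y), tolerance = 1e-8,
                   label = paste("KS enumeration, case", i))
    }
  })
})

test_that("Mann-Whitney U and p match exhaustive enumeration", {
  expect_equal(mannWhitney(1:4, 1:4)$U, 4 * 4 / 2)  # identical multisets
  expect_equal(mannWhitney(11:14, 1:4)$U, 16)       # full separation
  withr::with_seed(7, {
    for (i in 1:4) {
      x <- round(rnorm(4), 6)
      y <- round(rnorm(4) + 0.3, 6)
      res <- mannWhitney(x, y)
      expect_equal(res$p, mwEnumP(x, y), tolerance = 1e-10,
                   label = paste("MW enumeration, case", i))
    }
  })
})
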