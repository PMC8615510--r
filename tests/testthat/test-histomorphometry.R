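# Section morphometry: blur, stain separation, segmentation, hull
# circularity, cellularity, invasion depth, compartments.

test_that("preblur is an identity at sigma 0 and preserves constants", {
  img <- matrix(runif(400), 20, 20)
  expect_identical(preblur(img, 0, 1), img)
  const <- matrix(0.4, 30, 30)
  expect_equal(preblur(const, 3, 1), const, tolerance = 1e-12)
  expect_error(preblur(img, 10, 1), "exceeds")
})

test_that("preblur impulse response matches the sampled 2D Gaussian", {
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  out <- preblur(imp, 2, 1)   # sigma_px = 2
  expect_equal(sum(out), 1, tolerance = 1e-12)
  r <- 8L
  x <- seq(-r, r)
  g1 <- exp(-x^2 / (2 * 4)); g2d <- outer(g1, g1); g2d <- g2d / sum(g2d)
  expect_lt(max(abs(out[(21 - r):(21 + r), (21 - r):(21 + r)] - g2d)),
            1e-6)
})

test_that("deconvolution recovers pure-stain and background images", {
  M <- defaultStainMatrix()
  white <- array(1, c(6, 6, 3))
  sWhite <- deconvolveStains(white, M)
  expect_lt(max(sWhite@cells, sWhite@matrixChannel, sWhite@background),
            1e-5)
  # image painted with stain 1 at OD 0.7
  img <- array(0, c(6, 6, 3))
  for (ch in 1:3) img[, , ch] <- 10^(-0.7 * M[1, ch])
  s <- deconvolveStains(img, M)
  expect_equal(mean(s@cells), 0.7, tolerance = 1e-4)
  expect_lt(max(s@matrixChannel, s@background), 1e-4)
  expect_lt(s@residualNorm, 1e-6)
  # near-singular stain matrix is rejected
  bad <- M; bad[2, ] <- M[1, ] + c(1e-8, 0, 0); bad[2, ] <- bad[2, ] /
    sqrt(sum(bad[2, ]^2))
  expect_error(deconvolveStains(img, bad), "singular")
})

test_that("cell-stain mass concentrates on true cell pixels", {
  h <- synthHistology(histologySpec(noiseSd = 0.005, seed = 4))
  sep <- deconvolveStains(preblur(h$image, 0.65, 1))
  dil <- EBImage::dilate(h$truth$cellMask * 1, EBImage::makeBrush(7, "disc"))
  inMass <- sum(sep@cells[dil > 0])
  expect_gt(inMass / sum(sep@cells), 0.9)
})

test_that("segmentation finds isolated cells with accurate centroids", {
  expect_equal(sum(segmentCells(matrix(0, 50, 50))), 0)
  # two disjoint synthetic cells at fixed centres
  centers <- data.frame(row = c(40, 40), col = c(40, 120),
                        compartment = c("parenchymal", "parenchymal"))
  spec <- histologySpec(rows = 80, cols = 160, cellCount = c(2, 0),
                        axisRatio = c(1.3, 1), axisRatioSd = 0,
                        noiseSd = 0, marginPx = 0, seed = 6)
  h <- synthHistology(spec, centers = centers)
  sep <- deconvolveStains(h$image)
  labels <- segmentCells(sep@cells, 1)
  cells <- measureCells(labels, 1)
  expect_equal(nrow(cells), 2L)
  cells <- cells[order(cells$col), ]
  expect_lt(max(abs(cells$row - c(40, 40))), 1)
  expect_lt(max(abs(cells$col - c(40, 120))), 1)
  expect_error(segmentCells(matrix(1, 10, 10) + matrix(runif(100), 10),
                            threshold = -1), "background")
})

test_that("segmentation recall on a 100-cell section is at least 0.98", {
  spec <- histologySpec(rows = 420, cols = 420, cellCount = c(50, 50),
                        noiseSd = 0.01, seed = 8)
  h <- synthHistology(spec)
  res <- analyzeHistology(h$image, 1, h$sectionMask, h$compartmentMask)
  truthLab <- h$truth$labelImage
  hit <- 0L
  for (i in h$truth$cells$id) {
    tmask <- truthLab == i
    segIds <- res$labels[tmask]
    segIds <- segIds[segIds > 0]
    if (!length(segIds)) next
    j <- as.integer(names(which.max(table(segIds))))
    smask <- res$labels == j
    iou <- sum(tmask & smask) / sum(tmask | smask)
    if (iou >= 0.5) hit <- hit + 1L
  }
  expect_gte(hit / nrow(h$truth$cells), 0.98)
})

test_that("hull circularity matches closed forms for canonical shapes", {
  disk <- digitalDisk(30)
  expect_gte(hullCircularity(disk), 0.95)
  expect_lte(hullCircularity(disk), 1.0)
  sq <- matrix(FALSE, 60, 60); sq[11:50, 11:50] <- TRUE
  expect_equal(hullCircularity(sq), pi / 4, tolerance = 0.03)
  rect <- matrix(FALSE, 40, 220); rect[16:25, 11:110] <- TRUE
  expect_equal(hullCircularity(rect), 4 * pi * 10 / 22^2, tolerance = 0.03)
  # collinear region degenerates to 0 with a warning
  line <- matrix(FALSE, 10, 10); line[5, 2:9] <- TRUE
  expect_warning(c0 <- hullCircularity(line), "degenerate")
  expect_equal(c0, 0)
})

test_that("circularity is scale-invariant within discretization error", {
  rect <- matrix(FALSE, 60, 160); rect[21:40, 31:130] <- TRUE
  rect2 <- matrix(FALSE, 120, 320); rect2[41:80, 61:260] <- TRUE
  expect_lt(abs(hullCircularity(rect2) / hullCircularity(rect) - 1), 0.02)
})

test_that("morphotype classification applies the cutoff and tie rule", {
  expect_equal(classifyMorphotype(1.0, 0.99), "epithelioid")
  expect_equal(classifyMorphotype(0.2, 0.7), "mesenchymal-like")
  expect_equal(classifyMorphotype(0.7, 0.7), "epithelioid")  # tie rule
  expect_error(classifyMorphotype(0.5, 1.5), "cutoff")
})

test_that("Otsu circularity split recovers bimodal generator labels", {
  spec <- histologySpec(rows = 420, cols = 420, cellCount = c(50, 50),
                        axisRatio = c(1.1, 4), noiseSd = 0.01, seed = 12)
  h <- synthHistology(spec)
  res <- analyzeHistology(h$image, 1, h$sectionMask, h$compartmentMask,
                          circularityCutoff = "otsu")
  # match each truth cell to the measured cell at its centre
  truthLab <- h$truth$labelImage
  agree <- 0L; n <- 0L
  for (i in seq_len(nrow(h$truth$cells))) {
    tc <- h$truth$cells[i, ]
    lab <- res$labels[round(tc$row), round(tc$col)]
    if (lab == 0) next
    n <- n + 1L
    want <- if (tc$compartment == "parenchymal") "epithelioid"
    else "mesenchymal-like"
    if (res$cells$morphotype[res$cells$label == lab] == want)
      agree <- agree + 1L
  }
  expect_gte(n, 95L)
  expect_gte(agree / n, 0.95)
})

test_that("relative cellularity matches analytic truth and is monotone", {
  labs <- matrix(0L, 20, 20)
  section <- matrix(TRUE, 20, 20)
  expect_equal(relativeCellularity(labs, section), 0)
  labs[] <- 1L
  expect_equal(relativeCellularity(labs, section), 100)
  expect_error(relativeCellularity(labs, matrix(FALSE, 20, 20)), "empty")
  # synthetic truth within one percentage point
  h <- synthHistology(histologySpec(seed = 5))
  res <- analyzeHistology(h$image, 1, h$sectionMask, h$compartmentMask)
  expect_lt(abs(res$summary$relativeCellularityPct -
                  100 * h$truth$cellAreaFraction), 1)
  # adding cells can only increase cellularity
  labs2 <- res$labels
  labs2[1:5, 1:5] <- max(labs2) + 1L
  expect_gte(relativeCellularity(labs2, h$sectionMask),
             res$summary$relativeCellularityPct)
})

test_that("invasion depth equals distance from the section surface", {
  section <- digitalDisk(100, pad = 10)
  ctr <- 111
  # centroid on the surface: depth 0 (within quantization)
  surf <- invasionDepths(data.frame(row = ctr, col = ctr + 100), section, 1)
  expect_lte(surf$depthsUm, 1)
  # centre of a radius-100 disk: depth 100 within 1 px
  dcen <- invasionDepths(data.frame(row = ctr, col = ctr), section, 1)
  expect_equal(dcen$depthsUm, 100, tolerance = 0.011)
  # seeded known offsets from a flat surface
  flat <- matrix(FALSE, 120, 60); flat[21:120, ] <- TRUE
  offs <- c(5, 20, 60)
  d <- invasionDepths(data.frame(row = 20 + offs, col = 30), flat, 2)
  expect_equal(d$depthsUm, (offs - 1) * 2, tolerance = 2.01)
  # centroid outside the section is flagged
  out <- invasionDepths(data.frame(row = 5, col = 5), flat, 1)
  expect_true(is.na(out$depthsUm))
  expect_equal(out$summary$nOutside, 1L)
})

test_that("compartment assignment follows the centroid and majority rule", {
  labs <- matrix(0L, 40, 40); labs[10:14, 10:14] <- 1L
  cells <- measureCells(labs, 1)
  allPar <- matrix(1L, 40, 40)
  expect_equal(assignCompartments(cells, labs, allPar)$compartment,
               "parenchymal")
  allStr <- matrix(2L, 40, 40)
  expect_equal(assignCompartments(cells, labs, allStr)$compartment,
               "stromal")
  expect_error(assignCompartments(cells, labs, matrix(1L, 10, 10)),
               "shape")
  # synthetic: interior cells agree with the generator 100%
  h <- synthHistology(histologySpec(seed = 5))
  res <- analyzeHistology(h$image, 1, h$sectionMask, h$compartmentMask)
  tr <- h$truth$cells
  for (i in seq_len(nrow(tr))) {
    lab <- h$truth$labelImage[round(tr$row[i]), round(tr$col[i])]
    got <- res$cells$compartment[res$cells$label ==
                                   res$labels[round(tr$row[i]),
                                              round(tr$col[i])]]
    if (length(got) == 1L && got != "mixed")
      expect_equal(got, tr$compartment[i])
  }
})

test_that("morphotype fractions sum to 100% over classified cells", {
  h <- synthHistology(histologySpec(seed = 13))
  res <- analyzeHistology(h$image, 1, h$sectionMask, h$compartmentMask)
  for (comp in res$summary$perCompartment) {
    if (!is.na(comp$epithelioidPct))
      expect_equal(comp$epithelioidPct + comp$mesenchymalPct, 100,
                   tolerance = 1e-9)
  }
})
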