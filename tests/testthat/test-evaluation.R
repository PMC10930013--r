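test_that("image RMSE matches closed forms and a brute-force oracle", {
  a <- flatImage(100, 32)
  expect_equal(imageRMSE(a, a), 0)
  b <- ctImage(pixelData(a) + 10, 3.0, grid = gridSpec(a))
  expect_equal(imageRMSE(a, b), 10)
  set.seed(14)
  x <- matrix(rnorm(64^2, 0, 300), 64, 64)
  y <- matrix(rnorm(64^2, 0, 300), 64, 64)
  acc <- 0
  for (i in 1:64) for (j in 1:64) acc <- acc + (y[i, j] - x[i, j])^2
  expect_equal(imageRMSE(x, y), sqrt(acc / 64^2), tolerance = 1e-10)
  expect_error(imageRMSE(x, matrix(0, 32, 32)), "grid mismatch")
})

test_that("PSNR uses the reference peak over a base-10 log", {
  ref <- matrix(c(1000, rep(0, 99)), 10, 10)
  img <- ref + 10
  expect_equal(imagePSNR(img, ref), 40)           # 20 log10(1000/10)
  img2 <- ref + 5                                  # halved RMSE: +6.02 dB
  expect_equal(imagePSNR(img2, ref) - imagePSNR(img, ref), 20 * log10(2))
  expect_identical(imagePSNR(ref, ref), Inf)
})

test_that("ROI statistics use a two-sided Welch t-test at p < 0.01", {
  img <- flatImage(50, 64)
  set.seed(3)
  noisy <- ctImage(pixelData(img) + rnorm(64^2, 0, 10), 1.5,
                   grid = gridSpec(img))
  roi <- circleROI("c", c(0, 0), 30)
  # identical samples: p = 1, not significant
  st <- roiStats(noisy, roi, noisy)
  expect_equal(st$p, 1)
  expect_false(st$significant)
  # large offset: significant
  shifted <- ctImage(pixelData(noisy) + 50, 3.0, grid = gridSpec(img))
  expect_true(roiStats(noisy, roi, shifted)$significant)

  # closed-form Welch oracle on two small fixed samples
  v <- c(55.1, 52.3, 58.7, 49.9, 54.2, 56.8, 51.4, 53.0, 57.5, 50.6)
  w <- c(61.2, 59.8, 64.1, 58.3, 62.7, 60.0, 63.5, 59.1, 61.8, 62.2)
  sv <- var(v) / 10; sw <- var(w) / 10
  tstat <- (mean(v) - mean(w)) / sqrt(sv + sw)
  df <- (sv + sw)^2 / (sv^2 / 9 + sw^2 / 9)
  pWant <- 2 * pt(-abs(tstat), df)
  n <- 64
  mk <- function(vals) {
    px <- matrix(0, n, n)
    px[1:10, 1] <- vals
    ctImage(px, 1.5, grid = GridSpec(n, 220))
  }
  m <- matrix(FALSE, n, n); m[1:10, 1] <- TRUE
  st2 <- roiStats(mk(v), maskROI("ten", m), mk(w))
  expect_equal(st2$p, pWant, tolerance = 1e-12)
  expect_equal(st2$mean, mean(v))
  expect_equal(st2$sd, sd(v))
  expect_error(roiStats(mk(v), circleROI("far", c(500, 500), 1)), "empty ROI")
})

test_that("calcification mask applies the inclusive 130 HU threshold", {
  px <- matrix(60, 16, 16)
  px[4, 4] <- 130; px[5, 5] <- 129.999; px[6, 6] <- 500
  img <- ctImage(px, 3.0, grid = GridSpec(16L, 220))
  m <- calcificationMask(img)
  expect_true(m[4, 4]); expect_false(m[5, 5]); expect_true(m[6, 6])
  expect_equal(sum(m), 2L)
  expect_equal(sum(calcificationMask(flatImage(60, 16))), 0L)
})

test_that("noise-free calcification mask area matches the disc geometry", {
  img <- qrmRaster512()
  spec <- makePhantomSpec("QRM_S")
  g <- fullGrid()
  psz <- pixelSpacing(g)
  ins <- insertTable(spec)
  for (lb in c("ha_800_d5mm", "ha_800_d3mm", "ha_200_d5mm")) {
    row <- ins[ins$label == lb, ]
    roi <- circleROI(lb, c(row$cx, row$cy), row$diameter / 2 + 2,
                     kind = "calcification")
    area <- sum(calcificationMask(img, roi))
    discPx <- pi * (row$diameter / 2)^2 / psz^2
    perimPx <- pi * row$diameter / psz
    expect_lt(abs(area - discPx), perimPx)  # within one pixel of perimeter
  }
})

test_that("Dice coefficient satisfies its defining identities", {
  a <- matrix(FALSE, 10, 10); a[1:5, 1:4] <- TRUE
  b <- matrix(FALSE, 10, 10); b[1:5, 3:6] <- TRUE
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(a, !a), 0)
  expect_equal(diceCoefficient(a, b), 0.5)   # |A|=|B|=20, overlap 10
  expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
  none <- matrix(FALSE, 10, 10)
  expect_equal(diceCoefficient(none, none), 1)
  expect_error(diceCoefficient(a, matrix(FALSE, 5, 5)), "grid mismatch")
})

test_that("1-mm calcifications are excluded from evaluation", {
  ins <- insertTable(makePhantomSpec("QRM_S"))
  kept <- filterSmallCalcifications(ins)
  expect_equal(nrow(kept), 6L)
  expect_true(all(kept$diameter >= 3))
  expect_identical(filterSmallCalcifications(kept), kept)
  empty <- ins[0, ]
  expect_identical(filterSmallCalcifications(empty), empty)
})

test_that("Agatston weighting bins partition the HU axis", {
  expect_identical(agatstonWeight(c(129, 130, 150, 199, 200, 250, 299,
                                    300, 350, 399, 400, 450, 2000)),
                   c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L))
})

test_that("weighted pixel counts classify the calcification mask", {
  px <- matrix(0, 32, 32)
  px[1, 1:10] <- 150
  img <- ctImage(px, 3.0, grid = GridSpec(32L, 220))
  ct <- countWeightedPixels(img)
  expect_equal(ct, data.frame(w1 = 10L, w2 = 0L, w3 = 0L, w4 = 0L,
                              total = 10L))
  expect_equal(countWeightedPixels(flatImage(0, 32))$total, 0L)
  # every mask pixel lands in exactly one bin
  pair <- qrmPair512()
  ctq <- countWeightedPixels(thickImage(pair))
  expect_equal(ctq$w1 + ctq$w2 + ctq$w3 + ctq$w4, ctq$total)
  # the densest calcification (HU > 400 at its core) fills bin 4
  img800 <- qrmRaster512()
  ins <- insertTable(makePhantomSpec("QRM_S"))
  row <- ins[ins$label == "ha_800_d5mm", ]
  roi <- circleROI("c", c(row$cx, row$cy), 5, kind = "calcification")
  expect_gt(countWeightedPixels(img800, roi)$w4, 0)
})

test_that("evaluation reports collect all tables and export cleanly", {
  pair <- qrmPair512()
  spec <- makePhantomSpec("QRM_S")
  rois <- defaultROIs(spec)
  expect_length(rois, 7L)  # background + 6 retained calcifications
  rep <- evaluateImages(list(I1.5mm = thinImage(pair)), thickImage(pair),
                        rois)
  expect_s4_class(rep, "EvalReport")
  expect_equal(nrow(rep@global), 1L)
  expect_true(all(c("mean", "sd", "p", "significant") %in%
                  names(rep@roiTable)))
  expect_equal(nrow(rep@diceTable), 6L)
  expect_true(all(rep@diceTable$dice >= 0 & rep@diceTable$dice <= 1))
  d <- file.path(tempdir(), "evalrep")
  exportEvalReport(rep, d)
  expect_true(file.exists(file.path(d, "global_metrics.csv")))
  expect_true(file.exists(file.path(d, "report.json")))
  parsed <- jsonlite::read_json(file.path(d, "report.json"),
                                simplifyVector = TRUE)
  expect_equal(nrow(parsed$agatston), 2L)
})
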