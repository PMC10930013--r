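test_that("grid geometry matches the CAC reconstruction protocol", {
  g <- fullGrid()
  expect_equal(round(pixelSpacing(g), 4), 0.4297)
  expect_equal(g@matrixSize, 512L)
})

test_that("phantom specifications expose the documented geometry", {
  s <- makePhantomSpec("CIRS_S", 0)
  expect_equal(nrow(insertTable(s)), 9L)
  expect_equal(s@bodyAxesMm, c(180, 180))
  expect_true(all(insertTable(s)$diameter == 30))

  m <- makePhantomSpec("QRM_M")
  ins <- insertTable(m)
  expect_equal(nrow(ins), 9L)
  expect_equal(m@bodyAxesMm, c(350, 250))
  expect_equal(sort(unique(ins$diameter)), c(1, 3, 5))
  expect_equal(length(unique(ins$material)), 3L)

  expect_equal(makePhantomSpec("CIRS_L")@bodyAxesMm, c(320, 270))
  expect_error(makePhantomSpec("NOT_A_PHANTOM"), "unknown phantom")
  expect_error(makePhantomSpec("CIRS_S", 5), "configuration")
})

test_that("rod-removal configurations leave 9 - 2k rods", {
  for (k in 0:4)
    expect_equal(nrow(insertTable(makePhantomSpec("CIRS_S", k))), 9L - 2L * k)
  # removed rods vanish cumulatively: present sets are nested
  prev <- insertTable(makePhantomSpec("CIRS_M", 0))$label
  for (k in 1:4) {
    cur <- insertTable(makePhantomSpec("CIRS_M", k))$label
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # QRM phantoms ignore the configuration index
  expect_equal(insertTable(makePhantomSpec("QRM_S", 0)),
               insertTable(makePhantomSpec("QRM_S", 3)))
})

test_that("rasterisation reproduces reference HU values", {
  img <- cirsRaster512()
  px <- pixelData(img)
  # liver rod occupies the phantom centre; its core is the tabulated mean
  expect_equal(px[256, 256], 71.83)
  # far outside the body: air
  expect_equal(px[1, 1], -1000)
  # inside the body, away from all rods: body material exactly (water, 0 HU)
  g <- fullGrid()
  r <- round(256.5 - 40 / pixelSpacing(g))
  expect_equal(px[r, 256], 0)
  # removing a rod replaces its HU with the body material
  img4 <- rasterize(makePhantomSpec("CIRS_S", 4), g)
  gone <- setdiff(insertTable(makePhantomSpec("CIRS_S", 0))$label,
                  insertTable(makePhantomSpec("CIRS_S", 4))$label)
  ins <- insertTable(makePhantomSpec("CIRS_S", 0))
  for (lb in gone) {
    row <- ins[ins$label == lb, ]
    i <- round(256.5 + row$cy / pixelSpacing(g))
    j <- round(256.5 + row$cx / pixelSpacing(g))
    expect_equal(pixelData(img4)[i, j], 0)
  }
  # idempotent and seed-free
  expect_identical(pixelData(rasterize(makePhantomSpec("CIRS_S", 0), g)),
                   px)
})

test_that("partial volume blends boundary pixels", {
  img <- qrmRaster512()
  px <- pixelData(img)
  # boundary pixels of a 5-mm calcification take intermediate HU
  spec <- makePhantomSpec("QRM_S")
  ins <- insertTable(spec)
  row <- ins[ins$label == "ha_800_d5mm", ]
  g <- fullGrid()
  i <- round(256.5 + row$cy / pixelSpacing(g))
  j <- round(256.5 + row$cx / pixelSpacing(g))
  core <- px[i, j]
  expect_equal(core, materialTable(spec)$hu[
    materialTable(spec)$name == "ha_800"])
  halo <- px[(i - 8):(i + 8), (j - 8):(j + 8)]
  frac <- (halo - 41.65) / (core - 41.65)
  expect_true(any(frac > 0.05 & frac < 0.95))  # genuinely blended pixels
})

test_that("simulated pairs obey the stated noise physics", {
  pair <- cirsPair512()
  g <- fullGrid()
  thin <- pixelData(thinImage(pair)); thick <- pixelData(thickImage(pair))
  expect_equal(sliceThickness(thinImage(pair)), 1.5)
  expect_equal(sliceThickness(thickImage(pair)), 3.0)

  # calibrated thin/thick SD ratio in a muscle ROI: printed value ~1.35
  ins <- insertTable(makePhantomSpec("CIRS_S", 0))
  mr <- ins[ins$label == "muscle", ]
  m <- roiMask(circleROI("m", c(mr$cx, mr$cy), 10), g)
  ratio <- sd(thin[m]) / sd(thick[m])
  expect_gt(ratio, 1.35 * 0.85)
  expect_lt(ratio, 1.35 * 1.15)

  # zero-mean noise: ROI means agree with the material value
  expect_lt(abs(mean(thin[m]) - 56.77), 5)
  expect_lt(abs(mean(thick[m]) - 56.77), 5)

  # determinism: same seed gives bit-identical pairs
  p2 <- simulateScan(makePhantomSpec("CIRS_S", 0), g, z = 1.5, seed = 7)
  expect_identical(pixelData(thinImage(p2)), thin)
  expect_identical(pixelData(thickImage(p2)), thick)
})

test_that("the 3-mm image is exactly the mean of its thin stack", {
  spec <- makePhantomSpec("CIRS_S", 2)
  pair <- simulateScan(spec, coarseGrid(128L), z = 1.0, seed = 5,
                       keepStack = TRUE)
  st <- attr(pair, "stack")
  expect_equal(dim(st)[3], 3L)
  expect_identical(pixelData(thickImage(pair)),
                   (st[, , 1] + st[, , 2] + st[, , 3]) / 3)
  expect_identical(pixelData(thinImage(pair)), st[, , 1])
})

test_that("zero noise amplitude reproduces the rasterisation", {
  spec <- makePhantomSpec("CIRS_S", 0)
  g <- coarseGrid(128L)
  pair <- simulateScan(spec, g, z = 1.5, seed = 9, noiseScale = 0)
  ideal <- pixelData(rasterize(spec, g))
  expect_identical(pixelData(thinImage(pair)), ideal)
  expect_identical(pixelData(thickImage(pair)), ideal)
})

test_that("independent-slice noise SD scales as 1/sqrt(z)", {
  spec <- makePhantomSpec("CIRS_S", 4)   # one central rod, wide water field
  g <- fullGrid()
  roi <- roiMask(circleROI("w", c(0, -45), 28), g)
  expect_gt(sum(roi), 1e4)
  sdRef <- materialTable(spec)$sd3mm[materialTable(spec)$name == "water"]
  for (z in c(0.5, 1.0, 1.5)) {
    p <- simulateScan(spec, g, z = z, seed = 11 + z * 10, rho = 0)
    expect_lt(abs(sd(pixelData(thinImage(p))[roi]) /
                  (sdRef * sqrt(3 / z)) - 1), 0.05)
    expect_lt(abs(sd(pixelData(thickImage(p))[roi]) / sdRef - 1), 0.05)
  }
})

test_that("acquisition protocol yields 5 datasets per phantom", {
  g <- coarseGrid()
  all3 <- acquisitionProtocol(c("CIRS_S", "CIRS_M", "CIRS_L"), z = 1.5,
                              baseSeed = 3, grid = g)
  expect_length(all3, 15L)
  one <- acquisitionProtocol("CIRS_S", z = 1.5, baseSeed = 3, grid = g)
  expect_length(one, 5L)
  expect_named(one, sprintf("CIRS_S_cfg%d", 0:4))
  # same base seed -> bit-identical datasets
  one2 <- acquisitionProtocol("CIRS_S", z = 1.5, baseSeed = 3, grid = g)
  expect_identical(lapply(one, function(p) pixelData(thinImage(p))),
                   lapply(one2, function(p) pixelData(thinImage(p))))
  expect_error(acquisitionProtocol(c("CIRS_S", "QRM_S"), z = 1.5,
                                   baseSeed = 1, grid = g),
               "electron density phantoms only")
})
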