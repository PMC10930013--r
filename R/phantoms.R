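#' @include accessors.R
NULL

# Reference material tables.
#
# Mean HU and noise SD (3-mm reconstruction at each phantom's reference tube
# current) of the rod inserts of the three electron density phantom sizes and
# of the thorax phantom background, as measured on the scanner the method was
# calibrated on. The calcification entries use the measured mean HU of each
# hydroxyapatite (HA) density; their noise SD is set bone-like (40 HU), since
# the spread of HU inside a thresholded calcification ROI is dominated by the
# partial-volume gradient rather than by quantum noise.
.CIRS_MATERIALS <- list(
  CIRS_S = data.frame(
    name = c("lung_inhale", "lung_exhale", "adipose", "breast", "muscle",
             "liver", "bone_200", "bone_800", "bone_1250"),
    hu = c(-829.59, -481.16, -72.86, -25.93, 56.77, 71.83,
           257.64, 1037.05, 1577.16),
    sd3mm = c(22.87, 27.53, 27.69, 27.80, 25.29, 24.31,
              37.71, 40.51, 42.04)),
  CIRS_M = data.frame(
    name = c("lung_inhale", "lung_exhale", "adipose", "breast", "muscle",
             "liver", "bone_200", "bone_800", "bone_1250"),
    hu = c(-822.11, -467.80, -68.26, -22.65, 44.62, 73.83,
           274.56, 955.10, 1532.88),
    sd3mm = c(25.07, 27.58, 32.70, 29.55, 31.71, 28.49,
              40.76, 40.85, 43.65)),
  CIRS_L = data.frame(
    name = c("lung_inhale", "lung_exhale", "adipose", "breast", "muscle",
             "liver", "bone_200", "bone_800", "bone_1250"),
    hu = c(-792.05, -463.03, -64.57, -1.10, 54.83, 78.95,
           289.87, 924.29, 1437.49),
    sd3mm = c(29.97, 27.22, 38.76, 30.99, 38.07, 34.16,
              44.79, 42.09, 48.52)))

.QRM_BACKGROUND <- data.frame(
  name = c("QRM_S", "QRM_M", "QRM_L"),
  hu = c(41.65, 40.26, 47.33),
  sd3mm = c(22.77, 21.77, 21.33))

.QRM_CALC_HU <- list(
  QRM_S = c(ha_200 = 243.41, ha_400 = 372.45, ha_800 = 611.27),
  QRM_M = c(ha_200 = 231.04, ha_400 = 368.88, ha_800 = 591.05),
  QRM_L = c(ha_200 = 225.72, ha_400 = 348.57, ha_800 = 566.63))

.PHANTOM_BODY <- list(
  CIRS_S = list(shape = "circle",  axes = c(180, 180), mA = 40),
  CIRS_M = list(shape = "circle",  axes = c(230, 230), mA = 80),
  CIRS_L = list(shape = "ellipse", axes = c(320, 270), mA = 300),
  QRM_S  = list(shape = "ellipse", axes = c(300, 200), mA = 40),
  QRM_M  = list(shape = "ellipse", axes = c(350, 250), mA = 50),
  QRM_L  = list(shape = "ellipse", axes = c(400, 300), mA = 140))

.AIR <- data.frame(name = "air", hu = -1000, sd3mm = 12)

#' Phantom names known to the simulator
#' @return character vector of the six phantom names
#' @export
phantomNames <- function() names(.PHANTOM_BODY)

#' Build a phantom specification
#'
#' Electron density phantoms (CIRS_S/M/L) carry 9 tissue-equivalent rod
#' inserts, 30 mm in diameter and 50 mm long: one central rod and eight on a
#' 60-mm ring. The \code{configuration} index emulates the rod-removal
#' acquisition protocol used to build training data: configuration 0 has all
#' 9 rods, and each increment removes the next designated opposite pair of
#' ring rods, leaving 9 - 2k rods at configuration k (the central rod is never
#' removed; which pair goes at each step is a fixed, documented convention of
#' this simulator). Thorax phantoms (QRM_S/M/L) carry a calibration insert
#' with nine cylindrical calcifications, 3 sizes (1, 3, 5 mm in diameter and
#' height) x 3 HA densities (200, 400, 800 mg/cc), on a 30-mm ring; they
#' ignore \code{configuration}.
#'
#' @param name one of \code{phantomNames()}.
#' @param configuration rod-removal index 0..4 (CIRS only).
#' @return a \linkS4class{PhantomSpec}
#' @examples
#' spec <- makePhantomSpec("CIRS_S", 0)
#' nrow(insertTable(spec))  # 9
#' @export
makePhantomSpec <- function(name, configuration = 0L) {
  if (!name %in% phantomNames())
    stop("unknown phantom name: ", name)
  configuration <- as.integer(configuration)
  body <- .PHANTOM_BODY[[name]]
  cirs <- startsWith(name, "CIRS")
  if (cirs && (configuration < 0L || configuration > 4L))
    stop("configuration must be in 0..4")
  if (!cirs) configuration <- 0L

  if (cirs) {
    mats <- rbind(.AIR,
                  data.frame(name = "water", hu = 0,
                             sd3mm = .CIRS_MATERIALS[[name]]$sd3mm[5]),
                  .CIRS_MATERIALS[[name]])
    ring <- .CIRS_MATERIALS[[name]]$name[-6]  # liver sits in the centre
    ang <- (0:7) * 45 * pi / 180
    inserts <- data.frame(
      label = c("liver", ring),
      kind = "rod", shape = "cylinder",
      cx = c(0, 60 * cos(ang)), cy = c(0, 60 * sin(ang)),
      diameter = 30, height = 50,
      material = c("liver", ring),
      removalRank = c(NA_integer_, (0:7) %% 4L + 1L))
    inserts$present <- is.na(inserts$removalRank) |
      inserts$removalRank > configuration
    bodyMat <- "water"
  } else {
    bg <- .QRM_BACKGROUND[.QRM_BACKGROUND$name == name, ]
    calcs <- .QRM_CALC_HU[[name]]
    mats <- rbind(.AIR,
                  data.frame(name = "soft_tissue", hu = bg$hu,
                             sd3mm = bg$sd3mm),
                  data.frame(name = names(calcs), hu = unname(calcs),
                             sd3mm = 40))
    dens <- rep(names(calcs), each = 3)
    dia <- rep(c(1, 3, 5), times = 3)
    ang <- (0:8) * 40 * pi / 180
    inserts <- data.frame(
      label = paste0(dens, "_d", dia, "mm"),
      kind = "calcification", shape = "cylinder",
      cx = 30 * cos(ang), cy = 30 * sin(ang),
      diameter = dia, height = dia,
      material = dens,
      removalRank = NA_integer_, present = TRUE)
    bodyMat <- "soft_tissue"
  }
  new("PhantomSpec", name = name, bodyShape = body$shape,
      bodyAxesMm = as.numeric(body$axes), bodyMaterial = bodyMat,
      materials = mats, inserts = inserts, tubeCurrent = body$mA,
      configuration = configuration)
}

# 4x4 block mean of a 4p x 4q matrix down to p x q
.blockMean4 <- function(m, p, q) {
  m1 <- matrix(colMeans(matrix(m, nrow = 4L)), nrow = p)    # pool rows
  t(matrix(colMeans(matrix(t(m1), nrow = 4L)), nrow = q))   # pool columns
}

# area coverage of an ellipse (full axes a, b, centre cx, cy in mm) per
# pixel, via 4x supersampled area weighting (16 subsamples per pixel);
# evaluated only inside the primitive's bounding box
.coverageEllipse <- function(grid, cx, cy, a, b) {
  n <- grid@matrixSize
  ps <- pixelSpacing(grid)
  sub <- (seq_len(4L * n) - (4L * n + 1) / 2) * ps / 4
  out <- matrix(0, n, n)
  snap <- function(idx) {
    if (!length(idx)) return(integer(0))
    seq.int(((min(idx) - 1L) %/% 4L) * 4L + 1L,
            ((max(idx) - 1L) %/% 4L) * 4L + 4L)
  }
  ix <- snap(which(abs(sub - cx) <= a / 2 + ps))  # columns (x)
  iy <- snap(which(abs(sub - cy) <= b / 2 + ps))  # rows (y)
  if (!length(ix) || !length(iy)) return(out)
  inside <- outer(((sub[iy] - cy) / (b / 2))^2,
                  ((sub[ix] - cx) / (a / 2))^2, "+") <= 1
  p <- length(iy) %/% 4L; q <- length(ix) %/% 4L
  out[seq.int((iy[1] - 1L) %/% 4L + 1L, length.out = p),
      seq.int((ix[1] - 1L) %/% 4L + 1L, length.out = q)] <-
    .blockMean4(inside, p, q)
  out
}

# internal rasteriser: noise-free HU plus the 3-mm-anchor noise-SD field
.rasterFields <- function(spec, grid) {
  stopifnot(is(spec, "PhantomSpec"), is(grid, "GridSpec"))
  mats <- spec@materials
  mhu <- stats::setNames(mats$hu, mats$name)
  msd <- stats::setNames(mats$sd3mm, mats$name)
  bhu <- mhu[[spec@bodyMaterial]]; bsd <- msd[[spec@bodyMaterial]]

  covb <- .coverageEllipse(grid, 0, 0, spec@bodyAxesMm[1], spec@bodyAxesMm[2])
  hu <- mhu[["air"]] + covb * (bhu - mhu[["air"]])
  varmap <- msd[["air"]]^2 + covb * (bsd^2 - msd[["air"]]^2)

  ins <- insertTable(spec, presentOnly = TRUE)
  for (i in seq_len(nrow(ins))) {
    covi <- .coverageEllipse(grid, ins$cx[i], ins$cy[i],
                             ins$diameter[i], ins$diameter[i])
    hu <- hu + covi * (mhu[[ins$material[i]]] - bhu)
    varmap <- varmap + covi * (msd[[ins$material[i]]]^2 - bsd^2)
  }
  list(hu = hu, sd3mm = sqrt(varmap))
}

#' Rasterise a phantom to a noise-free HU image
#'
#' Each pixel takes the HU of the innermost containing primitive; pixels
#' outside the body are air (-1000 HU). Material boundaries are handled by
#' 4x supersampled area-weighted blending, so small calcifications (1-5 mm,
#' about 2-12 pixels across) carry realistic in-plane partial-volume
#' gradients. Rasterisation is deterministic and seed-independent.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param grid a \linkS4class{GridSpec}.
#' @return a \linkS4class{CTImage} with \code{sliceThickness} NA (ideal image)
#' @export
rasterize <- function(spec, grid = GridSpec()) {
  f <- .rasterFields(spec, grid)
  ctImage(f$hu, thicknessMm = NA_real_, grid = grid,
          tubeCurrent = spec@tubeCurrent,
          provenance = sprintf("rasterized %s cfg %d", spec@name,
                               spec@configuration))
}

# zero-mean, unit-variance spatially correlated Gaussian field: white noise
# low-pass filtered in Fourier space with an isotropic Gaussian transfer
# function (FWHM in pixels), then normalised analytically to unit variance
.correlatedField <- function(n, fwhmPx = 2) {
  white <- matrix(stats::rnorm(n * n), n, n)
  if (fwhmPx <= 0) return(white)
  sigma <- fwhmPx / (2 * sqrt(2 * log(2)))
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  tf <- exp(-2 * pi^2 * sigma^2 * outer(f^2, f^2, "+"))
  filt <- Re(stats::fft(stats::fft(white) * tf, inverse = TRUE)) / n^2
  filt / sqrt(mean(tf^2))
}

#' Simulate a paired thin / 3-mm acquisition
#'
#' Generates \code{n = 3/z} thin-slice noise realisations of the rasterised
#' phantom; the thin image is the first realisation and the 3-mm image is the
#' exact pixelwise mean of all \code{n} realisations (thin and thick share
#' the noise-free content). Each realisation's noise is a zero-mean,
#' spatially correlated Gaussian field whose local SD follows the quantum
#' noise law \code{sd3mm * sqrt(3 * mA_ref / (z * mA))} per material.
#' Adjacent thin slices share a fraction \code{rho} of their noise variance
#' (a common low-frequency field), which reproduces the measured thin/3-mm SD
#' ratios; \code{rho = 0} is the independent-slice mode in which the SD
#' scales exactly as \code{1/sqrt(z)}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param grid a \linkS4class{GridSpec}.
#' @param z thin slice thickness (mm), one of 0.5, 1.0, 1.5.
#' @param seed integer seed; the pair is deterministic given the seed.
#' @param rho inter-slice shared-variance fraction in [0, 1); default 0.10
#'   reproduces the calibrated 1.5-mm SD ratio of about 1.35.
#' @param fwhmPx FWHM (pixels) of the noise autocorrelation kernel.
#' @param tubeCurrent tube current (mA); defaults to the phantom's reference.
#' @param noiseScale global multiplier on all noise SDs (0 gives the
#'   noise-free pair).
#' @param keepStack attach the full realisation stack as attribute
#'   \code{"stack"} of the returned pair (for auditing the thick = mean
#'   identity).
#' @return a \linkS4class{ScanPair}
#' @export
simulateScan <- function(spec, grid = GridSpec(), z, seed, rho = 0.10,
                         fwhmPx = 2, tubeCurrent = NULL, noiseScale = 1,
                         keepStack = FALSE) {
  if (!z %in% c(0.5, 1.0, 1.5))
    stop("z must be one of 0.5, 1.0, 1.5 (a divisor of 3.0)")
  nslice <- as.integer(round(3.0 / z))
  if (abs(nslice * z - 3.0) > 1e-9) stop("3.0 is not divisible by z")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  mA <- if (is.null(tubeCurrent)) spec@tubeCurrent else tubeCurrent

  f <- .rasterFields(spec, grid)
  sdz <- f$sd3mm * sqrt(3 * spec@tubeCurrent / (z * mA)) * noiseScale

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  n <- grid@matrixSize
  shared <- .correlatedField(n, fwhmPx)
  stack <- vector("list", nslice)
  for (i in seq_len(nslice)) {
    own <- .correlatedField(n, fwhmPx)
    stack[[i]] <- f$hu + sdz * (sqrt(rho) * shared + sqrt(1 - rho) * own)
  }
  thickPx <- Reduce(`+`, stack) / nslice

  prov <- sprintf("simulated %s cfg %d seed %d", spec@name,
                  spec@configuration, seed)
  pair <- new("ScanPair",
    thin = ctImage(stack[[1L]], thicknessMm = z, grid = grid,
                   tubeCurrent = mA, seed = seed, provenance = prov),
    thick = ctImage(thickPx, thicknessMm = 3.0, grid = grid,
                    tubeCurrent = mA, seed = seed, provenance = prov))
  if (keepStack)
    attr(pair, "stack") <- array(unlist(stack), dim = c(n, n, nslice))
  pair
}

#' Run the rod-removal acquisition protocol
#'
#' Emulates the training-data acquisition: each electron density phantom is
#' scanned at configurations 0..4 (9, 7, 5, 3, 1 rods present), yielding
#' 5 datasets per phantom and 15 in total over the three phantom sizes.
#' Dataset i uses seed \code{baseSeed + i}, so every dataset is individually
#' regenerable.
#'
#' @param phantoms subset of \code{c("CIRS_S", "CIRS_M", "CIRS_L")}.
#' @param z thin slice thickness (mm).
#' @param baseSeed integer base seed.
#' @param grid a \linkS4class{GridSpec}.
#' @param ... passed on to \code{\link{simulateScan}}.
#' @return named list of \linkS4class{ScanPair} objects
#'   ("<phantom>_cfg<k>")
#' @export
acquisitionProtocol <- function(phantoms = c("CIRS_S", "CIRS_M", "CIRS_L"),
                                z, baseSeed, grid = GridSpec(), ...) {
  bad <- setdiff(phantoms, c("CIRS_S", "CIRS_M", "CIRS_L"))
  if (length(bad))
    stop("training protocol accepts electron density phantoms only, not: ",
         paste(bad, collapse = ", "))
  out <- list()
  i <- 0L
  for (ph in phantoms) {
    for (k in 0:4) {
      i <- i + 1L
      spec <- makePhantomSpec(ph, k)
      out[[sprintf("%s_cfg%d", ph, k)]] <-
        simulateScan(spec, grid, z, seed = baseSeed + i, ...)
    }
  }
  out
}
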