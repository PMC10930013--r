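#' @include accessors.R
NULL

.newNoiseMap <- function(values, role, parent) {
  new("NoiseMap", pixels = values, thicknessMm = parent@thicknessMm,
      tubeCurrent = parent@tubeCurrent, grid = parent@grid,
      seed = parent@seed,
      provenance = sprintf("%s noise map of [%s]", role, parent@provenance),
      role = role, z = parent@thicknessMm)
}

.sameGrid <- function(a, b) {
  a@grid@matrixSize == b@grid@matrixSize && a@grid@fovMm == b@grid@fovMm
}

#' Real noise map: thin minus 3-mm
#'
#' The training label of the residual-learning workflow. The sign convention
#' is \code{thin - thick}, so that subtracting the map from the thin image
#' recovers the 3-mm image exactly: \code{thin - realNoiseMap == thick}.
#'
#' @param thick the 3-mm \linkS4class{CTImage}.
#' @param thin the thin-slice \linkS4class{CTImage} (z in \{0.5, 1.0, 1.5\}).
#' @return a \linkS4class{NoiseMap} with role "real"
#' @export
realNoiseMap <- function(thick, thin) {
  if (!.sameGrid(thick, thin)) stop("grid mismatch between thin and thick")
  if (isTRUE(all.equal(thick@thicknessMm, thin@thicknessMm)))
    stop("thin and thick have the same slice thickness")
  if (!thin@thicknessMm %in% c(0.5, 1.0, 1.5))
    stop("thin slice thickness must be 0.5, 1.0 or 1.5 mm")
  .newNoiseMap(thin@pixels - thick@pixels, "real", thin)
}

#' 2x2 block-average downsampling
#'
#' Each output pixel is the arithmetic mean of its 2 x 2 source block, so a
#' 512 x 512 image becomes 256 x 256 and the global mean is preserved
#' exactly.
#'
#' @param image numeric matrix with even dimensions.
#' @return matrix of half the size
#' @export
blockDownsample <- function(image) {
  d <- dim(image)
  if (any(d %% 2L != 0L)) stop("blockDownsample requires even dimensions")
  p <- d[1] %/% 2L; q <- d[2] %/% 2L
  m1 <- matrix(colMeans(matrix(image, nrow = 2L)), nrow = p)
  t(matrix(colMeans(matrix(t(m1), nrow = 2L)), nrow = q))
}

# Keys cubic convolution kernel, a = -0.5
.keys <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * (x^3 - 5 * x^2 + 8 * x - 4), 0))
}

# 1-D 2x upsampling operator (2n x n matrix), half-pixel-centre alignment:
# output sample t (0-based) interpolates source coordinate (t + 0.5)/2 - 0.5.
# Border taps are clamped to the edge sample (edge replication).
.upsampleOperator <- function(n) {
  W <- matrix(0, 2L * n, n)
  for (t in 0:(2L * n - 1L)) {
    s <- (t + 0.5) / 2 - 0.5
    base <- floor(s)
    for (j in (base - 1):(base + 2)) {
      w <- .keys(s - j)
      jc <- min(max(j, 0), n - 1)          # edge replication
      W[t + 1L, jc + 1L] <- W[t + 1L, jc + 1L] + w
    }
  }
  W
}

#' Separable bicubic 2x upsampling
#'
#' Keys cubic convolution (a = -0.5) with half-pixel-centre alignment: the
#' mean of each 2 x 2 block of the output grid sits at the corresponding
#' source pixel centre, matching \code{\link{blockDownsample}}. Border
#' samples replicate the edge row/column. Constant images map to constant
#' images and linear ramps are reproduced away from the borders.
#'
#' @param image numeric matrix (n x n).
#' @return matrix of twice the size
#' @export
bicubicUpsample <- function(image) {
  d <- dim(image)
  Wr <- .upsampleOperator(d[1])
  Wc <- if (d[2] == d[1]) Wr else .upsampleOperator(d[2])
  Wr %*% image %*% t(Wc)
}

#' Pseudo noise map: thin minus its smoothed self
#'
#' The network input of the residual-learning workflow: the thin image is
#' 2x2-block-averaged to half the matrix size, bicubically upsampled back,
#' and subtracted from the original. In flat regions this is a high-pass
#' filtered view of the quantum noise; near edges it also carries the
#' smoothing residual of the anatomy.
#'
#' @param thin a thin-slice \linkS4class{CTImage} with even matrix size.
#' @return a \linkS4class{NoiseMap} with role "pseudo"
#' @export
pseudoNoiseMap <- function(thin) {
  smooth <- bicubicUpsample(blockDownsample(thin@pixels))
  .newNoiseMap(thin@pixels - smooth, "pseudo", thin)
}

#' Cut co-located patch pairs from an input/label map pair
#'
#' Patches tile the maps from the origin with the given stride; a 512 x 512
#' map yields a 20 x 20 grid of 25 x 25 patches (400 pairs), discarding the
#' residual 12-pixel right/bottom margin. Input and label patches are
#' co-located, and the provenance table records the 1-based top-left pixel of
#' every patch.
#'
#' @param inputMap \linkS4class{NoiseMap} (typically role "pseudo").
#' @param labelMap \linkS4class{NoiseMap} on the same grid (role "real").
#' @param patch patch side length in pixels.
#' @param stride stride between patch origins in pixels.
#' @param dataset provenance label for the source map pair.
#' @return a \linkS4class{PatchSet}
#' @export
extractPatches <- function(inputMap, labelMap, patch = 25L, stride = 25L,
                           dataset = "dataset1") {
  if (!.sameGrid(inputMap, labelMap)) stop("grid mismatch between maps")
  n <- nrow(inputMap@pixels)
  patch <- as.integer(patch); stride <- as.integer(stride)
  if (patch > n) stop("patch larger than the matrix")
  if (stride < 1L) stop("stride must be >= 1")
  origins <- seq.int(1L, n - patch + 1L, by = stride)
  k <- length(origins)^2
  inputs <- array(0, c(patch, patch, k))
  labels <- array(0, c(patch, patch, k))
  prov <- data.frame(dataset = character(k), row = integer(k),
                     col = integer(k))
  i <- 0L
  for (c0 in origins) for (r0 in origins) {
    i <- i + 1L
    rr <- r0:(r0 + patch - 1L); cc <- c0:(c0 + patch - 1L)
    inputs[, , i] <- inputMap@pixels[rr, cc]
    labels[, , i] <- labelMap@pixels[rr, cc]
    prov$dataset[i] <- dataset; prov$row[i] <- r0; prov$col[i] <- c0
  }
  new("PatchSet", inputs = inputs, labels = labels, patchSize = patch,
      stride = stride, shuffleSeed = NA_integer_, provenance = prov)
}

#' Concatenate patch sets
#'
#' @param ... \linkS4class{PatchSet} objects with equal patch size.
#' @return a single \linkS4class{PatchSet}
#' @export
combinePatchSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "PatchSet"))
    sets <- sets[[1L]]
  p <- sets[[1L]]@patchSize
  stopifnot(all(vapply(sets, function(s) s@patchSize == p, logical(1))))
  new("PatchSet",
      inputs = array(unlist(lapply(sets, patchInputs)),
                     c(p, p, sum(vapply(sets, nPatches, integer(1))))),
      labels = array(unlist(lapply(sets, patchLabels)),
                     c(p, p, sum(vapply(sets, nPatches, integer(1))))),
      patchSize = p, stride = sets[[1L]]@stride,
      shuffleSeed = NA_integer_,
      provenance = do.call(rbind, lapply(sets, patchProvenance)))
}

#' Apply a seeded random permutation to a patch set
#'
#' Inputs, labels and provenance are permuted identically, so the multiset of
#' patch pairs is unchanged and the shuffle is reproducible from the seed.
#'
#' @param ps a \linkS4class{PatchSet}.
#' @param seed integer permutation seed.
#' @return the shuffled \linkS4class{PatchSet}
#' @export
shufflePatches <- function(ps, seed) {
  n <- nPatches(ps)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  perm <- sample.int(n)
  new("PatchSet", inputs = ps@inputs[, , perm, drop = FALSE],
      labels = ps@labels[, , perm, drop = FALSE],
      patchSize = ps@patchSize, stride = ps@stride,
      shuffleSeed = as.integer(seed),
      provenance = ps@provenance[perm, , drop = FALSE])
}
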