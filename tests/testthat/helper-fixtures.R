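# shared fixtures, memoised across test files within one run

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureEnv))
    assign(name, force(expr), envir = .fixtureEnv)
  get(name, envir = .fixtureEnv)
}

fullGrid <- function() GridSpec()                 # clinical 512 / 22 cm
coarseGrid <- function(n = 64L) GridSpec(n, 220)  # same FOV, coarse matrix

cirsRaster512 <- function()
  fixture("cirsRaster512", rasterize(makePhantomSpec("CIRS_S", 0), fullGrid()))

cirsPair512 <- function()
  fixture("cirsPair512",
          simulateScan(makePhantomSpec("CIRS_S", 0), fullGrid(), z = 1.5,
                       seed = 7))

qrmRaster512 <- function()
  fixture("qrmRaster512", rasterize(makePhantomSpec("QRM_S"), fullGrid()))

qrmPair512 <- function()
  fixture("qrmPair512",
          simulateScan(makePhantomSpec("QRM_S"), fullGrid(), z = 1.5,
                       seed = 401))

# a constant-valued CTImage
flatImage <- function(value, n = 64L, z = 1.5) {
  ctImage(matrix(value, n, n), thicknessMm = z, grid = GridSpec(n, 220))
}

# small synthetic training task shared by several tests: the label is a
# fixed linear map (0.5x) of the input, learnable by the network
.linearTask <- function(n = 256L, p = 15L, seed = 77) {
  set.seed(seed)
  inputs <- array(stats::rnorm(p * p * n, sd = 20), c(p, p, n))
  new("PatchSet", inputs = inputs, labels = inputs * 0.5,
      patchSize = p, stride = p, shuffleSeed = NA_integer_,
      provenance = data.frame(dataset = "linear", row = rep(1L, n),
                              col = rep(1L, n)))
}

# independent Keys bicubic oracle: direct kernel evaluation, double loop
bruteBicubic <- function(img) {
  keys <- function(x, a = -0.5) {
    x <- abs(x)
    if (x <= 1) (a + 2) * x^3 - (a + 3) * x^2 + 1
    else if (x < 2) a * (x^3 - 5 * x^2 + 8 * x - 4)
    else 0
  }
  n <- nrow(img)
  up1d <- function(v) {
    out <- numeric(2L * length(v))
    for (t in 0:(2L * length(v) - 1L)) {
      s <- (t + 0.5) / 2 - 0.5
      acc <- 0
      for (j in (floor(s) - 1):(floor(s) + 2)) {
        jc <- min(max(j, 0), length(v) - 1)
        acc <- acc + keys(s - j) * v[jc + 1]
      }
      out[t + 1] <- acc
    }
    out
  }
  half <- apply(img, 2, up1d)          # rows upsampled: 2n x n
  t(apply(half, 1, up1d))              # columns upsampled: 2n x 2n
}
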