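test_that("MSRA initialisation has variance 2/fan_in and zero biases", {
  cfg <- denseNetConfig(1L, 1L, 64L, 48L)   # wide layers for stable stats
  m <- buildDenseNet(cfg, seed = 10)
  ly <- m@layers[["b1l1"]]                  # 9 * 48 * 64 = 27 648 weights
  expect_gt(length(ly$W), 1e4)
  fanIn <- nrow(ly$W)
  expect_lt(abs(stats::var(as.vector(ly$W)) / (2 / fanIn) - 1), 0.05)
  expect_true(all(vapply(m@layers, function(l) all(l$b == 0), logical(1))))
  # deterministic given seed
  m2 <- buildDenseNet(cfg, seed = 10)
  expect_identical(m@layers, m2@layers)
  m3 <- buildDenseNet(cfg, seed = 11)
  expect_false(identical(m@layers[["init"]]$W, m3@layers[["init"]]$W))
})

test_that("a fresh model maps zero input to zero output", {
  m <- buildDenseNet(denseNetConfig(2L, 2L, 6L, 8L), seed = 2)
  out <- CACdenoise:::.forwardNet(m, array(0, c(25, 25, 1, 3)))$out
  expect_identical(max(abs(out)), 0)
})

test_that("rmse loss matches its closed forms and a brute-force oracle", {
  a <- array(stats::rnorm(5 * 5 * 1 * 4), c(5, 5, 1, 4))
  expect_equal(rmseLoss(a, a), 0)
  expect_equal(rmseLoss(a + 3.5, a), 3.5)
  b <- array(stats::rnorm(length(a)), dim(a))
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(rmseLoss(a, b), sqrt(acc / length(a)), tolerance = 1e-10)
  expect_error(rmseLoss(a, array(0, c(5, 5, 1, 2))), "shape mismatch")
})

test_that("analytic gradients agree with numerical differentiation", {
  cfg <- denseNetConfig(1L, 2L, 3L, 4L)
  m <- buildDenseNet(cfg, seed = 3)
  set.seed(5)
  x <- array(rnorm(7 * 7 * 2), c(7, 7, 1, 2))
  y <- array(rnorm(7 * 7 * 2), c(7, 7, 1, 2))
  fw <- CACdenoise:::.forwardNet(m, x, keep = TRUE)
  loss <- rmseLoss(fw$out, y)
  dout <- (fw$out - y) / (length(y) * loss)
  bw <- CACdenoise:::.backwardNet(m, dout, fw$cache)
  eps <- 1e-6
  for (nm in names(m@layers)) {
    for (idx in list(c(1L, 1L), c(2L, 1L))) {
      m2 <- m
      m2@layers[[nm]]$W[idx[1], idx[2]] <-
        m2@layers[[nm]]$W[idx[1], idx[2]] + eps
      lp <- rmseLoss(CACdenoise:::.forwardNet(m2, x)$out, y)
      m2@layers[[nm]]$W[idx[1], idx[2]] <-
        m2@layers[[nm]]$W[idx[1], idx[2]] - 2 * eps
      lm <- rmseLoss(CACdenoise:::.forwardNet(m2, x)$out, y)
      expect_equal(bw$grads[[nm]]$dW[idx[1], idx[2]], (lp - lm) / (2 * eps),
                   tolerance = 1e-5)
    }
    # bias gradient of the first output channel
    m2 <- m
    m2@layers[[nm]]$b[1] <- m2@layers[[nm]]$b[1] + eps
    lp <- rmseLoss(CACdenoise:::.forwardNet(m2, x)$out, y)
    m2@layers[[nm]]$b[1] <- m2@layers[[nm]]$b[1] - 2 * eps
    lm <- rmseLoss(CACdenoise:::.forwardNet(m2, x)$out, y)
    expect_equal(bw$grads[[nm]]$db[1], (lp - lm) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("training learns a linear input-label map", {
  ps <- .linearTask()
  m <- buildDenseNet(denseNetConfig(1L, 2L, 6L, 8L), seed = 4)
  st <- trainModel(m, ps, trainConfig(maxIterations = 400L,
                                      learningRate = 1e-3,
                                      evalInterval = 50L, seed = 9),
                   z = 1.5)
  lh <- lossHistory(st)
  expect_lt(utils::tail(lh$loss, 1), 0.2 * lh$loss[1])
  expect_true(all(diff(lh$iteration) > 0))
  expect_equal(st@model@z, 1.5)
})

test_that("zero learning rate leaves the loss trajectory constant", {
  ps <- .linearTask(n = 64L)
  m <- buildDenseNet(denseNetConfig(1L, 1L, 4L, 6L), seed = 4)
  st <- trainModel(m, ps, trainConfig(maxIterations = 30L, learningRate = 0,
                                      batchSize = 64L,  # full batch
                                      evalInterval = 10L, seed = 9))
  expect_equal(diff(range(lossHistory(st)$loss)), 0)
  expect_identical(st@model@layers, m@layers)
})

test_that("training is deterministic and resumes from checkpoints exactly", {
  ps <- .linearTask(n = 128L)
  m <- buildDenseNet(denseNetConfig(1L, 2L, 4L, 6L), seed = 4)
  tc <- function(iters) trainConfig(maxIterations = iters,
                                    learningRate = 1e-3,
                                    evalInterval = 10L, seed = 13)
  full <- trainModel(m, ps, tc(40L))
  again <- trainModel(m, ps, tc(40L))
  expect_identical(full@model@layers, again@model@layers)

  half <- trainModel(m, ps, tc(20L))
  ck <- file.path(tempdir(), "resume.ckpt")
  writeCheckpoint(half, ck)
  back <- readCheckpoint(ck)
  expect_identical(back$model@layers, half@model@layers)
  resumed <- trainModel(back$model, ps, tc(20L), optState = back$optState)
  expect_identical(resumed@model@layers, full@model@layers)
  expect_equal(resumed@model@iteration, 40L)

  expect_error(trainModel(m, new("PatchSet",
                                 inputs = array(0, c(5, 5, 0)),
                                 labels = array(0, c(5, 5, 0)),
                                 patchSize = 5L, stride = 5L,
                                 shuffleSeed = NA_integer_,
                                 provenance = data.frame()),
                          tc(5L)),
               "empty PatchSet")
})

test_that("whole-image inference equals tiled inference with a halo", {
  m <- buildDenseNet(denseNetConfig(1L, 2L, 4L, 6L), seed = 6)
  set.seed(31)
  px <- matrix(rnorm(64 * 64, sd = 25), 64, 64)
  whole <- CACdenoise:::.forwardNet(m, array(px, c(64, 64, 1, 1)))$out
  tiled <- CACdenoise:::.predictTiled(m, px, tile = 16L)
  expect_equal(matrix(whole, 64, 64), tiled, tolerance = 1e-10)
})

test_that("predictNoise evaluates the network on the pseudo map", {
  pair <- cirsPair512()
  thin <- thinImage(pair)
  # a model whose final layer is zeroed returns an all-zero map
  m <- buildDenseNet(denseNetConfig(1L, 1L, 4L, 6L), seed = 8)
  m@layers[["final"]]$W[] <- 0
  nm <- predictNoise(m, thin)
  expect_s4_class(nm, "NoiseMap")
  expect_equal(noiseRole(nm), "predicted")
  expect_identical(max(abs(pixelData(nm))), 0)
})
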