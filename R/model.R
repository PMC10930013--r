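#' @include accessors.R
#' @useDynLib CACdenoise, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Configuration of the dense noise-estimation network
#'
#' The network is a fully convolutional regressor with dense connectivity:
#' an initial 3x3 convolution to \code{initFeatures} channels, then
#' \code{nBlocks} dense blocks of \code{layersPerBlock} 3x3 convolutions each
#' producing \code{growthRate} channels and concatenating with everything
#' before them, a 1x1 transition convolution back to \code{initFeatures}
#' after each block, and a final 3x3 reconstruction convolution to one
#' channel. All convolutions use zero padding, so the output lives on the
#' input grid and a patch-trained model applies to whole slices without
#' tiling seams. The default is a desk-scale stand-in for the published
#' topology (about 0.1 M parameters), configurable upward.
#'
#' @param nBlocks number of dense blocks.
#' @param layersPerBlock 3x3 layers per block.
#' @param growthRate channels added by each dense layer.
#' @param initFeatures channels after the initial convolution and each
#'   transition.
#' @return a named list (class "denseNetConfig")
#' @export
denseNetConfig <- function(nBlocks = 4L, layersPerBlock = 4L,
                           growthRate = 12L, initFeatures = 16L) {
  stopifnot(nBlocks >= 1L, layersPerBlock >= 1L, growthRate >= 1L,
            initFeatures >= 1L)
  structure(list(nBlocks = as.integer(nBlocks),
                 layersPerBlock = as.integer(layersPerBlock),
                 growthRate = as.integer(growthRate),
                 initFeatures = as.integer(initFeatures),
                 kernel = 3L),
            class = "denseNetConfig")
}

# ordered layer geometry implied by a config
.layerPlan <- function(cfg) {
  plan <- list(list(name = "init", k = 3L, cin = 1L, cout = cfg$initFeatures,
                    relu = TRUE))
  for (b in seq_len(cfg$nBlocks)) {
    for (l in seq_len(cfg$layersPerBlock)) {
      cin <- cfg$initFeatures + (l - 1L) * cfg$growthRate
      plan[[length(plan) + 1L]] <-
        list(name = sprintf("b%dl%d", b, l), k = 3L, cin = cin,
             cout = cfg$growthRate, relu = TRUE)
    }
    plan[[length(plan) + 1L]] <-
      list(name = sprintf("trans%d", b), k = 1L,
           cin = cfg$initFeatures + cfg$layersPerBlock * cfg$growthRate,
           cout = cfg$initFeatures, relu = TRUE)
  }
  plan[[length(plan) + 1L]] <-
    list(name = "final", k = 3L, cin = cfg$initFeatures, cout = 1L,
         relu = FALSE)
  plan
}

#' Build and initialise a dense noise-estimation model
#'
#' Convolution weights are drawn from a zero-mean Gaussian with variance
#' \code{2 / fan_in} (MSRA initialisation for rectified networks, with
#' \code{fan_in = k * k * Cin}); all biases start at zero, so the freshly
#' initialised network maps an all-zero input to an all-zero output. The
#' initialisation is deterministic given the seed.
#'
#' @param cfg a \code{\link{denseNetConfig}}.
#' @param seed integer initialisation seed.
#' @return a \linkS4class{DenseNetModel}
#' @export
buildDenseNet <- function(cfg = denseNetConfig(), seed = 1L) {
  if (!inherits(cfg, "denseNetConfig")) stop("cfg must be a denseNetConfig")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  layers <- list()
  for (p in .layerPlan(cfg)) {
    fanIn <- p$k * p$k * p$cin
    layers[[p$name]] <- list(
      k = p$k, cin = p$cin, cout = p$cout, relu = p$relu,
      W = matrix(stats::rnorm(fanIn * p$cout, sd = sqrt(2 / fanIn)),
                 fanIn, p$cout),
      b = numeric(p$cout))
  }
  new("DenseNetModel", config = unclass(cfg), layers = layers,
      seed = as.integer(seed), iteration = 0L, z = NA_real_)
}

# columns-per-chunk heuristic keeping the im2col matrix around <= 64 MB
.chunkCols <- function(H, cin, k) {
  max(8L, min(4096L, as.integer(2^23 / max(1, H * k * k * cin))))
}

.convLayerFwd <- function(x, ly) {
  .conv_fwd(x, dim(x), ly$W, ly$b, ly$k,
            .chunkCols(dim(x)[1], ly$cin, ly$k))
}

.catChannels <- function(lst) {
  if (length(lst) == 1L) return(lst[[1L]])
  d <- dim(lst[[1L]])
  Cs <- vapply(lst, function(a) dim(a)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(Cs), d[4]))
  at <- 0L
  for (a in lst) {
    out[, , at + seq_len(dim(a)[3]), ] <- a
    at <- at + dim(a)[3]
  }
  out
}

.splitChannels <- function(a, widths) {
  out <- vector("list", length(widths))
  at <- 0L
  for (i in seq_along(widths)) {
    out[[i]] <- a[, , at + seq_len(widths[i]), , drop = FALSE]
    at <- at + widths[i]
  }
  out
}

# forward pass; x is (H, W, 1, N); returns list(out, cache)
.forwardNet <- function(model, x, keep = FALSE) {
  cfg <- model@config
  cache <- new.env(parent = emptyenv())
  conv <- function(name, inp) {
    ly <- model@layers[[name]]
    out <- .convLayerFwd(inp, ly)
    pre <- out
    if (ly$relu) out <- pmax(out, 0)
    if (keep) assign(name, list(input = inp, pre = pre), envir = cache)
    out
  }
  cur <- conv("init", x)
  for (b in seq_len(cfg$nBlocks)) {
    feats <- list(cur)
    for (l in seq_len(cfg$layersPerBlock))
      feats[[l + 1L]] <- conv(sprintf("b%dl%d", b, l), .catChannels(feats))
    cur <- conv(sprintf("trans%d", b), .catChannels(feats))
  }
  list(out = conv("final", cur), cache = cache)
}

# backward pass given d(loss)/d(out); returns list(grads, dx)
.backwardNet <- function(model, dout, cache) {
  cfg <- model@config
  grads <- list()
  bwd <- function(name, dY) {
    ly <- model@layers[[name]]
    ca <- get(name, envir = cache)
    if (ly$relu) dY <- dY * (ca$pre > 0)
    r <- .conv_bwd(ca$input, dim(ca$input), ly$W, dY, ly$k,
                   .chunkCols(dim(ca$input)[1], ly$cin, ly$k))
    grads[[name]] <<- list(dW = r$dW, db = r$db)
    r$dx
  }
  widths <- c(cfg$initFeatures, rep(cfg$growthRate, cfg$layersPerBlock))
  dcur <- bwd("final", dout)
  for (b in rev(seq_len(cfg$nBlocks))) {
    dfeats <- .splitChannels(bwd(sprintf("trans%d", b), dcur), widths)
    for (l in rev(seq_len(cfg$layersPerBlock))) {
      dinp <- bwd(sprintf("b%dl%d", b, l), dfeats[[l + 1L]])
      parts <- .splitChannels(dinp, widths[seq_len(l)])
      for (j in seq_len(l)) dfeats[[j]] <- dfeats[[j]] + parts[[j]]
    }
    dcur <- dfeats[[1L]]
  }
  list(dx = bwd("init", dcur), grads = grads)
}

#' Root-mean-square error loss in HU
#'
#' \code{sqrt(mean((predicted - label)^2))} over all pixels of the batch.
#'
#' @param predicted numeric array/matrix.
#' @param label numeric array/matrix of the same shape.
#' @return scalar RMSE (HU)
#' @export
rmseLoss <- function(predicted, label) {
  if (!identical(dim(predicted), dim(label)))
    stop("shape mismatch between predicted and label")
  sqrt(mean((predicted - label)^2))
}

#' Training hyperparameters
#'
#' Matches the published recipe: minibatch size 32, learning rate 1e-4,
#' first-moment decay 0.9 ("momentum" of the adaptive-moment optimiser),
#' weight decay 1e-4, RMSE loss. Weight decay is applied as decoupled L2 on
#' convolution weights only (not biases). The second-moment decay is fixed
#' at 0.999.
#'
#' @param maxIterations minibatch iterations to run.
#' @param batchSize patches per minibatch.
#' @param learningRate Adam step size.
#' @param beta1,beta2 Adam moment decays.
#' @param epsilon Adam numerical floor.
#' @param weightDecay decoupled L2 coefficient on convolution weights.
#' @param evalInterval record the minibatch loss every this many iterations.
#' @param seed seed for minibatch sampling.
#' @return a named list (class "trainConfig")
#' @export
trainConfig <- function(maxIterations = 100000L, batchSize = 32L,
                        learningRate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8, weightDecay = 1e-4,
                        evalInterval = 100L, seed = 1L) {
  stopifnot(batchSize >= 1L, learningRate >= 0, maxIterations >= 1L)
  structure(list(maxIterations = as.integer(maxIterations),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, weightDecay = weightDecay,
                 evalInterval = as.integer(evalInterval),
                 seed = as.integer(seed)),
            class = "trainConfig")
}

# minibatch of iteration t, derived deterministically from (seed, t) so that
# a resumed run continues the exact trajectory of an uninterrupted one
.batchIndices <- function(n, batchSize, seed, t) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed((seed + t) %% .Machine$integer.max)
  sample.int(n, min(batchSize, n), replace = batchSize > n)
}

#' Train a noise-estimation model on a patch set
#'
#' Minibatch optimisation of the RMSE loss with the adaptive-moment
#' optimiser. Minibatches are drawn by a counter-based seeded scheme, so
#' training is deterministic given the config seed and a run resumed from a
#' checkpoint at iteration k continues identically to an uninterrupted run.
#'
#' @param model a \linkS4class{DenseNetModel} (fresh or checkpointed).
#' @param ps a non-empty \linkS4class{PatchSet}.
#' @param tc a \code{\link{trainConfig}}.
#' @param z slice thickness (mm) this model is being trained for; recorded on
#'   the model and enforced at denoising time.
#' @param optState internal: optimiser state returned by a previous call
#'   (used when resuming).
#' @param verbose print the loss at every evaluation point.
#' @return a \linkS4class{TrainState}; the trained model is in
#'   \code{state@model} and the optimiser state in
#'   \code{attr(state, "optState")}
#' @export
trainModel <- function(model, ps, tc = trainConfig(), z = NA_real_,
                       optState = NULL, verbose = FALSE) {
  if (nPatches(ps) == 0L) stop("empty PatchSet")
  n <- nPatches(ps)
  p <- ps@patchSize
  layers <- model@layers
  if (is.null(optState))
    optState <- lapply(layers, function(ly)
      list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))

  hist_it <- integer(0); hist_loss <- numeric(0)
  t0 <- model@iteration
  for (t in (t0 + 1L):(t0 + tc$maxIterations)) {
    idx <- .batchIndices(n, tc$batchSize, tc$seed, t)
    x <- array(ps@inputs[, , idx], c(p, p, 1L, length(idx)))
    y <- array(ps@labels[, , idx], c(p, p, 1L, length(idx)))

    modelTmp <- model; modelTmp@layers <- layers
    fw <- .forwardNet(modelTmp, x, keep = TRUE)
    loss <- rmseLoss(fw$out, y)
    if (!is.finite(loss))
      stop(sprintf("non-finite loss at iteration %d", t))
    if (t == t0 + 1L || (t - t0) %% tc$evalInterval == 0L ||
        t == t0 + tc$maxIterations) {
      hist_it <- c(hist_it, t); hist_loss <- c(hist_loss, loss)
      if (verbose)
        message(sprintf("iter %6d  minibatch RMSE %8.4f HU", t, loss))
    }

    if (tc$learningRate > 0) {
      dout <- (fw$out - y) / (length(y) * max(loss, .Machine$double.eps))
      bw <- .backwardNet(modelTmp, dout, fw$cache)
      bc1 <- 1 - tc$beta1^t; bc2 <- 1 - tc$beta2^t
      for (nm in names(layers)) {
        g <- bw$grads[[nm]]; st <- optState[[nm]]
        st$mW <- tc$beta1 * st$mW + (1 - tc$beta1) * g$dW
        st$vW <- tc$beta2 * st$vW + (1 - tc$beta2) * g$dW^2
        st$mb <- tc$beta1 * st$mb + (1 - tc$beta1) * g$db
        st$vb <- tc$beta2 * st$vb + (1 - tc$beta2) * g$db^2
        layers[[nm]]$W <- layers[[nm]]$W -
          tc$learningRate * ((st$mW / bc1) / (sqrt(st$vW / bc2) + tc$epsilon) +
                             tc$weightDecay * layers[[nm]]$W)
        layers[[nm]]$b <- layers[[nm]]$b -
          tc$learningRate * (st$mb / bc1) / (sqrt(st$vb / bc2) + tc$epsilon)
        optState[[nm]] <- st
      }
    }
  }

  model@layers <- layers
  model@iteration <- t0 + tc$maxIterations
  if (!is.na(z)) model@z <- z
  state <- new("TrainState", model = model,
               lossHistory = data.frame(iteration = hist_it,
                                        loss = hist_loss),
               trainConfig = unclass(tc))
  attr(state, "optState") <- optState
  state
}

#' Predict the noise map of a thin slice
#'
#' Builds the pseudo noise map of the thin image and evaluates the network
#' fully convolutionally on the whole matrix (no tiling seams).
#'
#' @param model a trained \linkS4class{DenseNetModel}.
#' @param thin a thin-slice \linkS4class{CTImage}.
#' @return a \linkS4class{NoiseMap} with role "predicted"
#' @export
predictNoise <- function(model, thin) {
  pseudo <- pseudoNoiseMap(thin)
  n <- nrow(pseudo@pixels)
  x <- array(pseudo@pixels, c(n, n, 1L, 1L))
  out <- .forwardNet(model, x, keep = FALSE)$out
  .newNoiseMap(matrix(out, n, n), "predicted", thin)
}

# tile-wise inference with an explicit halo; interior values must agree with
# whole-image inference once the halo covers the receptive field
.predictTiled <- function(model, pixels, tile = 25L, halo = NULL) {
  cfg <- model@config
  nConv3 <- 1L + cfg$nBlocks * cfg$layersPerBlock + 1L
  if (is.null(halo)) halo <- nConv3  # receptive field radius
  n <- nrow(pixels)
  out <- matrix(NA_real_, n, n)
  for (r0 in seq.int(1L, n, by = tile)) for (c0 in seq.int(1L, n, by = tile)) {
    r1 <- min(n, r0 + tile - 1L); c1 <- min(n, c0 + tile - 1L)
    rr <- max(1L, r0 - halo):min(n, r1 + halo)
    cc <- max(1L, c0 - halo):min(n, c1 + halo)
    x <- array(pixels[rr, cc], c(length(rr), length(cc), 1L, 1L))
    y <- .forwardNet(model, x, keep = FALSE)$out
    out[r0:r1, c0:c1] <- matrix(y, length(rr), length(cc))[
      (r0 - rr[1] + 1L):(r1 - rr[1] + 1L), (c0 - cc[1] + 1L):(c1 - cc[1] + 1L)]
  }
  out
}

#' Write a model checkpoint
#'
#' Single-file container holding the weights, the model and training
#' configuration, the iteration counter and the optimiser state, so training
#' can resume bit-exactly.
#'
#' @param state a \linkS4class{TrainState} or \linkS4class{DenseNetModel}.
#' @param path file path.
#' @return the path, invisibly
#' @export
writeCheckpoint <- function(state, path) {
  if (is(state, "TrainState")) {
    model <- state@model
    payload <- list(model = list(config = model@config,
                                 layers = model@layers, seed = model@seed,
                                 iteration = model@iteration, z = model@z),
                    optState = attr(state, "optState"),
                    trainConfig = state@trainConfig,
                    lossHistory = state@lossHistory)
  } else {
    payload <- list(model = list(config = state@config, layers = state@layers,
                                 seed = state@seed,
                                 iteration = state@iteration, z = state@z),
                    optState = NULL, trainConfig = NULL, lossHistory = NULL)
  }
  payload$format <- "CACdenoise-checkpoint-1"
  saveRDS(payload, path)
  invisible(path)
}

#' Read a model checkpoint
#'
#' @param path file written by \code{\link{writeCheckpoint}}.
#' @return a list with elements \code{model} (\linkS4class{DenseNetModel}),
#'   \code{optState}, \code{trainConfig}, \code{lossHistory}
#' @export
readCheckpoint <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "CACdenoise-checkpoint-1"))
    stop("not a recognised checkpoint file: ", path)
  m <- payload$model
  model <- new("DenseNetModel", config = m$config, layers = m$layers,
               seed = m$seed, iteration = m$iteration, z = m$z)
  list(model = model, optState = payload$optState,
       trainConfig = payload$trainConfig, lossHistory = payload$lossHistory)
}
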