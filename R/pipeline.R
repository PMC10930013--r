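#' @include model.R evaluation.R
NULL

#' Subtract a noise map from a thin slice
#'
#' The workflow's subtraction step: \code{I_denoise = thin - map}. With the
#' real noise map this recovers the 3-mm image exactly (the oracle closure);
#' with the predicted map it is the denoised image.
#'
#' @param thin a thin-slice \linkS4class{CTImage}.
#' @param map a \linkS4class{NoiseMap} on the same grid.
#' @return a \linkS4class{CTImage}
#' @export
denoiseWithNoiseMap <- function(thin, map) {
  if (!.sameGrid(thin, map)) stop("grid mismatch between image and map")
  ctImage(thin@pixels - map@pixels, thicknessMm = thin@thicknessMm,
          grid = thin@grid, tubeCurrent = thin@tubeCurrent,
          seed = thin@seed,
          provenance = sprintf("denoised [%s] by %s map", thin@provenance,
                               map@role))
}

#' Denoise a thin slice with a trained model
#'
#' Predicts the noise map from the thin image and subtracts it. The model
#' must have been trained for the image's slice thickness; a mismatch is an
#' error, never silently ignored.
#'
#' @param thin a thin-slice \linkS4class{CTImage}.
#' @param model a trained \linkS4class{DenseNetModel}.
#' @return the denoised \linkS4class{CTImage}
#' @export
denoise <- function(thin, model) {
  if (model@iteration == 0L)
    stop("model has not been trained")
  if (!is.na(model@z) && !isTRUE(all.equal(model@z, thin@thicknessMm)))
    stop(sprintf("model was trained for z = %g mm but the image is %g mm",
                 model@z, thin@thicknessMm))
  denoiseWithNoiseMap(thin, predictNoise(model, thin))
}

#' Assemble a training patch set from simulated scan pairs
#'
#' For every pair, builds the pseudo noise map of the thin slice (network
#' input) and the real noise map (network label), cuts co-located 25 x 25
#' patches and concatenates them across datasets.
#'
#' @param pairs named list of \linkS4class{ScanPair} (e.g. from
#'   \code{\link{acquisitionProtocol}}).
#' @param patch,stride patch geometry in pixels.
#' @param shuffleSeed permutation seed applied to the combined set (NA skips
#'   the shuffle).
#' @return a \linkS4class{PatchSet}
#' @export
buildTrainingPatches <- function(pairs, patch = 25L, stride = 25L,
                                 shuffleSeed = NA_integer_) {
  nm <- names(pairs)
  if (is.null(nm)) nm <- sprintf("dataset%d", seq_along(pairs))
  sets <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    extractPatches(pseudoNoiseMap(thinImage(pr)),
                   realNoiseMap(thickImage(pr), thinImage(pr)),
                   patch = patch, stride = stride, dataset = nm[i])
  })
  ps <- combinePatchSets(sets)
  if (!is.na(shuffleSeed)) ps <- shufflePatches(ps, shuffleSeed)
  ps
}

.stageLog <- function(con, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE)), con)
}

.hashFile <- function(path) unname(tools::md5sum(path))

#' Default workflow configuration
#'
#' Describes one end-to-end run: simulate training data with the rod-removal
#' protocol, build and shuffle the patch set, train a per-thickness model,
#' denoise a held-out validation phantom and evaluate against its 3-mm
#' reference. The \code{profile = "ci"} scale (one training phantom, a small
#' dense network, a short optimisation) runs on one CPU in minutes; the
#' \code{"reference"} scale mirrors the published recipe (all three
#' phantoms, 100 000 iterations).
#'
#' @param mode one of "train", "denoise", "evaluate", "full".
#' @param z thin slice thickness (mm).
#' @param trainPhantoms electron density phantoms used for training.
#' @param validationPhantom thorax phantom used for validation.
#' @param seed master seed; all stage seeds derive from it.
#' @param profile "ci" or "reference".
#' @param outDir artifact directory.
#' @param modelPath existing checkpoint (modes "denoise"/"evaluate").
#' @return a named list (class "workflowConfig")
#' @export
workflowConfig <- function(mode = "full", z = 1.5,
                           trainPhantoms = "CIRS_S",
                           validationPhantom = "QRM_S",
                           seed = 1L, profile = c("ci", "reference"),
                           outDir = tempfile("cacdn_run_"),
                           modelPath = NULL) {
  profile <- match.arg(profile)
  stopifnot(mode %in% c("train", "denoise", "evaluate", "full"),
            z %in% c(0.5, 1.0, 1.5))
  structure(list(mode = mode, z = z, trainPhantoms = trainPhantoms,
                 validationPhantom = validationPhantom,
                 seed = as.integer(seed), profile = profile,
                 outDir = outDir, modelPath = modelPath),
            class = "workflowConfig")
}

#' Run the end-to-end denoising workflow
#'
#' Executes the requested stages in order (simulate, patches, train, denoise,
#' evaluate), writing every artifact plus a JSON-lines stage log and a
#' manifest with input hashes under \code{cfg$outDir}. A rerun with an
#' identical configuration reproduces identical artifacts.
#'
#' @param cfg a \code{\link{workflowConfig}} or the path of a YAML file with
#'   the same fields.
#' @return the manifest (named list), invisibly written as
#'   \code{manifest.json}
#' @export
runWorkflow <- function(cfg) {
  if (is.character(cfg)) {
    y <- yaml::read_yaml(cfg)
    cfg <- do.call(workflowConfig, y)
  }
  stopifnot(inherits(cfg, "workflowConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logCon <- file(file.path(cfg$outDir, "stages.jsonl"), open = "wt")
  on.exit(close(logCon))
  manifest <- list(config = unclass(cfg), artifacts = list())
  small <- cfg$profile == "ci"
  mcfg <- if (small) denseNetConfig(2L, 3L, 8L, 12L) else denseNetConfig()
  iters <- if (small) 800L else 100000L
  state <- NULL

  if (cfg$mode %in% c("train", "full")) {
    .stageLog(logCon, "simulate", phantoms = cfg$trainPhantoms, z = cfg$z)
    pairs <- acquisitionProtocol(cfg$trainPhantoms, z = cfg$z,
                                 baseSeed = cfg$seed)
    .stageLog(logCon, "patches", datasets = length(pairs))
    ps <- buildTrainingPatches(pairs, shuffleSeed = cfg$seed + 100L)
    .stageLog(logCon, "train", iterations = iters,
              patches = nPatches(ps))
    model <- buildDenseNet(mcfg, seed = cfg$seed + 200L)
    state <- trainModel(model, ps,
                        trainConfig(maxIterations = iters,
                                    seed = cfg$seed + 300L),
                        z = cfg$z)
    ckpt <- file.path(cfg$outDir, "model.ckpt")
    writeCheckpoint(state, ckpt)
    manifest$artifacts$checkpoint <- ckpt
    manifest$artifacts$finalLoss <-
      utils::tail(state@lossHistory$loss, 1)
    cfg$modelPath <- ckpt
  }

  if (cfg$mode %in% c("denoise", "evaluate", "full")) {
    if (is.null(cfg$modelPath))
      stop("missing artifact: model checkpoint (cfg$modelPath)")
    model <- readCheckpoint(cfg$modelPath)$model
    .stageLog(logCon, "denoise", phantom = cfg$validationPhantom)
    spec <- makePhantomSpec(cfg$validationPhantom)
    pair <- simulateScan(spec, z = cfg$z, seed = cfg$seed + 400L)
    den <- denoise(thinImage(pair), model)
    denPath <- file.path(cfg$outDir, "denoised")
    writeSeries(den, denPath)
    manifest$artifacts$denoised <- paste0(denPath, ".bin.gz")

    if (cfg$mode %in% c("evaluate", "full")) {
      .stageLog(logCon, "evaluate")
      rois <- defaultROIs(spec)
      imgs <- stats::setNames(
        list(thinImage(pair), den),
        c(sprintf("I%gmm", cfg$z), sprintf("Idenoise%gmm", cfg$z)))
      report <- evaluateImages(imgs, thickImage(pair), rois)
      repDir <- file.path(cfg$outDir, "report")
      exportEvalReport(report, repDir)
      manifest$artifacts$report <- repDir
    }
  }

  manifest$hashes <- lapply(
    Filter(function(p) is.character(p) && file.exists(p) && !dir.exists(p),
           manifest$artifacts),
    .hashFile)
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  .stageLog(logCon, "done")
  invisible(manifest)
}
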