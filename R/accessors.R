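#' @include AllGenerics.R
NULL

#' Construct a reconstruction grid
#'
#' @param matrixSize pixels per side; the CAC protocol uses 512.
#' @param fovMm display field of view in mm; the CAC protocol uses 220.
#' @return a \linkS4class{GridSpec}
#' @examples
#' pixelSpacing(GridSpec())  # 220/512 = 0.4297 mm
#' @export
GridSpec <- function(matrixSize = 512L, fovMm = 220) {
  new("GridSpec", matrixSize = as.integer(matrixSize), fovMm = fovMm)
}

#' Construct a CT image
#'
#' @param pixels numeric HU matrix.
#' @param thicknessMm slice thickness in mm.
#' @param grid a \linkS4class{GridSpec}; defaults to one matching the matrix.
#' @param tubeCurrent tube current (mA).
#' @param seed generating seed (NA for ingested data).
#' @param provenance free-text origin.
#' @return a \linkS4class{CTImage}
#' @export
ctImage <- function(pixels, thicknessMm, grid = NULL, tubeCurrent = NA_real_,
                    seed = NA_integer_, provenance = "") {
  if (is.null(grid)) {
    stopifnot(nrow(pixels) == ncol(pixels))
    grid <- GridSpec(nrow(pixels), nrow(pixels) * 0.4296875)
  }
  new("CTImage", pixels = pixels, thicknessMm = thicknessMm,
      tubeCurrent = as.numeric(tubeCurrent), grid = grid,
      seed = as.integer(seed), provenance = provenance)
}

#' @describeIn pixelData method for CTImage
#' @export
setMethod("pixelData", "CTImage", function(x) x@pixels)

#' @describeIn sliceThickness method for CTImage
#' @export
setMethod("sliceThickness", "CTImage", function(x) x@thicknessMm)

#' @describeIn tubeCurrent method for CTImage
#' @export
setMethod("tubeCurrent", "CTImage", function(x) x@tubeCurrent)

#' @describeIn tubeCurrent method for PhantomSpec
#' @export
setMethod("tubeCurrent", "PhantomSpec", function(x) x@tubeCurrent)

#' @describeIn gridSpec method for CTImage
#' @export
setMethod("gridSpec", "CTImage", function(x) x@grid)

#' @describeIn pixelSpacing method for GridSpec
#' @export
setMethod("pixelSpacing", "GridSpec",
          function(x) x@fovMm / x@matrixSize)

#' @describeIn pixelSpacing method for CTImage
#' @export
setMethod("pixelSpacing", "CTImage", function(x) pixelSpacing(x@grid))

#' @describeIn noiseRole method for NoiseMap
#' @export
setMethod("noiseRole", "NoiseMap", function(x) x@role)

#' @describeIn thinImage method for ScanPair
#' @export
setMethod("thinImage", "ScanPair", function(x) x@thin)

#' @describeIn thickImage method for ScanPair
#' @export
setMethod("thickImage", "ScanPair", function(x) x@thick)

#' @describeIn insertTable method for PhantomSpec
#' @export
setMethod("insertTable", "PhantomSpec", function(x, presentOnly = TRUE) {
  ins <- x@inserts
  if (presentOnly && nrow(ins)) ins <- ins[ins$present, , drop = FALSE]
  ins
})

#' @describeIn materialTable method for PhantomSpec
#' @export
setMethod("materialTable", "PhantomSpec", function(x) x@materials)

#' @describeIn nPatches method for PatchSet
#' @export
setMethod("nPatches", "PatchSet", function(x) dim(x@inputs)[3])

#' @describeIn patchInputs method for PatchSet
#' @export
setMethod("patchInputs", "PatchSet", function(x) x@inputs)

#' @describeIn patchLabels method for PatchSet
#' @export
setMethod("patchLabels", "PatchSet", function(x) x@labels)

#' @describeIn patchProvenance method for PatchSet
#' @export
setMethod("patchProvenance", "PatchSet", function(x) x@provenance)

#' @describeIn lossHistory method for TrainState
#' @export
setMethod("lossHistory", "TrainState", function(x) x@lossHistory)

#' Construct a circular ROI
#'
#' @param label ROI name.
#' @param centerMm numeric(2), centre in mm from the isocentre.
#' @param radiusMm radius in mm.
#' @param kind "rod", "background" or "calcification".
#' @return a \linkS4class{ROISpec}
#' @export
circleROI <- function(label, centerMm, radiusMm, kind = "background") {
  new("ROISpec", label = label, kind = kind, shape = "circle",
      centerMm = centerMm, radiusMm = radiusMm,
      mask = matrix(logical(0), 0, 0))
}

#' Construct an explicit-mask ROI
#'
#' @param label ROI name.
#' @param mask logical matrix on the grid.
#' @param kind ROI kind.
#' @return a \linkS4class{ROISpec}
#' @export
maskROI <- function(label, mask, kind = "background") {
  new("ROISpec", label = label, kind = kind, shape = "mask",
      centerMm = c(NA_real_, NA_real_), radiusMm = NA_real_,
      mask = mask)
}

#' @describeIn roiMask pixel support of a circle or mask ROI
#' @export
setMethod("roiMask", signature("ROISpec", "GridSpec"), function(x, grid) {
  if (x@shape == "mask") {
    stopifnot(nrow(x@mask) == grid@matrixSize)
    return(x@mask)
  }
  xy <- .pixelCentersMm(grid)
  outer((xy - x@centerMm[2])^2, (xy - x@centerMm[1])^2, "+") <=
    x@radiusMm^2
})

# pixel-centre coordinates (mm, isocentre origin) along one axis; row index
# maps to y, column index to x
.pixelCentersMm <- function(grid) {
  n <- grid@matrixSize
  ps <- pixelSpacing(grid)
  (seq_len(n) - (n + 1) / 2) * ps
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d, FOV %.1f mm, pixel %.4f mm\n",
              object@matrixSize, object@matrixSize, object@fovMm,
              pixelSpacing(object)))
})

setMethod("show", "CTImage", function(object) {
  cat(sprintf("CTImage: %d x %d, z = %s mm, %s mA\n",
              nrow(object@pixels), ncol(object@pixels),
              format(object@thicknessMm), format(object@tubeCurrent)))
  cat(sprintf("  HU range [%.1f, %.1f]%s\n",
              min(object@pixels), max(object@pixels),
              if (nzchar(object@provenance))
                paste0("  <", object@provenance, ">") else ""))
})

setMethod("show", "NoiseMap", function(object) {
  cat(sprintf("NoiseMap (%s, z = %s mm): %d x %d, SD %.2f HU\n",
              object@role, format(object@z), nrow(object@pixels),
              ncol(object@pixels), stats::sd(object@pixels)))
})

setMethod("show", "ScanPair", function(object) {
  cat(sprintf("ScanPair: thin z = %s mm / thick 3 mm, %d x %d\n",
              format(object@thin@thicknessMm), nrow(object@thin@pixels),
              ncol(object@thin@pixels)))
})

setMethod("show", "PhantomSpec", function(object) {
  ins <- object@inserts
  cat(sprintf("PhantomSpec %s (config %d): body %s %s mm, %d/%d inserts present, %g mA\n",
              object@name, object@configuration, object@bodyShape,
              paste(object@bodyAxesMm, collapse = " x "),
              sum(ins$present), nrow(ins), object@tubeCurrent))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patch pairs, %d x %d px, stride %d%s\n",
              dim(object@inputs)[3], object@patchSize, object@patchSize,
              object@stride,
              if (is.na(object@shuffleSeed)) " (unshuffled)"
              else sprintf(", shuffled (seed %d)", object@shuffleSeed)))
})

setMethod("show", "DenseNetModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@layers,
                   function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf("DenseNetModel: %d blocks x %d layers, growth %d, %d params, %d iterations%s\n",
              cfg$nBlocks, cfg$layersPerBlock, cfg$growthRate, np,
              object@iteration,
              if (is.na(object@z)) "" else sprintf(" (z = %g mm)", object@z)))
})

setMethod("show", "TrainState", function(object) {
  lh <- object@lossHistory
  cat(sprintf("TrainState: %d iterations, loss %.3f -> %.3f HU\n",
              object@model@iteration,
              if (nrow(lh)) lh$loss[1] else NA,
              if (nrow(lh)) lh$loss[nrow(lh)] else NA))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  if (nrow(object@global)) {
    cat("  global:\n")
    print(object@global, row.names = FALSE)
  }
  if (nrow(object@roiTable))
    cat(sprintf("  %d ROI rows, %d Dice rows, %d Agatston rows\n",
                nrow(object@roiTable), nrow(object@diceTable),
                nrow(object@agatston)))
})

setMethod("show", "ROISpec", function(object) {
  if (object@shape == "circle")
    cat(sprintf("ROISpec '%s' (%s): circle (%.1f, %.1f) mm r = %.1f mm\n",
                object@label, object@kind, object@centerMm[1],
                object@centerMm[2], object@radiusMm))
  else
    cat(sprintf("ROISpec '%s' (%s): mask, %d px\n", object@label,
                object@kind, sum(object@mask)))
})
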