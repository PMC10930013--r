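#' @include AllClasses.R
NULL

#' Pixel matrix of an image
#' @param x a \linkS4class{CTImage} or \linkS4class{NoiseMap}
#' @return numeric matrix of HU values
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' Slice thickness in mm
#' @param x a \linkS4class{CTImage}
#' @return numeric thickness (mm)
#' @export
setGeneric("sliceThickness", function(x) standardGeneric("sliceThickness"))

#' Tube current in mA
#' @param x a \linkS4class{CTImage} or \linkS4class{PhantomSpec}
#' @return numeric tube current (mA)
#' @export
setGeneric("tubeCurrent", function(x) standardGeneric("tubeCurrent"))

#' Grid specification of an object
#' @param x an object carrying a reconstruction grid
#' @return a \linkS4class{GridSpec}
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' Pixel spacing in mm (fov / matrix)
#' @param x a \linkS4class{GridSpec} or object carrying one
#' @return numeric pixel spacing (mm)
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' Role of a noise map
#' @param x a \linkS4class{NoiseMap}
#' @return "real", "pseudo" or "predicted"
#' @export
setGeneric("noiseRole", function(x) standardGeneric("noiseRole"))

#' Thin-slice member of a scan pair
#' @param x a \linkS4class{ScanPair}
#' @return a \linkS4class{CTImage}
#' @export
setGeneric("thinImage", function(x) standardGeneric("thinImage"))

#' 3-mm member of a scan pair
#' @param x a \linkS4class{ScanPair}
#' @return a \linkS4class{CTImage}
#' @export
setGeneric("thickImage", function(x) standardGeneric("thickImage"))

#' Insert table of a phantom
#' @param x a \linkS4class{PhantomSpec}
#' @param presentOnly drop removed inserts?
#' @return data.frame of inserts
#' @export
setGeneric("insertTable",
           function(x, presentOnly = TRUE) standardGeneric("insertTable"))

#' Material table of a phantom
#' @param x a \linkS4class{PhantomSpec}
#' @return data.frame (name, hu, sd3mm)
#' @export
setGeneric("materialTable", function(x) standardGeneric("materialTable"))

#' Number of patches in a patch set
#' @param x a \linkS4class{PatchSet}
#' @return integer count
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' Input patches
#' @param x a \linkS4class{PatchSet}
#' @return array (patch, patch, n)
#' @export
setGeneric("patchInputs", function(x) standardGeneric("patchInputs"))

#' Label patches
#' @param x a \linkS4class{PatchSet}
#' @return array (patch, patch, n)
#' @export
setGeneric("patchLabels", function(x) standardGeneric("patchLabels"))

#' Patch provenance table
#' @param x a \linkS4class{PatchSet}
#' @return data.frame (dataset, row, col)
#' @export
setGeneric("patchProvenance", function(x) standardGeneric("patchProvenance"))

#' Loss trajectory of a training run
#' @param x a \linkS4class{TrainState}
#' @return data.frame (iteration, loss)
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' Pixel mask of an ROI on a grid
#' @param x a \linkS4class{ROISpec}
#' @param grid a \linkS4class{GridSpec}
#' @return logical matrix
#' @export
setGeneric("roiMask", function(x, grid) standardGeneric("roiMask"))
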