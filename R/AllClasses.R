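#' @import methods
NULL

#' Reconstruction grid of a CAC scan
#'
#' Matrix size and display field of view of a reconstructed axial slice.
#' Pixel spacing is derived as \code{fov / matrix}; the routine CAC protocol
#' uses a 512 x 512 matrix with a 22-cm display FOV, i.e. 0.4297 mm pixels.
#' Pixel (1,1) is the top-left corner; geometry is expressed in mm with the
#' origin at the image centre and half-pixel pixel centres.
#'
#' @slot matrixSize integer, pixels per side (square matrix).
#' @slot fovMm numeric, display field of view in mm.
#' @export
setClass("GridSpec",
  representation(matrixSize = "integer", fovMm = "numeric"),
  validity = function(object) {
    if (length(object@matrixSize) != 1L || object@matrixSize < 2L)
      return("matrixSize must be a single integer >= 2")
    if (length(object@fovMm) != 1L || object@fovMm <= 0)
      return("fovMm must be a single positive number")
    TRUE
  })

#' A reconstructed CT slice in Hounsfield units
#'
#' One axial slice with its grid metadata. Pixels are stored as floating-point
#' HU (air = -1000, water = 0); quantisation to integers happens only at
#' DICOM export.
#'
#' @slot pixels numeric matrix of HU values, dimensions equal to the grid.
#' @slot thicknessMm reconstructed slice thickness in mm (0.5, 1.0, 1.5 or 3.0
#'   for simulated CAC series; any positive value for ingested data).
#' @slot tubeCurrent tube current in mA used (or recorded) for the scan.
#' @slot grid a \linkS4class{GridSpec}.
#' @slot seed integer seed that generated the slice (NA for ingested data).
#' @slot provenance free-text origin of the slice.
#' @export
setClass("CTImage",
  representation(pixels = "matrix", thicknessMm = "numeric",
                 tubeCurrent = "numeric", grid = "GridSpec",
                 seed = "integer", provenance = "character"),
  validity = function(object) {
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (!all(is.finite(object@pixels))) return("pixels must be finite")
    d <- dim(object@pixels)
    if (d[1] != object@grid@matrixSize || d[2] != object@grid@matrixSize)
      return("pixel matrix does not match the grid matrix size")
    if (length(object@thicknessMm) != 1L || !(is.na(object@thicknessMm) ||
        object@thicknessMm > 0))
      return("thicknessMm must be a single positive number")
    TRUE
  })

#' A signed HU noise map
#'
#' Extends \linkS4class{CTImage}. The map lives on the same grid as its parent
#' thin-slice image and carries the role it plays in the residual-learning
#' workflow: \code{"real"} (thin minus 3-mm, the training label),
#' \code{"pseudo"} (thin minus its block-downsampled/bicubically-upsampled
#' self, the network input) or \code{"predicted"} (the network output).
#'
#' @slot role one of "real", "pseudo", "predicted".
#' @slot z slice thickness (mm) of the parent thin image.
#' @export
setClass("NoiseMap",
  contains = "CTImage",
  representation(role = "character", z = "numeric"),
  validity = function(object) {
    if (!object@role %in% c("real", "pseudo", "predicted"))
      return("role must be one of 'real', 'pseudo', 'predicted'")
    if (object@role == "real" && isTRUE(object@z == 3.0))
      return("a real noise map requires a thin (z != 3 mm) parent")
    TRUE
  })

#' A paired thin / 3-mm reconstruction of the same anatomy
#'
#' The thin slice and the 3-mm slice share the grid and the noise-free
#' content; the 3-mm image is the pixelwise mean of the thin-slice noise
#' realisations that tile the 3-mm slab.
#'
#' @slot thin \linkS4class{CTImage} at z in \{0.5, 1.0, 1.5\} mm.
#' @slot thick \linkS4class{CTImage} at 3.0 mm.
#' @export
setClass("ScanPair",
  representation(thin = "CTImage", thick = "CTImage"),
  validity = function(object) {
    if (object@thin@grid@matrixSize != object@thick@grid@matrixSize ||
        object@thin@grid@fovMm != object@thick@grid@fovMm)
      return("thin and thick must share the grid")
    if (!isTRUE(all.equal(object@thick@thicknessMm, 3.0)))
      return("thick must be the 3.0-mm reconstruction")
    if (object@thin@thicknessMm >= 3.0)
      return("thin must be thinner than 3 mm")
    TRUE
  })

#' Parametric phantom geometry and material table
#'
#' Describes one configuration of a CIRS-style electron density phantom
#' (training) or a QRM-style anthropomorphic thorax phantom (validation):
#' the body outline, the material lookup table (mean HU and noise SD at the
#' 3-mm anchor) and the cylindrical inserts.
#'
#' @slot name phantom name (CIRS_S/M/L, QRM_S/M/L).
#' @slot bodyShape "circle" or "ellipse".
#' @slot bodyAxesMm numeric(2), full axes of the body outline in mm.
#' @slot bodyMaterial name of the body material (row of \code{materials}).
#' @slot materials data.frame with columns \code{name}, \code{hu},
#'   \code{sd3mm} (noise SD in HU at the 3-mm / reference-mA anchor).
#' @slot inserts data.frame with one row per insert: \code{label},
#'   \code{kind} ("rod" or "calcification"), \code{shape}, \code{cx},
#'   \code{cy} (mm from isocentre), \code{diameter}, \code{height} (mm),
#'   \code{material}, \code{present}, \code{removalRank}.
#' @slot tubeCurrent tube current (mA) of the reference acquisition.
#' @slot configuration rod-removal configuration index (0..4; 0 for QRM).
#' @export
setClass("PhantomSpec",
  representation(name = "character", bodyShape = "character",
                 bodyAxesMm = "numeric", bodyMaterial = "character",
                 materials = "data.frame", inserts = "data.frame",
                 tubeCurrent = "numeric", configuration = "integer"),
  validity = function(object) {
    if (!object@bodyShape %in% c("circle", "ellipse"))
      return("bodyShape must be 'circle' or 'ellipse'")
    need <- c("name", "hu", "sd3mm")
    if (!all(need %in% names(object@materials)))
      return("materials needs columns name, hu, sd3mm")
    if (any(object@materials$hu < -1024 | object@materials$hu > 3071))
      return("material HU must lie in [-1024, 3071]")
    if (any(object@materials$sd3mm <= 0))
      return("material sd3mm must be > 0")
    if (!object@bodyMaterial %in% object@materials$name)
      return("bodyMaterial missing from the material table")
    ins <- object@inserts
    if (nrow(ins)) {
      if (any(ins$diameter <= 0)) return("insert diameters must be > 0")
      if (!all(ins$material %in% object@materials$name))
        return("insert material missing from the material table")
      # inserts must fit inside the body outline
      a <- object@bodyAxesMm[1] / 2; b <- object@bodyAxesMm[2] / 2
      r <- ins$diameter / 2
      out <- (ins$cx / (a - r))^2 + (ins$cy / (b - r))^2 > 1 & (a - r) > 0
      if (any(out)) return("an insert overlaps the body boundary")
    }
    TRUE
  })

#' Paired 25 x 25 training patches
#'
#' Aligned input (pseudo noise) and label (real noise) sub-images cut from
#' noise maps on a regular stride grid, with provenance that permits exact
#' reconstruction of every patch origin.
#'
#' @slot inputs numeric array (patch, patch, n).
#' @slot labels numeric array (patch, patch, n), co-located with inputs.
#' @slot patchSize patch side length in pixels.
#' @slot stride stride between patch origins in pixels.
#' @slot shuffleSeed seed of the applied permutation (NA if unshuffled).
#' @slot provenance data.frame with columns \code{dataset}, \code{row},
#'   \code{col} (1-based top-left pixel of each patch in its source map).
#' @export
setClass("PatchSet",
  representation(inputs = "array", labels = "array", patchSize = "integer",
                 stride = "integer", shuffleSeed = "integer",
                 provenance = "data.frame"),
  validity = function(object) {
    di <- dim(object@inputs); dl <- dim(object@labels)
    if (length(di) != 3L || length(dl) != 3L)
      return("inputs/labels must be (patch, patch, n) arrays")
    if (!identical(di, dl)) return("inputs and labels must align")
    if (di[1] != object@patchSize || di[2] != object@patchSize)
      return("patch arrays do not match patchSize")
    if (nrow(object@provenance) != di[3])
      return("provenance must have one row per patch")
    TRUE
  })

#' Dense-connectivity convolutional noise estimator
#'
#' A fully convolutional regression network with DenseNet-style feature
#' concatenation: an initial 3x3 convolution, dense blocks whose layers each
#' append \code{growthRate} feature maps to the running concatenation, a 1x1
#' transition convolution after each block, and a final 3x3 reconstruction
#' convolution to one channel. Zero padding keeps the output on the input
#' grid, so the network trained on 25 x 25 patches applies seamlessly to a
#' whole 512 x 512 map.
#'
#' @slot config list with nBlocks, layersPerBlock, growthRate, initFeatures,
#'   kernel.
#' @slot layers list of conv layers (weight matrix, bias, geometry, relu flag).
#' @slot seed initialisation seed.
#' @slot iteration training iterations applied so far.
#' @slot z slice thickness (mm) the model is trained for (NA before training).
#' @export
setClass("DenseNetModel",
  representation(config = "list", layers = "list", seed = "integer",
                 iteration = "integer", z = "numeric"))

#' Training trajectory of a noise-estimation model
#'
#' @slot model the trained \linkS4class{DenseNetModel}.
#' @slot lossHistory data.frame (iteration, loss) with strictly increasing
#'   iteration; loss is the minibatch RMSE in HU.
#' @slot trainConfig the hyperparameter list used.
#' @export
setClass("TrainState",
  representation(model = "DenseNetModel", lossHistory = "data.frame",
                 trainConfig = "list"),
  validity = function(object) {
    it <- object@lossHistory$iteration
    if (length(it) > 1L && any(diff(it) <= 0))
      return("lossHistory iterations must be strictly increasing")
    TRUE
  })

#' Evaluation report for a denoised series
#'
#' Collects the comparisons against the 3-mm reference: global RMSE/PSNR,
#' per-ROI mean/SD with Welch t-test p-values and the p < 0.01 significance
#' flag, per-calcification Dice coefficients, and Agatston weighting-bin
#' pixel counts.
#'
#' @slot global data.frame (image, rmse, psnr).
#' @slot roiTable data.frame (image, roi, mean, sd, n, p, significant).
#' @slot diceTable data.frame (image, roi, dice).
#' @slot agatston data.frame (image, w1, w2, w3, w4, total).
#' @slot provenance character description of the inputs.
#' @export
setClass("EvalReport",
  representation(global = "data.frame", roiTable = "data.frame",
                 diceTable = "data.frame", agatston = "data.frame",
                 provenance = "character"))

#' Region of interest on the reconstruction grid
#'
#' Either a circle (centre and radius in mm, isocentre origin) or an explicit
#' pixel mask.
#'
#' @slot label ROI name.
#' @slot kind one of "rod", "background", "calcification".
#' @slot shape "circle" or "mask".
#' @slot centerMm numeric(2) circle centre (mm), unused for masks.
#' @slot radiusMm circle radius (mm), unused for masks.
#' @slot mask logical matrix for shape "mask" (0 x 0 otherwise).
#' @export
setClass("ROISpec",
  representation(label = "character", kind = "character", shape = "character",
                 centerMm = "numeric", radiusMm = "numeric", mask = "matrix"),
  validity = function(object) {
    if (!object@kind %in% c("rod", "background", "calcification"))
      return("kind must be rod, background or calcification")
    if (!object@shape %in% c("circle", "mask"))
      return("shape must be circle or mask")
    if (object@shape == "circle" && object@radiusMm <= 0)
      return("circle radius must be positive")
    TRUE
  })
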