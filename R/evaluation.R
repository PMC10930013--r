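#' @include accessors.R
NULL

.asPixels <- function(x) if (is(x, "CTImage")) x@pixels else x

#' Whole-image root-mean-square error
#'
#' \code{sqrt(sum((reference - image)^2) / k)} with \code{k} the number of
#' voxels in the whole image.
#'
#' @param image candidate \linkS4class{CTImage} (or matrix).
#' @param reference reference \linkS4class{CTImage} (or matrix), same grid.
#' @return RMSE in HU
#' @export
imageRMSE <- function(image, reference) {
  a <- .asPixels(image); b <- .asPixels(reference)
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  sqrt(sum((b - a)^2) / length(a))
}

#' Peak signal-to-noise ratio
#'
#' \code{20 * log10(HUmax / RMSE)} in dB, with \code{HUmax} the maximum HU
#' value of the reference image (a common ceiling, so PSNR values of
#' different candidates against the same reference are comparable).
#' Identical images give \code{Inf}.
#'
#' @param image candidate image.
#' @param reference reference image, same grid.
#' @return PSNR in dB (\code{Inf} when RMSE is zero)
#' @export
imagePSNR <- function(image, reference) {
  r <- imageRMSE(image, reference)
  if (r == 0) return(Inf)
  20 * log10(max(.asPixels(reference)) / r)
}

#' ROI mean/SD and Welch t-test against a reference
#'
#' Computes the mean and SD of the candidate image over the ROI pixels and a
#' two-sample (Welch, unequal-variance) t-test comparing the candidate's ROI
#' pixels with the reference's ROI pixels; two-sided p-value, significance
#' declared at p < 0.01.
#'
#' @param image candidate \linkS4class{CTImage}.
#' @param roi an \linkS4class{ROISpec}.
#' @param reference reference \linkS4class{CTImage} (same grid); NULL skips
#'   the test.
#' @return data.frame (roi, mean, sd, n, p, significant)
#' @export
roiStats <- function(image, roi, reference = NULL) {
  m <- roiMask(roi, gridSpec(image))
  if (!any(m)) stop("empty ROI on this grid")
  v <- pixelData(image)[m]
  p <- NA_real_
  if (!is.null(reference)) {
    w <- pixelData(reference)[m]
    p <- if (isTRUE(all.equal(v, w))) 1
         else stats::t.test(v, w, var.equal = FALSE)$p.value
  }
  data.frame(roi = roi@label, mean = mean(v), sd = stats::sd(v),
             n = sum(m), p = p,
             significant = !is.na(p) & p < 0.01)
}

#' Calcification mask at the 130 HU threshold
#'
#' Pixels with HU >= 130 (the standard calcium-scoring threshold; the
#' boundary value 130 is included) within the given region.
#'
#' @param image a \linkS4class{CTImage}.
#' @param region an \linkS4class{ROISpec} restricting the search, or NULL for
#'   the full image.
#' @param threshold HU threshold (default 130).
#' @return logical matrix
#' @export
calcificationMask <- function(image, region = NULL, threshold = 130) {
  m <- pixelData(image) >= threshold
  if (!is.null(region)) m <- m & roiMask(region, gridSpec(image))
  m
}

#' Dice similarity coefficient
#'
#' \code{2|A n B| / (|A| + |B|)}. Two empty masks agree perfectly on the
#' absence of signal and return 1 by convention.
#'
#' @param maskA,maskB logical matrices on the same grid.
#' @return Dice coefficient in [0, 1]
#' @export
diceCoefficient <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) stop("grid mismatch")
  denom <- sum(maskA) + sum(maskB)
  if (denom == 0) return(1)
  2 * sum(maskA & maskB) / denom
}

#' Drop 1-mm calcifications from an insert table
#'
#' 1-mm-diameter calcifications are not detectable on 3-mm slice images, so
#' they are excluded from the reference-based evaluation; 3- and 5-mm
#' calcifications are retained.
#'
#' @param inserts insert data.frame (see \linkS4class{PhantomSpec}).
#' @return the filtered data.frame
#' @export
filterSmallCalcifications <- function(inserts) {
  if (!nrow(inserts)) return(inserts)
  keep <- !(inserts$kind == "calcification" & inserts$diameter <= 1)
  inserts[keep, , drop = FALSE]
}

#' Agatston weighting factor of a peak HU value
#'
#' 0 below 130 HU; 1 on [130, 200); 2 on [200, 300); 3 on [300, 400);
#' 4 at and above 400 HU (bin upper bounds are half-open, so 200/300/400
#' fall into the higher bin).
#'
#' @param hu numeric HU value(s).
#' @return integer weighting factor(s) in 0..4
#' @examples
#' agatstonWeight(c(129, 150, 250, 350, 450))  # 0 1 2 3 4
#' @export
agatstonWeight <- function(hu) {
  w <- findInterval(hu, c(130, 200, 300, 400))
  as.integer(w)
}

#' Calcification pixel counts per Agatston weighting bin
#'
#' Counts the pixels of the calcification mask (HU >= 130 within the region)
#' that fall into each weighting bin; \code{total} is the mask size and the
#' bins partition it.
#'
#' @param image a \linkS4class{CTImage}.
#' @param region optional \linkS4class{ROISpec} restriction.
#' @return data.frame (w1, w2, w3, w4, total)
#' @export
countWeightedPixels <- function(image, region = NULL) {
  m <- calcificationMask(image, region)
  w <- agatstonWeight(pixelData(image)[m])
  data.frame(w1 = sum(w == 1L), w2 = sum(w == 2L), w3 = sum(w == 3L),
             w4 = sum(w == 4L), total = sum(m))
}

#' Default analysis ROIs of a phantom
#'
#' Electron density phantoms: a circular ROI at the centre of every present
#' rod insert, with radius 2/3 of the rod radius (10 mm for 30-mm rods) to
#' stay clear of boundary partial volume. Thorax phantoms: one background
#' ROI (10-mm circle at the calibration-insert centre, which carries no
#' calcification) plus one region per calcification, a circle of radius
#' \code{diameter/2 + marginMm} used to localise the Dice comparison.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param dropSmall exclude 1-mm calcifications (default TRUE).
#' @param marginMm halo around calcification regions in mm.
#' @return named list of \linkS4class{ROISpec}
#' @export
defaultROIs <- function(spec, dropSmall = TRUE, marginMm = 2) {
  ins <- insertTable(spec, presentOnly = TRUE)
  rois <- list()
  if (startsWith(spec@name, "CIRS")) {
    for (i in seq_len(nrow(ins)))
      rois[[ins$label[i]]] <- circleROI(ins$label[i],
                                        c(ins$cx[i], ins$cy[i]),
                                        ins$diameter[i] / 2 * (2 / 3),
                                        kind = "rod")
  } else {
    rois[["background"]] <- circleROI("background", c(0, 0), 10,
                                      kind = "background")
    if (dropSmall) ins <- filterSmallCalcifications(ins)
    ins <- ins[ins$kind == "calcification", , drop = FALSE]
    for (i in seq_len(nrow(ins)))
      rois[[ins$label[i]]] <- circleROI(ins$label[i],
                                        c(ins$cx[i], ins$cy[i]),
                                        ins$diameter[i] / 2 + marginMm,
                                        kind = "calcification")
  }
  rois
}

#' Evaluate candidate images against the 3-mm reference
#'
#' Builds the full report: per-image RMSE/PSNR over the whole image, per-ROI
#' mean/SD with Welch t-test p-values against the reference, per-calcification
#' Dice coefficients of the 130-HU masks, and Agatston weighting-bin pixel
#' counts.
#'
#' @param images named list of candidate \linkS4class{CTImage}s.
#' @param reference the 3-mm reference \linkS4class{CTImage}.
#' @param rois named list of \linkS4class{ROISpec} (e.g.
#'   \code{\link{defaultROIs}}).
#' @return an \linkS4class{EvalReport}
#' @export
evaluateImages <- function(images, reference, rois = list()) {
  stopifnot(length(images) > 0, !is.null(names(images)))
  glob <- do.call(rbind, lapply(names(images), function(nm)
    data.frame(image = nm, rmse = imageRMSE(images[[nm]], reference),
               psnr = imagePSNR(images[[nm]], reference))))

  roiT <- diceT <- data.frame()
  allImgs <- c(images, list(reference3mm = reference))
  for (nm in names(allImgs)) {
    for (roi in rois) {
      st <- roiStats(allImgs[[nm]], roi,
                     if (nm == "reference3mm") NULL else reference)
      roiT <- rbind(roiT, cbind(image = nm, st))
      if (roi@kind == "calcification" && nm != "reference3mm") {
        dA <- calcificationMask(allImgs[[nm]], roi)
        dB <- calcificationMask(reference, roi)
        diceT <- rbind(diceT, data.frame(image = nm, roi = roi@label,
                                         dice = diceCoefficient(dA, dB)))
      }
    }
  }
  agat <- do.call(rbind, lapply(names(allImgs), function(nm)
    cbind(image = nm, countWeightedPixels(allImgs[[nm]]))))

  new("EvalReport", global = glob, roiTable = roiT, diceTable = diceT,
      agatston = agat,
      provenance = sprintf("reference: %s", reference@provenance))
}

#' Export an evaluation report as CSV tables and JSON
#'
#' @param report an \linkS4class{EvalReport}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly
#' @export
exportEvalReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report@global, file.path(dir, "global_metrics.csv"))
  data.table::fwrite(report@roiTable, file.path(dir, "roi_stats.csv"))
  if (nrow(report@diceTable))
    data.table::fwrite(report@diceTable, file.path(dir, "dice.csv"))
  data.table::fwrite(report@agatston, file.path(dir, "agatston_bins.csv"))
  jsonlite::write_json(
    list(global = report@global, roi = report@roiTable,
         dice = report@diceTable, agatston = report@agatston,
         provenance = report@provenance),
    file.path(dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
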