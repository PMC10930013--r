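#' @include accessors.R
NULL

# ---- array-container backend -------------------------------------------------
# <path>.bin.gz : gzipped float64 little-endian pixels, column-major
# <path>.json   : sidecar with grid, thickness, current, seed, provenance

.sidecar <- function(img) {
  list(format = "CACdenoise-series-1",
       matrixSize = img@grid@matrixSize, fovMm = img@grid@fovMm,
       thicknessMm = img@thicknessMm, tubeCurrent = img@tubeCurrent,
       seed = img@seed, provenance = img@provenance,
       dtype = "float64", order = "column-major", endian = "little")
}

#' Write a CT image series
#'
#' The array backend stores pixels losslessly (float64) with a JSON sidecar
#' carrying the full provenance; \code{readSeries(writeSeries(x))} is
#' bit-identical. The DICOM backend writes a single-frame CT object
#' (explicit VR little endian) with modality, slice thickness, pixel spacing
#' and Rescale Slope/Intercept set so stored values map to HU; pixels are
#' quantised to signed 16-bit integers with half-to-even rounding.
#'
#' @param img a \linkS4class{CTImage}.
#' @param path output path; the array backend appends \code{.bin.gz} /
#'   \code{.json}, the DICOM backend writes \code{path} as-is (use a
#'   \code{.dcm} name).
#' @param backend "array" or "dicom".
#' @return the main written path, invisibly
#' @export
writeSeries <- function(img, path, backend = c("array", "dicom")) {
  backend <- match.arg(backend)
  if (backend == "array") {
    con <- gzfile(paste0(path, ".bin.gz"), open = "wb")
    writeBin(as.vector(img@pixels), con, size = 8L, endian = "little")
    close(con)
    jsonlite::write_json(.sidecar(img), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(paste0(path, ".bin.gz"))
  } else {
    .writeDicom(img, path)
    invisible(path)
  }
}

#' Read a CT image series
#'
#' Accepts the array-container backend (pass the base path used at write
#' time, or either of its two files) or a single-frame DICOM file
#' (\code{.dcm}); DICOM HU values are reconstructed via Rescale
#' Slope/Intercept. A missing slice-thickness tag is an error, never a
#' guess.
#'
#' @param path series path.
#' @return a \linkS4class{CTImage}
#' @export
readSeries <- function(path) {
  if (grepl("\\.dcm$", path, ignore.case = TRUE)) return(.readDicom(path))
  base <- sub("\\.(bin\\.gz|json)$", "", path)
  sc <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  if (!identical(sc$format, "CACdenoise-series-1"))
    stop("unrecognised series sidecar: ", paste0(base, ".json"))
  con <- gzfile(paste0(base, ".bin.gz"), open = "rb")
  px <- readBin(con, what = "double", n = sc$matrixSize^2, size = 8L,
                endian = "little")
  close(con)
  ctImage(matrix(px, sc$matrixSize, sc$matrixSize),
          thicknessMm = sc$thicknessMm,
          grid = GridSpec(sc$matrixSize, sc$fovMm),
          tubeCurrent = sc$tubeCurrent,
          seed = if (is.null(sc$seed)) NA_integer_ else sc$seed,
          provenance = sc$provenance)
}

# ---- minimal single-frame CT DICOM (explicit VR little endian) --------------
# Only the subset needed for a conformant secondary-capture-style CT slice is
# implemented; no installed R package reads or writes DICOM.

.CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"
.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.IMPL_UID <- "1.2.826.0.1.3680043.10.1457.1"

.dcmPad <- function(raw, padByte) {
  if (length(raw) %% 2L == 1L) c(raw, padByte) else raw
}

.dcmElement <- function(group, element, vr, value) {
  head <- writeBin(as.integer(c(group, element)), raw(), size = 2L,
                   endian = "little")
  if (vr %in% c("OB", "OW")) {
    return(c(head, charToRaw(vr), as.raw(c(0, 0)),
             writeBin(length(value), raw(), size = 4L, endian = "little"),
             value))
  }
  body <- if (vr == "US")
    writeBin(as.integer(value), raw(), size = 2L, endian = "little")
  else
    .dcmPad(charToRaw(value), if (vr == "UI") as.raw(0L) else charToRaw(" "))
  c(head, charToRaw(vr),
    writeBin(length(body), raw(), size = 2L, endian = "little"), body)
}

.writeDicom <- function(img, path) {
  n <- nrow(img@pixels)
  stored <- round(img@pixels)               # slope 1 / intercept 0, banker's
  storage.mode(stored) <- "integer"
  if (any(stored < -32768L | stored > 32767L))
    stop("HU values exceed the signed 16-bit DICOM range")
  pixelBytes <- writeBin(as.vector(t(stored)), raw(), size = 2L,
                         endian = "little")  # row-major per DICOM
  sopUID <- paste0(.IMPL_UID, ".", format(as.integer(Sys.time())), ".",
                   Sys.getpid())
  ps <- sprintf("%.6f", pixelSpacing(img))

  meta <- c(
    .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dcmElement(0x0002, 0x0002, "UI", .CT_SOP_CLASS),
    .dcmElement(0x0002, 0x0003, "UI", sopUID),
    .dcmElement(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
    .dcmElement(0x0002, 0x0012, "UI", .IMPL_UID))
  # file meta group length (0002,0000), UL over the remaining group bytes
  gl <- c(writeBin(as.integer(c(0x0002, 0x0000)), raw(), size = 2L,
                   endian = "little"),
          charToRaw("UL"),
          writeBin(4L, raw(), size = 2L, endian = "little"),
          writeBin(length(meta), raw(), size = 4L, endian = "little"))

  ds <- c(
    .dcmElement(0x0008, 0x0016, "UI", .CT_SOP_CLASS),
    .dcmElement(0x0008, 0x0018, "UI", sopUID),
    .dcmElement(0x0008, 0x0060, "CS", "CT"),
    .dcmElement(0x0018, 0x0050, "DS", format(img@thicknessMm)),
    .dcmElement(0x0018, 0x1151, "IS",
                if (is.na(img@tubeCurrent)) "0"
                else format(as.integer(round(img@tubeCurrent)))),
    .dcmElement(0x0028, 0x0002, "US", 1L),
    .dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcmElement(0x0028, 0x0010, "US", n),
    .dcmElement(0x0028, 0x0011, "US", n),
    .dcmElement(0x0028, 0x0030, "DS", paste0(ps, "\\", ps)),
    .dcmElement(0x0028, 0x0100, "US", 16L),
    .dcmElement(0x0028, 0x0101, "US", 16L),
    .dcmElement(0x0028, 0x0102, "US", 15L),
    .dcmElement(0x0028, 0x0103, "US", 1L),
    .dcmElement(0x0028, 0x1052, "DS", "0"),
    .dcmElement(0x0028, 0x1053, "DS", "1"),
    .dcmElement(0x7FE0, 0x0010, "OW", pixelBytes))

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(gl, con)
  writeBin(meta, con)
  writeBin(ds, con)
  invisible(path)
}

.readDicom <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, open = "rb")
  on.exit(close(con))
  buf <- readBin(con, "raw", n = sz)
  if (length(buf) < 132L || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  u16 <- function(at) sum(as.integer(buf[at + 0:1]) * c(1, 256))
  u32 <- function(at) sum(as.integer(buf[at + 0:3]) * c(1, 256, 65536,
                                                        16777216))
  tags <- list()
  while (pos + 7L <= length(buf)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit VR or malformed element; only explicit VR little ",
           "endian is supported")
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L); vpos <- pos + 12L
    } else {
      len <- u16(pos + 6L); vpos <- pos + 8L
    }
    if (vpos + len - 1L > length(buf)) stop("truncated DICOM element")
    key <- sprintf("%04X,%04X", group, element)
    tags[[key]] <- list(vr = vr, at = vpos, len = len)
    pos <- vpos + len
  }
  getStr <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    v <- buf[t$at + seq_len(t$len) - 1L]
    trimws(rawToChar(v[v != as.raw(0L)]))  # UI padding is a NUL byte
  }
  getU16 <- function(key) { t <- tags[[key]]; if (is.null(t)) NULL
                            else u16(t$at) }
  ts <- getStr("0002,0010")
  if (!is.null(ts) && ts != .TS_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts)
  nr <- getU16("0028,0010"); nc <- getU16("0028,0011")
  if (is.null(nr) || is.null(nc)) stop("missing Rows/Columns")
  thick <- getStr("0018,0050")
  if (is.null(thick) || !nzchar(thick))
    stop("missing SliceThickness (0018,0050); thickness is never guessed")
  slope <- getStr("0028,1053"); icept <- getStr("0028,1052")
  if (is.null(slope) || is.null(icept))
    stop("missing Rescale Slope/Intercept tags")
  pd <- tags[["7FE0,0010"]]
  if (is.null(pd)) stop("missing PixelData")
  pr <- getU16("0028,0103")
  signed <- !is.null(pr) && pr == 1
  stored <- readBin(buf[pd$at + seq_len(pd$len) - 1L], "integer",
                    n = nr * nc, size = 2L, signed = signed,
                    endian = "little")
  hu <- matrix(stored, nr, nc, byrow = TRUE) * as.numeric(slope) +
    as.numeric(icept)
  psTag <- getStr("0028,0030")
  psVal <- if (is.null(psTag)) 0.4296875
           else as.numeric(strsplit(psTag, "\\\\")[[1]][1])
  mA <- getStr("0018,1151")
  ctImage(hu, thicknessMm = as.numeric(thick),
          grid = GridSpec(nr, psVal * nr),
          tubeCurrent = if (is.null(mA)) NA_real_ else as.numeric(mA),
          provenance = sprintf("DICOM %s", basename(path)))
}
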