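#' Load a 2-D grayscale image and rescale it to \[0, 1\]
#'
#' Reads a single-frame grayscale image and linearly rescales its intensities
#' to the unit interval, the carrier convention used throughout the pipeline.
#' PNG and TIFF are read natively; single-frame grayscale DICOM is read
#' through the system `python` interpreter's `pydicom` (with rescale slope
#' and intercept applied before normalization).
#'
#' A constant image has zero dynamic range; by convention it maps to all
#' zeros, with a warning, rather than failing, so batch runs stay alive.
#' The original intensity range is kept in attributes `orig_min` / `orig_max`
#' for round-tripping.
#'
#' @param path Path to the image file.
#' @param modality `"auto"` (by extension), `"raster"` (PNG/TIFF) or
#'   `"dicom"`.
#' @return Numeric matrix with values in \[0, 1\] and attributes `orig_min`,
#'   `orig_max`.
#' @export
load_image <- function(path, modality = c("auto", "raster", "dicom")) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop_param("cannot read image: file not found: ", path)
  if (modality == "auto") {
    ext <- tolower(tools::file_ext(path))
    modality <- if (ext %in% c("dcm", "dicom", "ima")) "dicom" else "raster"
  }
  raw <- if (modality == "dicom") read_dicom_matrix(path) else
    read_raster_matrix(path)
  normalize_unit(raw)
}

read_raster_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      frames <- tiff::readTIFF(path, all = TRUE)
      if (length(frames) > 1L)
        stop_param("unsupported input: multi-frame TIFF (", length(frames),
                   " frames)")
      frames[[1L]]
    },
    stop_param("unsupported raster format: .", ext)
  )
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3L]
    same <- all(vapply(seq_len(ch), function(c) {
      isTRUE(all.equal(img[, , c], img[, , 1L]))
    }, logical(1L)))
    if (!same)
      stop_param("unsupported input: color image (", ch, " channels)")
    img <- img[, , 1L]
  }
  if (!is.matrix(img))
    stop_param("decode error: not a 2-D image: ", path)
  img
}

# DICOM via the system python's pydicom: the frame is dumped (after applying
# RescaleSlope/RescaleIntercept) to a temporary whitespace table and read back.
read_dicom_matrix <- function(path) {
  py <- Sys.which("python")
  if (!nzchar(py))
    stop_param("DICOM input requires a python interpreter with pydicom on PATH")
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp), add = TRUE)
  script <- paste(
    "import sys",
    "import numpy as np",
    "import pydicom",
    "ds = pydicom.dcmread(sys.argv[1], force=True)",
    "arr = ds.pixel_array",
    "if arr.ndim != 2: sys.exit('unsupported input: not a single 2-D frame')",
    "slope = float(getattr(ds, 'RescaleSlope', 1.0))",
    "inter = float(getattr(ds, 'RescaleIntercept', 0.0))",
    "np.savetxt(sys.argv[2], arr.astype(float) * slope + inter)",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(script), shQuote(path), shQuote(tmp)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) || !file.exists(tmp) ||
      file.info(tmp)$size == 0)
    stop_param("decode error: pydicom failed on ", path,
               if (length(status)) paste0(": ", paste(status, collapse = "; ")))
  as.matrix(utils::read.table(tmp))
}

normalize_unit <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw)))
    stop_param("decode error: non-numeric or non-finite pixel data")
  raw <- unname(as.matrix(raw))
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("constant image: zero dynamic range, mapped to all zeros",
            call. = FALSE)
    out <- matrix(0, nrow(raw), ncol(raw))
  } else {
    out <- (raw - rng[1L]) / diff(rng)
  }
  attr(out, "orig_min") <- rng[1L]
  attr(out, "orig_max") <- rng[2L]
  out
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground (1) is written as 255, background (0) as 0; the file
#' round-trips losslessly through [load_mask()].
#'
#' @param mask Matrix with values in \{0, 1\}.
#' @param path Output path.
#' @export
save_mask <- function(mask, path) {
  check_mask(mask)
  storage.mode(mask) <- "double"
  ok <- tryCatch({ png::writePNG(mask, path); TRUE },
                 error = function(e) stop_param("I/O error writing ", path,
                                                ": ", conditionMessage(e)))
  invisible(ok)
}

#' Read a binary mask written by [save_mask()]
#'
#' @param path PNG path.
#' @return Matrix with values in \{0, 1\}.
#' @export
load_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask <- (img > 0.5) + 0
  check_mask(mask)
  mask
}
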