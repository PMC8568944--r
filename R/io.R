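#' Read a micrograph from PNG or TIFF
#'
#' @param path Image path (`.png`, `.tif`/`.tiff`).
#' @param pixel_size_um Micrometres per pixel of the acquisition.
#' @param id Optional identifier; defaults to the file name.
#' @return A [histology_image()].
#' @export
read_histology_image <- function(path, pixel_size_um, id = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        abort_bad_arg("the png package is required to read PNG.")
      png::readPNG(path)
    },
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        abort_bad_arg("the tiff package is required to read TIFF.")
      tiff::readTIFF(path)
    },
    abort_bad_arg("unsupported image format `.%s`.", ext))
  if (length(dim(arr)) == 2L)                     # greyscale -> RGB
    arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  histology_image(arr, pixel_size_um, id = id %||% basename(path))
}

#' Write a micrograph or mask as PNG/TIFF (8-bit)
#'
#' @param x A [histology_image()], `airspace_mask`, or logical matrix.
#' @param path Output path; format from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  arr <- if (inherits(x, "histology_image")) x$array
         else if (inherits(x, "airspace_mask")) x$mask * 1
         else if (is.logical(x)) x * 1
         else abort_bad_arg("`x` must be a histology_image, airspace_mask or logical matrix.")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        abort_bad_arg("the png package is required to write PNG.")
      png::writePNG(arr, path)
    },
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        abort_bad_arg("the tiff package is required to write TIFF.")
      tiff::writeTIFF(arr, path, bits.per.sample = 8L)
    },
    abort_bad_arg("unsupported image format `.%s`.", ext))
  invisible(path)
}

#' Read a pressure-volume record from CSV
#'
#' Expects columns `pressure_cmh2o`, `volume_ml` and optionally `phase`.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_pv_csv <- function(path) {
  out <- as_tibble(utils::read.csv(path))
  check_columns(out, c("pressure_cmh2o", "volume_ml"), basename(path))
  out
}

#' Read a cohort table from CSV
#'
#' Coerces `genotype` to a WT/HT/HO factor, `gender` to an M/F factor and
#' the logical flags to logical.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_cohort_csv <- function(path) {
  out <- as_tibble(utils::read.csv(path))
  if ("genotype" %in% names(out))
    out$genotype <- factor(out$genotype, levels = c("WT", "HT", "HO"))
  if ("gender" %in% names(out))
    out$gender <- factor(out$gender, levels = c("M", "F"))
  for (cl in intersect(c("allergy_asthma", "smoker"), names(out)))
    out[[cl]] <- as.logical(out[[cl]])
  out
}
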