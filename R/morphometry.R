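#' Binarize a micrograph into air and tissue by HSV saturation
#'
#' Converts the RGB image to hue/saturation/brightness and classifies pixels
#' with saturation strictly below the threshold as air. This mirrors the
#' standard emphysema-quantification step in which the saturation channel
#' discriminates (near-white) airspace from stained tissue.
#'
#' @param image A [histology_image()], or a `parenchyma_sim` (its image is
#'   used).
#' @param saturation_threshold Number in `[0, 1]`, or `"auto"` to select the
#'   threshold by Otsu's method on the saturation channel. A constant
#'   saturation channel has no Otsu optimum; `"auto"` then falls back to 0.5.
#' @return An object of class `airspace_mask`: list with `mask` (logical
#'   matrix, `TRUE` = air), `pixel_size_um`, `threshold`.
#' @export
binarize_airspace <- function(image, saturation_threshold = "auto") {
  if (inherits(image, "parenchyma_sim")) image <- image$image
  if (!inherits(image, "histology_image"))
    abort_bad_arg("`image` must be a histology_image (RGB).")
  s <- rgb_saturation(image$array)
  thr <- if (identical(saturation_threshold, "auto")) {
    if (diff(range(s)) < .Machine$double.eps) 0.5
    else as.numeric(EBImage::otsu(EBImage::Image(s), range = c(0, 1)))
  } else {
    check_number(saturation_threshold, "saturation_threshold", min = 0, max = 1)
    saturation_threshold
  }
  structure(list(mask = s < thr, pixel_size_um = image$pixel_size_um,
                 threshold = thr),
            class = "airspace_mask")
}

#' Construct an airspace mask directly
#'
#' @param mask Logical matrix, `TRUE` = air.
#' @param pixel_size_um Micrometres per pixel.
#' @param threshold Optional provenance: the saturation threshold used.
#' @export
airspace_mask <- function(mask, pixel_size_um, threshold = NA_real_) {
  if (!is.logical(mask) || !is.matrix(mask))
    abort_bad_arg("`mask` must be a logical matrix.")
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  structure(list(mask = mask, pixel_size_um = pixel_size_um,
                 threshold = threshold), class = "airspace_mask")
}

#' @export
print.airspace_mask <- function(x, ...) {
  cat(sprintf("<airspace_mask> %d x %d px @ %g um/px, %.1f%% air\n",
              ncol(x$mask), nrow(x$mask), x$pixel_size_um,
              100 * mean(x$mask)))
  invisible(x)
}

as_airspace_mask <- function(x) {
  if (inherits(x, "airspace_mask")) return(x)
  if (inherits(x, "parenchyma_sim"))
    return(airspace_mask(x$mask, x$pixel_size_um))
  abort_bad_arg("expected an `airspace_mask` (see airspace_mask() or binarize_airspace()).")
}

#' Per-particle airspace measurements
#'
#' Labels 8-connected air components ("particles", one per airspace) and
#' measures each in physical units. Perimeter is estimated by counting
#' exposed pixel edges (exact for axis-aligned rectangles); the equivalent
#' circular diameter is `2 * sqrt(area / pi)`.
#'
#' @param mask An `airspace_mask` (or `parenchyma_sim`).
#' @param exclude_border Drop particles touching the image border
#'   (default `FALSE`: border airspaces are counted).
#' @return Tibble with one row per particle: `particle`, `n_pixels`,
#'   `area_um2`, `perimeter_um`, `equiv_diameter_um`, `touches_border`.
#' @export
airspace_particles <- function(mask, exclude_border = FALSE) {
  m <- as_airspace_mask(mask)
  lab <- label_components(m$mask)
  nl <- max(lab)
  if (nl == 0L)
    return(tibble(particle = integer(), n_pixels = integer(),
                  area_um2 = numeric(), perimeter_um = numeric(),
                  equiv_diameter_um = numeric(), touches_border = logical()))
  npx <- tabulate(lab[lab > 0L], nbins = nl)
  # exposed-edge counting: an air pixel contributes one perimeter edge for
  # every 4-neighbour that is background or lies beyond the border
  edges <- integer(nl)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- shift_mat(lab, d[1], d[2], fill = 0L)
    sel <- lab > 0L & nb == 0L
    edges <- edges + tabulate(lab[sel], nbins = nl)
  }
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  ps <- m$pixel_size_um
  out <- tibble(particle = seq_len(nl), n_pixels = npx,
                area_um2 = npx * ps^2, perimeter_um = edges * ps,
                equiv_diameter_um = 2 * sqrt(npx * ps^2 / pi),
                touches_border = seq_len(nl) %in% border[border > 0L])
  if (exclude_border) out <- dplyr::filter(out, !.data$touches_border)
  out
}

#' Summarise airspaces per image (emphysema quantification)
#'
#' Applies the minimum-diameter filter (particles with equivalent circular
#' diameter strictly below `min_diameter_um` are ignored, so a particle at
#' exactly the cutoff is kept) and reports the count, mean surface and mean
#' perimeter of the survivors.
#'
#' @inheritParams airspace_particles
#' @param min_diameter_um Minimum equivalent diameter retained
#'   (default 5 um).
#' @return One-row tibble: `count`, `mean_area_um2`, `mean_perimeter_um`,
#'   `min_diameter_um`. Means are `NA` when no particle survives.
#' @export
analyze_airspaces <- function(mask, min_diameter_um = 5,
                              exclude_border = FALSE) {
  check_number(min_diameter_um, "min_diameter_um", min = 0)
  parts <- airspace_particles(mask, exclude_border = exclude_border)
  keep <- dplyr::filter(parts, .data$equiv_diameter_um >= min_diameter_um)
  tibble(count = nrow(keep),
         mean_area_um2 = if (nrow(keep)) mean(keep$area_um2) else NA_real_,
         mean_perimeter_um = if (nrow(keep)) mean(keep$perimeter_um) else NA_real_,
         min_diameter_um = min_diameter_um)
}

#' Enumerate airspace chords for the mean linear intercept
#'
#' Scans the binary mask row by row and column by column (step: one pixel);
#' every maximal run of air pixels in a row contributes one horizontal chord
#' (its width), every maximal run in a column one vertical chord (its
#' height), in micrometres.
#'
#' @inheritParams airspace_particles
#' @return Tibble with columns `orientation` (`"horizontal"`/`"vertical"`)
#'   and `length_um`.
#' @export
mli_chords <- function(mask) {
  m <- as_airspace_mask(mask)
  runs <- function(v) { r <- rle(v); r$lengths[r$values] }
  h <- unlist(lapply(seq_len(nrow(m$mask)), function(i) runs(m$mask[i, ])))
  v <- unlist(lapply(seq_len(ncol(m$mask)), function(j) runs(m$mask[, j])))
  tibble(orientation = rep(c("horizontal", "vertical"),
                           c(length(h), length(v))),
         length_um = c(h, v) * m$pixel_size_um)
}

#' Mean linear intercept (MLI)
#'
#' The stereological airspace-size estimate: the arithmetic mean of all
#' horizontal and vertical chords (see [mli_chords()]) across the binarized
#' image.
#'
#' @inheritParams airspace_particles
#' @param min_chord_um Chords shorter than this are discarded before
#'   averaging (default 0: all chords count; the particle-size filter of
#'   [analyze_airspaces()] does not apply to MLI).
#' @return One-row tibble: `mli_um`, `n_chords`, `n_horizontal`,
#'   `n_vertical`. `mli_um` is `NA` when the mask holds no air.
#' @export
mean_linear_intercept <- function(mask, min_chord_um = 0) {
  check_number(min_chord_um, "min_chord_um", min = 0)
  ch <- dplyr::filter(mli_chords(mask), .data$length_um >= min_chord_um)
  tibble(mli_um = if (nrow(ch)) mean(ch$length_um) else NA_real_,
         n_chords = nrow(ch),
         n_horizontal = sum(ch$orientation == "horizontal"),
         n_vertical = sum(ch$orientation == "vertical"))
}

#' Mean epithelium height over a basal polyline
#'
#' Reproduces the epithelium-height measurement: the basal pole is given as
#' a manually-delimited polyline; the apical side is detected automatically
#' as the far edge of the contiguous tissue region adjacent to the basal
#' line (8-connected flood from the rasterised polyline); the mean height is
#' the ROI surface divided by the basal arc length.
#'
#' @param mask Logical tissue mask (`TRUE` = tissue) or an `epithelium_sim`.
#' @param basal Tibble with `x_um`, `y_um`: ordered basal polyline, at least
#'   2 points, positive length. Taken from the simulation object when `mask`
#'   is an `epithelium_sim` and `basal` is `NULL`.
#' @param pixel_size_um Micrometres per pixel (taken from the simulation
#'   object when omitted).
#' @return One-row tibble: `mean_height_um`, `roi_area_um2`,
#'   `basal_length_um`.
#' @export
epithelium_mean_height <- function(mask, basal = NULL, pixel_size_um = NULL) {
  if (inherits(mask, "epithelium_sim")) {
    basal <- basal %||% mask$basal
    pixel_size_um <- pixel_size_um %||% mask$pixel_size_um
    mask <- mask$mask
  }
  if (!is.logical(mask) || !is.matrix(mask))
    abort_bad_arg("`mask` must be a logical tissue matrix.")
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  check_columns(basal, c("x_um", "y_um"), "basal")
  if (nrow(basal) < 2L) abort_bad_arg("`basal` needs at least 2 points.")
  p <- cbind(basal$x_um, basal$y_um)
  seg <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  seg_len <- sqrt(rowSums(seg^2))
  basal_length <- sum(seg_len)
  if (basal_length <= 0) abort_bad_arg("basal polyline has zero length.")

  # rasterise the polyline by dense sampling (half-pixel step)
  ps <- pixel_size_um
  pts <- do.call(rbind, lapply(seq_len(nrow(p) - 1L), function(i) {
    n <- max(2L, ceiling(seg_len[i] / (ps / 2)) + 1L)
    t <- seq(0, 1, length.out = n)
    cbind(p[i, 1] + t * seg[i, 1], p[i, 2] + t * seg[i, 2])
  }))
  rows <- pmin(pmax(ceiling(pts[, 2] / ps), 1L), nrow(mask))
  cols <- pmin(pmax(ceiling(pts[, 1] / ps), 1L), ncol(mask))
  line_px <- unique(cbind(rows, cols))

  lab <- label_components(mask)
  # seed labels: tissue components touched by the line or its 8-neighbours
  touched <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    r <- pmin(pmax(line_px[, 1] + dr, 1L), nrow(mask))
    c <- pmin(pmax(line_px[, 2] + dc, 1L), ncol(mask))
    touched <- c(touched, lab[cbind(r, c)])
  }
  touched <- unique(touched[touched > 0L])
  if (!length(touched))
    abort_bad_arg("the basal polyline is not adjacent to any tissue.")
  roi_px <- sum(lab %in% touched)
  roi_area <- roi_px * ps^2
  tibble(mean_height_um = roi_area / basal_length,
         roi_area_um2 = roi_area, basal_length_um = basal_length)
}

#' Cells per millimetre of epithelium
#'
#' Density readout for stained-cell counts (e.g. Alcian Blue-positive
#' mucus-producing cells) expressed per mm of epithelium.
#'
#' @param positive_cell_count Non-negative count(s).
#' @param epithelium_length_mm Positive length(s), millimetres.
#' @return Numeric vector, cells/mm.
#' @export
cell_density <- function(positive_cell_count, epithelium_length_mm) {
  if (any(!is.finite(positive_cell_count)) || any(positive_cell_count < 0))
    abort_bad_arg("`positive_cell_count` must be finite and >= 0.")
  if (any(!is.finite(epithelium_length_mm)) || any(epithelium_length_mm <= 0))
    abort_bad_arg("`epithelium_length_mm` must be finite and > 0.")
  positive_cell_count / epithelium_length_mm
}
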