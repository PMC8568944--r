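#' Construct a histology image object
#'
#' A lightweight container for an RGB micrograph with a physical pixel size,
#' the unit every morphometry function works in.
#'
#' @param array Numeric array `height x width x 3` with values in `[0, 1]`
#'   (RGB channels).
#' @param pixel_size_um Physical side length of one pixel in micrometres
#'   (> 0).
#' @param id Optional identifier carried through to results.
#' @return An object of class `histology_image`.
#' @export
histology_image <- function(array, pixel_size_um, id = NULL) {
  if (!is.array(array) || length(dim(array)) != 3L || dim(array)[3] != 3L)
    abort_bad_arg("`array` must be a height x width x 3 RGB array.")
  if (any(dim(array)[1:2] < 1L)) abort_bad_arg("image must be at least 1 x 1.")
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  structure(list(array = array, pixel_size_um = pixel_size_um, id = id),
            class = "histology_image")
}

#' @export
print.histology_image <- function(x, ...) {
  d <- dim(x$array)
  cat(sprintf("<histology_image> %d x %d px @ %g um/px%s\n", d[2], d[1],
              x$pixel_size_um,
              if (!is.null(x$id)) paste0(" [", x$id, "]") else ""))
  invisible(x)
}

#' Describe airspaces for the parenchyma simulator
#'
#' @param shape Character vector, each element `"disc"` or `"square"`.
#' @param cx_um,cy_um Centre coordinates in micrometres (x rightwards,
#'   y downwards from the top-left image corner).
#' @param size_um Disc diameter or square side, micrometres.
#' @return A tibble with one row per airspace.
#' @export
airspace_spec <- function(shape, cx_um, cy_um, size_um) {
  shape <- match.arg(shape, c("disc", "square"), several.ok = TRUE)
  tibble(shape = shape, cx_um = cx_um, cy_um = cy_um, size_um = size_um)
}

#' Randomly place non-overlapping airspaces in a frame
#'
#' Rejection-samples centres until `n` airspaces fit without touching each
#' other (centre distance at least the sum of the radii plus `gap_um`).
#'
#' @param n Number of airspaces.
#' @param width_um,height_um Frame size in micrometres.
#' @param diameter_range_um Length-2 numeric: sampled uniformly.
#' @param shape `"disc"` or `"square"`.
#' @param gap_um Minimum clearance between airspace envelopes.
#' @param seed Optional integer seed.
#' @param max_tries Attempts before giving up.
#' @return An [airspace_spec()] tibble.
#' @export
random_airspaces <- function(n, width_um, height_um,
                             diameter_range_um = c(20, 60),
                             shape = "disc", gap_um = 4,
                             seed = NULL, max_tries = 5000L) {
  check_number(n, "n", min = 1)
  with_seed(seed, {
    out <- tibble(shape = character(), cx_um = numeric(),
                  cy_um = numeric(), size_um = numeric())
    tries <- 0L
    while (nrow(out) < n && tries < max_tries) {
      tries <- tries + 1L
      d <- runif(1, diameter_range_um[1], diameter_range_um[2])
      r <- d / 2
      cx <- runif(1, r, width_um - r)
      cy <- runif(1, r, height_um - r)
      ok <- if (nrow(out) == 0L) TRUE else
        all(sqrt((out$cx_um - cx)^2 + (out$cy_um - cy)^2) >
              (out$size_um + d) / 2 + gap_um)
      if (ok) out <- dplyr::bind_rows(out, tibble(shape = shape, cx_um = cx,
                                                  cy_um = cy, size_um = d))
    }
    if (nrow(out) < n)
      abort_bad_arg("could not place %d non-overlapping airspaces in %d tries.",
                    n, max_tries)
    out
  })
}

#' Simulate a lung-parenchyma micrograph with ground truth
#'
#' Renders an RGB image emulating an HES-stained parenchyma field: a
#' saturated tissue background with unsaturated (near-white) airspaces.
#' Pixels are classified hard (no antialiasing) so the returned ground-truth
#' mask is exact and downstream binarization can be checked pixel for pixel.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param airspaces An [airspace_spec()] tibble.
#' @param tissue_saturation,air_saturation HSV saturation of the two classes,
#'   in `[0, 1]`; tissue must be strictly more saturated than air.
#' @param hue Hue of both classes (default eosin-like pink).
#' @param noise_sd Gaussian noise added to the saturation channel before the
#'   RGB conversion (clamped to `[0, 1]`); the ground truth is unaffected.
#' @param allow_overlap If `FALSE` (default), two airspaces claiming the same
#'   pixel is an error.
#' @param seed Optional integer seed (noise only).
#' @return A list of class `parenchyma_sim`:
#'   `image` ([histology_image()]), `mask` (logical matrix, `TRUE` = air),
#'   `truth` (tibble with per-airspace pixel counts, true area in um^2 and
#'   equivalent circular diameter), and `pixel_size_um`.
#' @export
sim_parenchyma <- function(width_px, height_px, pixel_size_um, airspaces,
                           tissue_saturation = 0.8, air_saturation = 0.05,
                           hue = 0.93, noise_sd = 0, allow_overlap = FALSE,
                           seed = NULL) {
  check_number(width_px, "width_px", min = 1)
  check_number(height_px, "height_px", min = 1)
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  check_number(tissue_saturation, "tissue_saturation", min = 0, max = 1)
  check_number(air_saturation, "air_saturation", min = 0, max = 1)
  if (tissue_saturation <= air_saturation)
    abort_bad_arg("`tissue_saturation` (%g) must exceed `air_saturation` (%g).",
                  tissue_saturation, air_saturation)
  check_columns(airspaces, c("shape", "cx_um", "cy_um", "size_um"), "airspaces")

  # pixel centres in um
  xc <- (seq_len(width_px) - 0.5) * pixel_size_um
  yc <- (seq_len(height_px) - 0.5) * pixel_size_um
  X <- matrix(xc, height_px, width_px, byrow = TRUE)
  Y <- matrix(yc, height_px, width_px)

  mask <- matrix(FALSE, height_px, width_px)
  claimed <- matrix(0L, height_px, width_px)
  truth <- purrr::pmap_dfr(airspaces, function(shape, cx_um, cy_um, size_um) {
    inside <- if (shape == "disc") {
      (X - cx_um)^2 + (Y - cy_um)^2 <= (size_um / 2)^2
    } else {
      abs(X - cx_um) <= size_um / 2 & abs(Y - cy_um) <= size_um / 2
    }
    if (!any(inside))
      abort_bad_arg("an airspace at (%g, %g) um lies entirely outside the frame.",
                    cx_um, cy_um)
    if (!allow_overlap && any(claimed[inside] > 0L))
      abort_bad_arg("airspaces overlap; set `allow_overlap = TRUE` to permit this.")
    claimed[inside] <<- claimed[inside] + 1L
    mask[inside] <<- TRUE
    npx <- sum(inside)
    area <- npx * pixel_size_um^2
    tibble(shape = shape, cx_um = cx_um, cy_um = cy_um, size_um = size_um,
           n_pixels = npx, area_um2 = area,
           equiv_diameter_um = 2 * sqrt(area / pi))
  })

  sat <- matrix(tissue_saturation, height_px, width_px)
  sat[mask] <- air_saturation
  if (noise_sd > 0)
    sat <- with_seed(seed, pmin(1, pmax(0, sat + rnorm(length(sat), 0, noise_sd))))
  ch <- hsv_to_rgb(hue, sat)
  arr <- array(0, dim = c(height_px, width_px, 3))
  arr[, , 1] <- ch$r; arr[, , 2] <- ch$g; arr[, , 3] <- ch$b

  structure(list(image = histology_image(arr, pixel_size_um, id = "sim_parenchyma"),
                 mask = mask, truth = truth, pixel_size_um = pixel_size_um),
            class = "parenchyma_sim")
}

#' Simulate an epithelium band over a basal polyline
#'
#' Builds a binary tissue mask emulating a bronchiolo-alveolar junction
#' section: a band of tissue of prescribed (possibly varying) height sitting
#' on a manually-delimited basal polyline. The band is constructed as one
#' quadrilateral per polyline segment, offset along the segment normal, and
#' rasterised by hard pixel-centre classification. The analytic mean height
#' (trapezoid rule: sum of `L_i (h_i + h_{i+1}) / 2` over segments divided by
#' the total arc length) is returned as ground truth.
#'
#' @param basal Tibble/data.frame with columns `x_um`, `y_um`: the basal
#'   polyline (at least 2 points, non-zero length, non-self-intersecting).
#' @param heights_um Numeric vector, one height (>= 0) per basal vertex.
#' @param pixel_size_um Micrometres per pixel.
#' @param width_px,height_px Output mask size in pixels.
#' @return A list of class `epithelium_sim`: `mask` (logical, `TRUE` =
#'   tissue), `basal`, `pixel_size_um`, `true_mean_height_um`,
#'   `true_area_um2`, `basal_length_um`.
#' @export
sim_epithelium <- function(basal, heights_um, pixel_size_um,
                           width_px, height_px) {
  check_columns(basal, c("x_um", "y_um"), "basal")
  if (nrow(basal) < 2L) abort_bad_arg("`basal` needs at least 2 points.")
  if (length(heights_um) != nrow(basal))
    abort_bad_arg("`heights_um` must give one height per basal vertex.")
  if (any(!is.finite(heights_um)) || any(heights_um < 0))
    abort_bad_arg("heights must be finite and >= 0.")
  if (length(heights_um) == 0L || all(heights_um == 0))
    abort_bad_arg("height profile is empty (all zero).")
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)

  p <- cbind(basal$x_um, basal$y_um)
  seg_len <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (sum(seg_len) <= 0) abort_bad_arg("basal polyline has zero length.")

  xc <- (seq_len(width_px) - 0.5) * pixel_size_um
  yc <- (seq_len(height_px) - 0.5) * pixel_size_um
  X <- matrix(xc, height_px, width_px, byrow = TRUE)
  Y <- matrix(yc, height_px, width_px)
  mask <- matrix(FALSE, height_px, width_px)

  for (i in seq_len(nrow(p) - 1L)) {
    if (seg_len[i] == 0) next
    d <- (p[i + 1L, ] - p[i, ]) / seg_len[i]
    nrm <- c(d[2], -d[1])            # offset towards decreasing y for a
    if (nrm[2] > 0) nrm <- -nrm      # left-to-right horizontal basal line
    q <- rbind(p[i, ], p[i + 1L, ],
               p[i + 1L, ] + heights_um[i + 1L] * nrm,
               p[i, ] + heights_um[i] * nrm)
    # quad orientation from the shoelace formula, then a half-plane test per
    # edge; boundary pixels count as inside (hard classification)
    nxt <- c(2L, 3L, 4L, 1L)
    orient <- sign(sum(q[, 1] * q[nxt, 2] - q[nxt, 1] * q[, 2]))
    if (orient == 0) next                       # degenerate (zero heights)
    inside <- matrix(TRUE, height_px, width_px)
    for (k in 1:4) {
      a <- q[k, ]; b <- q[nxt[k], ]
      cross <- (b[1] - a[1]) * (Y - a[2]) - (b[2] - a[2]) * (X - a[1])
      inside <- inside & (cross * orient >= 0)
    }
    mask <- mask | inside
  }

  basal_length <- sum(seg_len)
  h <- heights_um
  true_area <- sum(seg_len * (h[-length(h)] + h[-1]) / 2)
  structure(list(mask = mask, basal = as_tibble(basal),
                 pixel_size_um = pixel_size_um,
                 true_mean_height_um = true_area / basal_length,
                 true_area_um2 = true_area,
                 basal_length_um = basal_length),
            class = "epithelium_sim")
}
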