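make_mask <- function(m) airspace_mask(m, 1)

test_that("saturation binarization handles the uniform extremes", {
  white <- histology_image(array(1, dim = c(8, 8, 3)), 1)
  expect_true(all(binarize_airspace(white, 0.5)$mask))
  sat <- array(0, dim = c(8, 8, 3)); sat[, , 1] <- 1  # pure red, S = 1
  expect_false(any(binarize_airspace(histology_image(sat, 1), 0.5)$mask))
  expect_error(binarize_airspace(matrix(1, 4, 4)), "histology_image")
})

test_that("binarization reproduces generator ground truth, threshold given or auto", {
  sp <- random_airspaces(8, 300, 300, c(15, 60), seed = 21)
  sim <- sim_parenchyma(300, 300, 1, sp, tissue_saturation = 0.8,
                        air_saturation = 0.05)
  expect_identical(binarize_airspace(sim$image, 0.4)$mask, sim$mask)
  auto <- binarize_airspace(sim$image, "auto")
  expect_identical(auto$mask, sim$mask)
  expect_gt(auto$threshold, 0.05); expect_lt(auto$threshold, 0.8)
})

test_that("particle analysis measures squares exactly", {
  m <- matrix(FALSE, 200, 200)
  m[51:150, 51:150] <- TRUE
  stats <- analyze_airspaces(make_mask(m))
  expect_equal(stats$count, 1)
  expect_equal(stats$mean_area_um2, 10000)
  expect_equal(stats$mean_perimeter_um, 400)  # edge counting exact for rectangles

  two <- matrix(FALSE, 100, 100)
  two[10:29, 10:29] <- TRUE      # 20 um side
  two[50:89, 50:89] <- TRUE      # 40 um side
  s2 <- analyze_airspaces(make_mask(two))
  expect_equal(s2$count, 2)
  expect_equal(s2$mean_area_um2, (400 + 1600) / 2)
})

test_that("the minimum-diameter filter ignores small airspaces, boundary kept", {
  # equivalent diameters 4 and 6 um from pixel counts
  area_px <- function(d) round(pi * (d / 2)^2)
  m <- matrix(FALSE, 60, 60)
  m[10:12, 10:13] <- TRUE                       # 12 px, d = 3.9 um -> dropped
  m[30:34, 30:35] <- TRUE                       # 30 px, d = 6.2 um -> kept
  expect_equal(analyze_airspaces(make_mask(m), 5)$count, 1)
  expect_equal(analyze_airspaces(make_mask(m), 0)$count, 2)
  # a particle exactly at the cutoff is retained (strictly-below rule)
  sq <- matrix(FALSE, 30, 30); sq[1:10, 1:10] <- TRUE
  d <- 2 * sqrt(100 / pi)
  expect_equal(analyze_airspaces(make_mask(sq), d)$count, 1)
})

test_that("particles are 8-connected and the filter is monotone", {
  diag2 <- matrix(FALSE, 4, 4); diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(nrow(airspace_particles(make_mask(diag2))), 1)
  sp <- random_airspaces(6, 200, 200, c(4, 40), seed = 5)
  sim <- sim_parenchyma(200, 200, 1, sp)
  counts <- vapply(c(0, 5, 10, 20, 40),
                   function(d) analyze_airspaces(sim, d)$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("empty masks are flagged, not silently averaged", {
  empty <- make_mask(matrix(FALSE, 10, 10))
  s <- analyze_airspaces(empty)
  expect_equal(s$count, 0); expect_true(is.na(s$mean_area_um2))
  mli <- mean_linear_intercept(empty)
  expect_true(is.na(mli$mli_um)); expect_equal(mli$n_chords, 0)
})

test_that("MLI of a single square equals its side", {
  m <- matrix(FALSE, 120, 120); m[31:80, 31:80] <- TRUE
  res <- mean_linear_intercept(make_mask(m))
  expect_equal(res$mli_um, 50)
  expect_equal(res$n_chords, 100)
})

test_that("MLI of two squares matches the hand-enumerated chord mean", {
  m <- matrix(FALSE, 100, 100)
  m[10:29, 10:29] <- TRUE; m[50:89, 40:79] <- TRUE
  expected <- (2 * 20 * 20 + 2 * 40 * 40) / (2 * (20 + 40))
  expect_equal(mean_linear_intercept(make_mask(m))$mli_um, expected)
})

test_that("MLI of a disc approaches the analytic mean chord pi*d/4", {
  for (d in c(50, 120, 200)) {
    sim <- sim_parenchyma(d + 20, d + 20, 1,
                          airspace_spec("disc", (d + 20) / 2, (d + 20) / 2, d))
    mli <- mean_linear_intercept(airspace_mask(sim$mask, 1))$mli_um
    expect_lt(abs(mli - pi * d / 4) / (pi * d / 4), 0.02)
  }
})

test_that("MLI is scale-equivariant and symmetric under 90-degree rotation", {
  set.seed(42)
  m <- random_mask(40, 64, 0.4)
  base <- mean_linear_intercept(airspace_mask(m, 1))
  scaled <- mean_linear_intercept(airspace_mask(m, 2.5))
  expect_equal(scaled$mli_um, base$mli_um * 2.5)
  expect_equal(scaled$n_chords, base$n_chords)
  rot <- mean_linear_intercept(airspace_mask(t(m[nrow(m):1, ]), 1))
  expect_equal(rot$mli_um, base$mli_um)
  expect_equal(rot$n_horizontal, base$n_vertical)
})

test_that("chord enumeration matches an exhaustive per-pixel scan", {
  set.seed(99)
  for (k in 1:50) {
    m <- random_mask(sample(4:32, 1), sample(4:32, 1), runif(1, 0.1, 0.9))
    got <- mli_chords(airspace_mask(m, 1))
    ora <- oracle_chords(m)
    expect_identical(sort(got$length_um[got$orientation == "horizontal"]),
                     sort(as.numeric(ora$horizontal)))
    expect_identical(sort(got$length_um[got$orientation == "vertical"]),
                     sort(as.numeric(ora$vertical)))
  }
})

test_that("epithelium height recovers band geometry", {
  basal <- tibble::tibble(x_um = c(20, 220), y_um = c(60, 60))
  rect <- sim_epithelium(basal, c(30, 30), 1, 240, 80)
  expect_equal(epithelium_mean_height(rect)$mean_height_um, 30)
  wedge <- sim_epithelium(basal, c(0, 40), 1, 240, 80)
  got <- epithelium_mean_height(wedge)$mean_height_um
  expect_lt(abs(got - 20) / 20, 0.01)
})

test_that("epithelium height rejects degenerate input", {
  m <- matrix(TRUE, 20, 20)
  expect_error(epithelium_mean_height(m, tibble::tibble(x_um = 1, y_um = 1), 1),
               "2 points")
  far <- matrix(FALSE, 50, 50); far[1:3, 1:3] <- TRUE
  expect_error(
    epithelium_mean_height(far, tibble::tibble(x_um = c(30, 45), y_um = c(40, 40)), 1),
    "not adjacent")
})

test_that("cell density is a guarded ratio", {
  expect_equal(cell_density(50, 2), 25)
  expect_equal(cell_density(0, 3), 0)
  expect_error(cell_density(10, 0), "> 0")
  expect_error(cell_density(-1, 1), ">= 0")
})
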