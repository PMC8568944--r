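test_that("simulated deflation volumes follow the closed form", {
  v <- sim_pv_curve(1.2, 1.0, 0.12, c(0, 10))$volume_ml
  expect_equal(v[1], 0.2)                     # P = 0: A - B
  expect_equal(v[2], 1.2 - exp(-1.2))         # ~0.8988
  expect_error(sim_pv_curve(1, 1, 0, c(0, 1)), "K")
  expect_error(sim_pv_curve(1, 1, 0.1, c(5, 1)), "non-decreasing")
  a <- sim_pv_curve(1, 1, 0.1, 0:10, noise_sd = 0.02, seed = 5)
  b <- sim_pv_curve(1, 1, 0.1, 0:10, noise_sd = 0.02, seed = 5)
  expect_identical(a, b)
})

test_that("deflation limb extraction finds the turning point", {
  loop <- sim_pv_loop(1.2, 1, 0.12, n_up = 20, n_down = 20)
  limb <- extract_deflation_limb(loop)
  expect_equal(nrow(limb), 20)
  expect_equal(limb$volume_ml, attr(loop, "deflation")$volume_ml)
  up_only <- tibble::tibble(pressure_cmh2o = 0:10, volume_ml = seq(0, 1, 0.1))
  expect_error(extract_deflation_limb(up_only), "no deflation limb")
})

test_that("noiseless curves are recovered to high precision", {
  for (p in list(c(1.2, 1.0, 0.12), c(2.5, 1.8, 0.4), c(0.9, 0.3, 0.05))) {
    span <- max(3 / p[3], 30)
    limb <- sim_pv_curve(p[1], p[2], p[3], seq(0, span, length.out = 30))
    fit <- fit_salazar_knowles(limb)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$estimates - c(A = p[1], B = p[2], K = p[3])) / p), 1e-6)
  }
})

test_that("the fit guards its preconditions and flags failure", {
  limb3 <- sim_pv_curve(1, 1, 0.1, c(0, 5, 10))
  expect_error(fit_salazar_knowles(limb3), "4 points")
  same_p <- tibble::tibble(pressure_cmh2o = rep(5, 6), volume_ml = rnorm(6))
  expect_error(fit_salazar_knowles(same_p), "distinct")
  # degenerate (exactly linear) data cannot satisfy the exponential model well;
  # whatever happens it must be reported, not silent
  lin <- tibble::tibble(pressure_cmh2o = 0:9, volume_ml = 0:9)
  fit <- fit_salazar_knowles(lin)
  expect_true(is.logical(fit$converged))
})

test_that("fits are order-invariant and scale with volume units", {
  limb <- sim_pv_curve(1.2, 1, 0.12, seq(0, 30, length.out = 25),
                       noise_sd = 0.01, seed = 8)
  f1 <- fit_salazar_knowles(limb)
  f2 <- fit_salazar_knowles(limb[sample(nrow(limb)), ])
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-8)
  ml_to_l <- limb; ml_to_l$volume_ml <- ml_to_l$volume_ml * 1000
  f3 <- fit_salazar_knowles(ml_to_l)
  expect_equal(f3$estimates[["A"]], f1$estimates[["A"]] * 1000, tolerance = 1e-6)
  expect_equal(f3$estimates[["K"]], f1$estimates[["K"]], tolerance = 1e-6)
  expect_equal(static_compliance(f3), static_compliance(f1) * 1000,
               tolerance = 1e-6)
})

test_that("K is recovered without material bias at 1% noise", {
  set.seed(123)
  K <- vapply(1:100, function(i) {
    limb <- sim_pv_curve(1.2, 1.0, 0.12, seq(0, 30, length.out = 30),
                         noise_sd = 0.01, seed = 1000 + i)
    fit_salazar_knowles(limb)$estimates[["K"]]
  }, numeric(1))
  expect_lt(abs(mean(K) - 0.12) / 0.12, 0.05)
})

test_that("static compliance is the derivative of the fitted curve", {
  expect_equal(static_compliance(list(B = 1, K = 0.1), 5), 0.1 * exp(-0.5))
  expect_equal(static_compliance(list(B = 2, K = 0.3), 0), 0.6)  # P = 0: B*K
  # monotone decay in K at fixed positive pressure
  cst <- vapply(c(0.1, 0.5, 1, 5), function(k)
    static_compliance(list(B = 1, K = k), 5), numeric(1))
  expect_true(all(diff(cst) < 0))
  expect_error(static_compliance(list(B = 1, K = 0.1), -1), ">= 0")
})

test_that("tidy and glance expose the sk fit", {
  fit <- fit_salazar_knowles(sim_pv_curve(1.2, 1, 0.12, seq(0, 30, 2)))
  td <- tidy(fit)
  expect_equal(td$term, c("A", "B", "K"))
  gl <- glance(fit)
  expect_true(gl$converged); expect_equal(gl$n, 16)
})
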