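#' Simulate a pressure-volume deflation limb
#'
#' Volumes follow the Salazar-Knowles exponential
#' `V(P) = A - B * exp(-K * P)` plus optional Gaussian noise, the model used
#' to summarise the deflation arm of a full-range PV manoeuvre.
#'
#' @param A Asymptotic volume (estimate of inspiratory capacity), mL.
#' @param B Volume span, mL (> 0).
#' @param K Shape constant, 1/cmH2O (> 0).
#' @param pressures Non-negative, non-decreasing pressures, cmH2O.
#' @param noise_sd SD of additive Gaussian noise, mL.
#' @param seed Optional integer seed.
#' @return Tibble `pressure_cmh2o`, `volume_ml` with the true parameters in
#'   `attr(, "truth")`.
#' @export
sim_pv_curve <- function(A, B, K, pressures, noise_sd = 0, seed = NULL) {
  check_number(A, "A"); check_number(B, "B", min = 0, strict_min = TRUE)
  check_number(K, "K", min = 0, strict_min = TRUE)
  if (any(pressures < 0) || is.unsorted(pressures))
    abort_bad_arg("`pressures` must be non-negative and non-decreasing.")
  v <- A - B * exp(-K * pressures)
  if (noise_sd > 0) v <- with_seed(seed, v + rnorm(length(v), 0, noise_sd))
  out <- tibble(pressure_cmh2o = pressures, volume_ml = v)
  attr(out, "truth") <- list(A = A, B = B, K = K)
  out
}

#' Simulate a full pressure-volume loop
#'
#' The inflation limb rises along a steeper exponential (hysteresis), the
#' deflation limb follows the Salazar-Knowles model; both share the endpoint
#' at peak pressure. The deflation samples are the ground truth for
#' [extract_deflation_limb()].
#'
#' @inheritParams sim_pv_curve
#' @param p_max Peak pressure, cmH2O.
#' @param n_up,n_down Samples per limb.
#' @return Tibble `pressure_cmh2o`, `volume_ml`, `phase`
#'   (`"inflation"`/`"deflation"`); `attr(, "deflation")` holds the clean
#'   deflation tibble, `attr(, "truth")` the parameters.
#' @export
sim_pv_loop <- function(A, B, K, p_max = 30, n_up = 20, n_down = 20,
                        noise_sd = 0, seed = NULL) {
  check_number(p_max, "p_max", min = 0, strict_min = TRUE)
  p_up <- seq(0, p_max, length.out = n_up)
  p_down <- seq(p_max, 0, length.out = n_down)
  v_at <- function(p) A - B * exp(-K * p)
  # inflation: same endpoints, lower volumes at mid-pressure (hysteresis)
  k_up <- K / 2
  v0 <- v_at(0); v1 <- v_at(p_max)
  v_up <- v0 + (v1 - v0) * (1 - exp(-k_up * p_up)) / (1 - exp(-k_up * p_max))
  v_down <- v_at(p_down)
  if (noise_sd > 0) {
    noise <- with_seed(seed, rnorm(n_up + n_down, 0, noise_sd))
    v_up <- v_up + noise[seq_len(n_up)]
    v_down <- v_down + noise[n_up + seq_len(n_down)]
  }
  out <- tibble(pressure_cmh2o = c(p_up, p_down),
                volume_ml = c(v_up, v_down),
                phase = rep(c("inflation", "deflation"), c(n_up, n_down)))
  attr(out, "deflation") <- tibble(pressure_cmh2o = p_down, volume_ml = v_down)
  attr(out, "truth") <- list(A = A, B = B, K = K)
  out
}

#' Extract the deflation limb of a PV loop
#'
#' Finds the turning point (first sample at peak pressure) and returns the
#' samples from the peak to the end, ordered by decreasing pressure. A
#' record that only goes up (peak at the final sample) has no deflation limb
#' and is an error.
#'
#' @param curve Tibble with `pressure_cmh2o`, `volume_ml`.
#' @return Tibble with the deflation samples, decreasing pressure.
#' @export
extract_deflation_limb <- function(curve) {
  check_columns(curve, c("pressure_cmh2o", "volume_ml"), "curve")
  # with a tie at peak pressure (inflation end = deflation start) the limb
  # begins at the last tied sample
  peak <- max(which(curve$pressure_cmh2o == max(curve$pressure_cmh2o)))
  if (peak >= nrow(curve))
    abort_bad_arg("record is monotone increasing: no deflation limb after the turning point.")
  limb <- curve[peak:nrow(curve), c("pressure_cmh2o", "volume_ml")]
  dplyr::arrange(limb, dplyr::desc(.data$pressure_cmh2o))
}

#' Fit the Salazar-Knowles exponential to a deflation limb
#'
#' Nonlinear least squares of `V = A - B * exp(-K * P)` (Levenberg-Marquardt
#' via minpack.lm, K bounded above 0). Starting values: `A0 = max(V)`,
#' `B0 = A0 - min(V)`, and `K0` from the slope of
#' `log(A0 + eps - V)` against `P` with `eps = 1e-9 * B0`. Non-convergence
#' or degenerate data is reported through the `converged` flag rather than a
#' silent result.
#'
#' @param limb Tibble with `pressure_cmh2o`, `volume_ml`; at least 4 points
#'   spanning at least 2 distinct pressures.
#' @return Object of class `sk_fit`: estimates `A`, `B`, `K` with standard
#'   errors, residual sum of squares, `converged`, the data, and the fit.
#'   See [tidy.sk_fit()], [glance.sk_fit()], [static_compliance()].
#' @export
fit_salazar_knowles <- function(limb) {
  check_columns(limb, c("pressure_cmh2o", "volume_ml"), "limb")
  P <- limb$pressure_cmh2o; V <- limb$volume_ml
  if (length(P) < 4L)
    abort_bad_arg("at least 4 points are required to fit the 3-parameter model (got %d).",
                  length(P))
  if (length(unique(P)) < 2L)
    abort_bad_arg("pressures must span at least 2 distinct values.")

  A0 <- max(V)
  B0 <- max(A0 - min(V), 1e-8)
  eps <- 1e-9 * B0
  K0 <- tryCatch({
    sl <- coef(lm(log(A0 + eps - V) ~ P))[["P"]]
    if (is.finite(sl) && sl < 0) -sl else 0.1
  }, error = function(e) 0.1)

  fit <- tryCatch(
    minpack.lm::nlsLM(V ~ A - B * exp(-K * P),
                      start = list(A = A0, B = B0, K = K0),
                      lower = c(A = -Inf, B = 1e-12, K = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    res <- structure(list(estimates = c(A = NA_real_, B = NA_real_, K = NA_real_),
                          se = c(A = NA_real_, B = NA_real_, K = NA_real_),
                          rss = NA_real_, converged = FALSE,
                          message = conditionMessage(fit),
                          n = length(P), data = as_tibble(limb), fit = NULL),
                     class = "sk_fit")
    return(res)
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(estimates = est, se = setNames(se, names(est)),
                 rss = sum(resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 message = fit$convInfo$stopMessage %||% "",
                 n = length(P), data = as_tibble(limb), fit = fit),
            class = "sk_fit")
}

#' @export
print.sk_fit <- function(x, ...) {
  cat("<sk_fit> V(P) = A - B * exp(-K * P)\n")
  if (x$converged) {
    cat(sprintf("  A = %.5g mL, B = %.5g mL, K = %.5g /cmH2O  (n = %d, RSS = %.3g)\n",
                x$estimates["A"], x$estimates["B"], x$estimates["K"], x$n, x$rss))
  } else {
    cat("  fit did not converge:", x$message, "\n")
  }
  invisible(x)
}

#' @describeIn fit_salazar_knowles Tidy the parameter estimates.
#' @param x An `sk_fit`.
#' @param ... Unused.
#' @export
tidy.sk_fit <- function(x, ...) {
  tibble(term = names(x$estimates),
         estimate = unname(x$estimates),
         std.error = unname(x$se[names(x$estimates)]))
}

#' @describeIn fit_salazar_knowles One-row fit summary.
#' @export
glance.sk_fit <- function(x, ...) {
  tibble(rss = x$rss, sigma = if (is.na(x$rss)) NA_real_ else sqrt(x$rss / max(x$n - 3, 1)),
         converged = x$converged, n = x$n)
}

#' Static compliance from a fitted PV curve
#'
#' The elastic recoil summary `Cst` is taken as the slope of the fitted
#' deflation curve, `dV/dP = B * K * exp(-K * P)`, evaluated at a chosen
#' pressure (default 5 cmH2O, configurable).
#'
#' @param params An `sk_fit`, or a list/one-row data frame with `B` and `K`.
#' @param eval_pressure_cmh2o Pressure(s) at which to evaluate the slope;
#'   must be >= 0.
#' @return Numeric vector, mL/cmH2O.
#' @export
static_compliance <- function(params, eval_pressure_cmh2o = 5) {
  if (inherits(params, "sk_fit")) {
    if (!params$converged) abort_bad_arg("cannot derive Cst from a failed fit.")
    B <- params$estimates[["B"]]; K <- params$estimates[["K"]]
  } else {
    B <- params[["B"]]; K <- params[["K"]]
  }
  if (is.null(B) || is.null(K) || !is.finite(B) || !is.finite(K))
    abort_bad_arg("`params` must provide finite B and K.")
  if (K <= 0 || B <= 0) abort_bad_arg("B and K must be > 0.")
  if (any(eval_pressure_cmh2o < 0))
    abort_bad_arg("`eval_pressure_cmh2o` must be >= 0.")
  B * K * exp(-K * eval_pressure_cmh2o)
}
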