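# schema of the YAML/list run configuration: allowed keys and ranges per stage
config_schema <- function() {
  list(
    parenchyma = list(
      width_px = c(16, Inf), height_px = c(16, Inf),
      pixel_size_um = c(1e-6, Inf), n_airspaces = c(1, Inf),
      diameter_range_um = NULL, tissue_saturation = c(0, 1),
      air_saturation = c(0, 1), saturation_threshold = NULL,
      min_diameter_um = c(0, Inf)),
    pv = list(A = NULL, B = c(1e-12, Inf), K = c(1e-12, Inf),
              p_max = c(1e-6, Inf), n_up = c(4, Inf), n_down = c(4, Inf),
              noise_sd = c(0, Inf), eval_pressure_cmh2o = c(0, Inf)),
    cohort = list(n_patients = c(1, Inf), abrasion_threshold_pct = c(0, 100),
                  exclude_smokers = NULL, alpha = c(0, 1),
                  smoker_p = c(0, 1)),
    genotyping = list(n_samples = c(1, Inf), length_nt = c(100, Inf)),
    calcium = list(baseline_f = c(0, Inf), peak_delta_f = c(0, Inf),
                   ionomycin_f = c(1e-12, Inf), noise_sd = c(0, Inf))
  )
}

stage_defaults <- function() {
  list(
    parenchyma = list(width_px = 256, height_px = 256, pixel_size_um = 1,
                      n_airspaces = 12, diameter_range_um = c(20, 60),
                      tissue_saturation = 0.8, air_saturation = 0.05,
                      saturation_threshold = "auto", min_diameter_um = 5),
    pv = list(A = 1.2, B = 1.0, K = 0.12, p_max = 30, n_up = 20, n_down = 30,
              noise_sd = 0.01, eval_pressure_cmh2o = 5),
    cohort = list(n_patients = 2000, abrasion_threshold_pct = 70,
                  exclude_smokers = TRUE, alpha = 0.1, smoker_p = 0.15),
    genotyping = list(n_samples = 12, length_nt = 250),
    calcium = list(baseline_f = 100, peak_delta_f = 80, ionomycin_f = 500,
                   noise_sd = 0)
  )
}

#' Validate a pipeline run configuration
#'
#' Schema and range checks for a configuration list or YAML file: unknown
#' stages or parameter keys, out-of-range thresholds and saturations,
#' non-positive pixel sizes, and a missing top-level seed are all reported
#' as findings (the function never errors; an empty result means valid).
#'
#' @param config A named list, or the path of a YAML file.
#' @return Tibble of findings: `field`, `message` (zero rows when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  findings <- list()
  note <- function(field, message)
    findings[[length(findings) + 1L]] <<- tibble(field = field, message = message)

  if (!is.list(config)) {
    note("(root)", "configuration must be a named list or YAML mapping")
    return(dplyr::bind_rows(findings))
  }
  unknown_top <- setdiff(names(config), c("seed", "stages"))
  for (k in unknown_top) note(k, "unknown top-level key")
  if (is.null(config$seed))
    note("seed", "a top-level integer seed is required (all stages are stochastic)")
  else if (!is.numeric(config$seed) || length(config$seed) != 1L)
    note("seed", "seed must be a single integer")

  schema <- config_schema()
  stages <- config$stages
  if (is.null(stages)) {
    note("stages", "no stages requested")
    return(dplyr::bind_rows(findings))
  }
  for (st in names(stages)) {
    if (!st %in% names(schema)) { note(st, "unknown stage"); next }
    pars <- stages[[st]] %||% list()
    for (key in names(pars)) {
      if (!key %in% names(schema[[st]])) {
        note(paste0(st, ".", key), "unknown parameter key")
        next
      }
      rng <- schema[[st]][[key]]
      val <- pars[[key]]
      if (!is.null(rng) && is.numeric(val) &&
          (any(val < rng[1]) || any(val > rng[2])))
        note(paste0(st, ".", key),
             sprintf("value %s outside [%g, %g]",
                     paste(signif(val, 6), collapse = ", "), rng[1], rng[2]))
    }
  }
  if (length(findings)) dplyr::bind_rows(findings)
  else tibble(field = character(), message = character())
}

stage_seed <- function(seed, stage) {
  offsets <- c(parenchyma = 101L, pv = 202L, cohort = 303L,
               genotyping = 404L, calcium = 505L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the simulate-analyze-report pipeline
#'
#' Executes the requested stages in a fixed dependency order (parenchyma
#' morphometry, PV fitting, cohort analysis, genotyping, calcium), each one
#' a plain composition of the package's module functions: the report of a
#' stage is identical to calling those functions directly with the same
#' parameters and seed. The configuration is validated before any stage
#' runs; per-stage seeds are derived deterministically from the top-level
#' seed, so identical configurations give identical reports.
#'
#' @param config A named list or YAML path; see [validate_config()] and the
#'   shipped default (`system.file("extdata", "default-config.yaml",
#'   package = "airmorph")`).
#' @return Object of class `run_report`: `results` per stage, the config
#'   echo and hash, package version and wall time.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  findings <- validate_config(config)
  if (nrow(findings))
    abort_bad_arg("invalid configuration:\n%s",
                  paste(sprintf("- %s: %s", findings$field, findings$message),
                        collapse = "\n"))
  t0 <- Sys.time()
  defs <- stage_defaults()
  order <- intersect(names(config_schema()), names(config$stages))
  warnings <- character()
  results <- list()

  for (st in order) {
    pars <- utils::modifyList(defs[[st]], config$stages[[st]] %||% list())
    sd <- stage_seed(config$seed, st)
    res <- withCallingHandlers(
      run_stage(st, pars, sd),
      warning = function(w) {
        warnings <<- c(warnings, paste0(st, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    results[[st]] <- c(res, list(params = pars, seed = sd))
  }

  structure(list(results = results,
                 config = config,
                 config_hash = rlang::hash(config),
                 version = as.character(utils::packageVersion("airmorph")),
                 wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                 warnings = warnings),
            class = "run_report")
}

run_stage <- function(stage, pars, seed) {
  switch(stage,
    parenchyma = {
      sp <- random_airspaces(pars$n_airspaces,
                             width_um = pars$width_px * pars$pixel_size_um,
                             height_um = pars$height_px * pars$pixel_size_um,
                             diameter_range_um = pars$diameter_range_um,
                             seed = seed)
      sim <- sim_parenchyma(pars$width_px, pars$height_px, pars$pixel_size_um,
                            sp, tissue_saturation = pars$tissue_saturation,
                            air_saturation = pars$air_saturation)
      mask <- binarize_airspace(sim$image, pars$saturation_threshold)
      list(airspace_stats = analyze_airspaces(mask, pars$min_diameter_um),
           mli = mean_linear_intercept(mask),
           mask_matches_truth = identical(mask$mask, sim$mask),
           truth = sim$truth)
    },
    pv = {
      loop <- sim_pv_loop(pars$A, pars$B, pars$K, p_max = pars$p_max,
                          n_up = pars$n_up, n_down = pars$n_down,
                          noise_sd = pars$noise_sd, seed = seed)
      fit <- fit_salazar_knowles(extract_deflation_limb(loop))
      list(sk = tidy(fit), fit_summary = glance(fit),
           cst = if (fit$converged)
             static_compliance(fit, pars$eval_pressure_cmh2o) else NA_real_)
    },
    cohort = {
      tab <- sim_cohort(pars$n_patients, smoker_p = pars$smoker_p, seed = seed)
      rep <- run_cohort_pipeline(tab,
                                 abrasion_threshold_pct = pars$abrasion_threshold_pct,
                                 exclude_smokers = pars$exclude_smokers,
                                 alpha = pars$alpha)
      list(odds_ratios = tidy(rep), summary = glance(rep),
           exclusions = rep$exclusions, n_retained = rep$n_retained)
    },
    genotyping = {
      gts <- rep(c("WT", "HT", "HO"), length.out = pars$n_samples)
      calls <- purrr::imap_dfr(gts, function(g, i) {
        al <- sim_allele_pair(g, length_nt = pars$length_nt, seed = seed + i)
        dplyr::mutate(genotype_from_digests(al), sample = i, truth = g,
                      .before = 1)
      })
      list(calls = calls, accuracy = mean(calls$call == calls$truth))
    },
    calcium = {
      tr <- sim_calcium_trace(pars$baseline_f, pars$peak_delta_f,
                              pars$ionomycin_f, noise_sd = pars$noise_sd,
                              seed = seed)
      list(response = normalize_calcium_response(tr))
    },
    abort_bad_arg("unknown stage `%s`.", stage))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> airmorph %s, config %s, %.2fs\n",
              x$version, substr(x$config_hash, 1, 8), x$wall_time_s))
  for (st in names(x$results)) cat(" -", st, "\n")
  if (length(x$warnings)) cat("warnings:", length(x$warnings), "\n")
  invisible(x)
}
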