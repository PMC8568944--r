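#' Specify a logistic outcome model for the cohort simulator
#'
#' Effects are given as odds ratios on the model's covariates: `HT` and `HO`
#' (genotype indicators against the WT reference), `age` (per year),
#' `genderF` (female vs male) and `allergy` (yes vs no). The intercept can
#' be given directly or solved so that the simulated prevalence hits a
#' target.
#'
#' @param or Named numeric vector of odds ratios; names must be a subset of
#'   `HT`, `HO`, `age`, `genderF`, `allergy`. Omitted covariates have OR 1.
#' @param intercept Log-odds intercept, or `NULL` to use
#'   `target_prevalence`.
#' @param target_prevalence Marginal outcome prevalence to solve the
#'   intercept for (used when `intercept` is `NULL`; default 0.4).
#' @return A list consumed by [sim_cohort()].
#' @export
outcome_model <- function(or, intercept = NULL, target_prevalence = 0.4) {
  known <- c("HT", "HO", "age", "genderF", "allergy")
  bad <- setdiff(names(or), known)
  if (length(bad))
    abort_bad_arg("unknown covariate(s) in outcome model: %s (known: %s).",
                  paste(bad, collapse = ", "), paste(known, collapse = ", "))
  if (any(or <= 0)) abort_bad_arg("odds ratios must be > 0.")
  if (is.null(intercept))
    check_number(target_prevalence, "target_prevalence", min = 1e-6, max = 1 - 1e-6)
  list(or = or, intercept = intercept, target_prevalence = target_prevalence)
}

reference_outcome_models <- function() {
  list(
    inflammation = outcome_model(c(HT = 3.5, HO = 6.47, age = 0.97)),
    secretory    = outcome_model(c(HT = 5.18, HO = 9.62, age = 0.99))
  )
}

#' Simulate a nasal-polyp style cohort with known ground truth
#'
#' Draws patient records (genotype at a biallelic SNP, age, gender,
#' allergy/asthma, smoking status, epithelial abrasion) and binary outcomes
#' from logistic models, then maps each binary outcome back to the raw
#' readout the histopathology pipeline consumes: a 0-3 inflammation score
#' (high = 2 or 3), a secretory-cell percentage (high = >= 10) and a
#' normal-epithelium percentage (high = >= 50). Exclusion flags (abrasion,
#' smoker) are generated independently of the outcomes.
#'
#' @param n Number of records (>= 1).
#' @param genotype_freqs Named probabilities for `WT`, `HT`, `HO`; must sum
#'   to 1.
#' @param age_mean,age_sd Age distribution (years), truncated at 18.
#' @param gender_p Probability of female.
#' @param allergy_p Probability of allergy/asthma.
#' @param outcome_models Named list of [outcome_model()]s; defaults to
#'   genotype/age effects matching the package's reference odds ratios for
#'   inflammation and secretory hyperplasia.
#' @param smoker_p Probability a record is a smoker.
#' @param abrasion_max Abrasion is drawn Uniform(0, `abrasion_max`) percent.
#' @param seed Optional integer seed.
#' @return Tibble with one row per patient; `attr(, "truth")` records the
#'   coefficients (log ORs) and solved intercepts actually used.
#' @export
sim_cohort <- function(n,
                       genotype_freqs = c(WT = 0.60, HT = 0.33, HO = 0.07),
                       age_mean = 45, age_sd = 15,
                       gender_p = 0.5, allergy_p = 0.3,
                       outcome_models = reference_outcome_models(),
                       smoker_p = 0.15, abrasion_max = 100,
                       seed = NULL) {
  check_number(n, "n", min = 1)
  if (abs(sum(genotype_freqs) - 1) > 1e-9)
    abort_bad_arg("`genotype_freqs` must sum to 1 (got %g).", sum(genotype_freqs))
  if (!all(c("WT", "HT", "HO") %in% names(genotype_freqs)))
    abort_bad_arg("`genotype_freqs` must name WT, HT and HO.")
  if (is.null(names(outcome_models)) || any(names(outcome_models) == ""))
    abort_bad_arg("`outcome_models` must be a named list.")

  with_seed(seed, {
    genotype <- factor(sample(c("WT", "HT", "HO"), n, replace = TRUE,
                              prob = genotype_freqs[c("WT", "HT", "HO")]),
                       levels = c("WT", "HT", "HO"))
    age <- pmax(18, rnorm(n, age_mean, age_sd))
    gender <- factor(ifelse(runif(n) < gender_p, "F", "M"), levels = c("M", "F"))
    allergy <- runif(n) < allergy_p
    smoker <- runif(n) < smoker_p
    abrasion <- runif(n, 0, abrasion_max)

    X <- cbind(HT = as.numeric(genotype == "HT"),
               HO = as.numeric(genotype == "HO"),
               age = age,
               genderF = as.numeric(gender == "F"),
               allergy = as.numeric(allergy))

    truth <- list()
    draws <- purrr::imap(outcome_models, function(m, nm) {
      beta <- setNames(numeric(ncol(X)), colnames(X))
      bad <- setdiff(names(m$or), colnames(X))
      if (length(bad))
        abort_bad_arg("outcome model `%s` references unknown covariate(s): %s.",
                      nm, paste(bad, collapse = ", "))
      beta[names(m$or)] <- log(m$or)
      lp0 <- drop(X %*% beta)
      b0 <- m$intercept %||%
        uniroot(function(b) mean(plogis(b + lp0)) - m$target_prevalence,
                c(-30, 30))$root
      truth[[nm]] <<- list(coef = beta, intercept = b0,
                           prevalence = mean(plogis(b0 + lp0)))
      runif(n) < plogis(b0 + lp0)
    })

    out <- tibble(
      id = seq_len(n), genotype = genotype, age = age, gender = gender,
      allergy_asthma = allergy, smoker = smoker, abrasion_pct = abrasion)

    # map binary outcomes back to the raw histopathology readouts
    if ("inflammation" %in% names(draws)) {
      hi <- draws$inflammation
      out$inflammation_score <- ifelse(hi, sample(2:3, n, replace = TRUE),
                                       sample(0:1, n, replace = TRUE))
    }
    if ("secretory" %in% names(draws)) {
      hi <- draws$secretory
      out$secretory_pct <- ifelse(hi, runif(n, 10, 100), runif(n, 0, 10 - 1e-9))
    }
    if ("normal" %in% names(draws)) {
      hi <- draws$normal
      out$normal_pct <- ifelse(hi, runif(n, 50, 100), runif(n, 0, 50 - 1e-9))
    }
    # any other outcome kept as a plain logical column
    for (nm in setdiff(names(draws), c("inflammation", "secretory", "normal")))
      out[[paste0(nm, "_high")]] <- draws[[nm]]

    attr(out, "truth") <- truth
    out
  })
}
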