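#' Apply the cohort exclusion filters
#'
#' Two ordered filters reproduce the study-selection arithmetic: records
#' with epithelial abrasion strictly above the threshold are removed first
#' (abrasion at exactly the threshold is retained), then smokers among the
#' remainder are removed. Counts per reason are therefore disjoint and
#' additive.
#'
#' @param data Cohort tibble with `abrasion_pct` and (if
#'   `exclude_smokers`) `smoker` columns.
#' @param abrasion_threshold_pct Abrasion cutoff, percent (default 70).
#' @param exclude_smokers Remove smokers from the remainder (default TRUE).
#' @return The filtered tibble; `attr(, "exclusion_log")` is a tibble with
#'   one row per reason (`reason`, `n_removed`) plus the retained count.
#'   See [exclusion_log()].
#' @export
apply_exclusions <- function(data, abrasion_threshold_pct = 70,
                             exclude_smokers = TRUE) {
  check_columns(data, "abrasion_pct", "data")
  if (exclude_smokers) check_columns(data, "smoker", "data")
  if (anyNA(data$abrasion_pct) || (exclude_smokers && anyNA(data$smoker)))
    abort_bad_arg("abrasion/smoker fields contain missing values.")
  check_number(abrasion_threshold_pct, "abrasion_threshold_pct", min = 0, max = 100)

  abraded <- data$abrasion_pct > abrasion_threshold_pct
  kept <- data[!abraded, , drop = FALSE]
  n_abr <- sum(abraded)
  n_smk <- 0L
  if (exclude_smokers) {
    smk <- kept$smoker
    n_smk <- sum(smk)
    kept <- kept[!smk, , drop = FALSE]
  }
  log <- tibble(reason = c(sprintf("abrasion > %g%%", abrasion_threshold_pct),
                           "smoker"),
                n_removed = c(n_abr, n_smk))
  attr(kept, "exclusion_log") <- list(log = log, n_input = nrow(data),
                                      n_retained = nrow(kept))
  kept
}

#' @rdname apply_exclusions
#' @param x A tibble returned by [apply_exclusions()].
#' @export
exclusion_log <- function(x) {
  attr(x, "exclusion_log") %||%
    abort_bad_arg("`x` carries no exclusion log; was it produced by apply_exclusions()?")
}

#' Binarize the histopathology readouts
#'
#' Applies the study cutpoints to every record: inflammation is high for
#' scores 2 and 3 (low for 0 and 1); secretory-cell hyperplasia is high at
#' 10 percent or more; normal-epithelium proportion is high at 50 percent
#' or more. Boundary values fall on the high side for the percentage
#' outcomes.
#'
#' @param data Cohort tibble. Columns `inflammation_score` (integers 0-3),
#'   `secretory_pct` and `normal_pct` (0-100) are each optional; present
#'   ones are binarized.
#' @return `data` with logical columns `inflammation_high`,
#'   `secretory_high`, `normal_high` appended (for the inputs present).
#' @export
binarize_outcomes <- function(data) {
  any_found <- FALSE
  if ("inflammation_score" %in% names(data)) {
    s <- data$inflammation_score
    if (any(!s %in% 0:3))
      abort_bad_arg("`inflammation_score` must be in {0, 1, 2, 3}.")
    data$inflammation_high <- s >= 2
    any_found <- TRUE
  }
  if ("secretory_pct" %in% names(data)) {
    p <- data$secretory_pct
    if (any(!is.finite(p)) || any(p < 0 | p > 100))
      abort_bad_arg("`secretory_pct` must be within [0, 100].")
    data$secretory_high <- p >= 10
    any_found <- TRUE
  }
  if ("normal_pct" %in% names(data)) {
    p <- data$normal_pct
    if (any(!is.finite(p)) || any(p < 0 | p > 100))
      abort_bad_arg("`normal_pct` must be within [0, 100].")
    data$normal_high <- p >= 50
    any_found <- TRUE
  }
  if (!any_found)
    abort_bad_arg("no binarizable outcome column found (inflammation_score, secretory_pct, normal_pct).")
  data
}

#' Univariate covariate screen for a binary outcome
#'
#' Categorical covariates are tested against the outcome with a Pearson
#' chi-squared test (no continuity correction); numeric covariates (age)
#' with a two-sided equal-variance Student t-test between outcome classes.
#'
#' @param data Cohort tibble containing `outcome` and the covariates.
#' @param outcome Name of a logical/binary column.
#' @param covariates Character vector of covariate columns to screen.
#' @return Tibble `covariate`, `test`, `statistic`, `p_value`. A degenerate
#'   table (zero margin) or class yields `NA` with a warning.
#' @export
univariate_screen <- function(data, outcome,
                              covariates = c("genotype", "gender",
                                             "allergy_asthma", "age")) {
  check_columns(data, c(outcome, covariates), "data")
  y <- data[[outcome]]
  if (!all(y %in% c(TRUE, FALSE)))
    abort_bad_arg("`%s` must be logical (binarize first).", outcome)
  purrr::map_dfr(covariates, function(cv) {
    x <- data[[cv]]
    if (is.numeric(x)) {
      if (min(table(y)) < 2L) {
        warn(sprintf("fewer than 2 records per class for `%s`: t-test undefined.", cv))
        return(tibble(covariate = cv, test = "t", statistic = NA_real_,
                      p_value = NA_real_))
      }
      tt <- t.test(x[y], x[!y], var.equal = TRUE)
      tibble(covariate = cv, test = "t",
             statistic = unname(tt$statistic), p_value = tt$p.value)
    } else {
      tab <- table(x, y)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warn(sprintf("zero margin in the `%s` x outcome table: chi-squared undefined.", cv))
        return(tibble(covariate = cv, test = "chisq", statistic = NA_real_,
                      p_value = NA_real_))
      }
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      tibble(covariate = cv, test = "chisq",
             statistic = unname(ct$statistic), p_value = ct$p.value)
    }
  })
}

#' Gate covariates on the univariate screen
#'
#' Keeps covariates with `p < alpha` (strict inequality: p exactly at the
#' gate is excluded), preserving the screen's ordering.
#'
#' @param screen_results Tibble from [univariate_screen()].
#' @param alpha Gate (default 0.1).
#' @return Character vector of covariate names (possibly empty).
#' @export
select_covariates <- function(screen_results, alpha = 0.1) {
  check_columns(screen_results, c("covariate", "p_value"), "screen_results")
  ok <- !is.na(screen_results$p_value) & screen_results$p_value < alpha
  screen_results$covariate[ok]
}

#' Multivariate logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit (IRLS via `stats::glm`) of a binary
#' outcome on the selected covariates. Genotype enters as two indicators
#' (HT, HO) against the WT reference; the reference levels are reported
#' with OR identically 1. Odds ratios are `exp(beta)` with Wald 95 percent
#' intervals `exp(beta +/- 1.959964 * SE)` and two-sided Wald p-values.
#' Perfect separation and non-convergence are flagged, never silent.
#'
#' @param data Cohort tibble.
#' @param outcome Name of a logical column.
#' @param covariates Covariate columns to include.
#' @return Object of class `cohort_logit`; [tidy.cohort_logit()] gives the
#'   per-term odds-ratio table, [glance.cohort_logit()] the model summary.
#' @export
fit_multivariate_logistic <- function(data, outcome, covariates) {
  check_columns(data, c(outcome, covariates), "data")
  if (anyNA(data[c(outcome, covariates)]))
    abort_bad_arg("missing values in outcome/covariates are rejected, not imputed.")
  y <- data[[outcome]]
  if (length(unique(y)) < 2L)
    abort_bad_arg("outcome `%s` is constant: the model is separated.", outcome)
  if (!length(covariates)) abort_bad_arg("no covariates to fit.")

  f <- stats::as.formula(paste0("`", outcome, "` ~ ",
                                paste0("`", covariates, "`", collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })

  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  zcrit <- 1.959964
  terms_tbl <- tibble(
    term = names(est),
    covariate = NA_character_,
    odds_ratio = exp(est),
    ci95_low = exp(est - zcrit * se),
    ci95_high = exp(est + zcrit * se),
    p_value = 2 * pnorm(-abs(z)))

  # attach covariate names and inject reference-level rows for factors
  rows <- list()
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.factor(x) || is.character(x) || is.logical(x)) {
      lev <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
      ref <- lev[1]
      rows[[cv]] <- dplyr::bind_rows(
        tibble(term = paste0(cv, ref, " (reference)"), covariate = cv,
               odds_ratio = 1, ci95_low = NA_real_, ci95_high = NA_real_,
               p_value = NA_real_),
        dplyr::mutate(
          dplyr::filter(terms_tbl, startsWith(.data$term, cv) |
                          startsWith(.data$term, paste0("`", cv, "`"))),
          covariate = cv))
    } else {
      rows[[cv]] <- dplyr::mutate(
        dplyr::filter(terms_tbl, .data$term %in% c(cv, paste0("`", cv, "`"))),
        covariate = cv)
    }
  }
  table <- dplyr::bind_rows(rows)
  table$term <- gsub("`", "", table$term)

  structure(list(table = table, outcome = outcome, covariates = covariates,
                 n = nrow(data), converged = fit$converged,
                 separation = separated, fit = fit),
            class = "cohort_logit")
}

#' @export
print.cohort_logit <- function(x, ...) {
  cat(sprintf("<cohort_logit> %s ~ %s  (n = %d%s%s)\n", x$outcome,
              paste(x$covariates, collapse = " + "), x$n,
              if (!x$converged) ", NOT converged" else "",
              if (x$separation) ", possible separation" else ""))
  print(x$table, n = Inf)
  invisible(x)
}

#' @describeIn fit_multivariate_logistic Odds-ratio table
#'   (`term`, `covariate`, `odds_ratio`, `ci95_low`, `ci95_high`,
#'   `p_value`).
#' @param x A `cohort_logit`.
#' @param ... Unused.
#' @export
tidy.cohort_logit <- function(x, ...) x$table

#' @describeIn fit_multivariate_logistic One-row model summary.
#' @export
glance.cohort_logit <- function(x, ...) {
  tibble(outcome = x$outcome, n = x$n, converged = x$converged,
         separation = x$separation,
         deviance = x$fit$deviance, null_deviance = x$fit$null.deviance)
}

#' Run the full cohort analysis pipeline
#'
#' Chains the four stages on a raw cohort table: exclusion filters,
#' outcome binarization, per-outcome univariate screening, the `p < 0.1`
#' covariate gate, and the multivariate logistic fit, producing a
#' table-shaped report of odds ratios with 95 percent CIs per covariate per
#' outcome. Outcomes for which no covariate passes the gate are reported
#' with an empty model and no fit is attempted.
#'
#' @param data Raw cohort tibble (see [sim_cohort()] for the columns).
#' @param outcomes Outcomes to analyse; each must have a binarized column
#'   `<outcome>_high` after [binarize_outcomes()].
#' @param covariates Covariates screened for every outcome.
#' @param abrasion_threshold_pct,exclude_smokers Passed to
#'   [apply_exclusions()].
#' @param alpha Univariate gate (default 0.1).
#' @return Object of class `cohort_report`: exclusion log, per-outcome
#'   screens, selected covariates and fits. `tidy()` returns the combined
#'   odds-ratio table.
#' @export
run_cohort_pipeline <- function(data,
                                outcomes = c("inflammation", "secretory"),
                                covariates = c("genotype", "gender",
                                               "allergy_asthma", "age"),
                                abrasion_threshold_pct = 70,
                                exclude_smokers = TRUE, alpha = 0.1) {
  kept <- apply_exclusions(data, abrasion_threshold_pct, exclude_smokers)
  log <- exclusion_log(kept)
  if (any(c("inflammation_score", "secretory_pct", "normal_pct") %in% names(kept)))
    kept <- binarize_outcomes(kept)

  per_outcome <- purrr::map(setNames(outcomes, outcomes), function(oc) {
    col <- paste0(oc, "_high")
    if (!col %in% names(kept))
      abort_bad_arg("outcome `%s` has no binarized column `%s`.", oc, col)
    screen <- univariate_screen(kept, col, covariates)
    selected <- select_covariates(screen, alpha)
    fit <- if (length(selected))
      fit_multivariate_logistic(kept, col, selected) else NULL
    list(screen = screen, selected = selected, fit = fit)
  })

  structure(list(n_input = log$n_input, n_retained = log$n_retained,
                 exclusions = log$log, alpha = alpha,
                 outcomes = per_outcome, data = kept),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d retained of %d\n", x$n_retained, x$n_input))
  print(x$exclusions)
  for (oc in names(x$outcomes)) {
    o <- x$outcomes[[oc]]
    cat(sprintf("\n-- %s: gate p < %g kept [%s]\n", oc, x$alpha,
                paste(o$selected, collapse = ", ")))
    if (is.null(o$fit)) cat("   no covariate passed the gate; no model fitted\n")
    else print(o$fit$table, n = Inf)
  }
  invisible(x)
}

#' @describeIn run_cohort_pipeline Combined odds-ratio table across
#'   outcomes (empty models contribute no rows).
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @export
tidy.cohort_report <- function(x, ...) {
  purrr::imap_dfr(x$outcomes, function(o, nm) {
    if (is.null(o$fit)) return(tibble())
    dplyr::mutate(o$fit$table, outcome = nm, .before = 1)
  })
}

#' @describeIn run_cohort_pipeline Per-outcome summary with counts and
#'   convergence flags.
#' @export
glance.cohort_report <- function(x, ...) {
  purrr::imap_dfr(x$outcomes, function(o, nm) {
    tibble(outcome = nm, n = x$n_retained,
           n_selected = length(o$selected),
           fitted = !is.null(o$fit),
           converged = if (is.null(o$fit)) NA else o$fit$converged,
           separation = if (is.null(o$fit)) NA else o$fit$separation)
  })
}
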