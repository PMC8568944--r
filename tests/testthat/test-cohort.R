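test_that("exclusion filters are ordered, strict and additive", {
  co <- make_exclusion_fixture()
  kept <- apply_exclusions(co)
  log <- exclusion_log(kept)
  expect_equal(log$n_retained, 123)
  expect_equal(log$log$n_removed, c(64, 26))
  expect_equal(nrow(co) - sum(log$log$n_removed), nrow(kept))
  # abrasion exactly at the threshold is retained
  edge <- tibble::tibble(abrasion_pct = c(70, 70.1), smoker = c(FALSE, FALSE))
  expect_equal(nrow(apply_exclusions(edge)), 1)
  # empty table passes through
  empty <- apply_exclusions(edge[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(exclusion_log(empty)$n_retained, 0)
  expect_error(apply_exclusions(tibble::tibble(x = 1)), "abrasion_pct")
})

test_that("outcome binarization applies the exact cutpoints", {
  rec <- tibble::tibble(inflammation_score = c(0, 1, 2, 3),
                        secretory_pct = c(9.99, 10, 10.01, 50),
                        normal_pct = c(49, 50, 51, 0))
  out <- binarize_outcomes(rec)
  expect_equal(out$inflammation_high, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$secretory_high, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$normal_high, c(FALSE, TRUE, TRUE, FALSE))
  expect_error(binarize_outcomes(tibble::tibble(inflammation_score = 4)),
               "0, 1, 2, 3")
  expect_error(binarize_outcomes(tibble::tibble(secretory_pct = 101)), "100")
})

test_that("univariate screen matches hand-computed chi-squared and t", {
  # perfectly balanced 2x2: statistic 0, p = 1
  bal <- tibble::tibble(
    genotype = factor(rep(c("WT", "HT"), each = 50), levels = c("WT", "HT")),
    y = rep(c(TRUE, FALSE, TRUE, FALSE), each = 25))
  s <- univariate_screen(bal, "y", "genotype")
  expect_equal(s$statistic, 0); expect_equal(s$p_value, 1)

  # association table [[30,10],[10,30]]: direct sum((O-E)^2/E) = 20
  assoc <- tibble::tibble(
    g = factor(rep(c("a", "b"), each = 40)),
    y = c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 30)))
  s2 <- univariate_screen(assoc, "y", "g")
  expect_equal(s2$statistic, oracle_chisq(table(assoc$g, assoc$y)))
  expect_equal(s2$statistic, 20)
  expect_equal(s2$p_value, 7.744216e-06, tolerance = 1e-4)

  # identical age distributions: t = 0, p = 1
  ages <- tibble::tibble(age = rep(c(30, 40, 50), 2),
                         y = rep(c(TRUE, FALSE), each = 3))
  s3 <- univariate_screen(ages, "y", "age")
  expect_equal(s3$statistic, 0); expect_equal(s3$p_value, 1)
})

test_that("degenerate screens are flagged NA with a warning", {
  one_level <- tibble::tibble(g = factor(rep("a", 10), levels = c("a", "b")),
                              y = rep(c(TRUE, FALSE), 5))
  expect_warning(s <- univariate_screen(one_level, "y", "g"), "zero margin")
  expect_true(is.na(s$p_value))
})

test_that("the covariate gate is strict and order-preserving", {
  screen <- tibble::tibble(covariate = c("genotype", "gender", "age"),
                           p_value = c(0.05, 0.2, 0.09))
  expect_equal(select_covariates(screen), c("genotype", "age"))
  expect_equal(select_covariates(tibble::tibble(covariate = "x", p_value = 0.1)),
               character(0))
  expect_equal(select_covariates(screen[0, ]), character(0))
})

test_that("logistic odds ratios agree with a brute-force likelihood oracle", {
  set.seed(31)
  n <- 180
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  y <- runif(n) < plogis(-0.3 + 0.8 * x1 - 0.5 * x2)
  d <- tibble::tibble(y = y, x1 = x1, x2 = as.numeric(x2))
  fit <- fit_multivariate_logistic(d, "y", c("x1", "x2"))
  beta_hat <- log(fit$table$odds_ratio)
  beta_ora <- oracle_logistic_fit(cbind(x1, x2), y)[-1]
  expect_equal(unname(beta_hat), unname(beta_ora), tolerance = 5e-4)
})

test_that("reference levels carry OR 1 and Wald intervals bracket the estimate", {
  co <- binarize_outcomes(sim_cohort(4000, smoker_p = 0, seed = 17))
  fit <- fit_multivariate_logistic(co, "inflammation_high",
                                   c("genotype", "age", "gender", "allergy_asthma"))
  tab <- tidy(fit)
  refs <- tab[grepl("reference", tab$term), ]
  expect_true(all(refs$odds_ratio == 1))
  est <- tab[!grepl("reference", tab$term), ]
  expect_true(all(est$ci95_low <= est$odds_ratio & est$odds_ratio <= est$ci95_high))
})

test_that("null cohorts recover odds ratios near 1", {
  co <- sim_cohort(20000,
                   outcome_models = list(flat = outcome_model(c(HT = 1, HO = 1),
                                                              intercept = 0)),
                   smoker_p = 0, seed = 23)
  expect_lt(abs(mean(co$flat_high) - 0.5), 3 * sqrt(0.25 / 20000))
  fit <- fit_multivariate_logistic(co, "flat_high",
                                   c("genotype", "age", "gender", "allergy_asthma"))
  tab <- tidy(fit)
  est <- tab[!grepl("reference", tab$term), ]
  expect_true(all(est$odds_ratio > 0.9 & est$odds_ratio < 1.1))
})

test_that("separation and constant outcomes are flagged, never silent", {
  d <- tibble::tibble(y = rep(TRUE, 20), x = rnorm(20))
  expect_error(fit_multivariate_logistic(d, "y", "x"), "separated")
  sep <- tibble::tibble(y = rep(c(FALSE, TRUE), each = 10),
                        x = c(rnorm(10, -5), rnorm(10, 5)))
  fit <- fit_multivariate_logistic(sep, "y", "x")
  expect_true(fit$separation)
})

test_that("unknown covariates in a generator outcome model error", {
  expect_error(outcome_model(c(smoking = 2)), "unknown covariate")
  raw <- list(x = list(or = c(bad = 2), intercept = 0))
  expect_error(sim_cohort(10, outcome_models = raw), "unknown covariate")
})

test_that("the full pipeline reports the tabular odds-ratio result", {
  co <- make_exclusion_fixture(seed = 29)
  rep <- run_cohort_pipeline(co)
  expect_equal(rep$n_retained, 123)
  expect_s3_class(tidy(rep), "tbl_df")
  gl <- glance(rep)
  expect_setequal(gl$outcome, c("inflammation", "secretory"))
})

test_that("an outcome where nothing passes the gate yields no fit", {
  co <- sim_cohort(300,
                   outcome_models = list(flat = outcome_model(c(HT = 1),
                                                              intercept = 0)),
                   smoker_p = 0, seed = 41)
  rep <- run_cohort_pipeline(co, outcomes = "flat", alpha = 1e-6)
  expect_null(rep$outcomes$flat$fit)
  expect_equal(nrow(tidy(rep)), 0)
})
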