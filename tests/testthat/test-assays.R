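test_that("TaqI digestion cuts between T and C at every site", {
  expect_equal(taq1_digest("AATCGATT"), c("AAT", "CGATT"))
  expect_equal(taq1_digest("TCGAAATCGA"), c("T", "CGAAAT", "CGA"))
  expect_equal(taq1_digest("AAACCCGGG"), "AAACCCGGG")   # no site: one fragment
  expect_error(taq1_digest(""), "non-empty")
  expect_error(taq1_digest("ACGN"), "ambiguity")
})

test_that("digestion round-trips: fragments concatenate to the input", {
  set.seed(7)
  for (k in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(50:400, 1), replace = TRUE),
               collapse = "")
    expect_identical(paste(taq1_digest(s), collapse = ""), s)
  }
})

test_that("band patterns separate the three genotypes", {
  wt <- genotype_from_digests(sim_allele_pair("WT", seed = 5))
  ht <- genotype_from_digests(sim_allele_pair("HT", seed = 5))
  ho <- genotype_from_digests(sim_allele_pair("HO", seed = 5))
  expect_equal(wt$call, "WT"); expect_equal(wt$n_bands, 2)
  expect_equal(ht$call, "HT"); expect_equal(ht$n_bands, 3)
  expect_equal(ho$call, "HO"); expect_equal(ho$n_bands, 1)
  # an allele with two sites does not fit the assay design
  amb <- genotype_from_digests(c("AATCGAATTCGAA", "AAAAAAAAAAAAA"))
  expect_true(amb$ambiguous); expect_true(is.na(amb$call))
  expect_error(genotype_from_digests("ACGT"), "exactly two")
})

test_that("amplicon construction isolates the engineered site", {
  n_site <- function(s) lengths(regmatches(s, gregexpr("TCGA", s, fixed = TRUE)))
  for (seed in 1:10) {
    wt <- sim_amplicon("WT", seed = seed)
    snp <- sim_amplicon("SNP", seed = seed)
    expect_equal(n_site(wt), 1L)
    expect_equal(n_site(snp), 0L)
    expect_gte(nchar(wt), 100)
    diffs <- sum(strsplit(wt, "")[[1]] != strsplit(snp, "")[[1]])
    expect_gte(diffs, 1); expect_lte(diffs, 2)
  }
})

test_that("calcium normalization follows the F/Fmax definition", {
  tr <- sim_calcium_trace(baseline_f = 100, peak_delta_f = 80, ionomycin_f = 500)
  res <- normalize_calcium_response(tr)
  expect_equal(res$ratio, (180 - 100) / 500)
  expect_equal(res$f, 80); expect_equal(res$fmax, 500)
  flat <- sim_calcium_trace(peak_delta_f = 0)
  expect_equal(normalize_calcium_response(flat)$ratio, 0)
  # 1 min baseline + 5 min agonist + 10 s ionomycin at 200 ms steps
  expect_equal(nrow(tr), 370 / 0.2 + 1)
  expect_error(normalize_calcium_response(tr[tr$epoch != "ionomycin", ]),
               "ionomycin")
  expect_error(sim_calcium_trace(ionomycin_f = 0), "ionomycin_f")
})

test_that("a constant offset moves Fmax but not F", {
  tr <- sim_calcium_trace(baseline_f = 100, peak_delta_f = 80, ionomycin_f = 500)
  shifted <- tr; shifted$fluorescence <- shifted$fluorescence + 50
  a <- normalize_calcium_response(tr); b <- normalize_calcium_response(shifted)
  expect_equal(b$f, a$f)                 # background-subtracted numerator
  expect_equal(b$fmax, a$fmax + 50)      # Fmax is not background-subtracted
  expect_false(isTRUE(all.equal(a$ratio, b$ratio)))
})

test_that("2^-ddCt closed forms and antisymmetry hold", {
  expect_equal(ddct(20, 20, 20, 20)$fold, 1)
  expect_equal(ddct(23, 22, 20, 20)$fold, 0.5)    # ddCt = 1
  expect_equal(ddct(20, 22, 20, 20)$fold, 4)      # ddCt = -2
  f <- ddct(24.3, 21.1, 22.8, 20.9)
  f_swapped <- ddct(22.8, 20.9, 24.3, 21.1)
  expect_equal(f_swapped$fold, 1 / f$fold)
  expect_error(ddct(Inf, 20, 20, 20), "finite")
})

test_that("proliferation index is the OLS slope of the growth curve", {
  d <- tibble::tibble(day = 1:3, od560 = c(0.1, 0.2, 0.3))
  expect_equal(proliferation_index(d)$slope_per_day, 0.1)
  flat <- tibble::tibble(day = 1:4, od560 = rep(0.2, 4))
  expect_equal(proliferation_index(flat)$slope_per_day, 0)
  expect_error(proliferation_index(d[1, ]), "2 observations")
  expect_error(proliferation_index(tibble::tibble(day = c(2, 2),
                                                  od560 = c(0.1, 0.2))),
               "distinct")
})

test_that("protein normalization is a guarded ratio", {
  expect_equal(normalize_to_protein(200, 2), 100)
  expect_equal(normalize_to_protein(0, 1.5), 0)
  expect_error(normalize_to_protein(10, 0), "> 0")
})

test_that("dose-response aggregation reports mean, SEM and the n = 1 flag", {
  d <- tibble::tibble(dose = rep(c(1, 10), c(3, 1)),
                      ratio = c(0.5, 0.7, 0.9, 0.4))
  expect_warning(out <- aggregate_dose_response(d), "single observation")
  expect_equal(out$mean[1], 0.7)
  expect_equal(out$sem[1], 0.2 / sqrt(3))
  expect_equal(out$sem[2], 0); expect_false(out$sem_defined[2])
  same <- tibble::tibble(dose = rep(1, 4), ratio = rep(0.3, 4))
  expect_equal(aggregate_dose_response(same)$sem, 0)
})
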