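#' In-silico TaqI digestion
#'
#' Cuts a nucleotide sequence at every occurrence of the TaqI recognition
#' site 5'-TCGA-3', between T and C (canonical T^CGA offset), scanning left
#' to right. Concatenating the fragments reproduces the input exactly.
#'
#' @param sequence Single non-empty uppercase string over A, C, G, T.
#' @return Character vector of fragments in 5' to 3' order.
#' @export
taq1_digest <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    abort_bad_arg("`sequence` must be a single non-empty string.")
  if (grepl("[^ACGT]", sequence))
    abort_bad_arg("`sequence` must be uppercase A/C/G/T only (no ambiguity codes).")
  starts <- gregexpr("TCGA", sequence, fixed = TRUE)[[1]]
  if (starts[1] == -1L) return(sequence)
  cut_after <- as.integer(starts)            # cut between T and C
  bounds <- c(0L, cut_after, nchar(sequence))
  bounds <- unique(bounds)
  substring(sequence, bounds[-length(bounds)] + 1L, bounds[-1])
}

#' Genotype a sample from its two allele digests
#'
#' The restriction site is carried by the G allele only, so digestion
#' separates the genotypes: both alleles cut gives WT (G/G), neither gives
#' HO (A/A), exactly one gives HT (G/A). Gel bands are the sorted unique
#' pooled fragment lengths (co-migrating equal lengths merge). An allele
#' with two or more sites does not fit the assay design and is flagged
#' ambiguous.
#'
#' @param alleles Character vector of exactly two allele sequences.
#' @return One-row tibble: `call` (`"WT"`, `"HT"`, `"HO"`, or `NA` when
#'   ambiguous), `n_bands`, `bands` (list-column of sorted unique fragment
#'   lengths), `ambiguous`.
#' @export
genotype_from_digests <- function(alleles) {
  if (!is.character(alleles) || length(alleles) != 2L)
    abort_bad_arg("`alleles` must be exactly two sequences.")
  frags <- lapply(alleles, taq1_digest)
  n_sites <- vapply(frags, length, integer(1)) - 1L
  bands <- sort(unique(nchar(unlist(frags))))
  if (any(n_sites >= 2L))
    return(tibble(call = NA_character_, n_bands = length(bands),
                  bands = list(bands), ambiguous = TRUE))
  n_cut <- sum(n_sites == 1L)
  call <- c("HO", "HT", "WT")[n_cut + 1L]
  tibble(call = call, n_bands = length(bands), bands = list(bands),
         ambiguous = FALSE)
}

#' Normalize an agonist calcium response to the ionomycin maximum
#'
#' Baseline is the mean fluorescence over the baseline epoch; the agonist
#' response F is the agonist-epoch peak minus baseline; Fmax is the
#' ionomycin-epoch peak (not background-subtracted); the reported ratio is
#' F/Fmax. Negative F is reported as-is, never clipped.
#'
#' @param trace Tibble with `time_s`, `fluorescence` and `epoch`
#'   (`"baseline"`, `"agonist"`, `"ionomycin"`).
#' @return One-row tibble: `f_baseline`, `f`, `fmax`, `ratio`.
#' @export
normalize_calcium_response <- function(trace) {
  check_columns(trace, c("time_s", "fluorescence", "epoch"), "trace")
  missing <- setdiff(c("baseline", "agonist", "ionomycin"),
                     unique(as.character(trace$epoch)))
  if (length(missing))
    abort_bad_arg("trace is missing epoch(s): %s.", paste(missing, collapse = ", "))
  if (is.unsorted(trace$time_s, strictly = TRUE))
    abort_bad_arg("`time_s` must be strictly increasing.")
  f0 <- mean(trace$fluorescence[trace$epoch == "baseline"])
  fpk <- max(trace$fluorescence[trace$epoch == "agonist"])
  fmax <- max(trace$fluorescence[trace$epoch == "ionomycin"])
  if (fmax <= 0) abort_bad_arg("ionomycin peak must be > 0 (got %g).", fmax)
  tibble(f_baseline = f0, f = fpk - f0, fmax = fmax, ratio = (fpk - f0) / fmax)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per condition `dCt = Ct_target - Ct_reference`; then
#' `ddCt = dCt_sample - dCt_control` and the fold change is `2^-ddCt`.
#' All arguments are vectorised.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample condition.
#' @param ct_target_control,ct_ref_control Same in the control condition.
#' @return Tibble: `dct_sample`, `dct_control`, `ddct`, `fold`.
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_control, ct_ref_control) {
  cts <- list(ct_target_sample, ct_ref_sample, ct_target_control, ct_ref_control)
  if (any(vapply(cts, function(x) any(!is.finite(x)) || any(x <= 0), logical(1))))
    abort_bad_arg("all Ct values must be finite and > 0.")
  dct_s <- ct_target_sample - ct_ref_sample
  dct_c <- ct_target_control - ct_ref_control
  dd <- dct_s - dct_c
  tibble(dct_sample = dct_s, dct_control = dct_c, ddct = dd, fold = 2^(-dd))
}

#' MTT proliferation index
#'
#' The ordinary least-squares slope of optical density against day, the
#' standardized growth-rate readout of the MTT time course.
#'
#' @param data Tibble with the time course.
#' @param day,od Column names (strings) for day and OD560.
#' @return One-row tibble: `slope_per_day`, `intercept`, `r_squared`, `n`.
#' @export
proliferation_index <- function(data, day = "day", od = "od560") {
  check_columns(data, c(day, od), "data")
  d <- data[[day]]; o <- data[[od]]
  if (length(d) < 2L || length(unique(d)) < 2L)
    abort_bad_arg("at least 2 observations on 2 distinct days are required.")
  fit <- lm(o ~ d)
  tss <- sum((o - mean(o))^2)
  r2 <- if (tss > 0) 1 - sum(resid(fit)^2) / tss else 1
  tibble(slope_per_day = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = r2, n = length(d))
}

#' Normalize an analyte to total protein
#'
#' @param analyte_pg_per_ml Analyte concentration(s), pg/mL.
#' @param protein_mg_per_ml Total protein concentration(s), mg/mL (> 0).
#' @return Numeric vector, pg analyte per mg protein.
#' @export
normalize_to_protein <- function(analyte_pg_per_ml, protein_mg_per_ml) {
  if (any(!is.finite(protein_mg_per_ml)) || any(protein_mg_per_ml <= 0))
    abort_bad_arg("`protein_mg_per_ml` must be finite and > 0.")
  analyte_pg_per_ml / protein_mg_per_ml
}

#' Aggregate per-cell responses into a dose-response summary
#'
#' Mean and SEM (`sd / sqrt(n)`) per dose, sorted by dose. A dose with a
#' single observation has no sample SD; its SEM is reported as 0 with
#' `sem_defined = FALSE`.
#'
#' @param data Tibble of per-cell observations.
#' @param dose,response Column names (strings).
#' @return Tibble: `dose`, `n`, `mean`, `sem`, `sem_defined`.
#' @export
aggregate_dose_response <- function(data, dose = "dose", response = "ratio") {
  check_columns(data, c(dose, response), "data")
  out <- data |>
    dplyr::group_by(dose = .data[[dose]]) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data[[response]]),
                     sem = ifelse(dplyr::n() > 1,
                                  sd(.data[[response]]) / sqrt(dplyr::n()), 0),
                     sem_defined = dplyr::n() > 1,
                     .groups = "drop") |>
    dplyr::arrange(.data$dose)
  if (any(!out$sem_defined))
    warn("some doses have a single observation; their SEM is reported as 0.")
  out
}
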