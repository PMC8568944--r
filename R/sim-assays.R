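#' Simulate a genotyping amplicon
#'
#' Builds an amplicon around the rs16969968-style restriction-site
#' polymorphism: the WT (G) allele carries exactly one TaqI site (TCGA),
#' the SNP (A) allele carries none; the two sequences are otherwise
#' identical (single-nucleotide difference within the site, TCGA vs TCAA).
#' The random backbone is scrubbed of accidental TCGA occurrences so the
#' digestion pattern is fully determined by the engineered site.
#'
#' @param genotype `"WT"` or `"SNP"` (allele-level).
#' @param length_nt Amplicon length (>= 100).
#' @param site_pos 1-based start of the engineered site; default mid-way.
#' @param seed Optional integer seed (same seed gives the same backbone for
#'   both alleles).
#' @return Single uppercase sequence string.
#' @export
sim_amplicon <- function(genotype = c("WT", "SNP"), length_nt = 250,
                         site_pos = NULL, seed = NULL) {
  genotype <- match.arg(genotype)
  check_number(length_nt, "length_nt", min = 100)
  # asymmetric default so the two WT fragments differ in length and the
  # heterozygote shows three distinct gel bands
  site_pos <- site_pos %||% floor(length_nt * 0.4)
  if (site_pos < 1 || site_pos + 3 > length_nt)
    abort_bad_arg("`site_pos` must leave room for the 4-nt site.")
  backbone <- with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length_nt, replace = TRUE), collapse = ""))
  # scrub accidental sites (G -> C inside any TCGA) until none remain
  while (grepl("TCGA", backbone, fixed = TRUE))
    backbone <- sub("TCGA", "TCCA", backbone, fixed = TRUE)
  site <- if (genotype == "WT") "TCGA" else "TCAA"
  seqn <- paste0(substring(backbone, 1, site_pos - 1), site,
                 substring(backbone, site_pos + 4, length_nt))
  # inserting the site can only create a new TCGA across a junction for the
  # WT allele; scrub outside the engineered window if it happens
  if (genotype == "WT") {
    starts <- gregexpr("TCGA", seqn, fixed = TRUE)[[1]]
    for (s in starts[starts != site_pos]) {
      substr(seqn, s + 2, s + 2) <- "C"
    }
  } else {
    while (grepl("TCGA", seqn, fixed = TRUE)) seqn <- sub("TCGA", "TCCA", seqn, fixed = TRUE)
  }
  seqn
}

#' Simulate the two amplicon alleles of a patient
#'
#' @param genotype `"WT"` (G/G), `"HT"` (G/A) or `"HO"` (A/A).
#' @inheritParams sim_amplicon
#' @return Character vector of two allele sequences sharing one backbone.
#' @export
sim_allele_pair <- function(genotype = c("WT", "HT", "HO"), length_nt = 250,
                            site_pos = NULL, seed = NULL) {
  genotype <- match.arg(genotype)
  alleles <- switch(genotype,
                    WT = c("WT", "WT"), HT = c("WT", "SNP"), HO = c("SNP", "SNP"))
  vapply(alleles, function(a)
    sim_amplicon(a, length_nt = length_nt, site_pos = site_pos, seed = seed),
    character(1), USE.NAMES = FALSE)
}

#' Write amplicons to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplicon_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    abort_bad_arg("Biostrings is required for FASTA output.")
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read amplicons from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_amplicon_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    abort_bad_arg("Biostrings is required for FASTA input.")
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Simulate a calcium-imaging fluorescence trace
#'
#' Emulates the standard recording protocol: a baseline epoch, agonist
#' addition with fluorescence recorded at 200 ms intervals, then ionomycin
#' to trigger the maximal calcium flux. The agonist and ionomycin responses
#' are smooth rise-and-decay transients whose peaks fall exactly on sample
#' points, so with zero noise the downstream F/Fmax equals
#' `peak_delta_f / ionomycin_f` exactly.
#'
#' @param baseline_f Baseline fluorescence, a.u.
#' @param peak_delta_f Agonist peak height above baseline, a.u. (>= 0).
#' @param ionomycin_f Ionomycin peak fluorescence, a.u. (> 0).
#' @param baseline_s,agonist_s,ionomycin_s Epoch durations, seconds
#'   (defaults: 1 min baseline, 5 min agonist, 10 s ionomycin).
#' @param interval_s Sampling interval (default 0.2 s).
#' @param noise_sd Additive Gaussian noise, a.u.
#' @param seed Optional integer seed.
#' @return Tibble `time_s`, `fluorescence`, `epoch`.
#' @export
sim_calcium_trace <- function(baseline_f = 100, peak_delta_f = 80,
                              ionomycin_f = 500, baseline_s = 60,
                              agonist_s = 300, ionomycin_s = 10,
                              interval_s = 0.2, noise_sd = 0, seed = NULL) {
  check_number(baseline_f, "baseline_f", min = 0)
  check_number(peak_delta_f, "peak_delta_f", min = 0)
  check_number(ionomycin_f, "ionomycin_f", min = 0, strict_min = TRUE)
  if (baseline_s <= 0 || agonist_s <= 0 || ionomycin_s <= 0)
    abort_bad_arg("epoch durations must be positive and ordered baseline, agonist, ionomycin.")
  total <- baseline_s + agonist_s + ionomycin_s
  t <- seq(0, total, by = interval_s)
  epoch <- ifelse(t < baseline_s, "baseline",
                  ifelse(t < baseline_s + agonist_s, "agonist", "ionomycin"))

  snap <- function(x) round(x / interval_s) * interval_s
  bump <- function(t, t_pk, height, rise, decay) {
    h <- numeric(length(t))
    up <- t <= t_pk
    h[up] <- height * exp(-((t[up] - t_pk) / rise)^2)
    h[!up] <- height * exp(-(t[!up] - t_pk) / decay)
    h
  }
  # each transient is confined to its epoch so the epoch maxima (and hence
  # F and Fmax downstream) are exact with zero noise
  t_ag <- snap(baseline_s + agonist_s * 0.1)
  t_io <- snap(baseline_s + agonist_s + ionomycin_s * 0.4)
  f <- rep(baseline_f, length(t))
  ag <- epoch == "agonist"
  f[ag] <- baseline_f + bump(t[ag], t_ag, peak_delta_f,
                             rise = 2, decay = agonist_s / 4)
  io <- epoch == "ionomycin"
  f[io] <- baseline_f + bump(t[io], t_io, ionomycin_f - baseline_f,
                             rise = 1, decay = ionomycin_s)
  if (noise_sd > 0) f <- with_seed(seed, f + rnorm(length(f), 0, noise_sd))
  tibble(time_s = t, fluorescence = f,
         epoch = factor(epoch, levels = c("baseline", "agonist", "ionomycin")))
}
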