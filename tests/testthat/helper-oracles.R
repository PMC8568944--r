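# Independent oracles used by the suite. These deliberately avoid the code
# paths they check: chords by an explicit per-pixel scan (no rle), the
# logistic likelihood maximized by optim (no glm), chi-squared from margins.

oracle_chords <- function(mask) {
  scan_line <- function(v) {
    out <- integer(0); run <- 0L
    for (x in v) {
      if (x) run <- run + 1L
      else { if (run > 0L) out <- c(out, run); run <- 0L }
    }
    if (run > 0L) out <- c(out, run)
    out
  }
  h <- unlist(lapply(seq_len(nrow(mask)), function(i) scan_line(mask[i, ])))
  v <- unlist(lapply(seq_len(ncol(mask)), function(j) scan_line(mask[, j])))
  list(horizontal = as.integer(h %||% integer(0)),
       vertical = as.integer(v %||% integer(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_logistic_fit <- function(X, y) {
  # maximum likelihood by direct optimization of the hand-written
  # log-likelihood; X includes no intercept column (added here)
  Xi <- cbind(1, X)
  nll <- function(beta) {
    eta <- drop(Xi %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, ncol(Xi)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  opt$par
}

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# deterministic random 0/1 mask
random_mask <- function(nr, nc, p) matrix(runif(nr * nc) < p, nr, nc)

# 213-record fixture with the study's exclusion arithmetic: 64 records over
# the abrasion cutoff, 26 smokers among the remainder
make_exclusion_fixture <- function(seed = 11) {
  co <- sim_cohort(213, smoker_p = 0, seed = seed)
  set.seed(seed + 1)
  co$abrasion_pct <- runif(213, 0, 60)
  co$smoker <- FALSE
  co$abrasion_pct[1:64] <- runif(64, 70.0001, 100)
  co$smoker[65:90] <- TRUE
  co
}
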