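# Shared fixtures and independent oracles used across the suite.

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 400, baseline_log_mean = log(200), seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

counts_from_matrix <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("T%05d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  twostepseq:::matrix_to_counts(m)
}

# Brute-force NB profile-likelihood grid for the log2 fold change of a single
# transcript: coarse grid over the slope, then a fine grid at 0.001 spacing,
# with the intercept profiled out by 1-D optimization at every grid point.
# Entirely independent of the package's Fisher-scoring fitter.
grid_lfc <- function(y, group, sf, alpha, span = 6, fine_step = 0.001) {
  ll_at <- function(c1) {
    f <- function(c0) {
      mu <- pmax(sf * 2^(c0 + c1 * group), 1e-12)
      -sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
    }
    opt <- stats::optimize(f, interval = c(-30, 30), tol = 1e-7)
    -opt$objective
  }
  coarse <- seq(-span, span, by = 0.05)
  lc <- vapply(coarse, ll_at, numeric(1))
  c1c <- coarse[which.max(lc)]
  fine <- seq(c1c - 0.06, c1c + 0.06, by = fine_step)
  lf <- vapply(fine, ll_at, numeric(1))
  fine[which.max(lf)]
}

# Step-up BH by direct transcription of the definition:
# q_(i) = min_{j >= i} (m / j) * p_(j), capped at 1.
bh_brute <- function(p) {
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  ord <- order(pv)
  qs <- numeric(m)
  for (i in seq_len(m)) {
    qs[i] <- min(1, min((m / seq(i, m)) * pv[ord][seq(i, m)]))
  }
  q[ok][ord] <- qs
  q
}
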