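# Negative-binomial Wald differential-expression engine: median-of-ratios
# size factors, method-of-moments dispersions shrunk toward an a0 + a1/mu
# trend, per-contrast NB GLM Wald tests, BH-FDR, and QQ calibration.
#
# This is a deliberately transparent NB engine, not a DESeq2 clone: no
# Cox-Reid adjustment, no outlier replacement, no independent filtering, no
# LFC shrinkage. It implements the model class (NB mean-variance with Wald
# tests at a BH-FDR threshold) needed to study two-step screening designs.

#' Median-of-ratios size factors
#'
#' For each sample, the median over transcripts of the ratio between its
#' count and the transcript's geometric mean across samples; transcripts
#' with a zero anywhere are excluded from the reference. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Counts tibble (`transcript_id` + sample columns).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- count_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    warn("no transcript is positive in every sample; using per-sample medians over each sample's positive transcripts.")
    log_ref <- rowMeans(ifelse(m > 0, log(m), NA), na.rm = TRUE)
    sf <- apply(m, 2, function(col) {
      ok <- col > 0 & is.finite(log_ref)
      if (!any(ok)) return(NA_real_)
      exp(median(log(col[ok]) - log_ref[ok]))
    })
  } else {
    log_ref <- rowMeans(log(m[pos, , drop = FALSE]))
    sf <- apply(m[pos, , drop = FALSE], 2, function(col) {
      exp(median(log(col) - log_ref))
    })
  }
  if (anyNA(sf) || any(sf <= 0)) abort("could not estimate a positive size factor for every sample.")
  sf <- sf / geometric_mean(sf)
  setNames(sf, colnames(m))
}

#' Drop weakly covered transcripts
#'
#' Keeps transcripts whose total raw count across all samples is strictly
#' greater than `threshold` (default 20 reads, the conventional screening
#' filter before model fitting).
#'
#' @param counts Counts tibble.
#' @param threshold Minimum total raw reads (exclusive).
#' @return Filtered counts tibble.
#' @export
filter_low <- function(counts, threshold = 20) {
  if (threshold < 0) abort("`threshold` must be >= 0.")
  m <- count_matrix(counts)
  keep <- rowSums(m) > threshold
  counts[keep, , drop = FALSE]
}

#' Estimate per-transcript NB dispersions with a mean trend
#'
#' Raw dispersions come from pooled within-condition moments: with
#' variance = mu + alpha * mu^2, each condition with >= 2 replicates
#' contributes its sample mean and variance of size-factor-normalized
#' counts, and alpha-hat is the (df-weighted) ratio
#' `sum((n_c-1) * (s2_c - m_c)) / sum((n_c-1) * (m_c^2 - s2_c/n_c))`; the
#' `- s2_c/n_c` term makes the denominator an unbiased estimate of mu^2, so
#' the ratio is not pulled down at low counts. Reported raw values are
#' floored at 1e-8. A trend `alpha(mu) = a0 + a1/mu` is then fitted in two
#' stages: least squares on binned means of the (unfloored) raw estimates
#' for a stable start - binning tames the heavy right skew of
#' few-replicate moment estimates without the downward bias that trimming
#' or M-estimation would introduce - then two rounds of gene-level weighted
#' least squares with weights `1/trend(mu)^2`, matching the
#' `Var(alpha-hat) ~ alpha^2` sampling variance so precisely measured
#' high-expression transcripts anchor `a0`. Coefficients are clipped at 0.
#' The final dispersion is a log-scale weighted
#' combination of raw and trend. The default weight 1 uses the trend alone:
#' with a handful of replicates the per-transcript estimate has so few
#' degrees of freedom that any weight on it destroys type-I control, and
#' the raw column remains available for diagnostics or for designs with
#' many replicates.
#'
#' @param counts Counts tibble.
#' @param design Design tibble (`sample_id`, `condition`, ...); dispersion is
#'   fitted jointly on all conditions at once.
#' @param sf Size factors from [size_factors()] (computed if missing).
#' @param shrink_weight Weight of the trend in the log-scale combination
#'   (0 = raw only, 1 = trend only; default 1).
#' @param n_bins Number of expression bins for the trend fit.
#' @param trend_min_mean Minimum base mean for a transcript to enter the
#'   trend fit (default 5): below a handful of normalized counts the moment
#'   ratio is numerically unstable and would dominate the 1/mu leverage;
#'   the fitted trend still extrapolates to those transcripts.
#' @return A `dispersion_model` tibble: transcript_id, base_mean, raw, trend,
#'   final; attributes `a0`, `a1`, `shrink_weight`.
#' @export
estimate_dispersions <- function(counts, design, sf = size_factors(counts),
                                 shrink_weight = 1, n_bins = 20,
                                 trend_min_mean = 5) {
  m <- count_matrix(counts)
  design <- as_tibble(design)
  stopifnot(all(colnames(m) %in% design$sample_id))
  sf <- sf[colnames(m)]
  k <- sweep(m, 2, sf, "/")
  cond <- design$condition[match(colnames(m), design$sample_id)]
  tab <- table(cond)
  usable <- names(tab)[tab >= 2]
  if (!length(usable)) abort("need at least one condition with >= 2 replicates to estimate dispersion.")
  if (length(usable) < length(tab)) {
    warn(sprintf("condition(s) with a single replicate contribute no within-condition variance: %s",
                 paste(setdiff(names(tab), usable), collapse = ", ")))
  }
  num <- den <- numeric(nrow(m))
  for (cc in usable) {
    cols <- which(cond == cc)
    n_c <- length(cols)
    mu_c <- rowMeans(k[, cols, drop = FALSE])
    v_c <- row_vars(k[, cols, drop = FALSE])
    num <- num + (n_c - 1) * (v_c - mu_c)
    den <- den + (n_c - 1) * pmax(mu_c^2 - v_c / n_c, 0)
  }
  raw_unclipped <- ifelse(den > 0, num / den, NA_real_)
  raw <- pmax(raw_unclipped, 1e-8)
  base_mean <- rowMeans(k)

  fit_ok <- is.finite(raw_unclipped) & base_mean >= trend_min_mean
  a0 <- a1 <- NA_real_
  if (sum(fit_ok) >= max(20, 2 * n_bins)) {
    x <- 1 / base_mean[fit_ok]
    y <- raw_unclipped[fit_ok]
    bins <- cut(log(base_mean[fit_ok]), breaks = n_bins)
    ybin <- tapply(y, bins, mean)
    xbin <- tapply(x, bins, mean)
    wbin <- tapply(y, bins, length)
    okb <- is.finite(ybin) & is.finite(xbin)
    if (sum(okb) >= 3) {
      fit <- lm(ybin[okb] ~ xbin[okb], weights = wbin[okb])
      a0 <- max(unname(coef(fit)[1]), 1e-4)
      a1 <- max(unname(coef(fit)[2]), 0)
      for (pass in 1:2) {
        tr <- pmax(a0 + a1 * x, 1e-4)
        fit <- lm(y ~ x, weights = 1 / tr^2)
        a0 <- max(unname(coef(fit)[1]), 1e-4)
        a1 <- max(unname(coef(fit)[2]), 0)
      }
      a0 <- max(0, a0)
    }
  }
  if (!is.finite(a0) || (a0 == 0 && (!is.finite(a1) || a1 == 0))) {
    a0 <- max(median(raw, na.rm = TRUE), 1e-8)
    a1 <- 0
  }
  trend <- pmax(a0 + a1 / pmax(base_mean, 1e-8), 1e-8)
  raw_f <- pmax(ifelse(is.na(raw), trend, raw), trend / 100)
  final <- exp((1 - shrink_weight) * log(raw_f) + shrink_weight * log(trend))
  out <- tibble(transcript_id = rownames(m), base_mean = unname(base_mean),
                raw = unname(raw), trend = unname(trend),
                final = unname(pmax(final, 1e-8)))
  structure(out, class = c("dispersion_model", class(out)),
            a0 = a0, a1 = a1, shrink_weight = shrink_weight)
}

# Vectorized Fisher-scoring fit of per-transcript NB GLMs with log link,
# design = intercept + group indicator, log size factors as offsets, fixed
# dispersion. Returns coefficients on the natural-log scale.
nb_two_group_fit <- function(y, group, offset, alpha,
                             max_iter = 100, tol = 1e-8) {
  G <- nrow(y); n <- ncol(y)
  x <- as.numeric(group)           # 0/1 indicator
  off <- matrix(offset, G, n, byrow = TRUE)
  sf <- exp(offset)
  mu_all <- pmax(rowMeans(sweep(y, 2, sf, "/")), 1e-8)
  b0 <- log(mu_all)
  b1 <- numeric(G)
  xm <- matrix(x, G, n, byrow = TRUE)
  converged <- rep(FALSE, G)
  estimable <- rep(TRUE, G)
  for (it in seq_len(max_iter)) {
    active <- which(!converged & estimable)
    if (!length(active)) break
    eta <- b0[active] + tcrossprod(b1[active], x) + off[active, , drop = FALSE]
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha[active] * mu)
    z <- (eta - off[active, , drop = FALSE]) +
      (y[active, , drop = FALSE] - mu) / mu
    A <- rowSums(w)
    B <- rowSums(w * xm[active, , drop = FALSE])
    U <- rowSums(w * z)
    V <- rowSums(w * z * xm[active, , drop = FALSE])
    det <- B * (A - B)
    ok <- is.finite(det) & det > 1e-12
    new_b1 <- ifelse(ok, (A * V - B * U) / det, NA_real_)
    new_b0 <- ifelse(ok, (U - B * new_b1) / A, NA_real_)
    new_b1 <- pmin(pmax(new_b1, -50), 50)
    new_b0 <- pmin(pmax(new_b0, -50), 50)
    delta <- pmax(abs(new_b0 - b0[active]), abs(new_b1 - b1[active]))
    estimable[active][!ok] <- FALSE
    conv_now <- ok & delta < tol
    b0[active] <- ifelse(ok, new_b0, b0[active])
    b1[active] <- ifelse(ok, new_b1, b1[active])
    converged[active][conv_now] <- TRUE
  }
  # observed/expected Fisher information at the final fit
  eta <- b0 + tcrossprod(b1, x) + off
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  A <- rowSums(w)
  B <- rowSums(w * xm)
  det <- B * (A - B)
  se1 <- ifelse(is.finite(det) & det > 1e-12, sqrt(A / det), NA_real_)
  list(b0 = b0, b1 = b1, se1 = se1,
       converged = converged, estimable = estimable)
}

#' NB Wald test for one treatment-vs-control contrast
#'
#' Fits, per transcript, an NB GLM with log link on the contrast's samples
#' (intercept + condition indicator, log size factors as offsets, fixed
#' final dispersion from the jointly fitted [estimate_dispersions()] model),
#' and reports the maximum-likelihood log2 fold change, its asymptotic
#' standard error from the Fisher information, the Wald statistic and the
#' two-sided normal p-value. Transcripts failing the coverage filter are
#' marked untested and carry missing p-values; non-converged fits are
#' flagged, never silently dropped.
#'
#' @param counts Counts tibble (all transcripts; filtering is flagged, not
#'   dropped, so results align with the input).
#' @param design Design tibble (`sample_id`, `condition`).
#' @param sf Size factors named by sample.
#' @param dispersion A `dispersion_model` or a numeric vector of final
#'   dispersions named by transcript.
#' @param contrast Character vector `c(treatment, control)` naming
#'   conditions in `design`.
#' @param tested Optional logical vector (named by transcript) marking
#'   transcripts that passed [filter_low()]; default: all tested.
#' @param max_iter,tol Fisher-scoring iteration cap and coefficient-change
#'   convergence tolerance.
#' @return Tibble: transcript_id, contrast, base_mean, log2fc, se, wald, p,
#'   tested, converged.
#' @export
wald_test <- function(counts, design, sf, dispersion, contrast,
                      tested = NULL, max_iter = 100, tol = 1e-8) {
  m <- count_matrix(counts)
  design <- as_tibble(design)
  stopifnot(length(contrast) == 2)
  treatment <- contrast[[1]]; control <- contrast[[2]]
  if (!all(c(treatment, control) %in% design$condition)) {
    abort(sprintf("contrast conditions not found in design: %s vs %s", treatment, control))
  }
  samples <- design$sample_id[design$condition %in% c(treatment, control)]
  samples <- intersect(colnames(m), samples)
  if (length(samples) < 2) abort("contrast selects fewer than 2 samples.")
  cond <- design$condition[match(samples, design$sample_id)]
  group <- as.numeric(cond == treatment)
  if (inherits(dispersion, "dispersion_model")) {
    disp <- setNames(dispersion$final, dispersion$transcript_id)
  } else {
    disp <- dispersion
  }
  if (!all(rownames(m) %in% names(disp))) abort("dispersion missing for some transcripts.")
  alpha <- pmax(disp[rownames(m)], 1e-8)
  sf_c <- sf[samples]
  y <- m[, samples, drop = FALSE]
  fit <- nb_two_group_fit(y, group, log(sf_c), alpha,
                          max_iter = max_iter, tol = tol)
  if (is.null(tested)) tested <- setNames(rep(TRUE, nrow(m)), rownames(m))
  tested <- as.logical(tested[rownames(m)])
  log2fc <- fit$b1 / log(2)
  se <- fit$se1 / log(2)
  ok <- fit$estimable & fit$converged & tested
  wald <- ifelse(ok, log2fc / se, NA_real_)
  tibble(
    transcript_id = rownames(m),
    contrast = paste(treatment, "vs", control),
    base_mean = rowMeans(sweep(y, 2, sf_c, "/")),
    log2fc = ifelse(fit$estimable, log2fc, NA_real_),
    se = ifelse(fit$estimable, se, NA_real_),
    wald = wald,
    p = ifelse(is.na(wald), NA_real_, 2 * pnorm(-abs(wald))),
    tested = tested,
    converged = fit$converged & fit$estimable
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values; missing p-values are excluded from the number of
#' tests m and returned as missing.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Run the full DE engine over all matched contrasts
#'
#' Size factors, the >`min_total_reads` coverage filter, joint dispersion
#' estimation across all conditions, one NB Wald test per
#' treatment-vs-matched-control contrast, and BH adjustment within each
#' contrast (m = transcripts tested in that contrast).
#'
#' @param counts Counts tibble.
#' @param design Design tibble (`sample_id`, `condition`,
#'   `control_for_condition`).
#' @param annotation Optional annotation tibble supplying `gene_id`; when
#'   absent each transcript is its own gene.
#' @param contrasts Optional list of `c(treatment, control)` pairs; default:
#'   every condition with a matched control in `design`.
#' @param fdr FDR level recorded on the fit (used by [de_genes()]).
#' @param min_total_reads Coverage filter threshold (strict >).
#' @param shrink_weight Dispersion shrink weight, see
#'   [estimate_dispersions()].
#' @return An `nb_de_fit` object; see [tidy.nb_de_fit()] /
#'   [glance.nb_de_fit()].
#' @export
de_test <- function(counts, design, annotation = NULL, contrasts = NULL,
                    fdr = 0.1, min_total_reads = 20, shrink_weight = 1) {
  design <- as_tibble(design)
  m <- count_matrix(counts)
  if (is.null(contrasts)) {
    tr <- design[!is.na(design$control_for_condition),
                 c("condition", "control_for_condition")]
    tr <- dplyr::distinct(tr)
    if (!nrow(tr)) abort("no matched treatment/control contrasts in `design`.")
    contrasts <- purrr::map2(tr$condition, tr$control_for_condition, c)
  }
  sf <- size_factors(counts)
  tested <- setNames(rowSums(m) > min_total_reads, rownames(m))
  disp <- estimate_dispersions(counts, design, sf, shrink_weight = shrink_weight)
  results <- purrr::map_dfr(contrasts, function(ct) {
    res <- wald_test(counts, design, sf, disp, ct, tested = tested)
    res$q <- bh_adjust(res$p)
    res
  })
  if (!is.null(annotation)) {
    ann <- as_tibble(annotation)[, c("transcript_id", "gene_id")]
    results <- dplyr::left_join(results, ann, by = "transcript_id")
  } else {
    results$gene_id <- results$transcript_id
  }
  structure(
    list(results = results, dispersion = disp, size_factors = sf,
         design = design, fdr = fdr, min_total_reads = min_total_reads,
         contrasts = contrasts),
    class = "nb_de_fit"
  )
}

#' @export
print.nb_de_fit <- function(x, ...) {
  n_ct <- length(x$contrasts)
  n_sig <- sum(x$results$q <= x$fdr, na.rm = TRUE)
  cat(sprintf("<nb_de_fit> %d transcripts, %d contrast(s); %d transcript hits at %.0f%% BH-FDR\n",
              length(unique(x$results$transcript_id)), n_ct, n_sig, 100 * x$fdr))
  invisible(x)
}

#' Differentially expressed genes at an FDR level
#'
#' A gene is DE in a contrast when at least one of its transcripts reaches
#' `q <= fdr`. Direction is reported two ways: `direction` from the sign of
#' each significant transcript (a gene whose significant transcripts
#' disagree appears once per direction and is flagged `conflicting`), and
#' `direction_top` from the most significant transcript.
#'
#' @param fit An `nb_de_fit`, or a results tibble with columns gene_id,
#'   contrast, q, log2fc.
#' @param fdr FDR threshold (default: the fit's, else 0.1).
#' @return Tibble: contrast, gene_id, direction, direction_top, min_q,
#'   n_transcripts_sig, conflicting.
#' @export
de_genes <- function(fit, fdr = NULL) {
  res <- if (inherits(fit, "nb_de_fit")) fit$results else as_tibble(fit)
  if (is.null(fdr)) fdr <- if (inherits(fit, "nb_de_fit")) fit$fdr else 0.1
  sig <- res[!is.na(res$q) & res$q <= fdr, , drop = FALSE]
  if (!nrow(sig)) {
    return(tibble(contrast = character(), gene_id = character(),
                  direction = character(), direction_top = character(),
                  min_q = numeric(), n_transcripts_sig = integer(),
                  conflicting = logical()))
  }
  sig |>
    dplyr::mutate(dir = ifelse(.data$log2fc >= 0, "up", "down")) |>
    dplyr::group_by(.data$contrast, .data$gene_id) |>
    dplyr::reframe(
      direction = unique(.data$dir),
      direction_top = .data$dir[which.min(.data$q)],
      min_q = min(.data$q),
      n_transcripts_sig = dplyr::n(),
      conflicting = length(unique(.data$dir)) > 1
    )
}

#' QQ calibration of a p-value set against uniformity
#'
#' Sorted observed p-values against expected quantiles (i - 0.5)/m, on the
#' -log10 scale, plus the Kolmogorov-Smirnov distance (and p-value) to the
#' uniform distribution. Well-calibrated null tests sit on the diagonal.
#'
#' @param p P-values (>= 10 non-missing values required).
#' @return A `qq_calibration` tibble (expected, observed; -log10 scale) with
#'   attributes `ks_stat` and `ks_p`.
#' @export
qq_calibration <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 10) abort("need at least 10 p-values.")
  m <- length(p)
  obs <- sort(p)
  expd <- (seq_len(m) - 0.5) / m
  ks <- suppressWarnings(ks.test(p, "punif"))
  out <- tibble(expected = -log10(expd), observed = -log10(pmax(obs, 1e-300)))
  structure(out, class = c("qq_calibration", class(out)),
            ks_stat = unname(ks$statistic), ks_p = unname(ks$p.value))
}
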