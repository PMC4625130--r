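# Shallow-versus-deep concordance evaluation: binomial thinning of count
# matrices, fold-change rank correlation, DE-gene recovery, and the DE-count
# versus depth response curve.

#' Binomially thin a count matrix
#'
#' Each count c is replaced by a Binomial(c, ratio) draw - the count-level
#' equivalent of retaining each read independently with probability `ratio`,
#' i.e. of sequencing the same libraries at `ratio` times the depth (or
#' multiplexing `1/ratio` times more samples on the same run). `ratio = 1`
#' returns the input untouched and consumes no random numbers.
#'
#' @param counts Counts tibble.
#' @param ratio Retention fraction in (0, 1].
#' @param seed Optional seed for a reproducible draw.
#' @return Thinned counts tibble.
#' @export
thin_counts <- function(counts, ratio, seed = NULL) {
  if (ratio <= 0 || ratio > 1) abort("`ratio` must lie in (0, 1].")
  if (ratio == 1) return(counts)
  m <- count_matrix(counts)
  draw <- function() matrix(rbinom(length(m), size = as.vector(m), prob = ratio),
                            nrow = nrow(m), dimnames = dimnames(m))
  thinned <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  matrix_to_counts(thinned)
}

#' Spearman correlation of log2 fold changes between two DE runs
#'
#' Rank correlation over all genes tested (and estimable) in both result
#' sets of the same contrast - all genes, not only the significant ones.
#'
#' @param results_a,results_b DE result tibbles (from [wald_test()] or
#'   `fit$results`) sharing a contrast; intersected on `transcript_id`.
#' @return Spearman rho (single numeric).
#' @export
fc_correlation <- function(results_a, results_b) {
  a <- as_tibble(results_a); b <- as_tibble(results_b)
  keep <- function(r) r[r$tested & !is.na(r$log2fc),
                        c("transcript_id", "log2fc")]
  merged <- dplyr::inner_join(keep(a), keep(b), by = "transcript_id",
                              suffix = c("_a", "_b"))
  if (nrow(merged) < 10) abort("fewer than 10 genes tested in both result sets.")
  cor(merged$log2fc_a, merged$log2fc_b, method = "spearman")
}

#' Fraction of a reference DE gene set recovered by another run
#'
#' @param reference Character vector of reference DE gene ids (nonempty).
#' @param test Character vector of DE gene ids from the run under test.
#' @return `|reference intersect test| / |reference|`; `NA` when the
#'   reference is empty.
#' @export
recovery_fraction <- function(reference, test) {
  reference <- unique(reference)
  if (!length(reference)) {
    warn("empty reference DE set; recovery undefined.")
    return(NA_real_)
  }
  length(intersect(reference, unique(test))) / length(reference)
}

#' Spearman rank correlation with p-value
#'
#' Exact permutation p-value for n <= 10 (no ties), normal approximation
#' otherwise - the generic statistic used, e.g., to relate per-condition
#' DE-gene counts to cell-viability measurements.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return Tibble: rho, p, n, method. rho is `NA` for a constant vector.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 4) abort("need at least 4 paired values.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: rank correlation undefined.")
    return(tibble(rho = NA_real_, p = NA_real_, n = length(x),
                  method = NA_character_))
  }
  exact <- length(x) <= 10 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
         method = if (exact) "exact" else "normal approximation")
}

#' Downsampling concordance report across ratios
#'
#' For each retention ratio, thins the shallow counts, reruns the DE engine,
#' and reports the Spearman correlation of log2 fold changes against a
#' reference (deep) DE run, the DE-gene count, and the fraction of the
#' reference DE set recovered. `multiplex_equiv = base_multiplex / ratio`
#' maps each ratio to the multiplexing level it emulates.
#'
#' @param counts Shallow counts tibble.
#' @param design Design tibble.
#' @param reference An `nb_de_fit` to compare against (e.g. from deep
#'   counts); when `NULL`, the DE run on the unthinned `counts` is used.
#' @param annotation Optional annotation for gene mapping.
#' @param ratios Retention ratios, sorted descending (default 1, 1/2, 1/4,
#'   1/6, 1/8, 1/10, 1/12).
#' @param fdr FDR level for DE calls.
#' @param seed Seed for the thinning draws.
#' @param base_multiplex Multiplexing level corresponding to ratio 1
#'   (default 96).
#' @param min_total_reads Coverage filter threshold.
#' @return A `downsample_report` tibble: ratio, multiplex_equiv, rho, n_de,
#'   recovery (per contrast, averaged across contrasts when several).
#' @export
downsample_report <- function(counts, design, reference = NULL,
                              annotation = NULL,
                              ratios = c(1, 1/2, 1/4, 1/6, 1/8, 1/10, 1/12),
                              fdr = 0.1, seed = 1L, base_multiplex = 96,
                              min_total_reads = 20) {
  if (any(ratios <= 0 | ratios > 1)) abort("ratios must lie in (0, 1].")
  ratios <- sort(ratios, decreasing = TRUE)
  if (is.null(reference)) {
    reference <- de_test(counts, design, annotation, fdr = fdr,
                         min_total_reads = min_total_reads)
  }
  ref_de <- de_genes(reference, fdr = fdr)
  out <- purrr::imap_dfr(ratios, function(r, i) {
    thinned <- thin_counts(counts, r, seed = as.integer(seed) + i)
    fit <- de_test(thinned, design, annotation, fdr = fdr,
                   min_total_reads = min_total_reads)
    de <- de_genes(fit, fdr = fdr)
    rho <- fc_correlation(fit$results, reference$results)
    rec <- if (nrow(ref_de)) {
      recovery_fraction(unique(ref_de$gene_id), unique(de$gene_id))
    } else NA_real_
    tibble(ratio = r, multiplex_equiv = base_multiplex / r, rho = rho,
           n_de = length(unique(de$gene_id)), recovery = rec)
  })
  structure(out, class = c("downsample_report", class(out)),
            fdr = fdr, seed = as.integer(seed))
}

#' DE-gene count as a function of sequencing depth
#'
#' For each target per-sample depth, thins the counts so each sample hits
#' that depth in expectation, reruns the DE engine and counts DE genes at
#' the given FDR; replicated across seeds with mean and spread reported.
#'
#' @param counts Counts tibble.
#' @param design Design tibble.
#' @param depths Target mean per-sample depths (each <= the observed mean
#'   depth).
#' @param annotation Optional annotation.
#' @param fdr FDR level.
#' @param seeds Integer vector of thinning seeds (replicates).
#' @param min_total_reads Coverage filter threshold.
#' @return Tibble: depth, mean_n_de, sd_n_de, n_seeds.
#' @export
depth_response_curve <- function(counts, design, depths, annotation = NULL,
                                 fdr = 0.1, seeds = 1:3,
                                 min_total_reads = 20) {
  m <- count_matrix(counts)
  current <- mean(colSums(m))
  # 1% allowance: a nominal target equal to the generating depth may sit a
  # shade above the realized mean; the ratio is clamped at 1 anyway
  if (any(depths > current * 1.01)) {
    abort("target depths must not exceed the observed mean per-sample depth.")
  }
  purrr::map_dfr(depths, function(d) {
    ratio <- min(1, d / current)
    n_de <- vapply(seeds, function(s) {
      thinned <- thin_counts(counts, ratio, seed = s)
      fit <- de_test(thinned, design, annotation, fdr = fdr,
                     min_total_reads = min_total_reads)
      length(unique(de_genes(fit, fdr = fdr)$gene_id))
    }, numeric(1))
    tibble(depth = d, mean_n_de = mean(n_de), sd_n_de = sd(n_de),
           n_seeds = length(seeds))
  })
}
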