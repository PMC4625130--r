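# broom-style tidiers for fitted objects.

#' Tidy an NB DE fit
#'
#' One row per transcript per contrast with estimate, standard error,
#' statistic, p-value and BH q-value.
#'
#' @param x An `nb_de_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy nb_de_fit
#' @export
tidy.nb_de_fit <- function(x, ...) {
  as_tibble(x$results)
}

#' One-row summary of an NB DE fit
#'
#' @param x An `nb_de_fit`.
#' @param ... Unused.
#' @return Tibble: n_transcripts, n_tested, n_contrasts, n_sig_transcripts,
#'   n_de_genes, fdr, disp_a0, disp_a1, median_dispersion.
#' @method glance nb_de_fit
#' @export
glance.nb_de_fit <- function(x, ...) {
  res <- x$results
  tibble(
    n_transcripts = length(unique(res$transcript_id)),
    n_tested = length(unique(res$transcript_id[res$tested])),
    n_contrasts = length(x$contrasts),
    n_sig_transcripts = sum(res$q <= x$fdr, na.rm = TRUE),
    n_de_genes = nrow(dplyr::distinct(de_genes(x), .data$contrast, .data$gene_id)),
    fdr = x$fdr,
    disp_a0 = attr(x$dispersion, "a0"),
    disp_a1 = attr(x$dispersion, "a1"),
    median_dispersion = median(x$dispersion$final)
  )
}

#' Tidy a sample cluster: pairwise correlations in long form
#'
#' @param x A `sample_cluster`.
#' @param ... Unused.
#' @return Tibble: sample_a, sample_b, correlation (each unordered pair
#'   once).
#' @method tidy sample_cluster
#' @export
tidy.sample_cluster <- function(x, ...) {
  cc <- x$correlation
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  tibble(sample_a = rownames(cc)[idx[, 1]],
         sample_b = colnames(cc)[idx[, 2]],
         correlation = cc[idx])
}

#' One-row summary of a sample cluster
#'
#' @param x A `sample_cluster`.
#' @param ... Unused.
#' @return Tibble: n_samples, mean_correlation, cophenetic_correlation,
#'   linkage.
#' @method glance sample_cluster
#' @export
glance.sample_cluster <- function(x, ...) {
  cc <- x$correlation
  d <- as.dist(1 - cc)
  tibble(
    n_samples = ncol(cc),
    mean_correlation = mean(cc[upper.tri(cc)]),
    cophenetic_correlation = cor(d, cophenetic(x$hclust)),
    linkage = x$linkage
  )
}
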