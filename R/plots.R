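# ggplot2 visualizations for the package's result types.

#' Volcano plot of an NB DE fit
#'
#' @param object An `nb_de_fit`.
#' @param fdr Highlight threshold (default: the fit's).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nb_de_fit
#' @export
autoplot.nb_de_fit <- function(object, fdr = object$fdr, ...) {
  res <- object$results[object$results$tested & !is.na(object$results$p), ]
  res$significant <- !is.na(res$q) & res$q <= fdr
  ggplot(res, aes(x = .data$log2fc, y = -log10(pmax(.data$p, 1e-300)),
                  colour = .data$significant)) +
    geom_point(size = 0.4, alpha = 0.5) +
    scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                        name = sprintf("q <= %.2g", fdr)) +
    facet_wrap(~contrast) +
    labs(x = "log2 fold change", y = "-log10 p") +
    theme_bw()
}

#' QQ plot of p-value calibration
#'
#' @param object A [qq_calibration()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qq_calibration
#' @export
autoplot.qq_calibration <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$expected, .data$observed)) +
    geom_abline(slope = 1, intercept = 0, colour = "red") +
    geom_point(size = 0.5) +
    labs(x = "expected -log10 p (uniform)", y = "observed -log10 p",
         subtitle = sprintf("KS distance %.3f (p = %.3g)",
                            attr(object, "ks_stat"), attr(object, "ks_p"))) +
    theme_bw()
}

#' Correlation heatmap with dendrogram-ordered samples
#'
#' @param object A `sample_cluster`.
#' @param ... Unused.
#' @return A ggplot tile heatmap; samples follow the dendrogram leaf order.
#' @method autoplot sample_cluster
#' @export
autoplot.sample_cluster <- function(object, ...) {
  cc <- object$correlation
  ord <- object$leaf_order
  df <- as_tibble(as.table(cc), .name_repair = ~c("sample_a", "sample_b", "correlation"))
  df$sample_a <- factor(df$sample_a, levels = ord)
  df$sample_b <- factor(df$sample_b, levels = ord)
  ggplot(df, aes(.data$sample_a, .data$sample_b, fill = .data$correlation)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                         midpoint = 0) +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Concordance versus multiplexing level
#'
#' Spearman rho of fold changes (and DE recovery, dashed) against the
#' equivalent multiplexing level of each downsampling ratio.
#'
#' @param object A [downsample_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot downsample_report
#' @export
autoplot.downsample_report <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$multiplex_equiv)) +
    geom_line(aes(y = .data$rho, colour = "Spearman rho")) +
    geom_point(aes(y = .data$rho, colour = "Spearman rho")) +
    geom_line(aes(y = .data$recovery, colour = "DE recovery"), linetype = 2) +
    geom_point(aes(y = .data$recovery, colour = "DE recovery")) +
    scale_x_continuous(breaks = df$multiplex_equiv) +
    scale_colour_manual(values = c("Spearman rho" = "black",
                                   "DE recovery" = "steelblue"), name = NULL) +
    labs(x = "equivalent multiplexing level", y = "concordance with reference") +
    theme_bw()
}

#' Depth distribution of a pool plan outcome
#'
#' Bars of cumulative depth (collected + predicted) per library with the
#' target line.
#'
#' @param object A `pool_plan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pool_plan
#' @export
autoplot.pool_plan <- function(object, ...) {
  df <- as_tibble(object)
  df$cumulative <- df$collected_reads + df$predicted_reads
  ggplot(df, aes(x = stats::reorder(.data$library_id, .data$cumulative),
                 y = .data$cumulative)) +
    geom_col(fill = "grey70") +
    geom_hline(yintercept = attr(object, "target"), colour = "red",
               linetype = 2) +
    labs(x = NULL, y = "cumulative reads (collected + planned)") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Density of per-sample sequencing depth for one or more steps
#'
#' Mirrors the shallow-versus-deep depth-density comparison used to judge
#' pooling uniformity: one density per named depth vector with a dotted mean
#' line each.
#'
#' @param ... Named numeric vectors of per-sample depths (or
#'   `depth_profile` objects).
#' @return A ggplot.
#' @export
plot_depth_densities <- function(...) {
  steps <- list(...)
  if (is.null(names(steps)) || any(names(steps) == "")) {
    names(steps) <- paste0("step", seq_along(steps))
  }
  df <- purrr::imap_dfr(steps, function(d, nm) {
    if (inherits(d, "depth_profile")) d <- d$per_sample_depth
    tibble(step = nm, depth = as.numeric(d))
  })
  means <- df |> dplyr::group_by(.data$step) |>
    dplyr::summarise(m = mean(.data$depth), .groups = "drop")
  ggplot(df, aes(.data$depth, colour = .data$step)) +
    geom_density() +
    geom_vline(data = means, aes(xintercept = .data$m, colour = .data$step),
               linetype = 3) +
    labs(x = "reads per sample", y = "density") +
    theme_bw()
}
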