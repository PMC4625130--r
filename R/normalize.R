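# Expression normalization chain for sample-level clustering:
# FPKM -> GC/length covariate regression residuals -> quantile normalization
# -> per-individual trimmed-mean centering; then Pearson-correlation
# hierarchical clustering of samples.
#
# Stage order is enforced via a `stage` attribute on the expression tibble,
# so an out-of-order call fails loudly instead of silently producing a
# differently normalized matrix.

expr_stage <- function(expr) attr(expr, "stage") %||% NA_character_

set_stage <- function(expr, stage) {
  attr(expr, "stage") <- stage
  class(expr) <- unique(c("expression_matrix", class(expr)))
  expr
}

require_stage <- function(expr, stage) {
  got <- expr_stage(expr)
  if (!identical(got, stage)) {
    abort(sprintf("expected an expression matrix at stage '%s', got '%s'; apply the chain in order fpkm -> residual -> quantile -> centered.",
                  stage, got))
  }
  invisible(expr)
}

expr_matrix <- function(expr) {
  m <- as.matrix(expr[, -1L, drop = FALSE])
  rownames(m) <- expr$transcript_id
  m
}

#' FPKM expression values
#'
#' Fragments per kilobase of transcript per million counted reads:
#' `fpkm = count * 1e9 / (length_bp * total_s)` with `total_s` the sum of
#' counted reads in sample s.
#'
#' @param counts Counts tibble.
#' @param annotation Annotation tibble with `transcript_id`, `length_bp`.
#' @return Expression tibble at stage `"fpkm"`.
#' @export
fpkm <- function(counts, annotation) {
  m <- count_matrix(counts)
  annotation <- as_tibble(annotation)
  idx <- match(rownames(m), annotation$transcript_id)
  if (anyNA(idx)) abort("annotation missing for some transcripts.")
  len <- annotation$length_bp[idx]
  if (any(len <= 0)) abort("transcript lengths must be positive.")
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort(sprintf("sample %s has zero total counts; FPKM undefined.",
                  colnames(m)[which(totals <= 0)[1L]]))
  }
  f <- sweep(m / len, 2, totals, "/") * 1e9
  set_stage(matrix_to_counts(f), "fpkm")
}

#' Regress GC/length bias out of log expression
#'
#' Per sample, ordinary least squares of `log2(FPKM + pseudocount)` on
#' \[1, GC, log10(length), GC x log10(length)\]; residuals are returned.
#' Removes the library-preparation covariate bias that otherwise dominates
#' between-sample correlation structure. Collinear columns (e.g. constant
#' GC) are dropped with a warning.
#'
#' @param expr Expression tibble at stage `"fpkm"`.
#' @param annotation Annotation tibble (`gc_fraction`, `length_bp`).
#' @param pseudocount Added before the log (default 0.5).
#' @return Expression tibble at stage `"residual"`.
#' @export
regress_out_covariates <- function(expr, annotation, pseudocount = 0.5) {
  require_stage(expr, "fpkm")
  m <- expr_matrix(expr)
  annotation <- as_tibble(annotation)
  idx <- match(rownames(m), annotation$transcript_id)
  if (anyNA(idx)) abort("annotation missing for some transcripts.")
  gc <- annotation$gc_fraction[idx]
  loglen <- log10(annotation$length_bp[idx])
  X <- cbind(intercept = 1, gc = gc, loglen = loglen, gc_loglen = gc * loglen)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warn(sprintf("rank-deficient covariate design; dropping column(s): %s",
                 paste(colnames(X)[-keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  Y <- log2(m + pseudocount)
  res <- qr.resid(qrX, Y)
  dimnames(res) <- dimnames(m)
  set_stage(matrix_to_counts(res), "residual")
}

#' Quantile normalization across samples
#'
#' Classic across-sample quantile normalization: within each sample values
#' are ranked and replaced by the mean of the order statistics across
#' samples, so every sample ends with an identical marginal distribution;
#' ties receive the mean of the reference values they span.
#'
#' @param expr Expression tibble at stage `"residual"`.
#' @return Expression tibble at stage `"quantile"`.
#' @export
quantile_normalize <- function(expr) {
  require_stage(expr, "residual")
  m <- expr_matrix(expr)
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  set_stage(matrix_to_counts(qn), "quantile")
}

#' Center each transcript within each individual by a trimmed mean
#'
#' Subtracts, per transcript and individual, the `trim`-fraction trimmed
#' mean (Tukey's mean; `mean(x, trim = trim)` semantics, dropping
#' `floor(trim * n)` values from each tail) of that transcript's values
#' across the individual's samples. Removes individual-level baseline
#' expression so samples cluster by treatment response.
#'
#' @param expr Expression tibble at stage `"quantile"`.
#' @param samples Tibble mapping `sample_id` to `individual`.
#' @param trim Trim fraction in \[0, 0.5) (default 0.1).
#' @return Expression tibble at stage `"centered"`.
#' @export
trimmed_center <- function(expr, samples, trim = 0.1) {
  require_stage(expr, "quantile")
  if (trim < 0 || trim >= 0.5) abort("`trim` must lie in [0, 0.5).")
  m <- expr_matrix(expr)
  samples <- as_tibble(samples)
  ind <- samples$individual[match(colnames(m), samples$sample_id)]
  if (anyNA(ind)) abort("sample sheet missing for some samples.")
  out <- m
  for (ii in unique(ind)) {
    cols <- which(ind == ii)
    if (length(cols) < 3 && trim > 0) {
      warn(sprintf("individual %s has %d sample(s); trimmed mean reduces to the plain mean.",
                   ii, length(cols)))
    }
    ctr <- apply(m[, cols, drop = FALSE], 1, mean, trim = trim)
    out[, cols] <- m[, cols, drop = FALSE] - ctr
  }
  set_stage(matrix_to_counts(out), "centered")
}

#' Correlate samples and cluster them hierarchically
#'
#' Pearson correlation between sample columns, agglomerative clustering on
#' distance `1 - correlation` (average linkage by default). Zero-variance
#' samples have no defined correlation and are excluded with a warning.
#'
#' @param expr Expression tibble at any stage (typically `"centered"`).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A `sample_cluster` object: `correlation` (matrix), `hclust`,
#'   `leaf_order` (sample ids in dendrogram order).
#' @export
correlate_and_cluster <- function(expr, linkage = "average") {
  m <- expr_matrix(expr)
  vars <- apply(m, 2, stats::var)
  if (any(vars == 0)) {
    warn(sprintf("excluding zero-variance sample(s): %s",
                 paste(colnames(m)[vars == 0], collapse = ", ")))
    m <- m[, vars > 0, drop = FALSE]
  }
  if (ncol(m) < 3) abort("need at least 3 (non-degenerate) samples to cluster.")
  cc <- cor(m, method = "pearson")
  hc <- hclust(as.dist(1 - cc), method = linkage)
  structure(
    list(correlation = cc, hclust = hc, leaf_order = colnames(cc)[hc$order],
         linkage = linkage),
    class = "sample_cluster"
  )
}

#' @export
print.sample_cluster <- function(x, ...) {
  cat(sprintf("<sample_cluster> %d samples, %s linkage on 1 - Pearson correlation\n",
              ncol(x$correlation), x$linkage))
  invisible(x)
}

#' Write a sample dendrogram as Newick
#'
#' @param cluster A `sample_cluster`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(cluster, path) {
  stopifnot(inherits(cluster, "sample_cluster"))
  phy <- ape::as.phylo(cluster$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Run the full normalization chain
#'
#' [fpkm()] then [regress_out_covariates()] then [quantile_normalize()] then
#' [trimmed_center()].
#'
#' @param counts Counts tibble.
#' @param annotation Annotation tibble.
#' @param samples Sample sheet with `sample_id`, `individual`.
#' @param trim Trim fraction for the centering step.
#' @param pseudocount Pseudo-count for the log transform.
#' @return Expression tibble at stage `"centered"`.
#' @export
normalize_expression <- function(counts, annotation, samples, trim = 0.1,
                                 pseudocount = 0.5) {
  counts |>
    fpkm(annotation) |>
    regress_out_covariates(annotation, pseudocount = pseudocount) |>
    quantile_normalize() |>
    trimmed_center(samples, trim = trim)
}
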