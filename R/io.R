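# Readers and writers for the package's plain-text interchange formats:
# counts TSV (transcript_id + one column per sample), annotation TSV, sample
# sheet CSV, run manifest CSV with a total_output header line, pool plan CSV
# and per-contrast DE results TSV. Every writer emits a provenance header.

provenance_header <- function(seed = NULL, config = NULL) {
  h <- sprintf("# twostepseq %s", as.character(packageVersion("twostepseq")))
  if (!is.null(seed)) h <- paste0(h, sprintf("; seed=%d", as.integer(seed)))
  if (!is.null(config)) h <- paste0(h, sprintf("; config_hash=%s", rlang::hash(config)))
  h
}

write_with_header <- function(x, path, delim, seed = NULL, config = NULL) {
  writeLines(provenance_header(seed, config), path)
  readr::write_delim(x, path, delim = delim, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a counts table
#'
#' Tab-separated, header row of sample ids, first column `transcript_id`,
#' integer counts. Lines starting with `#` are provenance comments.
#'
#' @param path File path.
#' @return Validated counts tibble.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (!nrow(x)) abort(sprintf("no transcripts in counts file '%s'.", path))
  if (names(x)[1L] != "transcript_id") {
    names(x)[1L] <- "transcript_id"
    x$transcript_id <- as.character(x$transcript_id)
  }
  for (j in seq(2L, ncol(x))) {
    col <- x[[j]]
    if (!is.numeric(col)) {
      abort(sprintf("non-numeric counts in column '%s'.", names(x)[j]))
    }
    bad <- which(col != round(col) | col < 0)
    if (length(bad)) {
      abort(sprintf("invalid count at line %d, column '%s': %s",
                    bad[1L] + 1L, names(x)[j], format(col[bad[1L]])))
    }
  }
  count_matrix(x)  # full validation (duplicates etc.)
  x
}

#' Write a counts table
#' @param counts Counts tibble.
#' @param path Output path.
#' @param seed,config Optional provenance recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, seed = NULL, config = NULL) {
  write_with_header(counts, path, "\t", seed, config)
}

#' Read an annotation table
#'
#' Tab-separated: transcript_id, gene_id, length_bp, gc_fraction.
#' @param path File path.
#' @return Validated annotation tibble.
#' @export
read_annotation <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("transcript_id", "gene_id", "length_bp", "gc_fraction")
  if (!all(need %in% names(x))) {
    abort(sprintf("annotation file missing column(s): %s",
                  paste(setdiff(need, names(x)), collapse = ", ")))
  }
  if (anyDuplicated(x$transcript_id)) abort("duplicate transcript ids in annotation.")
  if (any(x$length_bp <= 0)) abort("transcript lengths must be positive.")
  if (any(x$gc_fraction < 0 | x$gc_fraction > 1)) abort("gc_fraction must lie in [0, 1].")
  x
}

#' Write an annotation table
#' @inheritParams write_counts
#' @param annotation Annotation tibble.
#' @export
write_annotation <- function(annotation, path, seed = NULL, config = NULL) {
  write_with_header(annotation, path, "\t", seed, config)
}

#' Read a sample sheet
#'
#' CSV with columns sample_id, individual, condition,
#' control_for_condition (and optionally barcode, pooled_volume_ul).
#' @param path File path.
#' @return Design tibble.
#' @export
read_samplesheet <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("sample_id", "individual", "condition", "control_for_condition")
  if (!all(need %in% names(x))) {
    abort(sprintf("sample sheet missing column(s): %s",
                  paste(setdiff(need, names(x)), collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) abort("duplicate sample ids in sample sheet.")
  ctl <- x$control_for_condition
  missing_ctl <- setdiff(ctl[!is.na(ctl)], x$condition)
  if (length(missing_ctl)) {
    abort(sprintf("matched control condition(s) absent from sample sheet: %s",
                  paste(missing_ctl, collapse = ", ")))
  }
  x
}

#' Write a sample sheet
#' @inheritParams write_counts
#' @param design Design tibble.
#' @export
write_samplesheet <- function(design, path, seed = NULL, config = NULL) {
  write_with_header(design, path, ",", seed, config)
}

#' Read a run manifest
#'
#' CSV of (library_id, reads) preceded by a header line
#' `total_output=<int>`; the sum of per-library reads may be below the total
#' (undetermined barcodes).
#'
#' @param path File path.
#' @return Manifest tibble with attribute `total_output`.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  total <- NA_real_
  hdr <- grep("^total_output=", lines)
  if (length(hdr)) {
    total <- as.numeric(sub("^total_output=", "", lines[hdr[1L]]))
    lines <- lines[-hdr]
  }
  x <- readr::read_csv(I(paste(lines, collapse = "\n")),
                       show_col_types = FALSE, progress = FALSE)
  if (!all(c("library_id", "reads") %in% names(x))) {
    abort("manifest must have columns library_id, reads.")
  }
  if (anyDuplicated(x$library_id)) abort("duplicate library ids in manifest.")
  if (any(x$reads < 0)) abort("negative read counts in manifest.")
  if (is.na(total)) total <- sum(x$reads)
  if (sum(x$reads) > total * (1 + 1e-9)) {
    abort("per-library reads exceed the declared total_output.")
  }
  structure(as_tibble(x), total_output = total)
}

#' Write a run manifest
#' @inheritParams write_counts
#' @param manifest Manifest tibble (attribute `total_output` respected).
#' @export
write_manifest <- function(manifest, path, seed = NULL, config = NULL) {
  total <- attr(manifest, "total_output") %||% sum(manifest$reads)
  writeLines(c(provenance_header(seed, config),
               sprintf("total_output=%.0f", total)), path)
  readr::write_csv(as_tibble(manifest), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a pool plan
#' @inheritParams write_counts
#' @param plan A `pool_plan`; volumes are reported at 0.01 uL resolution
#'   (full precision is kept on the object itself).
#' @export
write_pool_plan <- function(plan, path, seed = NULL, config = NULL) {
  out <- as_tibble(plan)
  out$volume_ul <- round(out$volume_ul, 2)
  write_with_header(out, path, ",", seed, config)
}

#' Write per-contrast DE results
#'
#' Column names mirror the de-facto standard of NB DE tools (baseMean,
#' log2FoldChange, lfcSE, stat, pvalue, padj) so downstream tooling
#' interoperates.
#'
#' @inheritParams write_counts
#' @param fit An `nb_de_fit` (or its results tibble).
#' @export
write_de_results <- function(fit, path, seed = NULL, config = NULL) {
  res <- if (inherits(fit, "nb_de_fit")) fit$results else as_tibble(fit)
  out <- tibble(
    transcript_id = res$transcript_id,
    gene_id = res$gene_id %||% res$transcript_id,
    contrast = res$contrast,
    baseMean = res$base_mean,
    log2FoldChange = res$log2fc,
    lfcSE = res$se,
    stat = res$wald,
    pvalue = res$p,
    padj = res$q
  )
  write_with_header(out, path, "\t", seed, config)
}
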