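# Shared internal helpers: count-table validation, matrix conversion,
# seed substreams.

#' Convert a counts tibble to an integer matrix
#'
#' Counts travel through the package as a tibble whose first column,
#' `transcript_id`, identifies the feature and whose remaining columns are one
#' integer column per sample. This helper validates that layout and returns
#' the numeric matrix (transcripts x samples) used internally.
#'
#' @param counts A counts tibble (`transcript_id` + one column per sample).
#' @return Numeric matrix with transcript ids as rownames.
#' @keywords internal
count_matrix <- function(counts) {
  if (!is.data.frame(counts) || ncol(counts) < 2L) {
    abort("`counts` must be a data frame with a transcript_id column and at least one sample column.")
  }
  if (names(counts)[1L] != "transcript_id") {
    abort("first column of `counts` must be `transcript_id`.")
  }
  ids <- as.character(counts[["transcript_id"]])
  if (anyDuplicated(ids)) abort("duplicate transcript ids in `counts`.")
  sample_cols <- names(counts)[-1L]
  if (anyDuplicated(sample_cols)) abort("duplicate sample ids in `counts`.")
  m <- as.matrix(counts[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort("count columns must be numeric.")
  if (anyNA(m)) abort("missing values in `counts`.")
  if (any(m < 0)) abort("negative values in `counts`.")
  if (any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-integer count at transcript '%s', sample '%s'.",
                  ids[bad[1L]], sample_cols[bad[2L]]))
  }
  rownames(m) <- ids
  m
}

#' Rebuild a counts tibble from a matrix
#' @keywords internal
matrix_to_counts <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(transcript_id = rownames(m)), out)
  out
}

# Row-wise sample variance (n - 1 denominator) for a matrix.
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# Deterministic per-operation RNG substream: a fixed offset from the config
# seed, so stages can be re-run independently yet reproducibly.
with_substream <- function(seed, offset, code) {
  s <- as.integer((as.numeric(seed) + offset) %% 2147483647)
  withr::with_seed(s, code)
}

# Multinomial sampler free of the 32-bit `size` limit of rmultinom():
# sequential conditional binomials, distributionally exact, using rbinom()
# which accepts double-valued sizes.
rmultinom_large <- function(total, prob) {
  k <- length(prob)
  out <- numeric(k)
  remaining <- total
  p_left <- sum(prob)
  for (i in seq_len(k - 1L)) {
    if (remaining <= 0 || prob[i] <= 0) {
      out[i] <- 0
      p_left <- p_left - prob[i]
      next
    }
    p <- min(1, prob[i] / p_left)
    out[i] <- if (p >= 1) remaining else rbinom(1L, remaining, p)
    remaining <- remaining - out[i]
    p_left <- p_left - prob[i]
  }
  out[k] <- if (prob[k] > 0) remaining else 0
  if (prob[k] <= 0 && remaining > 0) {
    # push leftover to the last positive-mass category
    j <- max(which(prob > 0))
    out[j] <- out[j] + remaining
  }
  out
}

geometric_mean <- function(x) exp(mean(log(x)))
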