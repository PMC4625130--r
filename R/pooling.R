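# Digital-concentration re-pooling: learn reads/uL per library from a prior
# sequencing run and compute volumes that equalize cumulative depth at a
# target T across libraries.

#' Digital read concentration of each pooled library
#'
#' The digital concentration R_i is the number of raw sequencing reads a
#' library contributed per uL of pooled volume, learned from an actual run
#' rather than from physical quantification. It folds in each library's
#' cluster-generation efficiency, which makes it a better dosing basis than
#' qPCR or fluorometry.
#'
#' @param manifest Run manifest tibble with columns `library_id`, `reads`
#'   (see [read_manifest()]); an attribute `total_output` may carry the run
#'   total (undetermined barcodes allowed, i.e. `sum(reads) <= total_output`).
#' @param volumes Tibble with columns `library_id`, `volume_ul` giving the
#'   volume of each library pooled into the sequenced pool.
#' @return Tibble: library_id, reads, volume_ul, digital_conc (reads/uL).
#' @export
digital_concentration <- function(manifest, volumes) {
  manifest <- as_tibble(manifest)
  volumes <- as_tibble(volumes)
  stopifnot(all(c("library_id", "reads") %in% names(manifest)),
            all(c("library_id", "volume_ul") %in% names(volumes)))
  out <- dplyr::left_join(manifest, volumes, by = "library_id")
  if (anyNA(out$volume_ul)) {
    abort(sprintf("no pooled volume for library %s",
                  out$library_id[which(is.na(out$volume_ul))[1L]]))
  }
  bad <- out$volume_ul <= 0
  if (any(bad)) {
    abort(sprintf("non-positive pooled volume for library %s",
                  out$library_id[which(bad)[1L]]))
  }
  if (any(out$reads < 0)) abort("negative read counts in manifest.")
  dplyr::mutate(out, digital_conc = .data$reads / .data$volume_ul)
}

#' Re-pooling volumes equalizing cumulative depth at a target
#'
#' For each library i with target cumulative depth `T`, reads already
#' collected `D_i` and digital concentration `R_i` (reads/uL), the volume to
#' re-pool is `V_i = max(0, T - D_i) / R_i`; proportions are `V_i / sum(V)`.
#' Libraries already at or beyond the target get volume 0. Predicted reads
#' for the planned run split `run_output` proportionally to the remaining
#' deficits `(T - D_i)+`, so when `run_output` equals the total deficit every
#' deficient library lands exactly at `T` in expectation.
#'
#' @param target Desired cumulative reads per library (T; e.g. 75e6).
#' @param libraries Tibble with columns `library_id`, `collected_reads`
#'   (D_i) and `digital_conc` (R_i, reads/uL).
#' @param run_output Expected assignable read output of the planned run;
#'   default: the total remaining deficit, i.e. a run sized to finish the job.
#' @param assignable_fraction Fraction of `run_output` expected to carry an
#'   assignable barcode (default 1).
#' @return A `pool_plan` tibble: library_id, collected_reads, digital_conc,
#'   volume_ul, proportion, predicted_reads; attributes `target`,
#'   `run_output` and `nothing_to_pool`.
#' @export
repool_volumes <- function(target, libraries, run_output = NULL,
                           assignable_fraction = 1) {
  libraries <- as_tibble(libraries)
  stopifnot(all(c("library_id", "collected_reads", "digital_conc") %in% names(libraries)))
  if (target <= 0) abort("`target` must be > 0.")
  D <- libraries$collected_reads
  R <- libraries$digital_conc
  deficit <- pmax(0, target - D)
  bad <- deficit > 0 & R <= 0
  if (any(bad)) {
    abort(sprintf("library %s is below target but has zero digital concentration; it cannot be dosed.",
                  libraries$library_id[which(bad)[1L]]))
  }
  if (is.null(run_output)) run_output <- sum(deficit)
  run_output <- run_output * assignable_fraction
  V <- ifelse(deficit > 0, deficit / R, 0)
  tot_V <- sum(V)
  tot_def <- sum(deficit)
  plan <- dplyr::mutate(
    libraries,
    volume_ul = V,
    proportion = if (tot_V > 0) V / tot_V else 0,
    predicted_reads = if (tot_def > 0) run_output * deficit / tot_def else 0
  )
  structure(plan,
            class = c("pool_plan", class(plan)),
            target = target, run_output = run_output,
            nothing_to_pool = tot_V == 0)
}

#' @export
print.pool_plan <- function(x, ...) {
  cat(sprintf("<pool_plan> target %.4g reads/library, planned run output %.4g\n",
              attr(x, "target"), attr(x, "run_output")))
  if (isTRUE(attr(x, "nothing_to_pool"))) {
    cat("  all libraries at target: nothing to pool\n")
  }
  NextMethod()
}

#' Update a pool plan after another sequencing run
#'
#' Adds the new run's reads to each library's cumulative `D_i`, re-estimates
#' the digital concentration from the most recent run (reads delivered per uL
#' actually re-pooled; libraries receiving zero reads keep their previous
#' estimate, and an optional flag averages old and new concentrations
#' weighted by pooled volume), and recomputes [repool_volumes()]. Iterating
#' converges cumulative depths to the target across runs.
#'
#' @param plan A `pool_plan` from [repool_volumes()].
#' @param new_manifest Manifest tibble (`library_id`, `reads`) of the run
#'   performed with `plan`; must cover the plan's libraries.
#' @param run_output Expected output of the next planned run (default:
#'   remaining deficit).
#' @param average_conc If `TRUE`, volume-weighted average of previous and new
#'   digital concentrations instead of latest-run-only.
#' @return A new `pool_plan`.
#' @export
iterate_plan <- function(plan, new_manifest, run_output = NULL,
                         average_conc = FALSE) {
  stopifnot(inherits(plan, "pool_plan"))
  new_manifest <- as_tibble(new_manifest)
  target <- attr(plan, "target")
  missing <- setdiff(plan$library_id, new_manifest$library_id)
  if (length(missing)) {
    abort(sprintf("new manifest does not cover library %s", missing[1L]))
  }
  upd <- dplyr::left_join(
    plan[, c("library_id", "collected_reads", "digital_conc", "volume_ul")],
    new_manifest[, c("library_id", "reads")],
    by = "library_id"
  )
  new_R <- ifelse(upd$volume_ul > 0 & upd$reads > 0,
                  upd$reads / upd$volume_ul, NA_real_)
  R <- ifelse(is.na(new_R), upd$digital_conc,
              if (average_conc) {
                # weight old R by 1 "unit" volume and new by the re-pooled volume
                (upd$digital_conc + new_R * upd$volume_ul) / (1 + upd$volume_ul)
              } else new_R)
  libs <- tibble(library_id = upd$library_id,
                 collected_reads = upd$collected_reads + upd$reads,
                 digital_conc = R)
  repool_volumes(target, libs, run_output = run_output)
}

#' Summarize the uniformity of per-sample sequencing depth
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation of per-sample depths, optionally after pooling technical
#' replicates of the same biological sample (as control replicates are pooled
#' when judging depth uniformity across conditions).
#'
#' @param depths Numeric vector of per-sample read counts (>= 2 values), or a
#'   tibble with columns `sample_id` and `depth`.
#' @param pool_by Optional factor/character grouping; depths are summed
#'   within groups before profiling.
#' @return A `depth_profile` list: per_sample_depth, mean, sd, cv
#'   (cv is `NA` when the mean is 0).
#' @export
depth_profile <- function(depths, pool_by = NULL) {
  if (is.data.frame(depths)) {
    stopifnot(all(c("sample_id", "depth") %in% names(depths)))
    d <- setNames(depths$depth, depths$sample_id)
  } else {
    d <- depths
  }
  if (!is.null(pool_by)) {
    d <- tapply(d, pool_by, sum)
    d <- setNames(as.numeric(d), names(d))
  }
  if (length(d) < 2) abort("need at least 2 samples to profile depth.")
  m <- mean(d)
  s <- sd(d)
  structure(
    list(per_sample_depth = d, mean = m, sd = s,
         cv = if (m > 0) s / m else NA_real_),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> n=%d  mean=%.4g  sd=%.4g  cv=%s\n",
              length(x$per_sample_depth), x$mean, x$sd,
              ifelse(is.na(x$cv), "NA", sprintf("%.4f", x$cv))))
  invisible(x)
}
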