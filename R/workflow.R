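# End-to-end two-step workflow on simulated data: shallow multiplexed
# screen, condition ranking by DE-gene count, digital-concentration re-pool
# plan for the selected conditions, deep sequencing, and a shallow-vs-deep
# concordance report.

#' Workflow configuration
#'
#' Validates and fills defaults for [run_two_step()]. Accepts either a named
#' list or a YAML file path whose keys map 1:1 to the arguments of
#' [sim_config()] plus the workflow parameters listed here.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated list of class `workflow_config`.
#' @export
workflow_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found.", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    # simulation (passed to sim_config)
    n_genes = 2000, frac_de = 0.1, effect_sd = 1,
    baseline_log_mean = log(250), baseline_log_sd = 1.5,
    disp_a0 = 0.05, disp_a1 = 2, eff_log_sd = 0.25,
    gc_beta = 0, len_beta = 0, gclen_beta = 0,
    ref_depth = 5e6, seed = 1L,
    groups = NULL,
    # workflow
    shallow_total_output = NULL,   # default: n_samples * shallow_depth
    shallow_depth = 1e6,
    target_T = 10e6,
    n_select = 1L,                 # conditions to carry into step two
    fdr = 0.1, min_total_reads = 20, trim = 0.1,
    ratios = c(1, 1/2, 1/4, 1/6, 1/8, 1/10, 1/12),
    out_dir = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown workflow config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config)
  if (cfg$fdr <= 0 || cfg$fdr >= 1) abort("`fdr` must lie in (0, 1).")
  if (cfg$target_T <= 0) abort("`target_T` must be > 0.")
  if (cfg$n_select < 0) abort("`n_select` must be >= 0.")
  structure(cfg, class = "workflow_config")
}

#' Run the two-step screening workflow on simulated data
#'
#' Simulates a multiplexed screen (uneven flow-cell allocation across
#' libraries), runs the shallow DE screen, ranks treatment conditions by
#' DE-gene count at the configured FDR, selects the top conditions, computes
#' the digital-concentration re-pool plan that brings the selected libraries
#' to the target cumulative depth, simulates the deep run on the same
#' physical libraries, reruns DE on the deep counts alone (step-one and
#' step-two reads are never merged for testing; only the cumulative depth
#' `D_i` accumulates for pooling), and reports shallow/deep concordance.
#'
#' @param config A [workflow_config()], named list, or YAML path.
#' @return List of class `twostep_run`: sim, shallow_fit, ranking, selected,
#'   plan, deep_counts, deep_fit, concordance, depth_profiles, config.
#' @export
run_two_step <- function(config = list()) {
  cfg <- if (inherits(config, "workflow_config")) config else workflow_config(config)
  sim_args <- cfg[intersect(names(cfg), names(formals(sim_config)))]
  sim_args <- sim_args[!vapply(sim_args, is.null, logical(1))]
  scfg <- do.call(sim_config, sim_args)

  total1 <- cfg$shallow_total_output %||% (scfg$n_samples * cfg$shallow_depth)
  sim <- simulate_experiment(scfg, total_output = total1)

  shallow_fit <- de_test(sim$counts, sim$design, sim$annotation,
                         fdr = cfg$fdr, min_total_reads = cfg$min_total_reads)
  de1 <- de_genes(shallow_fit, fdr = cfg$fdr)
  treatments <- unique(sim$design$condition[!is.na(sim$design$control_for_condition)])
  ranking <- tibble(condition = treatments) |>
    dplyr::left_join(
      de1 |>
        dplyr::mutate(condition = sub(" vs .*$", "", .data$contrast)) |>
        dplyr::count(.data$condition, name = "n_de_genes"),
      by = "condition") |>
    dplyr::mutate(n_de_genes = ifelse(is.na(.data$n_de_genes), 0L, .data$n_de_genes)) |>
    dplyr::arrange(dplyr::desc(.data$n_de_genes))
  selected <- head(ranking$condition, cfg$n_select)

  sel_samples <- sim$design$sample_id[
    sim$design$condition %in% c(selected,
                                unique(sim$design$control_for_condition[
                                  sim$design$condition %in% selected]))]
  libs <- tibble(
    library_id = sim$design$sample_id,
    collected_reads = as.numeric(sim$depths),
    digital_conc = as.numeric(sim$depths) / sim$pooled_volume
  )
  libs_sel <- libs[libs$library_id %in% sel_samples, , drop = FALSE]
  concordance <- NULL; deep_fit <- NULL; deep_counts <- NULL; plan <- NULL
  profiles <- list(shallow = depth_profile(sim$depths))
  if (length(selected)) {
    plan <- repool_volumes(cfg$target_T, libs_sel)
    # deep run: same libraries (same latent rates), depth set by the plan
    deep_depths <- setNames(rep(0, nrow(sim$design)), sim$design$sample_id)
    deep_depths[plan$library_id] <- plan$predicted_reads
    deep_counts <- simulate_counts(scfg, sim$truth, deep_depths,
                                   sim$annotation, sim$design,
                                   rates = sim$rates, seed_offset = 17L)
    deep_design <- sim$design[sim$design$sample_id %in% plan$library_id, ]
    dm <- count_matrix(deep_counts)
    deep_counts <- matrix_to_counts(dm[, deep_design$sample_id, drop = FALSE])
    deep_fit <- de_test(deep_counts, deep_design, sim$annotation,
                        fdr = cfg$fdr, min_total_reads = cfg$min_total_reads)
    de2 <- de_genes(deep_fit, fdr = cfg$fdr)
    concordance <- purrr::map_dfr(unique(deep_fit$results$contrast), function(ct) {
      a <- shallow_fit$results[shallow_fit$results$contrast == ct, ]
      b <- deep_fit$results[deep_fit$results$contrast == ct, ]
      ref <- unique(de2$gene_id[de2$contrast == ct])
      tibble(
        contrast = ct,
        rho = fc_correlation(a, b),
        n_de_shallow = length(unique(de1$gene_id[de1$contrast == ct])),
        n_de_deep = length(ref),
        recovery_of_deep = if (length(ref)) {
          recovery_fraction(ref, unique(de1$gene_id[de1$contrast == ct]))
        } else NA_real_
      )
    })
    profiles$deep <- depth_profile(plan$predicted_reads + plan$collected_reads)
  }

  out <- structure(
    list(sim = sim, shallow_fit = shallow_fit, ranking = ranking,
         selected = selected, plan = plan, deep_counts = deep_counts,
         deep_fit = deep_fit, concordance = concordance,
         depth_profiles = profiles, config = cfg),
    class = "twostep_run"
  )
  if (!is.null(cfg$out_dir)) write_two_step(out, cfg$out_dir)
  out
}

#' @export
print.twostep_run <- function(x, ...) {
  cat("<twostep_run>\n")
  cat(sprintf("  shallow: %d samples, mean depth %.3g (cv %.3f)\n",
              length(x$sim$depths), x$depth_profiles$shallow$mean,
              x$depth_profiles$shallow$cv))
  cat(sprintf("  selected for step two: %s\n",
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)"))
  if (!is.null(x$concordance)) {
    cat(sprintf("  shallow/deep Spearman rho: %s\n",
                paste(sprintf("%.3f", x$concordance$rho), collapse = ", ")))
  }
  invisible(x)
}

#' Persist a two-step run's artifacts
#'
#' Writes counts, annotation, sample sheet, ranking, pool plan, deep counts
#' and both DE result sets (all with provenance headers) under `dir`.
#'
#' @param run A `twostep_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_two_step <- function(run, dir) {
  stopifnot(inherits(run, "twostep_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- unclass(run$config)
  seed <- run$sim$cfg$seed
  p <- function(f) file.path(dir, f)
  write_counts(run$sim$counts, p("shallow_counts.tsv"), seed, cfg)
  write_annotation(run$sim$annotation, p("annotation.tsv"), seed, cfg)
  write_samplesheet(run$sim$design, p("samples.csv"), seed, cfg)
  write_with_header(run$ranking, p("condition_ranking.csv"), ",", seed, cfg)
  write_de_results(run$shallow_fit, p("de_shallow.tsv"), seed, cfg)
  if (!is.null(run$plan)) write_pool_plan(run$plan, p("pool_plan.csv"), seed, cfg)
  if (!is.null(run$deep_counts)) write_counts(run$deep_counts, p("deep_counts.tsv"), seed, cfg)
  if (!is.null(run$deep_fit)) write_de_results(run$deep_fit, p("de_deep.tsv"), seed, cfg)
  if (!is.null(run$concordance)) {
    write_with_header(run$concordance, p("concordance.tsv"), "\t", seed, cfg)
  }
  invisible(dir)
}
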