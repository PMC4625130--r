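# Synthetic multiplexed RNA-seq experiment generator: transcript annotation,
# per-library cluster efficiencies, flow-cell read allocation, and NB counts
# with treatment effects and GC/length expression bias.

#' Configuration of a simulated multiplexed RNA-seq screen
#'
#' Collects every knob of the generator in one validated object. The defaults
#' describe a small screening experiment: one treated group versus its matched
#' vehicle control, three replicate cell lines per group, 10,000 transcripts
#' of which 10% respond to treatment with log2 fold changes of standard
#' deviation 1, and a negative-binomial dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu} anchored at the shallow screening depth.
#'
#' @param n_genes Number of transcripts to simulate.
#' @param groups Tibble with columns `condition`, `n` (replicates) and
#'   `control` (matched control condition, `NA` for controls themselves).
#' @param frac_de Fraction of transcripts with a true effect per treatment.
#' @param effect_sd Standard deviation of true log2 fold changes.
#' @param baseline_log_mean,baseline_log_sd Log-scale location and spread of
#'   transcript abundance (a log-normal abundance profile).
#' @param disp_a0,disp_a1 Coefficients of the dispersion trend
#'   \eqn{\alpha(\mu) = a_0 + a_1/\mu} used to assign per-transcript true
#'   dispersions, with \eqn{\mu} the expected count at `ref_depth`.
#' @param eff_log_sd Log-scale spread of per-library cluster efficiencies
#'   (log-normal, rescaled to mean 1).
#' @param gc_beta,len_beta,gclen_beta Covariate-bias coefficients: expression
#'   is multiplied by `exp(gc_beta*GC + len_beta*log(len) +
#'   gclen_beta*GC*log(len))`.
#' @param ref_depth Reads per sample at which the dispersion trend is
#'   anchored (default 5e6, a typical shallow screening depth).
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 10000,
                       groups = tibble(
                         condition = c("control", "treated"),
                         n = c(3L, 3L),
                         control = c(NA_character_, "control")
                       ),
                       frac_de = 0.1,
                       effect_sd = 1,
                       baseline_log_mean = log(250),
                       baseline_log_sd = 1.5,
                       disp_a0 = 0.05,
                       disp_a1 = 2,
                       eff_log_sd = 0.25,
                       gc_beta = 0,
                       len_beta = 0,
                       gclen_beta = 0,
                       ref_depth = 5e6,
                       seed = 1L) {
  groups <- as_tibble(groups)
  stopifnot(all(c("condition", "n", "control") %in% names(groups)))
  if (n_genes < 1) abort("`n_genes` must be >= 1.")
  if (any(groups$n < 1)) abort("every group must have size >= 1.")
  if (frac_de < 0 || frac_de > 1) abort("`frac_de` must lie in [0, 1].")
  if (disp_a0 < 0 || disp_a1 < 0) abort("dispersion trend coefficients must be >= 0.")
  if (eff_log_sd < 0) abort("`eff_log_sd` must be >= 0.")
  treated <- groups$condition[!is.na(groups$control)]
  missing_ctl <- setdiff(groups$control[!is.na(groups$control)], groups$condition)
  if (length(missing_ctl)) {
    abort(sprintf("matched control(s) not present as groups: %s",
                  paste(missing_ctl, collapse = ", ")))
  }
  structure(
    list(
      n_genes = as.integer(n_genes), groups = groups,
      n_samples = as.integer(sum(groups$n)),
      frac_de = frac_de, effect_sd = effect_sd,
      baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
      disp_a0 = disp_a0, disp_a1 = disp_a1,
      eff_log_sd = eff_log_sd,
      gc_beta = gc_beta, len_beta = len_beta, gclen_beta = gclen_beta,
      ref_depth = ref_depth,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d transcripts, %d samples (%d groups), %.0f%% DE, seed %d\n",
              x$n_genes, x$n_samples, nrow(x$groups), 100 * x$frac_de, x$seed))
  invisible(x)
}

#' Sample sheet implied by a simulation config
#'
#' One row per sample: `sample_id`, `individual` (replicate slot, shared
#' across conditions as for a panel of cell lines), `condition` and that
#' condition's matched control.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with columns sample_id, individual, condition,
#'   control_for_condition.
#' @export
sim_design <- function(cfg) {
  purrr::pmap_dfr(cfg$groups, function(condition, n, control) {
    tibble(
      sample_id = sprintf("%s_I%d", condition, seq_len(n)),
      individual = sprintf("I%d", seq_len(n)),
      condition = condition,
      control_for_condition = control
    )
  })
}

#' Simulate a transcript annotation table
#'
#' Lengths are log-uniform in \[200, 20000\] bp and GC fractions uniform in
#' \[0.2, 0.8\]. A minority of genes carry two transcripts so that the
#' transcript-to-gene mapping of downstream DE calls is exercised.
#'
#' @param cfg A [sim_config()].
#' @return Tibble: transcript_id, gene_id, length_bp, gc_fraction.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  with_substream(cfg$seed, 101, {
    # ~20% of genes get a second transcript
    sizes <- sample(c(1L, 2L), size = n, replace = TRUE, prob = c(0.8, 0.2))
    gene_index <- rep.int(seq_along(sizes), sizes)[seq_len(n)]
    tibble(
      transcript_id = sprintf("T%05d", seq_len(n)),
      gene_id = sprintf("G%05d", gene_index),
      length_bp = as.integer(round(exp(runif(n, log(200), log(20000))))),
      gc_fraction = runif(n, 0.2, 0.8)
    )
  })
}

#' Simulate per-library cluster efficiencies
#'
#' Each barcoded library converts pooled material into flow-cell clusters
#' with its own efficiency; empirically the spread of per-library depths is
#' right-skewed, which a log-normal reproduces. Factors are rescaled to mean
#' 1 so they redistribute, rather than change, total output.
#'
#' @param cfg A [sim_config()].
#' @return Numeric vector of length `n_samples`, mean exactly 1.
#' @export
simulate_efficiencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples
  if (cfg$eff_log_sd == 0) return(rep(1, n))
  e <- with_substream(cfg$seed, 202, exp(rnorm(n, 0, cfg$eff_log_sd)))
  e / mean(e)
}

#' Allocate a sequencing run's reads across pooled libraries
#'
#' Multinomial draw with probabilities proportional to the effective pooled
#' mass of each library (volume x cluster efficiency). Counts always sum to
#' `total_output`. Implemented as sequential conditional binomials so run
#' totals beyond the 32-bit integer range are supported.
#'
#' @param total_output Total reads produced by the run.
#' @param pooled_mass Nonnegative per-library effective mass; at least one
#'   entry must be positive.
#' @param seed Optional seed making the draw reproducible in isolation.
#' @return Numeric vector of per-library read counts summing to
#'   `total_output`, named like `pooled_mass`.
#' @export
allocate_reads <- function(total_output, pooled_mass, seed = NULL) {
  if (total_output < 0) abort("`total_output` must be >= 0.")
  if (any(pooled_mass < 0)) abort("`pooled_mass` entries must be >= 0.")
  if (all(pooled_mass == 0)) abort("all-zero `pooled_mass`: nothing can generate clusters.")
  draw <- function() rmultinom_large(total_output, pooled_mass / sum(pooled_mass))
  out <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  names(out) <- names(pooled_mass)
  out
}

#' Simulate the ground truth of an experiment
#'
#' Draws log-normal baseline abundances, assigns exactly
#' `round(frac_de * n_genes)` transcripts per treatment a true log2 fold
#' change drawn from N(0, effect_sd), and sets each transcript's true NB
#' dispersion from the trend \eqn{\alpha(\mu) = a_0 + a_1/\mu} evaluated at
#' its expected count under `ref_depth`.
#'
#' @param cfg A [sim_config()].
#' @param annotation Output of [simulate_annotation()] (ids are reused).
#' @return List of class `truth_set`: `genes` (transcript_id, baseline,
#'   rel_abundance, true_dispersion) and `effects` (transcript_id, condition,
#'   true_log2fc; zero for unaffected transcripts).
#' @export
simulate_truth <- function(cfg, annotation = simulate_annotation(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  treatments <- cfg$groups$condition[!is.na(cfg$groups$control)]
  with_substream(cfg$seed, 303, {
    baseline <- exp(rnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd))
    rel <- baseline / sum(baseline)
    mu_ref <- rel * cfg$ref_depth
    disp <- pmax(cfg$disp_a0 + cfg$disp_a1 / mu_ref, 1e-8)
    n_de <- round(cfg$frac_de * n)
    effects <- purrr::map_dfr(treatments, function(tr) {
      lfc <- numeric(n)
      if (n_de > 0) {
        idx <- sample.int(n, n_de)
        lfc[idx] <- rnorm(n_de, 0, cfg$effect_sd)
      }
      tibble(transcript_id = annotation$transcript_id, condition = tr,
             true_log2fc = lfc)
    })
    structure(
      list(
        genes = tibble(transcript_id = annotation$transcript_id,
                       baseline = baseline, rel_abundance = rel,
                       true_dispersion = disp),
        effects = effects
      ),
      class = "truth_set"
    )
  })
}

# Per-sample expected relative abundance (renormalized to sum 1) after
# applying treatment effects and covariate bias.
expected_profile <- function(cfg, truth, annotation, design) {
  bias <- exp(cfg$gc_beta * annotation$gc_fraction +
                cfg$len_beta * log(annotation$length_bp) +
                cfg$gclen_beta * annotation$gc_fraction * log(annotation$length_bp))
  eff_wide <- if (nrow(truth$effects)) {
    tidyr::pivot_wider(truth$effects, names_from = "condition",
                       values_from = "true_log2fc")
  } else {
    tibble(transcript_id = annotation$transcript_id)
  }
  prof <- vapply(seq_len(nrow(design)), function(j) {
    cond <- design$condition[j]
    lfc <- if (cond %in% names(eff_wide)) eff_wide[[cond]] else numeric(nrow(annotation))
    w <- truth$genes$rel_abundance * bias * 2^lfc
    w / sum(w)
  }, numeric(nrow(annotation)))
  colnames(prof) <- design$sample_id
  rownames(prof) <- annotation$transcript_id
  prof
}

#' Simulate per-library latent expression realizations
#'
#' The NB count model is generated hierarchically as Gamma x Poisson: each
#' library draws, once, a Gamma(shape = 1/alpha, mean = 1) multiplier per
#' transcript around its expected relative abundance. Sequencing the same
#' library at several depths (as a two-step design does by re-pooling the
#' step-one libraries) conditions on the same realization, so only the
#' counting noise differs between the shallow and the deep run.
#'
#' @param cfg,truth,annotation,design Simulation pieces (see
#'   [simulate_truth()], [sim_design()]).
#' @return Matrix (transcripts x samples) of per-library expected relative
#'   read proportions; columns sum to 1.
#' @export
simulate_library_rates <- function(cfg, truth,
                                   annotation = simulate_annotation(cfg),
                                   design = sim_design(cfg)) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "truth_set"))
  prof <- expected_profile(cfg, truth, annotation, design)
  with_substream(cfg$seed, 404, {
    shape <- 1 / truth$genes$true_dispersion
    g <- matrix(rgamma(length(prof), shape = shape, rate = shape),
                nrow = nrow(prof))
    lam <- prof * g
    sweep(lam, 2, colSums(lam), "/")
  })
}

#' Simulate an NB count matrix at given per-sample depths
#'
#' Counts for transcript g in sample s are NB with mean
#' `depth_s x relative-abundance_{g,s}` and dispersion
#' `true_dispersion_g`, where the relative abundance folds in baseline
#' abundance, the treatment effect `2^true_log2fc` for treated samples, and
#' the GC/length bias, renormalized per sample so depth is the only
#' column-total driver. When `rates` (from [simulate_library_rates()]) is
#' supplied the Gamma part of the NB is conditioned on, emulating
#' re-sequencing of the same physical libraries; otherwise a fresh
#' realization is drawn.
#'
#' @param cfg,truth Simulation config and truth.
#' @param depths Per-sample read totals (recycled if scalar); must be >= 0.
#' @param annotation,design As produced by the paired generators.
#' @param rates Optional latent library rates to condition on.
#' @param seed_offset Integer added to the config seed for the counting-noise
#'   substream (distinct offsets give independent sequencing runs).
#' @return Counts tibble (`transcript_id` + one integer column per sample).
#' @export
simulate_counts <- function(cfg, truth, depths,
                            annotation = simulate_annotation(cfg),
                            design = sim_design(cfg),
                            rates = NULL,
                            seed_offset = 0L) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "truth_set"))
  depths <- rep_len(depths, nrow(design))
  if (any(depths < 0)) abort("per-sample depths must be >= 0.")
  if (is.null(rates)) {
    rates <- simulate_library_rates(cfg, truth, annotation, design)
  }
  stopifnot(nrow(rates) == cfg$n_genes, ncol(rates) == nrow(design))
  with_substream(cfg$seed, 505 + seed_offset, {
    mu <- sweep(rates, 2, depths, "*")
    y <- matrix(rpois(length(mu), lambda = mu), nrow = nrow(mu))
  })
  dimnames(y) <- list(annotation$transcript_id, design$sample_id)
  matrix_to_counts(y)
}

#' Simulate a complete two-step-ready experiment
#'
#' Convenience wrapper producing design, annotation, truth, per-library
#' cluster efficiencies, flow-cell-allocated depths (if `total_output` is
#' given) or fixed depths, latent library rates, and the count matrix.
#'
#' @param cfg A [sim_config()].
#' @param depths Per-sample depths; ignored when `total_output` is given.
#' @param total_output If supplied, per-sample depths are drawn by
#'   [allocate_reads()] with mass = pooled volume x cluster efficiency.
#' @param pooled_volume Per-sample pooled volume in uL (default: equal, 2).
#' @return List of class `twostep_sim` with elements cfg, design, annotation,
#'   truth, efficiencies, depths, rates, counts.
#' @export
simulate_experiment <- function(cfg, depths = cfg$ref_depth,
                                total_output = NULL, pooled_volume = 2) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- sim_design(cfg)
  annotation <- simulate_annotation(cfg)
  truth <- simulate_truth(cfg, annotation)
  eff <- simulate_efficiencies(cfg)
  vol <- rep_len(pooled_volume, nrow(design))
  if (!is.null(total_output)) {
    depths <- with_substream(cfg$seed, 606,
                             allocate_reads(total_output, vol * eff))
  } else {
    depths <- rep_len(depths, nrow(design))
  }
  names(depths) <- design$sample_id
  rates <- simulate_library_rates(cfg, truth, annotation, design)
  counts <- simulate_counts(cfg, truth, depths, annotation, design, rates)
  structure(
    list(cfg = cfg, design = design, annotation = annotation, truth = truth,
         efficiencies = eff, pooled_volume = vol, depths = depths,
         rates = rates, counts = counts),
    class = "twostep_sim"
  )
}

#' @export
print.twostep_sim <- function(x, ...) {
  cat(sprintf("<twostep_sim> %d transcripts x %d samples; mean depth %.3g reads\n",
              x$cfg$n_genes, nrow(x$design), mean(x$depths)))
  invisible(x)
}
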