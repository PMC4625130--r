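---
title: "Two-step multiplexed RNA-seq screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step multiplexed RNA-seq screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
set.seed(1)
```

```{r load}
library(twostepseq)
```

## The design problem

Screening many cellular conditions by RNA-seq (dozens of treatments in a
panel of cell lines, time courses, knockdown panels) is wasteful when every
library is deep-sequenced: most conditions turn out to be uninteresting.
A two-step design spends resources differently. In **step one**, all
libraries (96 or more, barcoded) are pooled and sequenced *shallowly*
(a few million reads each) — enough to rank conditions by the strength of
their transcriptional response. In **step two**, the libraries for the most
responsive conditions are *re-pooled from the existing libraries* (no new
bench work) and sequenced deeply, with pooling volumes chosen so that every
library converges on a common target depth.

`twostepseq` implements the quantitative machinery of this design as
composable, testable pieces:

1. a **synthetic-data generator** for multiplexed screens (uneven flow-cell
   read allocation, negative-binomial counts with treatment effects and
   GC/length bias);
2. the **digital-concentration re-pooling** calculation;
3. a **negative-binomial Wald differential-expression (DE) engine** with a
   mean-dispersion trend and Benjamini-Hochberg FDR control;
4. the **expression normalization chain** used for sample-level clustering;
5. **binomial downsampling** tools that ask how much shallower step one
   could have been.

## Digital-concentration re-pooling

Library *i* contributed `D_i` raw reads in previous runs from `v_i` uL of
pooled volume. Its *digital concentration* is `R_i = D_i / v_i` reads/uL —
a read-based quantification that automatically folds in each library's
cluster-generation efficiency on the flow cell, which qPCR or fluorometric
quantification cannot see. To bring every library to a cumulative target
`T` (say 75 M reads), the next pool uses

```
V_i = max(0, T - D_i) / R_i,        proportion_i = V_i / sum_j V_j .
```

Because expected reads scale with `R_i * V_i`, a run whose assignable
output equals the total remaining deficit `sum_j (T - D_j)+` lands every
deficient library exactly on `T` in expectation; `iterate_plan()` repeats
the update (`D_i` accumulates, `R_i` is re-estimated from the latest run)
across as many runs as needed. Two boundary conventions are ours: libraries
already at or above `T` get volume 0 (the deficit is clamped, since an
over-sequenced library cannot return reads), and both volumes and
normalized proportions are reported, since either may be the quantity a
bench scientist doses with. Undetermined (unassignable-barcode) reads are
excluded from `R_i`; an `assignable_fraction` knob scales the planned run
output accordingly.

```{r pooling}
eff <- exp(rnorm(96, 0, 0.25)); eff <- eff / mean(eff)   # cluster efficiencies
d1 <- allocate_reads(96 * 5e6, 2 * eff, seed = 1)        # step-one depths
plan <- repool_volumes(75e6, tibble::tibble(
  library_id = sprintf("L%02d", 1:96),
  collected_reads = as.numeric(d1),
  digital_conc = as.numeric(d1) / 2))
d2 <- allocate_reads(sum(pmax(75e6 - d1, 0)), plan$volume_ul * eff, seed = 2)
c(cv_step1 = depth_profile(d1)$cv, cv_step2 = depth_profile(d1 + d2)$cv)
```

One round of re-pooling collapses the depth spread by roughly the ratio of
the multinomial counting noise to the efficiency spread — two orders of
magnitude here.

## The count model and what the generator emulates

Counts are negative binomial with the variance function
`Var = mu + alpha * mu^2` (the convention in which `alpha` is called the
dispersion). The generator draws, per transcript:

* a log-normal baseline abundance (`baseline_log_mean = log 250`,
  `baseline_log_sd = 1.5` by default, giving the 3-4 decades of expression
  a poly-A library spans);
* a true dispersion from the trend `alpha(mu) = a0 + a1/mu` evaluated at
  the transcript's expected count under `ref_depth` (defaults
  `a0 = 0.05`, `a1 = 2`, `ref_depth = 5e6`: a ~22% biological CV floor
  plus shot-noise-like excess for weakly covered transcripts);
* for `frac_de` of transcripts per treatment, a true log2 fold change
  `~ N(0, effect_sd)` (defaults 10% and 1.0 — a screening-strength
  response);
* optional multiplicative GC/length expression bias
  `exp(gc_beta*GC + len_beta*log L + gclen_beta*GC*log L)` (defaults 0).

Per-sample expected proportions are renormalized to sum to one, so
sequencing depth is the only driver of column totals — counts are
compositional, as sequencing is.

Generation is hierarchical Gamma x Poisson: each *library* draws one
Gamma(mean 1, variance `alpha`) realization per transcript
(`simulate_library_rates()`), and sequencing that library at depth `d`
draws Poisson counts around `d` times its realized proportions
(`simulate_counts(..., rates = )`). Marginally this is exactly
NB(`mu`, `alpha`); the point of the decomposition is that **step two
re-sequences the same physical libraries as step one**, so shallow and deep
runs must share the library realization and differ only in counting noise.
Simulating the two depths independently would misrepresent the design and
grossly understate the shallow/deep concordance that re-pooling actually
achieves. Uneven per-library depths come from a log-normal
cluster-efficiency model (`eff_log_sd = 0.25`, rescaled to mean 1) feeding
a multinomial read allocator; the log-normal is our choice for the
right-skewed depth spread seen across barcoded libraries, not an empirical
fit. Reads are the atomic unit throughout — no read-level simulation
(FASTQ, alignment, duplicates) and no isoform or allele-specific structure.

## The DE engine

The engine is a deliberately transparent NB Wald pipeline, not a DESeq2
clone — no Cox-Reid adjustment, outlier replacement, independent filtering
or fold-change shrinkage. Its stages:

**Size factors** are median-of-ratios (median over all-positive
transcripts of the count over its geometric mean across samples), rescaled
to geometric mean 1.

**Coverage filter**: transcripts with total raw count strictly greater
than 20 across samples are tested (`min_total_reads` knob); the rest are
reported untested with missing p-values.

**Dispersion** is estimated jointly on all conditions. The per-transcript
method-of-moments ratio pools within-condition moments:
`sum_c (n_c-1)(s2_c - m_c) / sum_c (n_c-1)(m_c^2 - s2_c/n_c)`; the
second-order term in the denominator makes it an unbiased estimate of
`mu^2`, without which dispersions are systematically pulled down at low
counts. The trend `a0 + a1/mu` is fitted in two stages on transcripts with
base mean at least 5: ordinary least squares on 20 binned means of the raw
estimates (a stable, skew-robust start), then two passes of gene-level
weighted least squares with weights `1/trend(mu)^2`, matching the
`Var(alpha-hat) ~ alpha^2` sampling law so that precisely measured
high-expression transcripts anchor `a0`. Classical robust regression is
deliberately *not* used here: with 4 residual degrees of freedom the raw
estimator is strongly right-skewed, M-estimators track its median rather
than its mean and underestimate the trend by 10-30%, which turns directly
into anticonservative tests. For the same reason the default
`shrink_weight = 1` takes the *final* dispersion from the trend alone: at
3 + 3 replicates the per-transcript estimate is nearly pure noise, and any
log-scale weight on it measurably inflates the false-positive rate. The
weight is a knob (`0 <= shrink_weight <= 1`, log-scale combination) for
designs with enough replicates to make per-transcript estimates
informative, and raw estimates are always reported for diagnostics.

**Wald tests** fit, per transcript and contrast, an NB GLM with log link,
intercept plus condition indicator, log size factors as offsets and fixed
dispersion, by vectorized Fisher scoring (at most 100 iterations, stopping
when coefficients move less than 1e-8; linear predictors are clipped at
+-30, coefficients at +-50). The reported `log2fc` is the maximum-likelihood
estimate, its standard error comes from the Fisher information, and the
p-value is two-sided normal — a large-sample reference, with no
small-sample t correction. Transcripts whose likelihood is flat (all-zero
in the contrast, or a group entirely at zero driving the estimate to the
boundary) are flagged non-converged and reported missing rather than
silently dropped. The test suite checks the fitter against a brute-force
profile-likelihood grid (0.001 log2-unit spacing) on a simulated panel.

**FDR**: Benjamini-Hochberg within each contrast, with `m` the number of
transcripts actually tested there. A *gene* is DE when at least one of its
transcripts passes the FDR threshold; direction is reported both per
significant transcript (a gene with disagreeing transcripts appears once
per direction, flagged) and from its most significant transcript, since
either convention is defensible. **Calibration** is summarized by uniform
QQ coordinates and a Kolmogorov-Smirnov distance (`qq_calibration()`).

```{r de}
sim <- simulate_experiment(sim_config(n_genes = 2000, seed = 1), depths = 5e6)
fit <- de_test(sim$counts, sim$design, sim$annotation)
glance(fit)
```

## Normalization and clustering chain

For sample-level structure (heatmaps, dendrograms) expression goes through
four audited stages — each function checks its input's stage tag, so the
chain cannot be applied out of order:

1. **FPKM**: `count * 1e9 / (length_bp * total_reads_in_sample)`.
2. **Covariate regression**: per sample, OLS of `log2(FPKM + 0.5)` on
   `[1, GC, log10 L, GC * log10 L]`; residuals carried forward. The 0.5
   pseudo-count and the log10 length scale are our choices (raw bp would
   hand the fit to a few 20 kb transcripts); both are knobs.
3. **Quantile normalization** across samples (each sample's values
   replaced by the mean order statistics; ties get the mean of the spanned
   reference values). "Normalizing within each sample" is read as the
   classic across-sample procedure applied to every sample's residual
   vector — the only reading that makes samples comparable.
4. **Trimmed-mean centering**: per transcript and individual, subtract the
   10% trimmed mean (`mean(x, trim = 0.1)` semantics: drop
   `floor(0.1 n)` values per tail) across that individual's samples,
   removing individual-level baselines so samples group by treatment
   response. Individuals with fewer than 3 samples fall back to the plain
   mean, with a warning.

Clustering is agglomerative on `1 - Pearson correlation` with average
linkage (neither is canonical; both are knobs), zero-variance samples are
excluded with a warning, and dendrograms export as Newick.

## Downsampling evaluation

`thin_counts()` replaces each count by a Binomial(count, ratio) draw — the
exact count-level distribution of keeping each read independently, so no
alignment files are needed. Thinning composes (`r1` then `r2` equals
`r1*r2` in distribution) and `ratio = 1` is the bit-identical identity.
`downsample_report()` maps each ratio to its multiplexing equivalent
(`96/ratio` by default) and reports, against a reference (deep) run, the
Spearman correlation of fold changes over all transcripts tested in both
(not only significant ones; transcripts failing the filter or
non-estimable in either run are excluded) and the recovered fraction of
the reference DE set. `depth_response_curve()` traces DE-gene count
against depth; `rank_correlation()` supplies the generic Spearman-with-p
statistic (exact permutation p for n <= 10 without ties) used, e.g., to
relate DE-gene counts to viability readouts.

## Problem sizes, determinism, degenerate inputs

The simulation surrogates in the test suite use 10,000 transcripts with
3 + 3 replicates for the shallow (5 M) versus deep (75 M) concordance and
downsampling checks, 50 replicate null screens of 5,000 transcripts for
calibration, and 96-library pools for depth equalization; smaller panels
(200-2,000 transcripts) back the oracle comparisons. These sizes give
stable Monte-Carlo estimates at interactive runtimes and are stated here
as the package's chosen benchmark conditions.

All randomness flows from one config seed through fixed per-operation
offsets, so any stage can be re-run independently and the whole pipeline
is bit-reproducible; `thin_counts()` and `allocate_reads()` accept their
own seeds for replicate draws. Degenerate inputs fail loudly and
specifically: zero-volume or unquantifiable libraries name the library;
all-satisfied pool plans return an explicit nothing-to-pool result rather
than dividing by zero; zero-total samples name the sample in `fpkm()`;
rank-deficient covariate designs drop the collinear column with a warning;
empty DE references make recovery `NA`, not 0.

## Limitations

* The generator's dispersions sit exactly on the `a0 + a1/mu` trend;
  real data scatter around it, so the trend-only default should be
  revisited (raise `shrink_weight` toward the raw estimates) when designs
  have many replicates.
* Normal-reference Wald p-values are only asymptotically exact; at 3 + 3
  they pass uniformity checks under the simulated conditions, but heavy
  dispersion outliers in real data could change that.
* Simulated library effects are i.i.d. across transcripts; real libraries
  show correlated, batch-structured distortions the generator does not
  emulate, so passing simulation checks bounds statistical, not technical,
  reproducibility.
* No read-level artifacts (mapping bias, duplicates), no isoform or
  allele-specific quantification, and no wet-lab quantification modeling:
  the digital concentration is the only library quantification
  implemented.
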