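test_that("size factors match the median-of-ratios closed form", {
  m <- matrix(c(10, 20, 40, 100,
                10, 20, 40, 100), ncol = 2,
              dimnames = list(sprintf("T%d", 1:4), c("A", "B")))
  expect_equal(unname(size_factors(counts_from_matrix(m))), c(1, 1))
  m2 <- m; m2[, 2] <- 2 * m2[, 1]
  sf <- size_factors(counts_from_matrix(m2))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(exp(mean(log(sf))), 1)
  # permutation invariance
  perm <- m2[c(3, 1, 4, 2), ]
  expect_equal(size_factors(counts_from_matrix(perm)), sf)
})

test_that("coverage filter is a strict greater-than on row totals", {
  m <- matrix(c(0, 5, 20, 21, 100), ncol = 1,
              dimnames = list(sprintf("T%d", 1:5), "A"))
  m <- cbind(m, A2 = 0)
  kept <- filter_low(counts_from_matrix(m), 20)
  expect_equal(nrow(kept), 2)           # totals 21 and 100 survive
  expect_equal(kept$transcript_id, c("T4", "T5"))
  kept0 <- filter_low(counts_from_matrix(m), 0)
  expect_equal(nrow(kept0), 4)          # only the all-zero transcript drops
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  reps <- tibble::tibble(condition = c("x", "y"), n = c(3L, 3L),
                         control = c(NA_character_, "x"))
  design <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                           condition = rep(c("x", "y"), each = 3))
  # Poisson counts (alpha = 0): final dispersion collapses to near zero
  m <- withr::with_seed(5, {
    mu <- exp(runif(2000, log(50), log(5000)))
    matrix(rpois(2000 * 6, rep(mu, 6)), nrow = 2000,
           dimnames = list(sprintf("T%04d", 1:2000), design$sample_id))
  })
  dm <- suppressWarnings(estimate_dispersions(counts_from_matrix(m), design))
  expect_lte(median(dm$final), 0.01)
  # NB with alpha = 0.2 everywhere: raw moment estimates center on 0.2
  m2 <- withr::with_seed(6, {
    mu <- exp(runif(2000, log(100), log(5000)))
    matrix(rnbinom(2000 * 6, mu = rep(mu, 6), size = 1 / 0.2), nrow = 2000,
           dimnames = list(sprintf("T%04d", 1:2000), design$sample_id))
  })
  dm2 <- estimate_dispersions(counts_from_matrix(m2), design)
  expect_gt(median(dm2$raw), 0.1)
  expect_lt(median(dm2$raw), 0.3)
  expect_gt(attr(dm2, "a0"), 0.1)
  expect_lt(attr(dm2, "a0"), 0.3)
  # zero within-condition variance clips to the floor
  m3 <- matrix(rep(c(50L, 80L), each = 3), nrow = 1,
               dimnames = list("T1", design$sample_id))
  dm3 <- estimate_dispersions(counts_from_matrix(m3), design)
  expect_equal(dm3$raw, 1e-8)
})

test_that("Wald fold changes match a brute-force NB profile-likelihood grid", {
  design <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                           condition = rep(c("ctl", "trt"), each = 3))
  sf <- setNames(rep(1, 6), design$sample_id)
  # 4x toy: exact doubling twice
  toy <- matrix(c(10, 10, 10, 40, 40, 40), nrow = 1,
                dimnames = list("T1", design$sample_id))
  res <- wald_test(counts_from_matrix(toy), design, sf,
                   c(T1 = 1e-8), c("trt", "ctl"))
  expect_equal(res$log2fc, 2, tolerance = 0.01)
  oracle <- grid_lfc(toy[1, ], c(0, 0, 0, 1, 1, 1), rep(1, 6), 1e-8)
  expect_equal(res$log2fc, oracle, tolerance = 0.0015)

  # symmetry: identical groups give zero fold change, p = 1
  same <- matrix(rep(c(15L, 30L, 22L), 2), nrow = 1,
                 dimnames = list("T1", design$sample_id))
  res_same <- wald_test(counts_from_matrix(same), design, sf,
                        c(T1 = 0.1), c("trt", "ctl"))
  expect_equal(res_same$log2fc, 0, tolerance = 1e-6)
  expect_equal(res_same$p, 1, tolerance = 1e-6)

  # antisymmetry under label swap
  m <- withr::with_seed(8, matrix(rnbinom(6, mu = c(30, 30, 30, 90, 90, 90),
                                          size = 10), nrow = 1,
                                  dimnames = list("T1", design$sample_id)))
  fwd <- wald_test(counts_from_matrix(m), design, sf, c(T1 = 0.1), c("trt", "ctl"))
  rev <- wald_test(counts_from_matrix(m), design, sf, c(T1 = 0.1), c("ctl", "trt"))
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-6)
  expect_equal(fwd$p, rev$p, tolerance = 1e-6)
})

test_that("fitter agrees with the grid oracle across a simulated panel", {
  cfg <- small_cfg(n_genes = 200, frac_de = 0.3, seed = 77)
  sim <- simulate_experiment(cfg, depths = 3e5)
  sf <- size_factors(sim$counts)
  disp <- estimate_dispersions(sim$counts, sim$design, sf)
  res <- wald_test(sim$counts, sim$design, sf, disp, c("treated", "control"))
  m <- twostepseq:::count_matrix(sim$counts)
  alpha <- setNames(disp$final, disp$transcript_id)
  ok <- which(res$converged & !is.na(res$log2fc) & abs(res$log2fc) < 5.5)
  grid <- vapply(ok, function(i) {
    grid_lfc(m[i, ], c(0, 0, 0, 1, 1, 1), unname(sf), alpha[[i]])
  }, numeric(1))
  agree <- abs(res$log2fc[ok] - grid) <= 0.01
  expect_gte(mean(agree), 0.99)
})

test_that("BH adjustment matches the step-up brute force and handles missingness", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.037), 0.037)
  withr::with_seed(13, {
    for (i in 1:10) {
      p <- runif(50)^sample(1:3, 1)
      p[sample(50, 5)] <- NA
      expect_equal(bh_adjust(p), bh_brute(p))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("gene-level DE calls follow the any-transcript rule with direction handling", {
  expect_equal(nrow(de_genes(tibble::tibble(
    gene_id = character(), contrast = character(),
    q = numeric(), log2fc = numeric()))), 0)
  res <- tibble::tibble(
    contrast = "t vs c",
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    transcript_id = sprintf("T%d", 1:5),
    q = c(0.05, 0.5, 0.2, 0.01, 0.08),
    log2fc = c(1, -2, 3, -1, 2))
  de <- de_genes(res, fdr = 0.1)
  # g1 DE via one transcript; g2 not; g3 DE with conflicting directions
  expect_setequal(unique(de$gene_id), c("g1", "g3"))
  g3 <- de[de$gene_id == "g3", ]
  expect_setequal(g3$direction, c("up", "down"))
  expect_true(all(g3$conflicting))
  expect_equal(unique(g3$direction_top), "down")
  g1 <- de[de$gene_id == "g1", ]
  expect_equal(g1$direction, "up")
  expect_false(g1$conflicting)
})

test_that("QQ calibration sits on the diagonal for uniform input and flags pathologies", {
  m <- 200
  qq <- qq_calibration((seq_len(m) - 0.5) / m)
  expect_lt(attr(qq, "ks_stat"), 0.005)
  expect_equal(qq$observed, qq$expected, tolerance = 1e-12)
  bad <- qq_calibration(rep(1e-10, 50))
  expect_gt(attr(bad, "ks_stat"), 0.99)
  expect_lt(attr(bad, "ks_p"), 1e-6)
  expect_error(qq_calibration(runif(5)), "at least 10")
})

test_that("DE power rises with depth and shallow errors exceed deep errors", {
  cfg <- sim_config(n_genes = 1500, frac_de = 0.1, effect_sd = 1,
                    disp_a0 = 0.05, disp_a1 = 2, seed = 3)
  design <- sim_design(cfg)
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  rates <- simulate_library_rates(cfg, truth, ann, design)
  depths <- c(1e6, 5e6, 25e6, 75e6) / 50   # scaled-down screen
  fits <- lapply(seq_along(depths), function(i) {
    cnt <- simulate_counts(cfg, truth, depths[i], ann, design, rates,
                           seed_offset = i)
    de_test(cnt, design, ann)
  })
  n_de <- vapply(fits, function(f) length(unique(de_genes(f)$gene_id)), numeric(1))
  expect_true(all(diff(n_de) >= 0))
  expect_gt(n_de[4], n_de[1])
  se <- vapply(fits, function(f) mean(f$results$se, na.rm = TRUE), numeric(1))
  expect_gt(se[1], se[4])
})

test_that("estimated fold changes track the truth at deep coverage", {
  cfg <- sim_config(n_genes = 2000, frac_de = 0.1, effect_sd = 1,
                    disp_a0 = 0.05, disp_a1 = 2, seed = 14)
  sim <- simulate_experiment(cfg, depths = 75e6 / 10)
  fit <- de_test(sim$counts, sim$design, sim$annotation)
  merged <- dplyr::inner_join(fit$results, sim$truth$effects,
                              by = "transcript_id")
  merged <- merged[merged$tested & !is.na(merged$log2fc), ]
  slope <- unname(coef(lm(log2fc ~ true_log2fc, merged))[2])
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})
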