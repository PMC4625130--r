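test_that("FPKM follows the count/length/depth identity", {
  m <- matrix(c(100, 900), ncol = 1, dimnames = list(c("T1", "T2"), "A"))
  m[2, 1] <- 1e7 - 100    # total 1e7
  ann <- tibble::tibble(transcript_id = c("T1", "T2"), gene_id = c("g1", "g2"),
                        length_bp = c(1000L, 5000L), gc_fraction = c(0.4, 0.6))
  f <- fpkm(counts_from_matrix(m), ann)
  expect_equal(f$A[1], 10)  # 100 * 1e9 / (1000 * 1e7)
  # all-zero transcript stays zero; doubling a sample's counts cancels
  m2 <- cbind(m, B = 2 * m[, 1])
  f2 <- fpkm(counts_from_matrix(m2), ann)
  expect_equal(f2$A, f2$B)
  zero <- matrix(c(0, 10, 0, 20), ncol = 2,
                 dimnames = list(c("T1", "T2"), c("A", "B")))
  fz <- fpkm(counts_from_matrix(zero), ann)
  expect_equal(unlist(fz[1, -1], use.names = FALSE), c(0, 0))
  allzero <- matrix(c(0, 0, 5, 5), ncol = 2,
                    dimnames = list(c("T1", "T2"), c("A", "B")))
  allzero[, 1] <- 0
  expect_error(fpkm(counts_from_matrix(allzero), ann), "A")
})

test_that("covariate regression removes exact GC trends and leaves orthogonal residuals", {
  n <- 60
  ann <- withr::with_seed(31, tibble::tibble(
    transcript_id = sprintf("T%03d", 1:n), gene_id = sprintf("g%03d", 1:n),
    length_bp = as.integer(round(exp(runif(n, log(300), log(8000))))),
    gc_fraction = runif(n, 0.25, 0.75)))
  # construct an fpkm-stage matrix with expression exactly 3 + 2*GC on log2 scale
  target <- 2^(3 + 2 * ann$gc_fraction) - 0.5
  expr <- counts_from_matrix(matrix(target, ncol = 2, nrow = n,
                                    dimnames = list(ann$transcript_id, c("A", "B"))))
  expr <- twostepseq:::set_stage(expr, "fpkm")
  res <- regress_out_covariates(expr, ann)
  expect_true(all(abs(res$A) < 1e-10))
  # orthogonality on noisy data
  noisy <- counts_from_matrix(matrix(2^(rnorm(2 * n, 5, 1)), nrow = n,
                                     dimnames = list(ann$transcript_id, c("A", "B"))))
  noisy <- twostepseq:::set_stage(noisy, "fpkm")
  r <- twostepseq:::expr_matrix(regress_out_covariates(noisy, ann))
  X <- cbind(1, ann$gc_fraction, log10(ann$length_bp),
             ann$gc_fraction * log10(ann$length_bp))
  expect_lt(max(abs(crossprod(X, r))), 1e-8)
  # stage order is enforced
  expect_error(quantile_normalize(expr), "stage")
})

test_that("quantile normalization equalizes sample distributions", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2,
              dimnames = list(c("T1", "T2", "T3"), c("A", "B")))
  expr <- twostepseq:::set_stage(counts_from_matrix(m), "residual")
  qn <- quantile_normalize(expr)
  expect_equal(qn$A, c(2.5, 3.5, 4.5))
  expect_equal(qn$B, c(2.5, 3.5, 4.5))
  # identical samples are a fixed point
  m2 <- matrix(rep(c(5, 1, 9), 2), ncol = 2,
               dimnames = list(c("T1", "T2", "T3"), c("A", "B")))
  expr2 <- twostepseq:::set_stage(counts_from_matrix(m2), "residual")
  qn2 <- quantile_normalize(expr2)
  expect_equal(qn2$A, m2[, 1], ignore_attr = TRUE)
  # defining property on random data: sorted columns identical
  m3 <- withr::with_seed(32, matrix(rnorm(400), ncol = 4,
                                    dimnames = list(sprintf("T%03d", 1:100),
                                                    sprintf("s%d", 1:4))))
  qn3 <- twostepseq:::expr_matrix(
    quantile_normalize(twostepseq:::set_stage(counts_from_matrix(m3), "residual")))
  sorted <- apply(qn3, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
})

test_that("trimmed-mean centering matches direct arithmetic", {
  # one transcript, one individual with 10 samples valued 1..10:
  # the 10% trimmed mean is 5.5 (mean of 2..9)
  m <- matrix(1:10, nrow = 1, dimnames = list("T1", sprintf("s%d", 1:10)))
  samples <- tibble::tibble(sample_id = sprintf("s%d", 1:10), individual = "I1")
  expr <- twostepseq:::set_stage(counts_from_matrix(m), "quantile")
  ctr <- trimmed_center(expr, samples, trim = 0.1)
  expect_equal(unlist(ctr[1, -1], use.names = FALSE), 1:10 - 5.5)
  expect_equal(mean(2:9), 5.5)
  # constant transcript centers to zero; trim = 0 is plain mean centering
  m2 <- matrix(rep(7, 10), nrow = 1, dimnames = dimnames(m))
  expr2 <- twostepseq:::set_stage(counts_from_matrix(m2), "quantile")
  expect_true(all(unlist(trimmed_center(expr2, samples, 0.1)[1, -1]) == 0))
  ctr0 <- trimmed_center(expr, samples, trim = 0)
  expect_equal(unlist(ctr0[1, -1], use.names = FALSE), 1:10 - 5.5)
  # centering is per individual
  samples2 <- tibble::tibble(sample_id = sprintf("s%d", 1:10),
                             individual = rep(c("I1", "I2"), each = 5))
  ctr2 <- suppressWarnings(trimmed_center(expr, samples2, trim = 0))
  expect_equal(unlist(ctr2[1, -1], use.names = FALSE),
               c(1:5 - 3, 6:10 - 8))
  expect_warning(trimmed_center(twostepseq:::set_stage(counts_from_matrix(
    m[, 1:2, drop = FALSE]), "quantile"),
    samples[1:2, ], trim = 0.1), "plain mean")
})

test_that("clustering groups identical samples first and recovers planted structure", {
  m <- withr::with_seed(41, matrix(rnorm(300), ncol = 3,
                                   dimnames = list(sprintf("T%03d", 1:100),
                                                   c("A", "B", "C"))))
  m[, 2] <- m[, 1]
  cl <- correlate_and_cluster(twostepseq:::set_stage(counts_from_matrix(m), "centered"))
  expect_equal(unname(diag(cl$correlation)), rep(1, 3))
  expect_true(isSymmetric(cl$correlation))
  first <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-first], c("A", "B"))
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)

  # planted treatments: replicates co-cluster (adjusted Rand index vs truth)
  skip_if_not_installed("mclust")
  groups <- tibble::tibble(
    condition = c("ctl", "t1", "t2", "t3", "t4"),
    n = rep(3L, 5),
    control = c(NA, rep("ctl", 4)))
  cfg <- sim_config(n_genes = 800, frac_de = 0.25, effect_sd = 2,
                    eff_log_sd = 0, groups = groups, seed = 55)
  sim <- simulate_experiment(cfg, depths = 2e6)
  centered <- normalize_expression(sim$counts, sim$annotation, sim$design,
                                   trim = 0.1)
  cl2 <- correlate_and_cluster(centered)
  k <- length(unique(sim$design$condition))
  cut <- stats::cutree(cl2$hclust, k = k)
  truth_lab <- sim$design$condition[match(names(cut), sim$design$sample_id)]
  ari <- mclust::adjustedRandIndex(cut, truth_lab)
  expect_gte(ari, 0.9)
})

test_that("GC bias is gone from residuals on biased simulations", {
  cfg <- sim_config(n_genes = 1000, frac_de = 0, gc_beta = 4, len_beta = 0.3,
                    gclen_beta = 0, eff_log_sd = 0, seed = 66)
  sim <- simulate_experiment(cfg, depths = 2e6)
  f <- fpkm(sim$counts, sim$annotation)
  lf <- log2(twostepseq:::expr_matrix(f) + 0.5)
  cor_before <- abs(cor(lf[, 1], sim$annotation$gc_fraction))
  res <- regress_out_covariates(f, sim$annotation)
  rm <- twostepseq:::expr_matrix(res)
  cor_after <- abs(cor(rm[, 1], sim$annotation$gc_fraction))
  expect_gt(cor_before, 0.3)
  expect_lt(cor_after, 0.05)
})

test_that("dendrograms export as Newick and cluster results summarize", {
  m <- withr::with_seed(43, matrix(rnorm(400), ncol = 4,
                                   dimnames = list(sprintf("T%03d", 1:100),
                                                   sprintf("s%d", 1:4))))
  cl <- correlate_and_cluster(twostepseq:::set_stage(counts_from_matrix(m), "centered"))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, sprintf("s%d", 1:4))
  td <- tidy(cl)
  expect_equal(nrow(td), choose(4, 2))
  expect_equal(glance(cl)$n_samples, 4)
})
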