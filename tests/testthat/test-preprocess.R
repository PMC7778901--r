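test_that("gene filters remove short and never-expressed genes only", {
  counts <- compendium(matrix(c(500, 500,
                                500, 500,
                                500, 500), 3, 2, byrow = TRUE,
                              dimnames = list(c("g1", "g2", "g3"),
                                              c("s1", "s2"))),
                       stage = "raw_counts")
  ann <- tiny_annotation(lengths = c(500, 500, 500))
  res <- filter_genes(counts, ann)
  expect_identical(rownames(res$compendium), c("g1", "g2", "g3"))
  expect_length(res$qc$genes_removed_short, 0L)
  expect_length(res$qc$genes_removed_low_fpm, 0L)

  # removal is by max FPM across samples: expressed-anywhere genes survive
  counts2 <- compendium(matrix(c(1, 5000,
                                 9, 9,
                                 1e6 - 10, 1e6 - 5009), 3, 2, byrow = TRUE,
                               dimnames = list(c("g1", "g2", "g3"),
                                               c("s1", "s2"))),
                        stage = "raw_counts")
  res2 <- filter_genes(counts2, ann)
  expect_identical(rownames(res2$compendium), c("g1", "g3"))
  expect_identical(res2$qc$genes_removed_low_fpm, "g2")
})

test_that("missing gene lengths raise an annotation error", {
  ann <- tiny_annotation()[1:2, ]
  expect_error(filter_genes(tiny_counts(), ann), "g3")
})

test_that("TPM matches the hand formula and columns sum to one million", {
  counts <- compendium(matrix(c(10, 10), 2, 1,
                              dimnames = list(c("g1", "g2"), "s1")),
                       stage = "raw_counts")
  ann <- data.frame(gene_id = c("g1", "g2"), length_nt = c(1000, 2000))
  tpm <- compute_tpm(counts, ann)
  # rate 0.01 vs 0.005 -> 2/3 and 1/3 of a million
  expect_equal(unclass(tpm)[, 1], c(g1 = 2e6 / 3, g2 = 1e6 / 3),
               tolerance = 1e-12)

  set.seed(21)
  big <- compendium(matrix(rpois(400, 50) + 1, 50, 8,
                           dimnames = list(sprintf("g%02d", 1:50),
                                           sprintf("s%d", 1:8))),
                    stage = "raw_counts")
  ann2 <- data.frame(gene_id = rownames(big),
                     length_nt = sample(200:2000, 50))
  tpm2 <- compute_tpm(big, ann2)
  expect_equal(unname(colSums(unclass(tpm2))), rep(1e6, 8),
               tolerance = 1e-6)

  zero <- compendium(matrix(c(0, 0, 5, 5), 2, 2,
                            dimnames = list(c("g1", "g2"), c("s1", "s2"))),
                     stage = "raw_counts")
  expect_error(compute_tpm(zero, ann), "degenerate.*s1")
})

test_that("log transform is log2(TPM + 1) and stage-guarded", {
  tpm <- compendium(matrix(c(0, 1, 3), 3, 1,
                           dimnames = list(c("g1", "g2", "g3"), "s1")),
                    stage = "tpm")
  lt <- log_transform(tpm)
  expect_equal(unname(unclass(lt)[, 1]), c(0, 1, 2))
  expect_identical(comp_stage(lt), "log_tpm")
  expect_error(log_transform(lt), "requires stage tpm")
})

test_that("replicate filter keeps identical replicates and applies the
           iterative rule in larger groups", {
  set.seed(31)
  base <- rnorm(100, 6, 1)
  vals <- cbind(r1 = base, r2 = base,
                r3 = base + rnorm(100, 0, 0.05),
                lone = rnorm(100, 6, 1))
  rownames(vals) <- sprintf("g%03d", 1:100)
  comp <- compendium(abs(vals), stage = "log_tpm")
  meta <- make_metadata(colnames(vals), c("c1", "c1", "c1", "c2"))
  res <- filter_replicates(comp, meta)
  expect_identical(colnames(res$compendium), colnames(vals))

  # one bad replicate out of three: oracle = exhaustive rule on the R2 matrix
  vals2 <- cbind(a = base, b = base + rnorm(100, 0, 0.05),
                 c = rnorm(100, 6, 1))
  r2m <- cor(vals2)^2
  oracle_removed <- colnames(vals2)[which.min((rowSums(r2m) - 1) / 2)]
  expect_identical(oracle_removed, "c")
  expect_true(all(r2m[c("a", "b"), "c"] < 0.9))
  comp2 <- compendium(abs(vals2), stage = "log_tpm",
                      gene_ids = rownames(vals))
  meta2 <- make_metadata(colnames(vals2), rep("c1", 3))
  res2 <- filter_replicates(comp2, meta2)
  expect_identical(res2$qc$samples_removed, "c")
  expect_identical(colnames(res2$compendium), c("a", "b"))
})

test_that("centering subtracts the reference mean and is idempotent", {
  vals <- matrix(c(5, 7, 9,
                   2, 2, 8), 2, 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("ref1", "ref2", "s3")))
  comp <- compendium(vals, stage = "log_tpm")
  meta <- make_metadata(colnames(vals), c("ref", "ref", "other"))
  cen <- center_on_reference(comp, meta)
  expect_equal(unclass(cen)["g1", ], c(ref1 = -1, ref2 = 1, s3 = 3))
  expect_equal(unclass(cen)["g2", ], c(ref1 = 0, ref2 = 0, s3 = 6))
  expect_equal(unname(rowMeans(unclass(cen)[, c("ref1", "ref2")])), c(0, 0))
  cen2 <- center_on_reference(cen, meta)
  expect_equal(unclass(cen2), unclass(cen))

  meta$is_reference <- FALSE
  expect_error(center_on_reference(comp, meta), "no reference")
})

test_that("single reference sample centers to an all-zero column", {
  vals <- matrix(rnorm(20), 5, 4,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  comp <- compendium(vals, stage = "centered")
  meta <- make_metadata(colnames(vals), c("ref", "a", "b", "c"))
  cen <- center_on_reference(comp, meta)
  expect_equal(unname(unclass(cen)[, "s1"]), rep(0, 5))
})

test_that("dimensionality recovers exact rank and equal-eigenvalue cases", {
  set.seed(41)
  u <- matrix(rnorm(60), 30, 2)
  v <- matrix(rnorm(16), 2, 8)
  comp <- compendium(u %*% v, gene_ids = paste0("g", 1:30),
                     sample_ids = paste0("s", 1:8), stage = "centered")
  est <- estimate_dimensionality(comp)
  expect_identical(est$d, 2L)
  expect_true(all(diff(est$cumulative_variance_curve) >= -1e-12))
  expect_equal(est$cumulative_variance_curve[length(
    est$cumulative_variance_curve)], 1, tolerance = 1e-9)

  eye <- compendium(diag(10), gene_ids = paste0("g", 1:10),
                    sample_ids = paste0("s", 1:10), stage = "centered")
  expect_identical(estimate_dimensionality(eye)$d, 10L)

  # planted modules dominate the eigen-spectrum: SVD oracle
  gen <- generate_compendium(planted_scenario(noise_sigma = 0.01,
                                              replicate_noise_sigma = 0,
                                              seed = 3))
  sv <- svd(unclass(gen$compendium))$d
  signal_frac <- sum(sv[1:5]^2) / sum(sv^2)
  est2 <- estimate_dimensionality(gen$compendium,
                                  variance_threshold = signal_frac - 0.001)
  expect_identical(est2$d, 5L)

  zero <- compendium(matrix(0, 3, 3, dimnames = list(paste0("g", 1:3),
                                                     paste0("s", 1:3))),
                     stage = "centered")
  expect_error(estimate_dimensionality(zero), "zero-variance")
})

test_that("the preprocessing chain enforces its stage order", {
  gen <- generate_compendium(planted_scenario(n_genes = 60, n_samples = 12,
                                              n_modules = 2,
                                              support_size = 8, seed = 9),
                             mode = "counts")
  expect_error(log_transform(gen$compendium), "requires stage tpm")
  expect_error(compute_tpm(log_transform(compute_tpm(gen$compendium,
                                                     gen$annotation))),
               "requires stage raw_counts")
  pre <- preprocess(gen$compendium, gen$metadata, gen$annotation)
  expect_identical(comp_stage(pre$centered), "centered")
  expect_true(pre$dimensionality$d >= 2)
})
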