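# Frozen oracle values: the same vectors evaluated with an independent
# omnibus-normality implementation (scipy.stats.normaltest).
test_that("the K-squared statistic matches the frozen external oracle", {
  set.seed(7)
  x1 <- rnorm(50)
  expect_equal(k2_statistic(x1), 2.553063989389, tolerance = 1e-10)
  x2 <- c(seq(0.1, 2, length.out = 30), 8, 9, 10)
  expect_equal(k2_statistic(x2), 35.588755331377, tolerance = 1e-10)
  x3 <- (1:25)^2
  expect_equal(k2_statistic(x3), 3.178442897031, tolerance = 1e-10)
  expect_error(k2_statistic(rnorm(19)), "at least 20")
})

test_that("a normal weight vector yields a memberless component", {
  set.seed(71)
  w <- rnorm(1000)
  names(w) <- sprintf("g%04d", seq_along(w))
  res <- threshold_component(w, cutoff = 50)
  expect_true(res$imodulon$memberless)
  expect_equal(nrow(res$imodulon$member_genes), 0L)
  expect_lt(res$trace$k2_sequence[1], 50)
})

test_that("planted heavy-tail genes are recovered exactly", {
  set.seed(72)
  w <- rnorm(1000, 0, 0.01)
  planted <- sample(1000, 20)
  w[planted] <- sample(c(-1, 1), 20, replace = TRUE)
  names(w) <- sprintf("g%04d", seq_along(w))
  res <- threshold_component(w, cutoff = 50)
  expect_setequal(res$imodulon$member_genes$gene_id,
                  sprintf("g%04d", planted))
  # removal order hits every planted gene before the statistic drops
  expect_setequal(res$trace$removal_order, sprintf("g%04d", planted))
  # the trace stays above the cutoff until the final step, and removing the
  # heavy tail brings the statistic down overall
  k2 <- res$trace$k2_sequence
  expect_lt(k2[length(k2)], 50)
  expect_true(all(k2[-length(k2)] >= 50))
  expect_lt(k2[length(k2)], k2[1])
})

test_that("member sets are |weight|-symmetric and threshold-consistent", {
  set.seed(73)
  w <- rnorm(500, 0, 0.05)
  w[1:12] <- 2 * sample(c(-1, 1), 12, replace = TRUE)
  names(w) <- sprintf("g%03d", seq_along(w))
  a <- threshold_component(w, cutoff = 50)$imodulon
  b <- threshold_component(-w, cutoff = 50)$imodulon
  expect_setequal(a$member_genes$gene_id, b$member_genes$gene_id)
  expect_equal(sort(a$member_genes$weight), sort(-b$member_genes$weight))
  # member set == {g : |w_g| >= threshold_abs}, exactly
  expect_setequal(a$member_genes$gene_id,
                  names(w)[abs(w) >= a$threshold_abs])
})

test_that("extract_imodulons flags pure-noise components and reports N
           consistently", {
  run <- default_truth_run()
  gen <- run$gen
  dec <- run$dec
  noise <- rnorm(nrow(dec$M))
  M2 <- cbind(dec$M, IC_noise = noise / sqrt(sum(noise^2)))
  dec2 <- as_decomposition(M2, compute_activities(gen$compendium, M2),
                           run_count = dec$run_count)
  ims <- extract_imodulons(dec2, cutoff = 50)
  memberless <- vapply(ims, `[[`, TRUE, "memberless")
  expect_identical(sum(!memberless), 5L)
  expect_true(memberless[[6]])
  # planted supports recovered (Jaccard >= 0.9 each)
  C <- abs(cor(dec2$M[, 1:5], gen$truth$M_true))
  for (j in 1:5) {
    im <- ims[[j]]
    planted <- gen$truth$supports[[which.max(C[j, ])]]
    jac <- length(intersect(im$member_genes$gene_id, planted)) /
      length(union(im$member_genes$gene_id, planted))
    expect_gte(jac, 0.9)
    expect_identical(nrow(im$member_genes), length(im$member_genes$gene_id))
  }
})

test_that("explained variance hits its limits and is monotone in the number
           of included iModulons", {
  gen <- generate_compendium(planted_scenario(noise_sigma = 0,
                                              replicate_noise_sigma = 0,
                                              seed = 5))
  X <- gen$compendium
  dec <- as_decomposition(gen$truth$M_true,
                          compute_activities(X, gen$truth$M_true))
  ims <- extract_imodulons(dec, cutoff = 50)
  expect_true(all(!vapply(ims, `[[`, TRUE, "memberless")))
  ev <- explained_variance(X, dec, ims)
  expect_equal(ev$overall, 1, tolerance = 1e-9)

  # memberless reconstruction explains nothing
  blank <- lapply(ims, function(im) {
    im$memberless <- TRUE
    im$member_genes <- im$member_genes[0, ]
    im
  })
  expect_equal(explained_variance(X, dec, blank)$overall, 0)

  # monotone nondecreasing as iModulons are added
  evs <- vapply(1:5, function(k) {
    sub <- c(ims[1:k], blank[-(1:k)])
    explained_variance(X, dec, sub)$overall
  }, 1.0)
  expect_true(all(diff(evs) >= -1e-12))
})

test_that("noisy-scenario explained variance matches the analytic variance
           budget", {
  gen <- generate_compendium(planted_scenario(seed = 1))
  dec <- as_decomposition(gen$truth$M_true,
                          compute_activities(gen$compendium,
                                             gen$truth$M_true))
  ims <- extract_imodulons(dec, cutoff = 50)
  ev <- explained_variance(gen$compendium, dec, ims)
  sig <- sum((gen$truth$M_true %*% gen$truth$A_true)^2)
  noise_var <- (0.25^2 + 0.05^2) * 300 * 40
  expect_equal(ev$overall, sig / (sig + noise_var), tolerance = 0.05)
})

test_that("the cutoff calibration sweep reports monotone member counts", {
  run <- default_truth_run()
  cal <- calibrate_cutoff(run$dec, cutoffs = c(20, 50, 200))
  expect_identical(nrow(cal), 15L)
  totals <- tapply(cal$n_members, cal$cutoff, sum)
  expect_true(all(diff(totals[order(as.numeric(names(totals)))]) <= 0))
})
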