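toy_trn <- function() {
  data.frame(
    regulator = c(rep("R1", 6), rep("R2", 6), rep("R3", 4), rep("R4", 2),
                  rep("R5", 3)),
    gene_id = c("a", "b", "c", "d", "e", "f",
                "d", "e", "f", "g", "h", "i",
                "j", "k", "l", "m",
                "a", "j",
                "x", "y", "z"),
    stringsAsFactors = FALSE)
}

test_that("regulator expressions evaluate as union / intersection / identity", {
  trn <- toy_trn()
  uni <- c(letters[1:13], "x", "y", "z")
  expect_setequal(regulon_gene_set(trn, "R1/R2", uni), letters[1:9])
  expect_setequal(regulon_gene_set(trn, "R1+R2", uni), c("d", "e", "f"))
  expect_setequal(regulon_gene_set(trn, "R1", uni), letters[1:6])
  expect_error(regulon_gene_set(trn, "R1/R2+R3", uni), "mixed")
  expect_error(regulon_gene_set(trn, "Nope", uni), "unknown regulator")
  # the universe clips regulon genes outside it
  expect_setequal(regulon_gene_set(trn, "R5", letters[1:8]), character(0))
})

test_that("precision, recall and Venn counts follow the set definitions", {
  im <- paste0("g", 1:10)
  reg <- c(paste0("g", 3:10), paste0("h", 1:8))  # 16 genes, 8 shared
  rec <- score_enrichment(im, reg, universe_size = 100)
  expect_equal(rec$precision, 0.8)
  expect_equal(rec$recall, 0.5)
  expect_equal(unname(rec$venn), c(2, 8, 8))
  expect_equal(sum(rec$venn), length(union(im, reg)))

  same <- score_enrichment(im, im, universe_size = 100)
  expect_equal(same$precision, 1)
  expect_equal(same$recall, 1)

  none <- score_enrichment(im, character(0), universe_size = 100)
  expect_true(none$empty_regulon)
  expect_equal(none$precision, 0)
  expect_true(is.na(none$recall))
})

test_that("the enrichment p-value is the exact hypergeometric tail", {
  im <- paste0("g", 1:10)
  rec <- score_enrichment(im, im, universe_size = 1000)
  expect_equal(rec$pvalue, 1 / choose(1000, 10), tolerance = 1e-12)

  # partial overlap: exact combinatorial sum over the tail
  reg <- c(paste0("g", 1:6), paste0("h", 1:4))
  rec2 <- score_enrichment(im, reg, universe_size = 50)
  oracle <- sum(vapply(6:10, function(k)
    choose(10, k) * choose(40, 10 - k), 1.0)) / choose(50, 10)
  expect_equal(rec2$pvalue, oracle, tolerance = 1e-12)
})

test_that("the regulator search agrees with exhaustive brute force", {
  trn <- toy_trn()
  uni <- c(letters[1:20], "x", "y", "z")

  # planted union of two regulons -> "/" with perfect precision and recall
  im_union <- letters[1:9]
  best <- search_best_regulator(im_union, trn, uni)
  expect_identical(best$regulator_expr, "R1/R2")
  expect_equal(best$precision, 1)
  expect_equal(best$recall, 1)
  expect_identical(brute_force_best(im_union, trn, uni), "R1/R2")

  # planted intersection of two overlapping regulons -> "+"
  im_inter <- c("d", "e", "f")
  best2 <- search_best_regulator(im_inter, trn, uni, q_cutoff = 0.05)
  expect_identical(best2$regulator_expr, "R1+R2")
  expect_equal(best2$precision, 1)
  expect_equal(best2$recall, 1)
  expect_identical(brute_force_best(im_inter, trn, uni, q_cutoff = 0.05),
                   "R1+R2")

  # every candidate the two routes score must agree
  for (im in list(c("e", "f", "g"), c("a", "j"), letters[1:6],
                  c("j", "k", "l"))) {
    pkg <- search_best_regulator(im, trn, uni, q_cutoff = 0.2)
    bf <- brute_force_best(im, trn, uni, q_cutoff = 0.2)
    expect_identical(if (is.null(pkg)) NULL else pkg$regulator_expr, bf)
  }

  # genes absent from every regulon -> no enrichment
  expect_null(search_best_regulator(c("q1", "q2", "q3"),
                                    trn, c(uni, "q1", "q2", "q3")))
})

test_that("parsed expressions respect set-size sanity bounds", {
  trn <- toy_trn()
  uni <- c(letters[1:8], "x", "y", "z")
  regs <- unique(trn$regulator)
  sizes <- vapply(regs, function(r)
    length(regulon_gene_set(trn, r, uni)), 1L)
  for (pair in combn(regs, 2, simplify = FALSE)) {
    u <- length(regulon_gene_set(trn, paste(pair, collapse = "/"), uni))
    i <- length(regulon_gene_set(trn, paste(pair, collapse = "+"), uni))
    expect_gte(u, max(sizes[pair]))
    expect_lte(i, min(sizes[pair]))
  }
})

test_that("annotation names sub-modules of one regulon with -1/-2 suffixes", {
  run <- default_truth_run()
  gen <- run$gen
  universe <- rownames(gen$truth$M_true)
  ims <- extract_imodulons(run$dec, cutoff = 50)
  trn <- generate_toy_trn(gen$truth)

  ann <- annotate_imodulons(ims, trn, universe)
  named <- vapply(ann$imodulons, `[[`, "", "name")
  expect_setequal(named, gen$truth$regulators)
  expect_equal(ann$table$N,
               vapply(ann$imodulons, function(i) nrow(i$member_genes), 1L))

  # split one planted regulon across two iModulons: suffix naming kicks in
  big <- ann$imodulons[[1]]
  reg <- big$enrichment$regulator_expr
  genes <- big$member_genes$gene_id
  half1 <- big; half1$member_genes <- big$member_genes[1:8, ]
  half2 <- big; half2$member_genes <- big$member_genes[9:15, ]
  half2$component_id <- "IC_x"
  ann2 <- annotate_imodulons(list(half1, half2), trn, universe,
                             q_cutoff = 0.05)
  names2 <- vapply(ann2$imodulons, `[[`, "", "name")
  expect_setequal(names2, paste0(reg, c("-1", "-2")))
  prec <- vapply(ann2$imodulons, function(i) i$enrichment$precision, 1.0)
  expect_equal(order(prec, decreasing = TRUE),
               order(match(names2, paste0(reg, c("-1", "-2")))))
})

test_that("unenriched iModulons keep their component id and a blank
           regulator column", {
  run <- default_truth_run()
  ims <- extract_imodulons(run$dec, cutoff = 50)
  empty_trn <- data.frame(regulator = "Rx",
                          gene_id = "not_a_gene",
                          stringsAsFactors = FALSE)
  ann <- annotate_imodulons(ims, empty_trn, rownames(run$dec$M))
  expect_identical(vapply(ann$imodulons, `[[`, "", "name"),
                   run$dec$component_ids)
  expect_true(all(ann$table$regulator == ""))
  expect_true(all(is.na(ann$table$precision)))
})
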