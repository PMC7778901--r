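# Shared fixture builders. Everything is generated in code; no files ship
# with the tests beyond what a test writes to its own tempdir.

tiny_counts <- function() {
  m <- matrix(c(10, 30,
                20, 20,
                5, 45), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  compendium(m, stage = "raw_counts")
}

tiny_annotation <- function(lengths = c(1000, 1000, 1000)) {
  data.frame(gene_id = c("g1", "g2", "g3"),
             name = c("gA", "gB", "gC"),
             product = "product",
             length_nt = lengths,
             stringsAsFactors = FALSE)
}

make_metadata <- function(sample_ids, condition_ids,
                          reference = condition_ids[1],
                          project = "proj") {
  data.frame(sample_id = sample_ids,
             condition_id = condition_ids,
             project_id = project,
             replicate_group = condition_ids,
             is_reference = condition_ids %in% reference,
             stringsAsFactors = FALSE)
}

# Integer vectors whose pairwise R^2 is exactly 9/(9 + b^2 * 1) with
# orthogonal unit blocks Sxx = Svv = 20; b = 1 gives R^2 = 0.9 exactly.
r2_boundary_pair <- function(b = 1) {
  x <- c(-3, -1, 1, 3)
  v <- c(1, -3, 3, -1)
  list(x = x + 10, y = 3 * x + b * v + 10)
}

# A run ensemble of `n_runs` runs sharing `shared` (genes x k) components,
# with `extra` (a single gene-weight vector) injected into the first
# `n_with_extra` runs and an independent random filler column elsewhere.
make_ensemble <- function(shared, extra, n_runs, n_with_extra, seed = 99) {
  set.seed(seed)
  g <- nrow(shared)
  runs <- lapply(seq_len(n_runs), function(i) {
    fill <- if (i <= n_with_extra) extra else rnorm(g)
    m <- cbind(shared, fill)
    m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
    rownames(m) <- rownames(shared)
    m
  })
  structure(list(runs = runs, seeds = seq_len(n_runs),
                 d = ncol(shared) + 1L),
            class = "run_ensemble")
}

# Sparse orthogonal gene-weight matrix: k disjoint blocks of `block` genes.
sparse_sources <- function(n_genes, k, block = 10) {
  M <- matrix(0, n_genes, k)
  for (j in seq_len(k)) M[((j - 1) * block + 1):(j * block), j] <- 1
  rownames(M) <- sprintf("g%04d", seq_len(n_genes))
  sweep(M, 2, sqrt(colSums(M^2)), "/")
}

default_truth_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generate_compendium(planted_scenario(seed = 1))
      dec <- robust_ica(gen$compendium, d = 5, n_runs = 20, base_seed = 42)
      cache <<- list(gen = gen, dec = dec)
    }
    cache
  }
})
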