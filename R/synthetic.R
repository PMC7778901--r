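#' Define a planted-module scenario
#'
#' Describes a synthetic expression compendium with known ground truth:
#' sparse gene-weight modules (disjoint supports of `support_size` genes at
#' weight `weight_magnitude`), condition-structured activities (one
#' activity vector per condition, shared by its replicates; the first
#' condition is the zero-activity reference), and Gaussian noise. The
#' default scenario is 300 genes x 40 samples (20 conditions x 2
#' replicates), 5 modules of 15 genes, unit weights, condition activities
#' N(0, 1), measurement noise sd 0.25 and replicate noise sd 0.05.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param n_modules Number of planted modules.
#' @param support_size Genes per module (supports are disjoint).
#' @param weight_magnitude Planted weight of member genes.
#' @param activity_sd Standard deviation of the per-condition activities.
#' @param noise_sigma Sd of the i.i.d. Gaussian measurement noise.
#' @param replicate_noise_sigma Sd of extra per-replicate noise.
#' @param n_replicates Replicates per condition (`n_samples` must be a
#'   multiple).
#' @param background_sd Sd of Gaussian background weights on non-member
#'   genes (0 = exactly sparse; a small value stresses the K-squared
#'   threshold).
#' @param seed RNG seed; the whole generation is reproducible given it.
#' @return A list of class `planted_scenario`.
#' @export
planted_scenario <- function(n_genes = 300, n_samples = 40, n_modules = 5,
                             support_size = 15, weight_magnitude = 1,
                             activity_sd = 1, noise_sigma = 0.25,
                             replicate_noise_sigma = 0.05, n_replicates = 2,
                             background_sd = 0, seed = 1) {
  stopifnot(n_genes > 0, n_samples > 0, n_modules > 0, support_size > 0,
            n_replicates > 0, noise_sigma >= 0, replicate_noise_sigma >= 0)
  if (n_modules * support_size > n_genes)
    stop("planted supports exceed the number of genes", call. = FALSE)
  if (n_samples %% n_replicates != 0)
    stop("n_samples must be a multiple of n_replicates", call. = FALSE)
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 n_modules = n_modules, support_size = support_size,
                 weight_magnitude = weight_magnitude,
                 activity_sd = activity_sd, noise_sigma = noise_sigma,
                 replicate_noise_sigma = replicate_noise_sigma,
                 n_replicates = n_replicates, background_sd = background_sd,
                 seed = seed),
            class = "planted_scenario")
}

#' Generate a synthetic compendium with known ground truth
#'
#' Builds `X = M_true A_true + noise` under a [planted_scenario()] and
#' returns the compendium together with sample metadata, gene annotation
#' and the planted truth for use as an oracle. With `mode = "centered"`
#' (default) X is emitted at stage `centered`, ready for ICA, with the
#' reference condition at zero activity. With `mode = "log_tpm"` a per-gene
#' baseline is added and values are clamped at zero. With `mode = "counts"`
#' the log values are inverted (`TPM` proportional to `2^x - 1`) and
#' Poisson-sampled to integer counts at a 5-million-read library with
#' per-gene lengths, exercising the count-based QC path.
#'
#' @param scenario A [planted_scenario()].
#' @param mode Output stage: `"centered"`, `"log_tpm"` or `"counts"`.
#' @return List with `compendium`, `metadata`, `annotation` and `truth`
#'   (`M_true` genes x k, `A_true` k x samples, `supports` list of member
#'   gene ids per module, `regulators` planted regulator names).
#' @export
generate_compendium <- function(scenario, mode = c("centered", "log_tpm",
                                                   "counts")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scenario, "planted_scenario"))
  sc <- scenario
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sc$seed)

  gene_ids <- sprintf("g%04d", seq_len(sc$n_genes))
  n_cond <- sc$n_samples / sc$n_replicates
  cond_ids <- sprintf("cond_%02d", seq_len(n_cond))
  sample_ids <- as.vector(t(outer(cond_ids, seq_len(sc$n_replicates),
                                  function(cc, r) paste0(cc, "_r", r))))
  cond_of <- rep(cond_ids, each = sc$n_replicates)

  picked <- sample(sc$n_genes, sc$n_modules * sc$support_size)
  supports <- split(gene_ids[picked],
                    rep(seq_len(sc$n_modules), each = sc$support_size))
  M_true <- matrix(0, sc$n_genes, sc$n_modules,
                   dimnames = list(gene_ids,
                                   paste0("module_", seq_len(sc$n_modules))))
  if (sc$background_sd > 0)
    M_true[] <- stats::rnorm(length(M_true), 0, sc$background_sd)
  for (m in seq_len(sc$n_modules))
    M_true[supports[[m]], m] <- sc$weight_magnitude

  A_cond <- matrix(stats::rnorm(sc$n_modules * n_cond, 0, sc$activity_sd),
                   sc$n_modules, n_cond,
                   dimnames = list(colnames(M_true), cond_ids))
  A_cond[, 1L] <- 0   # reference condition: baseline activity
  A_true <- A_cond[, cond_of, drop = FALSE]
  colnames(A_true) <- sample_ids

  X <- M_true %*% A_true +
    matrix(stats::rnorm(sc$n_genes * sc$n_samples, 0, sc$noise_sigma),
           sc$n_genes, sc$n_samples) +
    matrix(stats::rnorm(sc$n_genes * sc$n_samples, 0,
                        sc$replicate_noise_sigma),
           sc$n_genes, sc$n_samples)
  dimnames(X) <- list(gene_ids, sample_ids)

  lengths_nt <- sample(200:3000, sc$n_genes, replace = TRUE)
  annotation <- data.frame(
    gene_id = gene_ids,
    name = gene_ids,
    product = "synthetic gene product",
    length_nt = lengths_nt,
    cog_category = sample(LETTERS[1:8], sc$n_genes, replace = TRUE),
    operon = paste0("op", ceiling(seq_len(sc$n_genes) / 4)),
    stringsAsFactors = FALSE)
  metadata <- data.frame(
    sample_id = sample_ids,
    condition_id = cond_of,
    project_id = ifelse(match(cond_of, cond_ids) <= ceiling(n_cond / 2),
                        "project_A", "project_B"),
    replicate_group = cond_of,
    is_reference = cond_of == cond_ids[1L],
    stringsAsFactors = FALSE)

  if (mode == "centered") {
    comp <- compendium(X, stage = "centered")
  } else {
    baseline <- stats::runif(sc$n_genes, 4, 9)
    logx <- pmax(X + baseline, 0)
    if (mode == "log_tpm") {
      comp <- compendium(logx, stage = "log_tpm")
    } else {
      tpm_raw <- 2^logx - 1
      tpm <- sweep(tpm_raw, 2L, colSums(tpm_raw), "/") * 1e6
      frac <- sweep(tpm * lengths_nt, 2L,
                    colSums(tpm * lengths_nt), "/")
      counts <- matrix(stats::rpois(length(frac), frac * 5e6),
                       sc$n_genes, sc$n_samples,
                       dimnames = dimnames(X))
      comp <- compendium(counts * 1.0, stage = "raw_counts")
    }
  }
  list(compendium = comp, metadata = metadata, annotation = annotation,
       truth = list(M_true = M_true, A_true = A_true, supports = supports,
                    regulators = paste0("Reg", seq_len(sc$n_modules))))
}

#' Generate a toy literature TRN from planted truth
#'
#' Builds one regulon per planted module containing a `fidelity` fraction
#' of its support, optionally diluted with decoy genes, plus
#' `extra_regulons` regulons of random genes. This supports exact
#' set-arithmetic oracles for the enrichment search.
#'
#' @param truth The `truth` element of [generate_compendium()] output.
#' @param fidelity Fraction of each module's support included in its
#'   regulon, in (0, 1].
#' @param extra_regulons Number of random decoy regulons.
#' @param decoy_genes Decoy genes appended to each planted regulon.
#' @param universe Gene ids to draw decoys from (defaults to the genes of
#'   `M_true`).
#' @param seed RNG seed.
#' @return A TRN data frame (`regulator`, `gene_id`).
#' @export
generate_toy_trn <- function(truth, fidelity = 1, extra_regulons = 0,
                             decoy_genes = 0, universe = rownames(truth$M_true),
                             seed = 1) {
  stopifnot(fidelity > 0, fidelity <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rows <- list()
  for (m in seq_along(truth$supports)) {
    sup <- truth$supports[[m]]
    n_keep <- max(1L, round(fidelity * length(sup)))
    genes <- sup[seq_len(n_keep)]
    if (decoy_genes > 0)
      genes <- c(genes, sample(setdiff(universe, sup), decoy_genes))
    rows[[m]] <- data.frame(regulator = truth$regulators[m], gene_id = genes,
                            stringsAsFactors = FALSE)
  }
  if (extra_regulons > 0) {
    sup_size <- length(truth$supports[[1L]])
    for (e in seq_len(extra_regulons)) {
      rows[[length(rows) + 1L]] <- data.frame(
        regulator = paste0("Decoy", e),
        gene_id = sample(universe, sup_size),
        stringsAsFactors = FALSE)
    }
  }
  trn <- unique(do.call(rbind, rows))
  rownames(trn) <- NULL
  trn
}
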