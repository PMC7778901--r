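# Decimal rounding with ties away from zero (half-up), matching how the
# summary percentages are conventionally rendered.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Run the full iModulon pipeline
#'
#' Chains preprocessing, dimensionality estimation, robust ICA,
#' K-squared membership thresholding, regulon enrichment, activity
#' summaries and (optionally) the export bundle. Deterministic given the
#' seed in `config`.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{counts / log_tpm}{a `compendium` or a file path; `log_tpm`
#'       implies `microarray = TRUE` semantics (gene filters and TPM are
#'       skipped).}
#'     \item{metadata, annotation, trn}{data frames or file paths.}
#'     \item{cutoff}{K-squared membership cutoff (default 550).}
#'     \item{dims}{ICA dimensionality, or `"auto"` (default) to use the
#'       99%-variance PCA estimate.}
#'     \item{n_runs, seed, eps}{robust-ICA controls (defaults 100, 42, 0.1).}
#'     \item{min_length_nt, min_fpm, min_r2, variance_threshold}{QC
#'       thresholds (defaults 100, 10, 0.9, 0.99).}
#'     \item{out_dir}{if set, [write_bundle()] output directory.}
#'   }
#' @return A list with `log_tpm`, `centered`, `qc`, `dimensionality`,
#'   `decomposition`, `imodulons`, `imodulon_table`, `activities`,
#'   `explained_variance`, and `manifest` when a bundle was written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(cutoff = 550, dims = "auto", n_runs = 100, seed = 42, eps = 0.1,
         min_length_nt = 100, min_fpm = 10, min_r2 = 0.9,
         variance_threshold = 0.99, max_combo = 2, q_cutoff = 0.01,
         out_dir = NULL),
    config)

  load_tab <- function(x, reader) if (is.character(x)) reader(x) else x
  metadata <- load_tab(cfg$metadata, read_sample_metadata)
  if (is.null(metadata)) stop("config requires metadata", call. = FALSE)
  if (!any(metadata$is_reference))
    stop("configuration error: no reference condition flagged in metadata",
         call. = FALSE)
  annotation <- load_tab(cfg$annotation, read_gene_annotation)
  trn <- if (is.null(cfg$trn)) NULL else load_tab(cfg$trn, read_trn)

  microarray <- is.null(cfg$counts)
  input <- if (microarray) {
    load_tab(cfg$log_tpm, function(p) read_compendium(p, stage = "log_tpm"))
  } else {
    load_tab(cfg$counts, function(p) read_compendium(p, stage = "raw_counts"))
  }
  if (is.null(input))
    stop("config requires either counts or log_tpm input", call. = FALSE)

  pre <- preprocess(input, metadata, annotation, microarray = microarray,
                    min_length_nt = cfg$min_length_nt, min_fpm = cfg$min_fpm,
                    min_r2 = cfg$min_r2,
                    variance_threshold = cfg$variance_threshold)
  d <- if (identical(cfg$dims, "auto")) pre$dimensionality$d
       else as.integer(cfg$dims)

  dec <- robust_ica(pre$centered, d = d, n_runs = cfg$n_runs,
                    base_seed = cfg$seed, eps = cfg$eps)
  imodulons <- extract_imodulons(dec, cutoff = cfg$cutoff)
  universe <- rownames(pre$centered)
  if (!is.null(trn)) {
    ann <- annotate_imodulons(imodulons, trn, universe,
                              max_combo = cfg$max_combo,
                              q_cutoff = cfg$q_cutoff)
    imodulons <- ann$imodulons
  }
  tab <- imodulon_table(imodulons)
  meta_kept <- metadata[metadata$sample_id %in% colnames(pre$centered), ]
  activities <- condition_activities(dec$A, meta_kept)
  ev <- explained_variance(pre$centered, dec, imodulons)

  out <- list(log_tpm = pre$log_tpm, centered = pre$centered, qc = pre$qc,
              dimensionality = pre$dimensionality, decomposition = dec,
              imodulons = imodulons, imodulon_table = tab,
              activities = activities, explained_variance = ev)
  if (!is.null(cfg$out_dir)) {
    out$manifest <- write_bundle(pre$log_tpm, dec, imodulons, meta_kept,
                                 annotation,
                                 if (is.null(trn))
                                   data.frame(regulator = character(0),
                                              gene_id = character(0))
                                 else trn,
                                 cfg$out_dir)
  }
  out
}

#' Dataset summary table with a Total column
#'
#' Aggregates per-dataset statistics into the knowledgebase-style summary:
#' genes, samples, conditions, dimensionality, iModulon counts, the number
#' and percentage of characterized iModulons and of iModulons with mapped
#' regulators, and the explained variance. Count fields in the Total column
#' are sums; its percentages are recomputed from the summed counts (never
#' averaged), and all percentages are rounded half-up to one decimal.
#'
#' @param datasets A list of per-dataset lists, each with fields `name`,
#'   `genes`, `samples`, `conditions`, `dimensionality`, `total_imodulons`,
#'   `characterized`, `with_regulators` and optionally `explained_variance`
#'   (fraction in `[0, 1]`).
#' @return A data frame of class `dataset_summary`, one row per dataset
#'   plus a `"Total"` row; columns include `characterized_pct`,
#'   `with_regulators_pct` and `explained_variance_pct`.
#' @export
summary_table <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  row_of <- function(d) {
    ev <- if (is.null(d$explained_variance)) NA_real_ else d$explained_variance
    data.frame(
      name = d$name,
      genes = d$genes, samples = d$samples, conditions = d$conditions,
      dimensionality = d$dimensionality,
      total_imodulons = d$total_imodulons,
      characterized = d$characterized,
      characterized_pct = round_half_up(100 * d$characterized /
                                          d$total_imodulons, 1),
      with_regulators = d$with_regulators,
      with_regulators_pct = round_half_up(100 * d$with_regulators /
                                            d$total_imodulons, 1),
      explained_variance_pct = if (is.na(ev)) NA_real_
                               else round_half_up(100 * ev, 1),
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(datasets, row_of))
  tot_im <- sum(rows$total_imodulons)
  total <- data.frame(
    name = "Total",
    genes = sum(rows$genes), samples = sum(rows$samples),
    conditions = sum(rows$conditions),
    dimensionality = sum(rows$dimensionality),
    total_imodulons = tot_im,
    characterized = sum(rows$characterized),
    characterized_pct = round_half_up(100 * sum(rows$characterized) /
                                        tot_im, 1),
    with_regulators = sum(rows$with_regulators),
    with_regulators_pct = round_half_up(100 * sum(rows$with_regulators) /
                                          tot_im, 1),
    explained_variance_pct = NA_real_,
    stringsAsFactors = FALSE)
  out <- rbind(rows, total)
  rownames(out) <- NULL
  class(out) <- c("dataset_summary", "data.frame")
  out
}

#' Render a dataset summary the way the knowledgebase prints it
#'
#' Formats count-percentage pairs as `"n (p%)"` strings and explained
#' variance as an integer percentage.
#'
#' @param summary A `dataset_summary` from [summary_table()].
#' @return A character data frame.
#' @export
render_summary <- function(summary) {
  data.frame(
    name = summary$name,
    genes = as.character(summary$genes),
    samples = as.character(summary$samples),
    conditions = as.character(summary$conditions),
    dimensionality = as.character(summary$dimensionality),
    total_imodulons = as.character(summary$total_imodulons),
    characterized = sprintf("%d (%.1f%%)", summary$characterized,
                            summary$characterized_pct),
    with_regulators = sprintf("%d (%.1f%%)", summary$with_regulators,
                              summary$with_regulators_pct),
    explained_variance = ifelse(is.na(summary$explained_variance_pct), "",
                                sprintf("%.0f%%",
                                        summary$explained_variance_pct)),
    stringsAsFactors = FALSE)
}
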