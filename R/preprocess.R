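#' Remove short and lowly expressed genes
#'
#' Applies the RNA-Seq gene-level quality filters: genes shorter than
#' `min_length_nt` nucleotides, or whose expression never reaches
#' `min_fpm` fragments per million mapped reads (FPM) in any sample, are
#' removed. FPM for gene g in sample s is `1e6 * count[g,s] / sum(count[,s])`.
#' A gene is kept on the expression criterion if its maximum FPM across
#' samples is >= `min_fpm`, so condition-specific genes survive; both
#' boundaries keep the equal case (length 100 nt is kept at the default,
#' FPM exactly 10 is kept).
#'
#' @param counts A `compendium` at stage `raw_counts`.
#' @param annotation Gene annotation with `gene_id` and `length_nt`.
#' @param min_length_nt Minimum gene length in nucleotides (default 100).
#' @param min_fpm Minimum max-across-samples FPM (default 10).
#' @return A list with `compendium` (filtered counts) and `qc` (a
#'   `qc_report` listing removals by cause).
#' @export
filter_genes <- function(counts, annotation, min_length_nt = 100,
                         min_fpm = 10) {
  assert_stage(counts, "raw_counts", "filter_genes")
  len <- annotation$length_nt[match(rownames(counts), annotation$gene_id)]
  if (anyNA(len))
    stop("missing length_nt for genes: ",
         paste(utils::head(rownames(counts)[is.na(len)], 5L), collapse = ", "),
         call. = FALSE)
  vals <- unclass(counts)
  lib <- colSums(vals)
  if (any(lib <= 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "), call. = FALSE)
  fpm <- sweep(vals, 2L, lib, "/") * 1e6
  max_fpm <- apply(fpm, 1L, max)
  short <- len < min_length_nt
  low <- !short & max_fpm < min_fpm
  keep <- !short & !low
  qc <- qc_report(genes_removed_short = rownames(counts)[short],
                  genes_removed_low_fpm = rownames(counts)[low])
  list(compendium = compendium(vals[keep, , drop = FALSE], stage = "raw_counts"),
       qc = qc)
}

#' Transcripts per million
#'
#' Converts raw counts to TPM: per sample,
#' `TPM_g = 1e6 * (count_g / length_g) / sum_h(count_h / length_h)`.
#' Every column of the result sums to one million.
#'
#' @inheritParams filter_genes
#' @return A `compendium` at stage `tpm`.
#' @export
compute_tpm <- function(counts, annotation) {
  assert_stage(counts, "raw_counts", "compute_tpm")
  len <- annotation$length_nt[match(rownames(counts), annotation$gene_id)]
  if (anyNA(len) || any(len <= 0))
    stop("positive length_nt required for all genes", call. = FALSE)
  rate <- unclass(counts) / len
  denom <- colSums(rate)
  if (any(denom == 0))
    stop("degenerate sample with all-zero counts: ",
         paste(colnames(counts)[denom == 0], collapse = ", "), call. = FALSE)
  tpm <- sweep(rate, 2L, denom, "/") * 1e6
  compendium(tpm, stage = "tpm")
}

#' Log-transform TPM values
#'
#' Elementwise `log2(TPM + 1)`; monotone and zero-preserving.
#'
#' @param tpm A `compendium` at stage `tpm`.
#' @return A `compendium` at stage `log_tpm`.
#' @export
log_transform <- function(tpm) {
  assert_stage(tpm, "tpm", "log_transform")
  if (any(tpm < 0)) stop("negative TPM values", call. = FALSE)
  compendium(log2(unclass(tpm) + 1), stage = "log_tpm")
}

# R^2 between two expression profiles: squared Pearson correlation computed
# as Sxy^2 / (Sxx * Syy) so exact-rational inputs evaluate without extra
# rounding at the 0.9 boundary.
r_squared <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc * xc)
  syy <- sum(yc * yc)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sum(xc * yc)^2 / (sxx * syy)
}

#' Remove discordant biological replicates
#'
#' Within each replicate group, pairwise R-squared (squared Pearson
#' correlation over genes) is computed on the final expression values.
#' Samples are removed when replicates disagree with R-squared below
#' `min_r2` (strictly; a pair at exactly 0.9 is kept). In groups larger
#' than two, the sample with the lowest mean R-squared to the rest of its
#' group is removed iteratively until all remaining pairs pass; the last
#' sample of a group is never removed.
#'
#' @param log_tpm A `compendium` at stage `log_tpm` (or `centered` for
#'   pre-normalized microarray intensities).
#' @param metadata Sample metadata with `replicate_group`.
#' @param min_r2 Retention threshold on pairwise R-squared (default 0.9).
#' @return A list with `compendium` (passing samples) and `qc`.
#' @export
filter_replicates <- function(log_tpm, metadata, min_r2 = 0.9) {
  assert_stage(log_tpm, c("log_tpm", "centered"), "filter_replicates")
  validate_metadata(metadata, log_tpm)
  vals <- unclass(log_tpm)
  groups <- split(metadata$sample_id[metadata$sample_id %in% colnames(vals)],
                  metadata$replicate_group[metadata$sample_id %in%
                                           colnames(vals)])
  removed <- character(0)
  r2_by_group <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) < 2L) next
    r2m <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_along(ids)[-1L]) for (j in seq_len(i - 1L)) {
      r2 <- r_squared(vals[, ids[i]], vals[, ids[j]])
      r2m[i, j] <- r2m[j, i] <- if (is.na(r2)) 0 else r2
    }
    r2_by_group[[g]] <- r2m[lower.tri(r2m)]
    keep <- ids
    while (length(keep) > 1L) {
      sub <- r2m[keep, keep, drop = FALSE]
      off <- sub[lower.tri(sub)]
      if (all(off >= min_r2)) break
      mean_r2 <- (rowSums(sub) - 1) / (length(keep) - 1L)
      worst <- keep[which.min(mean_r2)]
      removed <- c(removed, worst)
      keep <- setdiff(keep, worst)
    }
  }
  keep_samples <- setdiff(colnames(vals), removed)
  qc <- qc_report(replicate_r2 = r2_by_group, samples_removed = removed)
  list(compendium = compendium(vals[, keep_samples, drop = FALSE],
                               stage = comp_stage(log_tpm)),
       qc = qc)
}

#' Center expression on a reference condition
#'
#' Subtracts, per gene, the mean expression over the reference samples
#' (those flagged `is_reference` in the metadata) from every sample.
#' Downstream component activities are then relative to that baseline, and
#' the reference columns average to zero for every gene. Centering is
#' idempotent.
#'
#' @param log_tpm A `compendium` at stage `log_tpm` or `centered`.
#' @param metadata Sample metadata with logical `is_reference`.
#' @return A `compendium` at stage `centered`.
#' @export
center_on_reference <- function(log_tpm, metadata) {
  assert_stage(log_tpm, c("log_tpm", "centered"), "center_on_reference")
  validate_metadata(metadata, log_tpm)
  ref <- metadata$sample_id[metadata$is_reference]
  ref <- intersect(ref, colnames(log_tpm))
  if (length(ref) == 0L)
    stop("no reference samples flagged in metadata", call. = FALSE)
  vals <- unclass(log_tpm)
  baseline <- rowMeans(vals[, ref, drop = FALSE])
  compendium(vals - baseline, stage = "centered")
}

#' Estimate the ICA dimensionality by PCA
#'
#' The dimensionality is the number of orthogonal principal components
#' needed to explain `variance_threshold` (default 99%) of the variance of
#' the centered matrix; eigenvalues come from the singular value
#' decomposition of the matrix.
#'
#' @param centered A `compendium` at stage `centered`.
#' @param variance_threshold Fraction of variance to explain, in (0, 1].
#' @return A list of class `dimensionality_estimate` with `d`,
#'   `variance_threshold` and the `cumulative_variance_curve`.
#' @export
estimate_dimensionality <- function(centered, variance_threshold = 0.99) {
  assert_stage(centered, "centered", "estimate_dimensionality")
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  sv <- svd(unclass(centered), nu = 0, nv = 0)$d
  tot <- sum(sv^2)
  if (tot == 0) stop("zero-variance matrix", call. = FALSE)
  curve <- cumsum(sv^2) / tot
  d <- which(curve >= variance_threshold - 1e-12)[1L]
  structure(list(d = as.integer(d),
                 variance_threshold = variance_threshold,
                 cumulative_variance_curve = curve),
            class = "dimensionality_estimate")
}

qc_report <- function(...) {
  fields <- list(genes_removed_short = character(0),
                 genes_removed_low_fpm = character(0),
                 replicate_r2 = list(),
                 samples_removed = character(0),
                 reference_condition = NA_character_,
                 fpm_rule = "max across samples")
  args <- list(...)
  fields[names(args)] <- args
  structure(fields, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n",
      " genes removed (short):  ", length(x$genes_removed_short), "\n",
      " genes removed (low FPM):", length(x$genes_removed_low_fpm), "\n",
      " samples removed (R2):   ", length(x$samples_removed), "\n", sep = "")
  invisible(x)
}

merge_qc <- function(a, b) {
  out <- a
  for (f in names(b)) {
    v <- b[[f]]
    if (is.character(v) && length(v) && !all(v %in% out[[f]]))
      out[[f]] <- c(out[[f]], v)
    else if (is.list(v) && length(v)) out[[f]] <- c(out[[f]], v)
    else if (is.character(v) && length(v)) out[[f]] <- v
  }
  out
}

#' Run the full normalization chain
#'
#' Convenience wrapper enforcing the fixed preprocessing order:
#' gene filters, TPM, log2(TPM+1), replicate R-squared filter, reference
#' centering. For microarray intensities (`microarray = TRUE`) the input
#' is taken as log-scale expression and the count-based steps are skipped.
#'
#' @param counts A `compendium`: stage `raw_counts`, or `log_tpm` when
#'   `microarray = TRUE`.
#' @param metadata,annotation Input tables.
#' @param microarray Skip gene filters and TPM (pre-normalized input).
#' @param min_length_nt,min_fpm,min_r2 Filter thresholds.
#' @param variance_threshold Passed to [estimate_dimensionality()].
#' @return List with `log_tpm`, `centered`, `qc`, `dimensionality`.
#' @export
preprocess <- function(counts, metadata, annotation, microarray = FALSE,
                       min_length_nt = 100, min_fpm = 10, min_r2 = 0.9,
                       variance_threshold = 0.99) {
  if (microarray) {
    log_tpm <- counts
    assert_stage(log_tpm, "log_tpm", "preprocess")
    qc <- qc_report()
  } else {
    fg <- filter_genes(counts, annotation, min_length_nt, min_fpm)
    qc <- fg$qc
    log_tpm <- log_transform(compute_tpm(fg$compendium, annotation))
  }
  fr <- filter_replicates(log_tpm, metadata, min_r2)
  qc <- merge_qc(qc, fr$qc)
  centered <- center_on_reference(fr$compendium, metadata)
  ref_cond <- unique(metadata$condition_id[metadata$is_reference])
  qc$reference_condition <- paste(ref_cond, collapse = ",")
  dim_est <- estimate_dimensionality(centered, variance_threshold)
  list(log_tpm = fr$compendium, centered = centered, qc = qc,
       dimensionality = dim_est)
}
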