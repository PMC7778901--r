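#' Construct an expression compendium
#'
#' An expression compendium is a genes-by-samples numeric matrix together
#' with a processing-stage tag. The stage records where the matrix sits in
#' the normalization chain: raw sequencing counts, transcripts per million
#' (TPM), log2(TPM + 1), or log values centered on a reference condition.
#'
#' @param values Numeric matrix, rows = genes, columns = samples.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   the matrix rownames).
#' @param sample_ids Character vector of unique sample identifiers (defaults
#'   to the matrix colnames).
#' @param stage One of `"raw_counts"`, `"tpm"`, `"log_tpm"`, `"centered"`.
#' @return An object of class `compendium`: the matrix with dimnames set and
#'   a `stage` attribute.
#' @export
compendium <- function(values, gene_ids = rownames(values),
                       sample_ids = colnames(values),
                       stage = c("raw_counts", "tpm", "log_tpm", "centered")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) != number of rows", call. = FALSE)
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != number of columns", call. = FALSE)
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (stage %in% c("log_tpm", "centered") && any(!is.finite(values)))
    stop("non-finite values are not allowed at stage ", stage, call. = FALSE)
  if (stage == "log_tpm" && any(values < 0))
    stop("log_tpm values must be >= 0", call. = FALSE)
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, stage = stage, class = c("compendium", "matrix", "array"))
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("<compendium> %d genes x %d samples, stage = %s\n",
              nrow(x), ncol(x), comp_stage(x)))
  invisible(x)
}

#' Processing stage of a compendium
#' @param x A `compendium`.
#' @return The stage string.
#' @export
comp_stage <- function(x) attr(x, "stage")

assert_stage <- function(x, stage, op) {
  if (!inherits(x, "compendium"))
    stop(op, " expects a compendium object", call. = FALSE)
  if (!comp_stage(x) %in% stage)
    stop(op, " requires stage ", paste(stage, collapse = "/"),
         ", got ", comp_stage(x), call. = FALSE)
  invisible(x)
}

# keep class/stage when subsetting by index
reclass_compendium <- function(values, stage) {
  compendium(values, stage = stage)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read an expression matrix from TSV/CSV
#'
#' The first column must hold gene identifiers; remaining columns are
#' samples. The delimiter is auto-detected (tab, then comma) unless given.
#'
#' @param path Path to a delimited text file.
#' @param stage Processing stage to tag the result with.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @return A [compendium()].
#' @export
read_compendium <- function(path, stage = "raw_counts", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 2L)
    stop("expression table needs a gene-id column plus >=1 sample", call. = FALSE)
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  num <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(col), numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L,
                                    dimnames = list(NULL, names(df)[-1L]))
  bad <- which(is.na(num) & !is.na(df[-1L]), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]), call. = FALSE)
  }
  if (anyNA(num))
    stop("missing values in expression table ", path, call. = FALSE)
  compendium(num, gene_ids = ids, sample_ids = colnames(df)[-1L],
             stage = stage)
}

#' Write an expression matrix to TSV/CSV
#'
#' @param x A [compendium()].
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_compendium <- function(x, path, sep = "\t") {
  assert_stage(x, c("raw_counts", "tpm", "log_tpm", "centered"),
               "write_compendium")
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x)[, ,
                   drop = FALSE]), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `condition_id`, `project_id`,
#' `replicate_group`, `is_reference` (logical or 0/1). Missing
#' `project_id`/`replicate_group` default to the condition.
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @return A data frame of sample metadata.
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  need <- c("sample_id", "condition_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$project_id)) df$project_id <- df$condition_id
  if (is.null(df$replicate_group)) df$replicate_group <- df$condition_id
  if (is.null(df$is_reference)) df$is_reference <- FALSE
  df$is_reference <- as.logical(df$is_reference)
  validate_metadata(df)
}

validate_metadata <- function(meta, comp = NULL) {
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup))
    stop("duplicate sample_id in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!is.null(comp)) {
    miss <- setdiff(colnames(comp), meta$sample_id)
    if (length(miss))
      stop("samples absent from metadata: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  meta
}

#' Read gene annotation
#'
#' Expects at least `gene_id`; recognised optional columns are `name`,
#' `product`, `length_nt`, `cog_category`, `operon`, `known_regulators`.
#'
#' @inheritParams read_sample_metadata
#' @return A data frame of gene annotation.
#' @export
read_gene_annotation <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (is.null(df$gene_id))
    stop("annotation must have a gene_id column", call. = FALSE)
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stop("duplicate gene_id in annotation: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!is.null(df$length_nt)) {
    df$length_nt <- as.numeric(df$length_nt)
    if (any(!is.na(df$length_nt) & df$length_nt <= 0))
      stop("length_nt must be positive", call. = FALSE)
  }
  df
}

#' Read a literature TRN table
#'
#' A transcriptional regulatory network (TRN) is a two-column
#' (regulator, gene) table; an optional third effect-sign column is
#' accepted and ignored. Pairs are deduplicated.
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @param annotation Optional gene annotation; pairs whose gene is absent
#'   from it are counted and reported via a warning.
#' @param header Whether the file has a header row.
#' @return A data frame with columns `regulator`, `gene_id` and attribute
#'   `n_unknown_genes`.
#' @export
read_trn <- function(path, sep = NULL, annotation = NULL, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = header, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L)
    stop("TRN table must have at least two columns (regulator, gene)",
         call. = FALSE)
  trn <- data.frame(regulator = as.character(df[[1L]]),
                    gene_id = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  trn <- unique(trn)
  rownames(trn) <- NULL
  if (nrow(trn) == 0L)
    warning("TRN table is empty", call. = FALSE)
  n_unknown <- 0L
  if (!is.null(annotation)) {
    n_unknown <- sum(!trn$gene_id %in% annotation$gene_id)
    if (n_unknown > 0L)
      warning(n_unknown, " TRN pairs reference genes absent from annotation",
              call. = FALSE)
  }
  attr(trn, "n_unknown_genes") <- n_unknown
  trn
}

#' Write a TRN table
#' @param trn Data frame with `regulator`, `gene_id`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_trn <- function(trn, path, sep = "\t") {
  utils::write.table(trn[, c("regulator", "gene_id")], path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_csv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the full analysis bundle
#'
#' Writes the downloadable file set of a decomposed compendium: the
#' log-TPM matrix, the gene-weight matrix M, the activity matrix A, gene
#' annotation, TRN, sample metadata and the iModulon table, plus a JSON
#' manifest with shapes and MD5 checksums. Identifier consistency across
#' all objects is verified before anything is written.
#'
#' @param log_tpm A `compendium` at stage `log_tpm` or `centered`.
#' @param decomposition A [decomposition] from [robust_ica()].
#' @param imodulons List of iModulons from [extract_imodulons()] /
#'   [annotate_imodulons()].
#' @param metadata,annotation,trn The three input tables.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_bundle <- function(log_tpm, decomposition, imodulons, metadata,
                         annotation, trn, out_dir) {
  if (!identical(rownames(log_tpm), rownames(decomposition$M)))
    stop("gene ids differ between compendium and decomposition",
         call. = FALSE)
  if (!identical(colnames(log_tpm), colnames(decomposition$A)))
    stop("sample ids differ between compendium and decomposition",
         call. = FALSE)
  validate_metadata(metadata, log_tpm)
  miss <- setdiff(rownames(log_tpm), annotation$gene_id)
  if (length(miss))
    stop("genes absent from annotation: ", paste(utils::head(miss, 5L),
         collapse = ", "), call. = FALSE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  p <- file.path(out_dir, "log_tpm.csv")
  write_matrix_csv(unclass(log_tpm), p, "gene_id")
  files$log_tpm.csv <- dim(log_tpm)
  p <- file.path(out_dir, "M.csv")
  write_matrix_csv(decomposition$M, p, "gene_id")
  files$M.csv <- dim(decomposition$M)
  p <- file.path(out_dir, "A.csv")
  write_matrix_csv(decomposition$A, p, "component_id")
  files$A.csv <- dim(decomposition$A)
  utils::write.csv(annotation, file.path(out_dir, "gene_annotation.csv"),
                   quote = TRUE, row.names = FALSE)
  files$gene_annotation.csv <- dim(annotation)
  write_trn(trn, file.path(out_dir, "trn.csv"), sep = ",")
  files$trn.csv <- c(nrow(trn), 2L)
  utils::write.csv(metadata, file.path(out_dir, "sample_metadata.csv"),
                   quote = FALSE, row.names = FALSE)
  files$sample_metadata.csv <- dim(metadata)
  tab <- imodulon_table(imodulons)
  utils::write.csv(tab, file.path(out_dir, "imodulon_table.csv"),
                   quote = TRUE, row.names = FALSE)
  files$imodulon_table.csv <- dim(tab)

  manifest <- list(files = lapply(names(files), function(f) {
    list(file = f,
         shape = as.integer(files[[f]]),
         md5 = unname(tools::md5sum(file.path(out_dir, f))))
  }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
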