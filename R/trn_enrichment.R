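#' Evaluate a boolean regulator expression against a TRN
#'
#' A regulator expression names one or more regulators combined with the
#' set operators `/` (OR: union of regulons) or `+` (AND: intersection of
#' regulons). For example, `"ExuR/FucR"` is the set of genes regulated by
#' either regulator, `"GutM+SrlR"` the genes regulated by both. Mixing the
#' two operators in one expression is rejected. The result is intersected
#' with the gene universe.
#'
#' @param trn TRN data frame (`regulator`, `gene_id`).
#' @param regulator_expr Expression string, e.g. `"R1"`, `"R1/R2"`, `"R1+R2"`.
#' @param universe Character vector of genes in the analysis universe.
#' @return Character vector of genes.
#' @export
regulon_gene_set <- function(trn, regulator_expr, universe) {
  parsed <- parse_regulator_expr(regulator_expr)
  sets <- lapply(parsed$regulators, function(r) {
    if (!r %in% trn$regulator)
      stop("unknown regulator: ", r, call. = FALSE)
    trn$gene_id[trn$regulator == r]
  })
  genes <- Reduce(if (parsed$op == "+") intersect else union, sets)
  intersect(genes, universe)
}

parse_regulator_expr <- function(expr) {
  if (!nzchar(expr)) stop("empty regulator expression", call. = FALSE)
  has_or <- grepl("/", expr, fixed = TRUE)
  has_and <- grepl("+", expr, fixed = TRUE)
  if (has_or && has_and)
    stop("mixed '/' and '+' operators are not supported without grouping: ",
         expr, call. = FALSE)
  op <- if (has_and) "+" else "/"
  regs <- trimws(strsplit(expr, "[/+]")[[1L]])
  if (any(!nzchar(regs)))
    stop("malformed regulator expression: ", expr, call. = FALSE)
  list(regulators = regs, op = op)
}

#' Score the overlap of an iModulon with a regulon
#'
#' Computes the Venn counts of the two gene sets, precision (fraction of
#' iModulon genes inside the regulon), recall (fraction of regulon genes
#' inside the iModulon) and the hypergeometric upper-tail p-value of
#' observing at least the seen overlap given the set sizes and universe.
#'
#' @param imodulon_genes Character vector (nonempty).
#' @param regulon_genes Character vector (subset of the universe).
#' @param universe_size Number of genes in the universe.
#' @param regulator_expr Expression string recorded in the result.
#' @return A list of class `enrichment_record`: `regulator_expr`,
#'   `precision`, `recall`, `pvalue`, `qvalue` (NA until corrected),
#'   `venn` (`only_imodulon`, `both`, `only_regulon`), `f1`.
#' @export
score_enrichment <- function(imodulon_genes, regulon_genes, universe_size,
                             regulator_expr = NA_character_) {
  imodulon_genes <- unique(imodulon_genes)
  regulon_genes <- unique(regulon_genes)
  if (length(imodulon_genes) == 0L)
    stop("empty iModulon gene set", call. = FALSE)
  both <- length(intersect(imodulon_genes, regulon_genes))
  only_im <- length(imodulon_genes) - both
  only_reg <- length(regulon_genes) - both
  if (length(regulon_genes) == 0L) {
    rec <- list(regulator_expr = regulator_expr, precision = 0,
                recall = NA_real_, pvalue = 1, qvalue = NA_real_,
                venn = c(only_imodulon = only_im, both = 0L, only_regulon = 0L),
                f1 = 0, empty_regulon = TRUE)
    return(structure(rec, class = "enrichment_record"))
  }
  precision <- both / length(imodulon_genes)
  recall <- both / length(regulon_genes)
  pvalue <- stats::phyper(both - 1, length(regulon_genes),
                          universe_size - length(regulon_genes),
                          length(imodulon_genes), lower.tail = FALSE)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(regulator_expr = regulator_expr, precision = precision,
                 recall = recall, pvalue = pvalue, qvalue = NA_real_,
                 venn = c(only_imodulon = only_im, both = both,
                          only_regulon = only_reg),
                 f1 = f1, empty_regulon = FALSE),
            class = "enrichment_record")
}

#' @export
print.enrichment_record <- function(x, ...) {
  cat(sprintf("<enrichment> %s: precision %.3f, recall %.3f, p = %.3g\n",
              x$regulator_expr, x$precision,
              if (is.na(x$recall)) NaN else x$recall, x$pvalue))
  invisible(x)
}

# All candidate regulator expressions up to max_combo regulators:
# singles, then every unordered pair with both "/" and "+".
candidate_expressions <- function(regulators, max_combo = 2) {
  regulators <- sort(unique(regulators))
  out <- regulators
  if (max_combo >= 2 && length(regulators) >= 2) {
    pairs <- utils::combn(regulators, 2L)
    out <- c(out,
             paste(pairs[1L, ], pairs[2L, ], sep = "/"),
             paste(pairs[1L, ], pairs[2L, ], sep = "+"))
  }
  out
}

#' Search the best regulator expression for an iModulon
#'
#' Evaluates every single regulator and every pairwise `/` (OR) and `+`
#' (AND) combination against the iModulon's member genes, corrects the
#' hypergeometric p-values with Benjamini-Hochberg across the candidates,
#' and among the candidates passing `q_cutoff` (and overlapping the
#' iModulon) returns the one with the highest F1 score. Ties prefer fewer
#' regulators, then the lexicographically first expression.
#'
#' @param imodulon_genes Character vector of member genes.
#' @param trn TRN data frame.
#' @param universe Character vector of universe genes.
#' @param max_combo Maximum regulators per expression (default 2).
#' @param q_cutoff BH-adjusted significance threshold (default 0.01).
#' @return An `enrichment_record` (with `qvalue` filled in) or `NULL` when
#'   no candidate passes.
#' @export
search_best_regulator <- function(imodulon_genes, trn, universe,
                                  max_combo = 2, q_cutoff = 0.01) {
  if (nrow(trn) == 0L) return(NULL)
  imodulon_genes <- intersect(unique(imodulon_genes), universe)
  if (length(imodulon_genes) == 0L) return(NULL)
  exprs <- candidate_expressions(unique(trn$regulator), max_combo)
  recs <- lapply(exprs, function(e) {
    genes <- regulon_gene_set(trn, e, universe)
    score_enrichment(imodulon_genes, genes, length(universe),
                     regulator_expr = e)
  })
  pvals <- vapply(recs, `[[`, 1.0, "pvalue")
  qvals <- stats::p.adjust(pvals, method = "BH")
  ok <- which(qvals < q_cutoff &
                vapply(recs, function(r) r$venn[["both"]] > 0, TRUE))
  if (length(ok) == 0L) return(NULL)
  f1 <- vapply(recs[ok], `[[`, 1.0, "f1")
  n_regs <- vapply(recs[ok], function(r)
    length(parse_regulator_expr(r$regulator_expr)$regulators), 1L)
  expr_names <- vapply(recs[ok], `[[`, "", "regulator_expr")
  best <- ok[order(-f1, n_regs, expr_names)[1L]]
  rec <- recs[[best]]
  rec$qvalue <- qvals[best]
  rec
}

#' Annotate iModulons with their best regulon enrichment
#'
#' Runs [search_best_regulator()] on every iModulon and assigns default
#' names: the winning regulator expression, with `-1`, `-2`, ... suffixes
#' (ordered by descending precision) when several iModulons map to the same
#' expression; unenriched or memberless iModulons keep their component id
#' as name.
#'
#' @inheritParams search_best_regulator
#' @param imodulons List of `imodulon` objects.
#' @return List with `imodulons` (enrichment + name filled in) and `table`,
#'   the dataset-page table (name, regulator, N, precision, recall).
#' @export
annotate_imodulons <- function(imodulons, trn, universe, max_combo = 2,
                               q_cutoff = 0.01) {
  for (i in seq_along(imodulons)) {
    im <- imodulons[[i]]
    if (!im$memberless) {
      im$enrichment <- search_best_regulator(im$member_genes$gene_id, trn,
                                             universe, max_combo, q_cutoff)
      if (!is.null(im$enrichment)) im$name <- im$enrichment$regulator_expr
    }
    imodulons[[i]] <- im
  }
  base_names <- vapply(imodulons, `[[`, "", "name")
  for (nm in unique(base_names[duplicated(base_names)])) {
    idx <- which(base_names == nm)
    prec <- vapply(imodulons[idx], function(im)
      if (is.null(im$enrichment)) -Inf else im$enrichment$precision, 1.0)
    idx <- idx[order(prec, decreasing = TRUE)]
    for (r in seq_along(idx))
      imodulons[[idx[r]]]$name <- paste0(nm, "-", r)
  }
  list(imodulons = imodulons, table = imodulon_table(imodulons))
}

#' Dataset-page iModulon table
#'
#' One row per iModulon: curated name, regulator expression (blank when
#' unenriched), member count N, precision and recall.
#'
#' @param imodulons List of `imodulon` objects.
#' @return A data frame.
#' @export
imodulon_table <- function(imodulons) {
  data.frame(
    name = vapply(imodulons, `[[`, "", "name"),
    regulator = vapply(imodulons, function(im)
      if (is.null(im$enrichment)) "" else im$enrichment$regulator_expr, ""),
    func = "",
    category = "",
    N = vapply(imodulons, function(im) nrow(im$member_genes), 1L),
    precision = vapply(imodulons, function(im)
      if (is.null(im$enrichment)) NA_real_ else im$enrichment$precision, 1.0),
    recall = vapply(imodulons, function(im)
      if (is.null(im$enrichment)) NA_real_ else im$enrichment$recall, 1.0),
    stringsAsFactors = FALSE)
}
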