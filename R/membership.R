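#' D'Agostino K-squared normality statistic
#'
#' Omnibus test statistic combining the transformed sample skewness
#' (D'Agostino 1970) and kurtosis (Anscombe & Glynn 1983) into
#' `K2 = Z_skew^2 + Z_kurt^2`, approximately chi-squared with 2 degrees of
#' freedom under normality. Large values indicate heavy tails or asymmetry;
#' the iterative membership threshold removes the largest-|weight| genes
#' until the remaining weight distribution looks normal by this statistic.
#'
#' @param x Numeric vector, length >= 20.
#' @return The K-squared statistic (scalar).
#' @export
k2_statistic <- function(x) {
  n <- length(x)
  if (n < 20L)
    stop("K-squared statistic requires at least 20 observations",
         call. = FALSE)
  z1 <- skewness_z(x)
  z2 <- kurtosis_z(x)
  z1^2 + z2^2
}

# D'Agostino (1970) transformed skewness Z.
skewness_z <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  m3 <- mean(xc^3)
  if (m2 == 0) return(0)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  if (y == 0) return(0)
  delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
}

# Anscombe & Glynn (1983) transformed kurtosis Z.
kurtosis_z <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  m4 <- mean(xc^4)
  if (m2 == 0) return(0)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  term1 <- 1 - 2 / (9 * a)
  denom <- 1 + xs * sqrt(2 / (a - 4))
  term2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  (term1 - term2) / sqrt(2 / (9 * a))
}

#' Threshold one component into an iModulon by iterative K-squared removal
#'
#' Genes are removed one at a time in order of decreasing absolute weight,
#' recomputing the K-squared statistic of the remaining weights after each
#' removal, until the statistic falls below `cutoff`; all removed genes are
#' the iModulon members. If the full weight vector is already normal-looking
#' (initial K-squared below the cutoff) the component is flagged memberless.
#' Ties in |weight| are broken by gene order. After the loop the member set
#' is closed over ties so that it equals exactly
#' `{g : |w_g| >= threshold_abs}`.
#'
#' @param weights Named numeric vector of gene weights (one M column),
#'   length >= 20.
#' @param cutoff Organism-specific K-squared cutoff (> 0).
#' @param component_id Label carried into the result.
#' @return A list with `imodulon` (class `imodulon`: `component_id`,
#'   `member_genes` data frame ordered by |weight| descending,
#'   `threshold_abs`, `k2_final`, `memberless`, `name`) and `trace` (class
#'   `threshold_trace`: `removal_order`, `k2_sequence`, `cutoff`).
#' @export
threshold_component <- function(weights, cutoff, component_id = "IC_1") {
  if (length(weights) < 20L)
    stop("need at least 20 genes to threshold a component", call. = FALSE)
  stopifnot(cutoff > 0)
  if (is.null(names(weights)))
    names(weights) <- paste0("g", seq_along(weights))
  ord <- order(abs(weights), decreasing = TRUE)
  k2_seq <- numeric(0)
  removed <- character(0)
  n_removed <- 0L
  repeat {
    remaining <- weights[if (n_removed) -ord[seq_len(n_removed)] else
                         seq_along(weights)]
    if (length(remaining) < 20L) break
    k2 <- k2_statistic(remaining)
    k2_seq <- c(k2_seq, k2)
    if (k2 < cutoff) break
    n_removed <- n_removed + 1L
    removed <- c(removed, names(weights)[ord[n_removed]])
  }
  memberless <- n_removed == 0L
  if (memberless) {
    members <- data.frame(gene_id = character(0), weight = numeric(0),
                          stringsAsFactors = FALSE)
    threshold_abs <- Inf
  } else {
    threshold_abs <- min(abs(weights[removed]))
    # close over |weight| ties at the threshold
    in_set <- abs(weights) >= threshold_abs
    sel <- weights[in_set]
    sel <- sel[order(abs(sel), decreasing = TRUE)]
    members <- data.frame(gene_id = names(sel), weight = unname(sel),
                          stringsAsFactors = FALSE)
  }
  imod <- structure(list(component_id = component_id,
                         name = component_id,
                         member_genes = members,
                         threshold_abs = threshold_abs,
                         k2_final = k2_seq[length(k2_seq)],
                         memberless = memberless,
                         enrichment = NULL),
                    class = "imodulon")
  trace <- structure(list(removal_order = removed, k2_sequence = k2_seq,
                          cutoff = cutoff),
                     class = "threshold_trace")
  list(imodulon = imod, trace = trace)
}

#' @export
print.imodulon <- function(x, ...) {
  cat(sprintf("<imodulon> %s: %d member genes%s\n", x$name,
              nrow(x$member_genes),
              if (x$memberless) " (memberless)" else ""))
  invisible(x)
}

#' Extract iModulons from a decomposition
#'
#' Applies [threshold_component()] to every consensus component. Memberless
#' components are retained and flagged so component indices stay aligned
#' with the activity matrix.
#'
#' @param decomposition A [decomposition].
#' @param cutoff K-squared cutoff passed to [threshold_component()].
#' @return A list of `imodulon` objects, one per component.
#' @export
extract_imodulons <- function(decomposition, cutoff) {
  stopifnot(inherits(decomposition, "decomposition"))
  lapply(decomposition$component_ids, function(id) {
    threshold_component(decomposition$M[, id], cutoff,
                        component_id = id)$imodulon
  })
}

#' Sweep K-squared cutoffs to calibrate the membership threshold
#'
#' Reports, for each candidate cutoff, the member count of every component
#' and the total, so a dataset-specific cutoff can be chosen and logged.
#'
#' @param decomposition A [decomposition].
#' @param cutoffs Numeric vector of candidate cutoffs.
#' @return Data frame with `cutoff`, `component_id`, `n_members`.
#' @export
calibrate_cutoff <- function(decomposition, cutoffs = c(100, 200, 300, 400,
                                                        550, 750, 1000)) {
  do.call(rbind, lapply(cutoffs, function(co) {
    ims <- extract_imodulons(decomposition, co)
    data.frame(cutoff = co,
               component_id = vapply(ims, `[[`, "", "component_id"),
               n_members = vapply(ims, function(i) nrow(i$member_genes), 1L),
               stringsAsFactors = FALSE)
  }))
}

#' Fraction of variance explained by iModulon reconstruction
#'
#' Rebuilds the expression matrix using only iModulon member genes and
#' their activities: every non-member weight in M is zeroed, giving
#' `overall = 1 - ||X - M_mem A||_F^2 / ||X||_F^2`. Per-iModulon values use
#' the analogous single-component reconstruction against X.
#'
#' @param centered A `compendium` at stage `centered` (the matrix that was
#'   decomposed).
#' @param decomposition A [decomposition] with activities.
#' @param imodulons List of `imodulon` objects aligned with the components.
#' @return List with `overall` (scalar in `[0, 1]` up to noise) and
#'   `per_imodulon` (named vector).
#' @export
explained_variance <- function(centered, decomposition, imodulons) {
  X <- unclass(centered)
  M <- decomposition$M
  A <- decomposition$A
  stopifnot(nrow(X) == nrow(M), ncol(X) == ncol(A), ncol(M) == nrow(A))
  tot <- sum(X^2)
  if (tot == 0) stop("zero-variance matrix", call. = FALSE)
  Mm <- M * 0
  for (im in imodulons) {
    if (im$memberless) next
    j <- im$component_id
    g <- im$member_genes$gene_id
    Mm[g, j] <- M[g, j]
  }
  overall <- 1 - sum((X - Mm %*% A)^2) / tot
  per <- vapply(imodulons, function(im) {
    j <- im$component_id
    1 - sum((X - Mm[, j, drop = FALSE] %*% A[j, , drop = FALSE])^2) / tot
  }, 1.0)
  names(per) <- vapply(imodulons, `[[`, "", "component_id")
  list(overall = overall, per_imodulon = per)
}
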