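#' Single FastICA run on a centered compendium
#'
#' Runs the fixed-point FastICA algorithm (logcosh contrast, parallel
#' updates, unit-variance whitening) on the genes-by-samples matrix,
#' treating genes as observations, and returns `d` source vectors over
#' genes. Each column is scaled to unit L2 norm and sign-oriented so that
#' the sum of cubed weights is positive (the heavy tail points up).
#' Randomness enters only through the seeded random initial rotation, so a
#' run is deterministic given its seed.
#'
#' @param centered A `compendium` at stage `centered`.
#' @param d Number of components, `2 <= d <= min(genes, samples)`.
#' @param seed Integer seed for the random initial rotation.
#' @param maxit,tol Fixed-point iteration controls.
#' @return A genes-by-d matrix of unit-norm gene weights, with attribute
#'   `converged`.
#' @export
run_ica_once <- function(centered, d, seed, maxit = 1000, tol = 1e-6) {
  assert_stage(centered, "centered", "run_ica_once")
  X <- unclass(centered)
  if (d < 1 || d > min(dim(X)))
    stop("d must be in [1, min(genes, samples)]", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  R0 <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  fit <- ica::icafast(X, nc = d, center = FALSE, maxit = maxit, tol = tol,
                      Rmat = R0, alg = "par", fun = "logcosh", alpha = 1)
  M <- fit$S
  M <- orient_columns(normalize_columns(M))
  rownames(M) <- rownames(X)
  colnames(M) <- paste0("run_", seed, "_", seq_len(ncol(M)))
  attr(M, "converged") <- isTRUE(fit$converged)
  M
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

normalize_columns <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  sweep(M, 2L, nrm, "/")
}

# Skew-positive sign convention: flip each column so sum(w^3) > 0; ties
# broken by making the largest-|weight| entry positive.
orient_columns <- function(M) {
  for (j in seq_len(ncol(M))) {
    s <- sum(M[, j]^3)
    if (s == 0) s <- M[which.max(abs(M[, j])), j]
    if (s < 0) M[, j] <- -M[, j]
  }
  M
}

#' Run an ensemble of ICA restarts
#'
#' Performs `n_runs` FastICA runs with seeds `base_seed + 0:(n_runs-1)`.
#' Non-convergent runs are excluded with a warning.
#'
#' @inheritParams run_ica_once
#' @param n_runs Number of restarts (default 100).
#' @param base_seed First seed of the grid.
#' @return An object of class `run_ensemble`: list of per-run gene-weight
#'   matrices, their seeds, and `d`.
#' @export
run_ica_ensemble <- function(centered, d, n_runs = 100, base_seed = 42,
                             maxit = 1000, tol = 1e-6) {
  runs <- list()
  seeds <- integer(0)
  dropped <- 0L
  for (i in seq_len(n_runs)) {
    s <- base_seed + i - 1L
    M <- run_ica_once(centered, d, seed = s, maxit = maxit, tol = tol)
    if (!attr(M, "converged")) {
      dropped <- dropped + 1L
      next
    }
    runs[[length(runs) + 1L]] <- M
    seeds <- c(seeds, s)
  }
  if (dropped > 0L)
    warning(dropped, " ICA run(s) did not converge and were excluded",
            call. = FALSE)
  structure(list(runs = runs, seeds = seeds, d = d), class = "run_ensemble")
}

# Exact DBSCAN on a precomputed distance matrix. Neighborhoods include the
# point itself; border points join the first core cluster that reaches them.
dbscan_matrix <- function(D, eps, min_pts) {
  n <- nrow(D)
  labels <- rep.int(0L, n)   # 0 = noise/unvisited
  visited <- rep.int(FALSE, n)
  cl <- 0L
  for (p in seq_len(n)) {
    if (visited[p]) next
    visited[p] <- TRUE
    nb <- which(D[p, ] <= eps)
    if (length(nb) < min_pts) next
    cl <- cl + 1L
    labels[p] <- cl
    queue <- setdiff(nb, p)
    while (length(queue)) {
      q <- queue[1L]
      queue <- queue[-1L]
      if (labels[q] == 0L) labels[q] <- cl
      if (!visited[q]) {
        visited[q] <- TRUE
        nbq <- which(D[q, ] <= eps)
        if (length(nbq) >= min_pts)
          queue <- union(queue, nbq[labels[nbq] == 0L])
      }
    }
  }
  labels
}

#' Cluster ICA components across runs into a consensus decomposition
#'
#' Pools the components of all runs and clusters them with DBSCAN on the
#' distance `1 - |Pearson correlation|` over genes. Only clusters supported
#' by strictly more than `min_support` of the distinct runs are retained
#' (a run contributing several near-duplicate components counts once). The
#' consensus gene-weight vector of a cluster is the sign-aligned mean of
#' its members (or the medoid), re-normalized to unit L2 and sign-oriented.
#'
#' @param ensemble A `run_ensemble`.
#' @param eps DBSCAN radius on the `1 - |rho|` metric (default 0.1).
#' @param min_support Minimum fraction of distinct runs, exclusive
#'   (default 0.5: a component must appear in more than half of the runs).
#' @param min_samples DBSCAN core-point neighborhood size; default
#'   `ceiling(n_runs / 2)`.
#' @param consensus `"mean"` (default) or `"medoid"`.
#' @return A [decomposition] with `M` and `support` (activities unset).
#' @export
cluster_components <- function(ensemble, eps = 0.1, min_support = 0.5,
                               min_samples = NULL, consensus = c("mean",
                               "medoid")) {
  consensus <- match.arg(consensus)
  stopifnot(inherits(ensemble, "run_ensemble"))
  n_runs <- length(ensemble$runs)
  if (n_runs < 2L) stop("need at least 2 successful runs", call. = FALSE)
  if (is.null(min_samples)) min_samples <- ceiling(n_runs / 2)
  pool <- do.call(cbind, ensemble$runs)
  run_of <- rep(seq_len(n_runs), vapply(ensemble$runs, ncol, 1L))
  D <- 1 - abs(stats::cor(pool))
  labels <- dbscan_matrix(D, eps = eps, min_pts = min_samples)
  kept <- list()
  supports <- numeric(0)
  for (cl in setdiff(sort(unique(labels)), 0L)) {
    members <- which(labels == cl)
    support <- length(unique(run_of[members])) / n_runs
    if (support <= min_support) next
    sub <- pool[, members, drop = FALSE]
    anchor <- sub[, 1L]
    signs <- sign(as.vector(crossprod(sub, anchor)))
    signs[signs == 0] <- 1
    aligned <- sweep(sub, 2L, signs, "*")
    vec <- if (consensus == "mean") {
      rowMeans(aligned)
    } else {
      within <- D[members, members, drop = FALSE]
      aligned[, which.min(rowSums(within))]
    }
    kept[[length(kept) + 1L]] <- vec
    supports <- c(supports, support)
  }
  if (length(kept) == 0L) {
    warning("no component recurred in more than ", min_support * 100,
            "% of runs; empty decomposition", call. = FALSE)
    M <- matrix(numeric(0), nrow = nrow(pool), ncol = 0,
                dimnames = list(rownames(pool), NULL))
    return(new_decomposition(M, NULL, numeric(0), n_runs))
  }
  ord <- order(supports, decreasing = TRUE)
  M <- orient_columns(normalize_columns(do.call(cbind, kept[ord])))
  rownames(M) <- rownames(pool)
  new_decomposition(M, NULL, supports[ord], n_runs)
}

#' Build a decomposition from existing matrices
#'
#' Wraps externally supplied gene-weight and activity matrices (for
#' example, planted ground truth or a decomposition imported from another
#' tool) into a `decomposition` object. Columns of `M` are normalized to
#' unit L2 and sign-oriented; `A` is rescaled accordingly so that `M A` is
#' unchanged.
#'
#' @param M Genes-by-k gene-weight matrix (rownames = gene ids).
#' @param A Optional k-by-samples activity matrix.
#' @param support Per-component cluster support fractions (default 1).
#' @param run_count Number of ICA runs behind the object (default 1).
#' @return A `decomposition`.
#' @export
as_decomposition <- function(M, A = NULL, support = rep(1, ncol(M)),
                             run_count = 1L) {
  stopifnot(is.matrix(M), is.null(A) || ncol(M) == nrow(A))
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  flip <- vapply(seq_len(ncol(M)), function(j) {
    s <- sum(M[, j]^3)
    if (s == 0) s <- M[which.max(abs(M[, j])), j]
    if (s < 0) -1 else 1
  }, 1.0)
  Mn <- sweep(M, 2L, nrm * flip, "/")
  if (!is.null(A)) A <- sweep(A, 1L, nrm * flip, "*")
  new_decomposition(Mn, A, support, run_count)
}

new_decomposition <- function(M, A, support, run_count) {
  ids <- if (ncol(M)) paste0("IC_", seq_len(ncol(M))) else character(0)
  colnames(M) <- ids
  if (!is.null(A)) rownames(A) <- ids
  structure(list(M = M, A = A, support = stats::setNames(support, ids),
                 run_count = run_count, component_ids = ids),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d genes x %d components (from %d runs)\n",
              nrow(x$M), ncol(x$M), x$run_count))
  invisible(x)
}

#' Compute component activities
#'
#' Solves `X = M A` for the activity matrix `A` by least squares
#' (pseudoinverse of M); with column-normalized M and exact sources this
#' reproduces X. A rank-deficient M falls back to the Moore-Penrose
#' pseudoinverse with a warning.
#'
#' @param centered A `compendium` at stage `centered` (or any matrix with
#'   matching gene order).
#' @param M Genes-by-k gene-weight matrix.
#' @return A k-by-samples activity matrix.
#' @export
compute_activities <- function(centered, M) {
  X <- unclass(centered)
  if (nrow(X) != nrow(M))
    stop("gene dimension of X and M differ", call. = FALSE)
  if (ncol(M) == 0L)
    return(matrix(numeric(0), 0L, ncol(X),
                  dimnames = list(NULL, colnames(X))))
  A <- tryCatch(
    solve(crossprod(M), crossprod(M, X)),
    error = function(e) {
      warning("rank-deficient M; using pseudoinverse least squares",
              call. = FALSE)
      MASS::ginv(M) %*% X
    })
  dimnames(A) <- list(colnames(M), colnames(X))
  A
}

#' Robust ICA decomposition
#'
#' End-to-end robust decomposition `X ~ M A`: runs FastICA `n_runs` times
#' with different seeds, clusters the pooled components with DBSCAN on
#' `1 - |rho|`, keeps components recurring in more than half of the runs,
#' and solves for the activities of the consensus components.
#'
#' @inheritParams run_ica_ensemble
#' @inheritParams cluster_components
#' @return A `decomposition` with `M` (genes x k, unit-norm columns), `A`
#'   (k x samples), per-component `support` and `run_count`.
#' @export
robust_ica <- function(centered, d, n_runs = 100, base_seed = 42, eps = 0.1,
                       min_support = 0.5, min_samples = NULL,
                       maxit = 1000, tol = 1e-6) {
  ens <- run_ica_ensemble(centered, d, n_runs = n_runs,
                          base_seed = base_seed, maxit = maxit, tol = tol)
  dec <- cluster_components(ens, eps = eps, min_support = min_support,
                            min_samples = min_samples)
  dec$A <- compute_activities(centered, dec$M)
  dec
}
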