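# Embeddings of individuals: PCA, classical (Torgerson) MDS, UMAP.

#' @keywords internal
new_embedding <- function(ids, coords, method, params, evar = NULL) {
  rownames(coords) <- ids
  colnames(coords) <- paste0(toupper(method), seq_len(ncol(coords)))
  structure(list(individual_ids = ids, coordinates = coords,
                 explained_variance_pct = evar, method = method,
                 params = params),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("embedding (", x$method, "): ", length(x$individual_ids),
      " individuals x ", ncol(x$coordinates), " components\n", sep = "")
  if (!is.null(x$explained_variance_pct))
    cat("  explained variance %:",
        paste(sprintf("%.2f", x$explained_variance_pct), collapse = ", "), "\n")
  invisible(x)
}

# impute missing dosages; "mean" = per-SNP mean, "drop" = remove SNPs with
# any missing call. All-missing SNPs are dropped with a warning either way.
impute_dosages <- function(G, missing_policy = c("mean", "drop")) {
  missing_policy <- match.arg(missing_policy)
  X <- G$dosages
  storage.mode(X) <- "double"
  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " all-missing SNP(s) dropped")
    X <- X[, !all_na, drop = FALSE]
  }
  if (anyNA(X)) {
    if (missing_policy == "drop") {
      X <- X[, colSums(is.na(X)) == 0, drop = FALSE]
    } else {
      mu <- colMeans(X, na.rm = TRUE)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- mu[idx[, 2]]
    }
  }
  X
}

# flip each column of scores (and loadings) so the loading entry with the
# largest magnitude is positive; first index wins ties -> deterministic signs
apply_sign_convention <- function(scores, loadings = NULL) {
  ref <- if (is.null(loadings)) scores else loadings
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(ref[, j]))
    if (ref[i, j] < 0) {
      scores[, j] <- -scores[, j]
      if (!is.null(loadings)) loadings[, j] <- -loadings[, j]
    }
  }
  scores
}

#' Principal component analysis of genotype dosages
#'
#' Column-centered (optionally unit-variance standardized) dosages are
#' decomposed with [stats::prcomp()]; coordinates are the projections onto
#' the top `k` eigenvectors and `explained_variance_pct` the usual
#' \eqn{100 \lambda_i / \sum \lambda} shares. Component signs follow a fixed
#' convention (largest-magnitude loading positive) so results do not depend
#' on individual ordering.
#'
#' @param G a `genotype_matrix`
#' @param k number of components, at most `min(n - 1, m)`
#' @param missing_policy `"mean"` (per-SNP mean imputation, default) or
#'   `"drop"` (drop SNPs with missing calls)
#' @param standardize scale each SNP to unit variance (default centers only)
#' @return an `embedding`
#' @export
pca_embed <- function(G, k = 2, missing_policy = c("mean", "drop"),
                      standardize = FALSE) {
  X <- impute_dosages(G, missing_policy)
  n <- nrow(X)
  kmax <- min(n - 1L, ncol(X))
  if (k > kmax) stop("k = ", k, " exceeds min(n - 1, m) = ", kmax)
  sds <- apply(X, 2, stats::sd)
  if (standardize) X <- X[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  lam <- pc$sdev^2
  evar <- if (sum(lam) > 0) 100 * lam / sum(lam) else rep(0, length(lam))
  scores <- apply_sign_convention(pc$x[, seq_len(k), drop = FALSE],
                                  pc$rotation[, seq_len(k), drop = FALSE])
  new_embedding(individual_ids(G), scores, "pca",
                list(k = k, missing_policy = missing_policy[1],
                     standardize = standardize),
                evar = evar[seq_len(k)])
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centering of squared distances followed by eigendecomposition
#' ([stats::cmdscale()]); negative eigenvalues are truncated to zero.
#'
#' @param D symmetric distance matrix with zero diagonal (a `dist` or a
#'   square matrix with individual IDs as dimnames)
#' @param k number of dimensions
#' @return an `embedding`
#' @export
classical_mds <- function(D, k = 2) {
  M <- as.matrix(D)
  if (!isSymmetric(unname(M), tol = 1e-8)) stop("distance matrix is not symmetric")
  if (any(abs(diag(M)) > 1e-12)) stop("distance matrix diagonal must be zero")
  ids <- rownames(M)
  if (is.null(ids)) ids <- paste0("I", seq_len(nrow(M)))
  # rank deficiency is handled below by zero-padding, so silence cmdscale's
  # "only p of the first k eigenvalues are > 0" notice
  fit <- suppressWarnings(stats::cmdscale(M, k = k, eig = TRUE))
  coords <- fit$points
  if (ncol(coords) < k) # rank-deficient input: pad with zero coordinates
    coords <- cbind(coords, matrix(0, nrow(coords), k - ncol(coords)))
  coords <- apply_sign_convention(coords)
  new_embedding(ids, coords, "mds", list(k = k))
}

#' UMAP embedding of individuals
#'
#' Delegates to [uwot::umap()] (a published algorithm invoked, not
#' re-implemented), seeded and single-threaded for reproducibility.
#'
#' @param G a `genotype_matrix`
#' @param k embedding dimensions (default 2)
#' @param n_neighbors UMAP neighborhood size; must be < n
#' @param min_dist UMAP minimum distance parameter
#' @param seed integer RNG seed
#' @param missing_policy passed to the dosage imputation step
#' @return an `embedding`
#' @export
umap_embed <- function(G, k = 2, n_neighbors = 15, min_dist = 0.1, seed = 1,
                       missing_policy = c("mean", "drop")) {
  X <- impute_dosages(G, missing_policy)
  if (nrow(X) < n_neighbors + 1)
    stop("n = ", nrow(X), " individuals but n_neighbors = ", n_neighbors,
         "; need n >= n_neighbors + 1")
  set.seed(seed)
  coords <- uwot::umap(X, n_components = k, n_neighbors = n_neighbors,
                       min_dist = min_dist, n_threads = 1, n_sgd_threads = 0)
  new_embedding(individual_ids(G), coords, "umap",
                list(k = k, n_neighbors = n_neighbors, min_dist = min_dist,
                     seed = seed))
}
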