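# Genotype distances and distance-based trees.
#
# The distance is allele-sharing (1 - identity-by-state); tree construction
# delegates to the standard implementations (ape::nj, ape::bionj,
# average-linkage UPGMA) with a negative-branch-length policy and
# SNP-bootstrap support computed here.

#' Allele-sharing (1 - IBS) distance between individuals
#'
#' For each pair, the mean over shared non-missing SNPs of
#' \eqn{|g_i - g_j| / 2}. Ranges from 0 (identical genotypes) to 1
#' (opposite homozygotes everywhere).
#'
#' @param G a `genotype_matrix`
#' @return symmetric n x n distance matrix with individual IDs as dimnames
#' @export
ibs_distance <- function(G) {
  X <- G$dosages
  storage.mode(X) <- "double"
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0
  # sum |gi - gj| over shared SNPs via |a-b| = a + b - 2*min(a,b); dosages in
  # {0,1,2} let us expand min() from indicator matrices
  shared <- obs %*% t(obs)
  if (any(shared == 0 & !diag(nrow(X)))) {
    bad <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop("individuals '", rownames(X)[bad[1]], "' and '", rownames(X)[bad[2]],
         "' share no non-missing SNP")
  }
  ge1 <- (X0 >= 1) & obs   # dosage >= 1
  ge2 <- (X0 >= 2) & obs   # dosage == 2
  # min(a,b) summed over shared loci = sum over thresholds of 1{a>=t}1{b>=t}
  smin <- ge1 %*% t(ge1) + ge2 %*% t(ge2)
  sa <- X0 %*% t(obs)      # sum of a over loci shared with j
  sb <- obs %*% t(X0)
  D <- (sa + sb - 2 * smin) / (2 * shared)
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

check_distance <- function(D) {
  M <- as.matrix(D)
  if (is.null(rownames(M))) stop("distance matrix needs individual IDs as dimnames")
  if (!isSymmetric(unname(M), tol = 1e-8)) stop("distance matrix is not symmetric")
  M
}

# move negative branch lengths to zero, transferring the deficit to the
# sibling edge (classic NJ convention); raw lengths kept as an attribute
clamp_negative_branches <- function(tree) {
  raw <- tree$edge.length
  el <- tree$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent & seq_along(el) != e)
    if (length(sibs)) el[sibs[1]] <- el[sibs[1]] + el[e]
    el[e] <- 0
  }
  el[el < 0] <- 0
  tree$edge.length <- el
  attr(tree, "raw_edge_lengths") <- raw
  tree
}

#' Neighbor-joining tree
#'
#' Saitou–Nei agglomeration via [ape::nj()]; on an exactly additive distance
#' matrix the generating topology and branch lengths are recovered. Negative
#' branch lengths are clamped to zero with the deficit moved to the sibling
#' edge (raw lengths kept in `attr(tree, "raw_edge_lengths")`).
#'
#' @param D symmetric distance matrix (>= 3 taxa)
#' @return an unrooted `ape::phylo` tree
#' @export
nj_tree <- function(D) {
  M <- check_distance(D)
  if (nrow(M) < 3) stop("neighbor-joining needs at least 3 taxa")
  clamp_negative_branches(ape::nj(stats::as.dist(M)))
}

#' BioNJ tree
#'
#' Variance-weighted neighbor-joining ([ape::bionj()]); identical to plain
#' NJ on exactly additive inputs. Same negative-length policy as [nj_tree()].
#'
#' @inheritParams nj_tree
#' @return an unrooted `ape::phylo` tree
#' @export
bionj_tree <- function(D) {
  M <- check_distance(D)
  if (nrow(M) < 3) stop("BioNJ needs at least 3 taxa")
  clamp_negative_branches(ape::bionj(stats::as.dist(M)))
}

#' UPGMA tree
#'
#' Rooted ultrametric tree by average-linkage agglomeration; each node sits
#' at half the between-cluster average distance, so all root-to-leaf paths
#' are equal.
#'
#' @inheritParams nj_tree
#' @return a rooted `ape::phylo` tree
#' @export
upgma_tree <- function(D) {
  M <- check_distance(D)
  if (nrow(M) < 2) stop("UPGMA needs at least 2 taxa")
  phangorn::upgma(stats::as.dist(M))
}

tree_builder <- function(method = c("nj", "bionj", "upgma")) {
  switch(match.arg(method), nj = nj_tree, bionj = bionj_tree, upgma = upgma_tree)
}

#' SNP-bootstrap support for a genotype tree
#'
#' Builds the full-data tree, then resamples SNP columns with replacement
#' `B` times, rebuilds, and labels each internal edge of the full-data tree
#' with the percentage of replicate trees containing the same bipartition.
#'
#' @param G a `genotype_matrix`
#' @param method tree builder: `"nj"`, `"bionj"` or `"upgma"`
#' @param B number of bootstrap replicates (>= 1)
#' @param seed integer RNG seed
#' @return the full-data `phylo` tree with support percentages in
#'   `node.label` (root label empty)
#' @export
bootstrap_support <- function(G, method = c("nj", "bionj", "upgma"),
                              B = 100, seed = 1) {
  method <- match.arg(method)
  if (B < 1) stop("B must be >= 1")
  build <- tree_builder(method)
  tree <- build(ibs_distance(G))
  m <- ncol(G$dosages)
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(m, m, replace = TRUE)
    dos <- G$dosages[, cols, drop = FALSE]
    colnames(dos) <- paste0("bs", seq_len(m))
    snps <- G$snps[cols, , drop = FALSE]
    snps$id <- colnames(dos)
    reps[[b]] <- build(ibs_distance(genotype_matrix(dos, snps)))
  }
  counts <- ape::prop.clades(tree, reps, rooted = method == "upgma")
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / B, 6)
  lab <- as.character(support)
  lab[1] <- ""                      # root of the (arbitrarily rooted) display
  tree$node.label <- lab
  attr(tree, "bootstrap") <- list(B = B, seed = seed, support = support)
  tree
}
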