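# Per-SNP breed-association scoring, redundancy pruning, panel cutting.
#
# Test statistics (chi2, Fisher) work on the 2 x C allele-count-by-breed
# table (each individual contributes two alleles; missing calls omitted).
# Information measures (mutual information / information gain, in bits) work
# on the 3-genotype-class x breed table, retaining non-additive signal.

# per-SNP allele counts by breed: list(alt = C x m, tot = C x m)
allele_counts_by_breed <- function(G, fac) {
  X <- G$dosages
  storage.mode(X) <- "double"
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0
  Z <- stats::model.matrix(~ fac - 1)   # n x C indicators
  alt <- t(Z) %*% X0
  tot <- 2 * (t(Z) %*% obs)
  rownames(alt) <- rownames(tot) <- levels(fac)
  list(alt = alt, tot = tot)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# plug-in mutual information (bits) from a joint count table
mi_bits <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  entropy_bits(px) + entropy_bits(py) - entropy_bits(as.vector(p))
}

#' Per-SNP breed association scores
#'
#' Ranks every polymorphic SNP by its association with breed using one of
#' four methods. `chi2`: Pearson statistic (no continuity correction) on the
#' 2 x C allele table, p from the chi-square distribution with C - 1 df.
#' `fisher`: exact p on the same table ([stats::fisher.test()]) when C <= 3
#' and at most 60 alleles are involved, otherwise seeded Monte-Carlo with
#' 1e5 tables; the reported statistic is -log10(p). `mutual_info`: plug-in
#' mutual information in bits between the genotype class (0/1/2) and the
#' breed label. `entropy_gain`: information gain H(breed) - H(breed |
#' genotype class), in bits — numerically identical to mutual information,
#' computed via the conditional-entropy route. Monomorphic and all-missing
#' SNPs are excluded with a warning. Ranking is by descending statistic
#' (equivalently ascending p for the test methods); ties break by SNP ID.
#'
#' @param G a `genotype_matrix`
#' @param breeds breed table covering the individuals of `G`
#' @param method one of `"chi2"`, `"fisher"`, `"mutual_info"`,
#'   `"entropy_gain"`
#' @param mc_reps Monte-Carlo table count for the large-table Fisher fallback
#' @param seed seed for the Monte-Carlo fallback
#' @return a `snp_scores` data frame: `snp_id`, `method`, `statistic`,
#'   `p_value` (NA for information methods), `rank`
#' @export
snp_association_scores <- function(G, breeds,
                                   method = c("chi2", "fisher", "mutual_info",
                                              "entropy_gain"),
                                   mc_reps = 1e5, seed = 1) {
  method <- match.arg(method)
  fac <- breed_factor(G, breeds)
  if (nlevels(fac) < 2) stop("need at least two breeds to score SNPs")
  X <- G$dosages
  cnt <- allele_counts_by_breed(G, fac)
  tot_alt <- colSums(cnt$alt)
  tot_all <- colSums(cnt$tot)
  informative <- tot_all > 0 & tot_alt > 0 & tot_alt < tot_all
  if (any(!informative))
    warning(sum(!informative), " monomorphic or all-missing SNP(s) excluded")
  keep <- which(informative)
  ids <- snp_ids(G)[keep]
  stat <- p <- rep(NA_real_, length(keep))

  if (method == "chi2") {
    C <- nlevels(fac)
    chi <- numeric(length(keep))
    for (i in seq_along(keep)) {
      j <- keep[i]
      O <- rbind(cnt$alt[, j], cnt$tot[, j] - cnt$alt[, j])
      O <- O[, colSums(O) > 0, drop = FALSE]
      E <- outer(rowSums(O), colSums(O)) / sum(O)
      chi[i] <- sum((O - E)^2 / E)
    }
    stat <- chi
    p <- stats::pchisq(chi, df = C - 1, lower.tail = FALSE)
  } else if (method == "fisher") {
    set.seed(seed)
    for (i in seq_along(keep)) {
      j <- keep[i]
      O <- rbind(cnt$alt[, j], cnt$tot[, j] - cnt$alt[, j])
      O <- O[, colSums(O) > 0, drop = FALSE]
      exact <- ncol(O) <= 3 && sum(O) <= 60
      p[i] <- if (exact) stats::fisher.test(O)$p.value
              else stats::fisher.test(O, simulate.p.value = TRUE,
                                      B = mc_reps)$p.value
    }
    stat <- -log10(p)
  } else {                          # mutual_info / entropy_gain
    for (i in seq_along(keep)) {
      j <- keep[i]
      ok <- !is.na(X[, j])
      tab <- table(factor(X[ok, j], levels = 0:2), fac[ok])
      stat[i] <- if (method == "mutual_info") mi_bits(tab)
                 else {              # H(breed) - H(breed | genotype class)
                   n <- sum(tab)
                   hb <- entropy_bits(colSums(tab) / n)
                   hcond <- sum(vapply(seq_len(nrow(tab)), function(r) {
                     nr <- sum(tab[r, ])
                     if (nr == 0) 0 else (nr / n) * entropy_bits(tab[r, ] / nr)
                   }, numeric(1)))
                   hb - hcond
                 }
    }
  }
  ord <- order(if (all(is.na(p))) -stat else p, ids)
  out <- data.frame(snp_id = ids, method = method, statistic = stat,
                    p_value = p, stringsAsFactors = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("snp_scores", "data.frame")
  out
}

#' Prune SNPs correlated with higher-ranked SNPs
#'
#' Greedy scan in rank order: a SNP is dropped when the squared Pearson
#' correlation of its dosages (pairwise-complete observations) with any
#' already-kept SNP exceeds `r2_threshold`.
#'
#' @param G the `genotype_matrix` the scores came from
#' @param scores a `snp_scores` table
#' @param r2_threshold squared-correlation threshold in (0, 1]
#' @return the pruned `snp_scores` table, ranks renumbered
#' @export
redundancy_prune <- function(G, scores, r2_threshold = 0.9) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]")
  X <- G$dosages[, scores$snp_id, drop = FALSE]
  storage.mode(X) <- "double"
  kept <- integer(0)
  for (i in seq_len(ncol(X))) {
    if (length(kept)) {
      r <- suppressWarnings(stats::cor(X[, i], X[, kept, drop = FALSE],
                                       use = "pairwise.complete.obs"))
      r[!is.finite(r)] <- 0
      if (any(r^2 > r2_threshold)) next
    }
    kept <- c(kept, i)
  }
  out <- scores[kept, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "r2_threshold") <- r2_threshold
  out
}

#' Cut the top of a ranked SNP table into a panel
#'
#' @param scores a `snp_scores` table (rank order respected)
#' @param fraction keep the top `round(fraction * m)` SNPs
#' @param count keep exactly this many top SNPs (overrides `fraction`)
#' @return a `snp_panel`: list with `snp_ids` (in rank order), `method`,
#'   `fraction`, `count`
#' @export
select_top <- function(scores, fraction = NULL, count = NULL) {
  m <- nrow(scores)
  if (is.null(count)) {
    if (is.null(fraction)) stop("give either fraction or count")
    if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
    count <- max(1L, round(fraction * m))
  }
  if (count < 1 || count > m)
    stop("count = ", count, " outside 1..", m)
  ord <- scores[order(scores$rank), , drop = FALSE]
  structure(list(snp_ids = ord$snp_id[seq_len(count)],
                 method = scores$method[1],
                 fraction = fraction, count = as.integer(count)),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("snp_panel:", length(x$snp_ids), "SNPs (method:", x$method, ")\n")
  invisible(x)
}
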