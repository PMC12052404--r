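# Shared fixture builders: everything is generated in code at test time.

# write a small HapMap file from a header + per-SNP rows given as lists
write_toy_hapmap <- function(path, ids, snps) {
  header <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
              "center", "protLSID", "assayLSID", "panelLSID", "QCcode")
  lines <- paste(c(header, ids), collapse = "\t")
  for (s in snps)
    lines <- c(lines, paste(c(s$id, s$alleles, s$chrom %||% "1",
                              s$pos %||% 1, "+", "NA", "NA", "NA", "NA",
                              "NA", "NA", s$calls), collapse = "\t"))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny genotype_matrix straight from a dosage matrix
toy_G <- function(dos, ids = NULL, snp_ids = NULL) {
  n <- nrow(dos); m <- ncol(dos)
  rownames(dos) <- ids %||% sprintf("S%d", seq_len(n))
  genotype_matrix(dos, data.frame(
    id = snp_ids %||% sprintf("snp%d", seq_len(m)), chrom = "1",
    pos = seq_len(m), ref = "A", alt = "G", stringsAsFactors = FALSE))
}

# standard small simulated dataset used across modules
small_sim <- function(n_breeds = 3, n_per_breed = 12, n_snps = 300,
                      fst = 0.25, seed = 42, ...) {
  simulate_breeds(sim_config(n_breeds = n_breeds, n_per_breed = n_per_breed,
                             n_snps = n_snps, fst = fst, seed = seed, ...))
}

# exact two-sided Fisher p for a 2 x 2 table by hypergeometric enumeration
# (independent of stats::fisher.test)
fisher_2x2_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Fisher p for a 2 x C table by full enumeration of tables
# with the observed margins (probability-mass criterion)
fisher_2xC_enum <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  C <- ncol(tab)
  lfact <- function(x) lgamma(x + 1)
  log_prob <- function(top) {
    bot <- cs - top
    sum(lfact(rs)) + sum(lfact(cs)) - lfact(sum(tab)) -
      sum(lfact(top)) - sum(lfact(bot))
  }
  grids <- lapply(seq_len(C), function(j) 0:cs[j])
  tops <- as.matrix(expand.grid(grids))
  tops <- tops[rowSums(tops) == rs[1], , drop = FALSE]
  lp <- apply(tops, 1, log_prob)
  p_obs <- log_prob(tab[1, ])
  sum(exp(lp[lp <= p_obs + 1e-7]))
}

# brute-force AUC: all-pairs comparison count with half-credit for ties
auc_bruteforce <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# all K! permutations of 1..K (tiny K only)
all_permutations <- function(K) {
  if (K == 1) return(matrix(1))
  sub <- all_permutations(K - 1)
  out <- NULL
  for (i in seq_len(K)) {
    rest <- setdiff(seq_len(K), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
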