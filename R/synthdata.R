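# Balding-Nichols multi-breed genotype simulator.
#
# Per SNP j an ancestral frequency p_j ~ Uniform(range); per breed k a
# breed frequency f_kj ~ Beta(p_j (1-F)/F, (1-p_j)(1-F)/F) with F the
# target FST (so E[f] = p and Var[f] = p (1-p) F); individual dosages are
# Binomial(2, f_kj). Admixed individuals draw from the mixture frequency
# sum_k q_k f_kj. This is the island-model prior matching the admixture
# likelihood, so parameter-recovery tests are coherent end to end.

#' Simulation configuration
#'
#' Defaults emulate the shape of a medium-density SNP-chip multi-breed
#' study scaled to desk size: 10 breeds of 20 individuals at 2,000 SNPs
#' with moderate differentiation (FST 0.15).
#'
#' @param n_breeds number of breeds
#' @param n_per_breed individuals per breed (scalar or one value per breed)
#' @param n_snps number of SNPs
#' @param fst Balding-Nichols differentiation, in (0, 1)
#' @param ancestral_freq_range range of the uniform ancestral frequency draw
#' @param admixed optional list of admixed groups, each
#'   `list(q = <length-n_breeds weights summing to 1>, n = <count>)`
#' @param missing_rate fraction of calls masked as missing, in [0, 1)
#' @param seed integer RNG seed
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_breeds = 10, n_per_breed = 20, n_snps = 2000,
                       fst = 0.15, ancestral_freq_range = c(0.05, 0.95),
                       admixed = NULL, missing_rate = 0, seed = 1) {
  if (n_breeds < 1) stop("invalid n_breeds: must be >= 1")
  if (any(n_per_breed < 0)) stop("invalid n_per_breed: must be >= 0")
  if (!(length(n_per_breed) %in% c(1L, n_breeds)))
    stop("invalid n_per_breed: give one value or one per breed")
  if (n_snps < 1) stop("invalid n_snps: must be >= 1")
  if (!is.finite(fst) || fst <= 0 || fst >= 1)
    stop("invalid fst: must lie in (0, 1)")
  r <- ancestral_freq_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] >= r[2])
    stop("invalid ancestral_freq_range: need 0 < lo < hi < 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("invalid missing_rate: must lie in [0, 1)")
  if (!is.null(admixed))
    for (a in admixed) {
      if (length(a$q) != n_breeds || abs(sum(a$q) - 1) > 1e-8 || any(a$q < 0))
        stop("invalid admixed: each q must be length n_breeds, >= 0, sum 1")
      if (is.null(a$n) || a$n < 1) stop("invalid admixed: each n must be >= 1")
    }
  structure(list(n_breeds = n_breeds,
                 n_per_breed = rep_len(n_per_breed, n_breeds),
                 n_snps = n_snps, fst = fst,
                 ancestral_freq_range = r, admixed = admixed,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_config")
}

#' Simulate a multi-breed genotype dataset
#'
#' @param config a [sim_config()]
#' @return list with `genotypes` (a `genotype_matrix`), `breeds` (breed
#'   table), `geo` (geography table with grid coordinates), and `truth`
#'   (list: ancestral `p`, breed-frequency matrix `F`, true ancestry `Q`)
#' @export
simulate_breeds <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_breeds; m <- config$n_snps; F <- config$fst
  breed_names <- sprintf("Breed%02d", seq_len(K))
  p <- stats::runif(m, config$ancestral_freq_range[1],
                    config$ancestral_freq_range[2])
  Fm <- matrix(stats::rbeta(K * m, rep(p * (1 - F) / F, each = K),
                            rep((1 - p) * (1 - F) / F, each = K)),
               K, m, dimnames = list(breed_names, NULL))

  ids <- character(0); labels <- character(0); Qrows <- list()
  dos <- NULL
  for (k in seq_len(K)) {
    nk <- config$n_per_breed[k]
    if (nk == 0) next
    g <- matrix(stats::rbinom(nk * m, 2, rep(Fm[k, ], each = nk)), nk, m)
    dos <- rbind(dos, g)
    ids <- c(ids, sprintf("%s_I%03d", breed_names[k], seq_len(nk)))
    labels <- c(labels, rep(breed_names[k], nk))
    Qrows <- c(Qrows, rep(list(as.numeric(seq_len(K) == k)), nk))
  }
  if (!is.null(config$admixed))
    for (ai in seq_along(config$admixed)) {
      a <- config$admixed[[ai]]
      fmix <- as.numeric(a$q %*% Fm)
      g <- matrix(stats::rbinom(a$n * m, 2, rep(fmix, each = a$n)), a$n, m)
      dos <- rbind(dos, g)
      ids <- c(ids, sprintf("Admixed%02d_I%03d", ai, seq_len(a$n)))
      labels <- c(labels, rep(sprintf("Admixed%02d", ai), a$n))
      Qrows <- c(Qrows, rep(list(a$q), a$n))
    }
  if (is.null(dos)) dos <- matrix(integer(0), 0, m)
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(dos)) < config$missing_rate
    dos[mask] <- NA_integer_
  }
  rownames(dos) <- ids
  snps <- data.frame(id = sprintf("snp%05d", seq_len(m)), chrom = "1",
                     pos = 1000L * seq_len(m), ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  colnames(Fm) <- snps$id
  G <- genotype_matrix(dos, snps)
  breeds <- data.frame(ID = ids, breed = labels, stringsAsFactors = FALSE)
  all_groups <- unique(labels)
  ng <- length(all_groups)
  geo <- data.frame(
    breed = all_groups,
    Latitude = round(seq(-60, 60, length.out = max(ng, 2))[seq_len(ng)], 4),
    Longitude = round(seq(-150, 150, length.out = max(ng, 2))[seq_len(ng)], 4),
    Location = paste("Site", seq_len(ng)),
    stringsAsFactors = FALSE)
  Q <- do.call(rbind, Qrows)
  if (is.null(Q)) Q <- matrix(numeric(0), 0, K)
  dimnames(Q) <- list(ids, breed_names)
  list(genotypes = G, breeds = breeds, geo = geo,
       truth = list(p = p, F = Fm, Q = Q))
}

#' Uniform-random genotypes sharing a SNP set
#'
#' Dosages i.i.d. uniform over {0, 1, 2}; used to exercise the one-class
#' screen with genotypes unlike any breed.
#'
#' @param n number of individuals (0 allowed)
#' @param snps SNP metadata data frame (e.g. `G$snps` of a reference
#'   dataset) so the SNP IDs line up with a trained panel
#' @param seed integer RNG seed
#' @return a `genotype_matrix`
#' @export
random_genotypes <- function(n, snps, seed = 1) {
  set.seed(seed)
  m <- nrow(snps)
  dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  rownames(dos) <- if (n) sprintf("rand_I%03d", seq_len(n)) else character(0)
  genotype_matrix(dos, snps)
}

#' Write a simulated dataset as the three standard input files
#'
#' Emits `genotype.hmp.txt` (HapMap), `classification.txt` (breed table)
#' and `location.txt` (geography table) into `outdir`. Deterministic: the
#' same config produces byte-identical files.
#'
#' @param outdir output directory (created if needed)
#' @param config a [sim_config()]
#' @return named character vector of the three file paths, invisibly
#' @export
write_fixture_suite <- function(outdir, config = sim_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_breeds(config)
  paths <- c(genotypes = file.path(outdir, "genotype.hmp.txt"),
             breeds = file.path(outdir, "classification.txt"),
             geo = file.path(outdir, "location.txt"))
  write_hapmap(sim$genotypes, paths["genotypes"])
  write_table(sim$breeds, paths["breeds"])
  write_table(sim$geo, paths["geo"])
  invisible(paths)
}

#' Hudson estimator of pairwise FST between two breeds
#'
#' Ratio-of-averages Hudson estimator from allele frequencies and sample
#' sizes; used to verify that simulated differentiation matches the
#' configured value.
#'
#' @param G a `genotype_matrix`
#' @param breeds breed table
#' @param breed_a,breed_b the two breed labels to compare
#' @return scalar FST estimate
#' @export
hudson_fst <- function(G, breeds, breed_a, breed_b) {
  fac <- breed_factor(G, breeds)
  X <- G$dosages
  stats_for <- function(b) {
    Xb <- X[fac == b, , drop = FALSE]
    nall <- 2 * colSums(!is.na(Xb))
    p <- colSums(Xb, na.rm = TRUE) / nall
    list(p = p, n = nall)
  }
  a <- stats_for(breed_a); b <- stats_for(breed_b)
  ok <- a$n > 1 & b$n > 1 & is.finite(a$p) & is.finite(b$p)
  num <- (a$p - b$p)^2 -
    a$p * (1 - a$p) / (a$n - 1) - b$p * (1 - b$p) / (b$n - 1)
  den <- a$p * (1 - b$p) + b$p * (1 - a$p)
  sum(num[ok & den > 0]) / sum(den[ok & den > 0])
}
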