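# Sample-size guidance and class balancing.
#
# The effect model is a per-SNP two-proportion z-test on allele frequencies:
# each individual contributes two alleles, so n individuals per breed give
# 2n alleles per group.

#' Power specification for the per-breed sample-size recommendation
#'
#' @param delta detectable allele-frequency difference, in (0, 1)
#' @param alpha two-sided test size, in (0, 1)
#' @param power target power, in (0, 1)
#' @return a validated `power_spec` list
#' @export
power_spec <- function(delta = 0.2, alpha = 0.05, power = 0.8) {
  for (v in c(delta = delta, alpha = alpha, power = power))
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop("power_spec values must lie strictly in (0, 1)")
  structure(list(delta = delta, alpha = alpha, power = power),
            class = "power_spec")
}

#' Recommended minimum individuals per breed
#'
#' Smallest per-breed sample size n such that a two-proportion z-test on
#' allele counts (2n alleles per group, pooled standard error) detects an
#' allele-frequency difference `delta` between `p_base` and `p_base - delta`
#' at size `alpha` with the target power. The normal-approximation sample
#' size \eqn{n_a = (z_{1-\alpha/2} + z_{1-\beta})^2 (p_1 q_1 + p_2 q_2) /
#' \delta^2} alleles per group is computed first; with `exact = TRUE`
#' (default) the recommendation is then raised, if needed, until the exact
#' power of the test — evaluated by summing binomial probabilities over all
#' allele-count outcomes — reaches the target.
#'
#' @param spec a [power_spec()]
#' @param p_base baseline allele frequency (group 1); group 2 has
#'   `p_base - delta`
#' @param exact verify and raise the approximation by exact power evaluation
#' @return integer number of individuals per breed (at least 1)
#' @export
recommend_min_n <- function(spec = power_spec(), p_base = 0.5, exact = TRUE) {
  stopifnot(inherits(spec, "power_spec"))
  p1 <- p_base
  p2 <- p_base - spec$delta
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
    stop("infeasible spec: frequencies ", signif(p1, 4), " and ", signif(p2, 4),
         " must lie strictly in (0, 1)")
  za <- stats::qnorm(1 - spec$alpha / 2)
  zb <- stats::qnorm(spec$power)
  if (za + zb <= 0) return(1L)   # power at or below the test size: floor n = 1
  n_alleles <- (za + zb)^2 * (p1 * (1 - p1) + p2 * (1 - p2)) / spec$delta^2
  n <- max(1L, as.integer(ceiling(ceiling(n_alleles) / 2)))
  if (exact) {
    while (exact_power_two_prop(2L * n, p1, p2, spec$alpha) < spec$power &&
           n < 1e6)
      n <- n + 1L
  }
  n
}

# exact power of the pooled two-proportion z-test with n_alleles per group:
# enumerate both binomial allele counts and sum P(reject)
exact_power_two_prop <- function(n_alleles, p1, p2, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  x <- 0:n_alleles
  ph <- x / n_alleles
  pp <- outer(x, x, "+") / (2 * n_alleles)
  se <- sqrt(pp * (1 - pp) * 2 / n_alleles)
  stat <- abs(outer(ph, ph, "-")) / se
  rej <- !is.na(stat) & se > 0 & stat > z
  sum(outer(stats::dbinom(x, n_alleles, p1),
            stats::dbinom(x, n_alleles, p2)) * rej)
}

#' Balance per-breed sample sizes
#'
#' `"up"` resamples every breed with replacement to the largest class size
#' (all originals retained; duplicated individuals get `__dupK` ID suffixes
#' to keep IDs unique); `"down"` subsamples without replacement to the
#' smallest class size. Seeded and reproducible.
#'
#' @param G a `genotype_matrix`
#' @param breeds breed table covering all individuals of `G`
#' @param strategy `"up"` or `"down"`
#' @param seed integer RNG seed
#' @return list with rebalanced `genotypes` and `breeds`
#' @export
balance_breeds <- function(G, breeds, strategy = c("down", "up"), seed = 1) {
  strategy <- match.arg(strategy)
  fac <- breed_factor(G, breeds)
  counts <- table(fac)
  if (length(counts) < 2) stop("need at least two breeds to balance")
  if (any(counts == 0)) stop("breed with zero individuals: ",
                             paste(names(counts)[counts == 0], collapse = ", "))
  target <- if (strategy == "up") max(counts) else min(counts)
  ids <- individual_ids(G)
  set.seed(seed)
  pick <- unlist(lapply(levels(fac), function(b) {
    bi <- ids[fac == b]
    if (strategy == "down") sample(bi, target)
    else c(bi, sample(bi, target - length(bi), replace = TRUE))
  }), use.names = FALSE)
  new_ids <- make.unique(pick, sep = "__dup")
  dos <- G$dosages[pick, , drop = FALSE]
  rownames(dos) <- new_ids
  b2 <- data.frame(ID = new_ids, breed = breeds$breed[match(pick, breeds$ID)],
                   stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dos, G$snps), breeds = b2)
}
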