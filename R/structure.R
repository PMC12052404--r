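# Admixture-style ancestry inference.
#
# Model: dosage g_ij ~ Binomial(2, sum_k q_ik f_kj) — the classic
# STRUCTURE/ADMIXTURE frequency model with per-individual ancestry
# proportions Q (rows sum to 1) and per-cluster allele frequencies F.
# Maximization is by EM; missing dosages are simply skipped in the
# likelihood and the update sums.

F_EPS <- 1e-6

admix_loglik <- function(G01, obs, Q, F) {
  P <- Q %*% F
  P <- pmin(pmax(P, F_EPS), 1 - F_EPS)
  sum((G01 * log(P) + (2 - G01) * log1p(-P))[obs])
}

#' Fit the admixture model for a given K
#'
#' EM maximization of the binomial admixture log-likelihood
#' \eqn{\ell = \sum_{ij} [ g_{ij} \log \sum_k q_{ik} f_{kj} + (2 - g_{ij})
#' \log \sum_k q_{ik} (1 - f_{kj}) ]}. The best of `restarts` seeded random
#' initializations is returned. Allele frequencies are clamped to
#' \eqn{[10^{-6}, 1 - 10^{-6}]} each iteration; convergence is declared when
#' the log-likelihood improves by less than `tol`.
#'
#' @param G a `genotype_matrix` (missing dosages allowed)
#' @param K number of ancestral clusters (>= 1)
#' @param seed integer RNG seed
#' @param restarts number of random initializations
#' @param tol absolute log-likelihood convergence tolerance
#' @param max_iter maximum EM iterations per restart
#' @return an `admixture_fit`: list with `K`, `Q` (n x K), `F` (K x m),
#'   `loglik`, `loglik_trace`, `iterations`, `converged`
#' @export
fit_admixture <- function(G, K, seed = 1, restarts = 5, tol = 1e-6,
                          max_iter = 500) {
  X <- G$dosages
  n <- nrow(X); m <- ncol(X)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K = ", K, " exceeds the number of individuals (", n, ")")
  storage.mode(X) <- "double"
  obs <- !is.na(X)
  G01 <- X; G01[!obs] <- 0

  if (K == 1) {            # closed-form single-population MLE
    fj <- colSums(G01) / pmax(2 * colSums(obs), 1)
    fj <- pmin(pmax(fj, F_EPS), 1 - F_EPS)
    Q <- matrix(1, n, 1, dimnames = list(rownames(X), "K1"))
    F <- matrix(fj, 1, m, dimnames = list("K1", colnames(X)))
    ll <- admix_loglik(G01, obs, Q, F)
    return(structure(list(K = 1L, Q = Q, F = F, loglik = ll,
                          loglik_trace = ll, iterations = 0L,
                          converged = TRUE),
                     class = "admixture_fit"))
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    F <- matrix(stats::runif(K * m, 0.1, 0.9), K, m)
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    it <- 0L
    Gm <- G01            # alt-allele counts, 0 at missing
    Hm <- (2 - G01) * obs # ref-allele counts, 0 at missing
    denomQ <- 2 * rowSums(obs)
    for (it in seq_len(max_iter)) {
      P <- Q %*% F
      P <- pmin(pmax(P, F_EPS), 1 - F_EPS)
      RA <- Gm / P        # alt-allele responsibilities scale
      RB <- Hm / (1 - P)
      E1 <- Q * (RA %*% t(F))        # expected alt alleles from cluster k
      E0 <- Q * (RB %*% t(1 - F))    # expected ref alleles from cluster k
      Qn <- (E1 + E0) / denomQ
      Fa <- F * (t(Q) %*% RA)        # per-cluster alt-allele expectations
      Fb <- (1 - F) * (t(Q) %*% RB)
      Fn <- Fa / (Fa + Fb)
      Fn[!is.finite(Fn)] <- 0.5
      Q <- Qn / rowSums(Qn)          # guard against drift from clamping
      F <- pmin(pmax(Fn, F_EPS), 1 - F_EPS)
      ll <- admix_loglik(G01, obs, Q, F)
      trace <- c(trace, ll)
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) { converged <- TRUE; break }
      ll_prev <- ll
    }
    fit <- list(K = as.integer(K), Q = Q, F = F, loglik = trace[length(trace)],
                loglik_trace = trace, iterations = it, converged = converged)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  dimnames(best$Q) <- list(rownames(X), paste0("K", seq_len(K)))
  dimnames(best$F) <- list(paste0("K", seq_len(K)), colnames(X))
  class(best) <- "admixture_fit"
  best
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, "| loglik =", format(x$loglik),
      "|", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Cross-validated choice of the number of clusters K
#'
#' For each replicate a random fraction of the non-missing genotype entries
#' is masked, the model is fitted on the remainder for every candidate K,
#' and the masked dosages are predicted as \eqn{2 \sum_k \hat q_{ik} \hat
#' f_{kj}}. The CV error for K is the mean squared deviation between
#' predicted and held-out dosages, averaged over replicates; the chosen K is
#' the argmin (lowest K on ties).
#'
#' @param G a `genotype_matrix`
#' @param k_values candidate K values
#' @param mask_fraction fraction of entries masked per replicate, in (0, 0.5)
#' @param reps number of masking replicates
#' @param seed integer RNG seed
#' @param restarts,tol,max_iter EM settings for the inner fits (lighter
#'   defaults than [fit_admixture()]: the CV surface needs relative, not
#'   absolute, likelihood precision)
#' @return a `k_selection`: list with `k_values`, `cv_error`, `chosen_k`
#' @export
cv_error <- function(G, k_values = 1:5, mask_fraction = 0.1, reps = 3,
                     seed = 1, restarts = 2, tol = 1e-5, max_iter = 200) {
  if (mask_fraction <= 0 || mask_fraction >= 0.5)
    stop("mask_fraction must lie in (0, 0.5)")
  X <- G$dosages
  nonmiss <- which(!is.na(X))
  err <- matrix(NA_real_, reps, length(k_values))
  for (r in seq_len(reps)) {
    set.seed(seed + 1000L * r)
    masked <- sample(nonmiss, max(1L, round(mask_fraction * length(nonmiss))))
    Xm <- X
    Xm[masked] <- NA_integer_
    Gm <- genotype_matrix(Xm, G$snps)
    for (ki in seq_along(k_values)) {
      fit <- fit_admixture(Gm, k_values[ki], seed = seed + 17L * r + ki,
                           restarts = restarts, tol = tol, max_iter = max_iter)
      pred <- 2 * (fit$Q %*% fit$F)
      err[r, ki] <- mean((pred[masked] - X[masked])^2)
    }
  }
  cv <- colMeans(err)
  structure(list(k_values = k_values, cv_error = cv,
                 chosen_k = k_values[which.min(cv)]),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("K selection by masked-entry cross-validation:\n")
  for (i in seq_along(x$k_values))
    cat(sprintf("  K = %d: CV error %.5f%s\n", x$k_values[i], x$cv_error[i],
                if (x$k_values[i] == x$chosen_k) "  <- chosen" else ""))
  invisible(x)
}

#' Resolve label switching against a reference
#'
#' Permutes the cluster columns of a fit to best match a reference — either
#' another fit with the same K or a vector of population labels (converted
#' to a one-hot ancestry matrix). The permutation maximizes the sum of
#' column correlations via the Hungarian assignment
#' ([clue::solve_LSAP()]).
#'
#' @param fit an `admixture_fit`
#' @param reference an `admixture_fit` with the same K, or a label vector of
#'   length n with exactly K distinct values
#' @return the fit with `Q` columns and `F` rows permuted; the permutation
#'   is stored in `attr(, "permutation")`
#' @export
align_q <- function(fit, reference) {
  Qr <- if (inherits(reference, "admixture_fit")) reference$Q
        else {
          lab <- factor(reference)
          if (nlevels(lab) != fit$K)
            stop("reference has ", nlevels(lab), " labels but fit has K = ", fit$K)
          stats::model.matrix(~ lab - 1)
        }
  if (ncol(Qr) != fit$K) stop("reference K (", ncol(Qr),
                              ") does not match fit K (", fit$K, ")")
  if (nrow(Qr) != nrow(fit$Q)) stop("reference and fit cover different individuals")
  if (fit$K == 1) { attr(fit, "permutation") <- 1L; return(fit) }
  cors <- suppressWarnings(stats::cor(fit$Q, Qr))
  cors[!is.finite(cors)] <- 0
  perm <- as.integer(clue::solve_LSAP(cors - min(cors) + 1, maximum = TRUE))
  inv <- order(perm)   # column j of the result is the fit column matching ref j
  out <- fit
  out$Q <- fit$Q[, inv, drop = FALSE]
  out$F <- fit$F[inv, , drop = FALSE]
  colnames(out$Q) <- rownames(out$F) <- paste0("K", seq_len(fit$K))
  attr(out, "permutation") <- inv
  out
}
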