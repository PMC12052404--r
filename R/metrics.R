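# Classification metrics: accuracy, Cohen's kappa, macro one-vs-rest AUC.

# rank-based two-class AUC with midpoint tie handling
# (equals the Mann-Whitney U statistic / (n1 * n0))
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for multi-class breed predictions
#'
#' Accuracy is the fraction correct; Cohen's kappa is
#' \eqn{(p_o - p_e)/(1 - p_e)} with chance agreement from the marginal
#' products; macro AUC is the unweighted mean of one-vs-rest rank AUCs
#' (midpoint tie handling) over classes present in the truth — classes
#' absent from the truth are excluded with a warning. The confusion matrix
#' has true breeds in rows.
#'
#' @param truth vector of true breed labels
#' @param predicted vector of predicted breed labels
#' @param prob optional n x C matrix of class probabilities (columns named
#'   by breed); required for the AUC
#' @return list with `accuracy`, `kappa`, `macro_auc`, `confusion`
#' @export
evaluate_metrics <- function(truth, predicted, prob = NULL) {
  stopifnot(length(truth) == length(predicted))
  lev <- sort(unique(c(as.character(truth), as.character(predicted),
                       colnames(prob))))
  tf <- factor(truth, levels = lev)
  pf <- factor(predicted, levels = lev)
  confusion <- table(truth = tf, predicted = pf)
  n <- length(truth)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) {
    if (po >= 1 - 1e-12) 1 else 0   # degenerate margins
  } else (po - pe) / (1 - pe)
  macro_auc <- NA_real_
  if (!is.null(prob)) {
    stopifnot(nrow(prob) == n)
    if (any(abs(rowSums(prob) - 1) > 1e-6))
      stop("probability rows must sum to 1")
    present <- lev[lev %in% as.character(truth)]
    absent <- setdiff(colnames(prob), present)
    if (length(absent))
      warning("class(es) absent from truth excluded from macro AUC: ",
              paste(absent, collapse = ", "))
    aucs <- vapply(intersect(present, colnames(prob)), function(cl)
      auc_rank(prob[, cl], as.character(truth) == cl), numeric(1))
    macro_auc <- mean(aucs, na.rm = TRUE)
  }
  list(accuracy = po, kappa = kappa, macro_auc = macro_auc,
       confusion = confusion)
}

#' Stratified k-fold assignment
#'
#' Every individual lands in exactly one test fold; within each breed the
#' fold sizes differ by at most one.
#'
#' @param labels breed labels (length n)
#' @param k number of folds
#' @param seed integer RNG seed
#' @return integer vector of fold indices in 1..k
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  fac <- factor(labels)
  if (any(table(fac) < 2))
    stop("breed(s) with a single individual cannot be stratified: ",
         paste(names(which(table(fac) < 2)), collapse = ", "))
  if (k < 2) stop("k must be >= 2")
  set.seed(seed)
  fold <- integer(length(labels))
  for (b in levels(fac)) {
    idx <- sample(which(fac == b))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}
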