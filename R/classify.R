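# Breed classifiers, cross-validation, one-class validation, and the
# calibrated z-score confidence transform.

#' Calibrated z-score from a raw classifier probability
#'
#' With \eqn{t = P^\alpha / (P^\alpha + (1-P)^\alpha)}: for \eqn{P > 0.5}
#' the z-score is \eqn{t}; for \eqn{P \le 0.5} it is
#' \eqn{t + \alpha (0.5 - t)}. The transform sharpens confident
#' probabilities (\eqn{\alpha > 1}) and is continuous at \eqn{P = 0.5},
#' where both branches give 0.5. Because the low-P branch can exceed 1 for
#' large \eqn{\alpha}, the returned value is clamped to [0, 1]; the
#' unclamped value is kept in `attr(, "raw")`. Note the low-P branch is not
#' monotone in P for \eqn{\alpha > 1}: a very low top-class probability can
#' map to a high z-score, so the score should be read together with the
#' one-class flag.
#'
#' @param P raw top-class probability in [0, 1] (vectorized)
#' @param alpha tuning parameter, > 0 (default 2)
#' @return calibrated z-score(s) in [0, 1], with `attr(, "raw")`
#' @export
calibrate_zscore <- function(P, alpha = 2) {
  if (any(!is.finite(P)) || any(P < 0) || any(P > 1))
    stop("P must lie in [0, 1]")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  t <- P^alpha / (P^alpha + (1 - P)^alpha)
  t[P == 0] <- 0; t[P == 1] <- 1            # 0/0 guards at the endpoints
  z <- ifelse(P > 0.5, t, t + alpha * (0.5 - t))
  out <- pmin(pmax(z, 0), 1)
  attr(out, "raw") <- z
  out
}

parse_cv_scheme <- function(cv) {
  if (is.list(cv)) return(cv)
  parts <- strsplit(cv, ":", fixed = TRUE)[[1]]
  scheme <- parts[1]
  if (scheme == "loo") return(list(scheme = "loo"))
  if (scheme == "kfold")
    return(list(scheme = "kfold", k = as.integer(parts[2])))
  if (scheme == "repeated_kfold") {
    kr <- as.integer(strsplit(parts[2], "x", fixed = TRUE)[[1]])
    return(list(scheme = "repeated_kfold", k = kr[1], times = kr[2]))
  }
  stop("unknown CV scheme: ", cv)
}

# ---- per-algorithm fit/predict -------------------------------------------

fit_algorithm <- function(X, y, algorithm, hp, seed) {
  set.seed(seed)
  switch(algorithm,
    knn = caret::knn3(X, y, k = hp$knn_k %||% 5),
    rf  = randomForest::randomForest(X, y, ntree = hp$rf_trees %||% 500),
    svm = e1071::svm(X, y, kernel = "radial", probability = TRUE,
                     cost = hp$svm_cost %||% 1),
    xgb = {
      bst <- xgboost::xgboost(
        X, y, nrounds = hp$xgb_rounds %||% 200,
        max_depth = hp$xgb_depth %||% 6,
        learning_rate = hp$xgb_eta %||% 0.3,
        nthreads = 1, verbosity = 0)
      attr(bst, "levels") <- levels(y)
      bst
    },
    stop("unknown algorithm: ", algorithm))
}

predict_prob <- function(fitted, algorithm, X, levels) {
  # S3 predict methods live in the backend namespaces; make sure the right
  # one is loaded even when `fitted` arrived via readRDS in a fresh session
  requireNamespace(switch(algorithm, knn = "caret", rf = "randomForest",
                          svm = "e1071", xgb = "xgboost"), quietly = TRUE)
  P <- switch(algorithm,
    knn = stats::predict(fitted, X, type = "prob"),
    rf  = stats::predict(fitted, X, type = "prob"),
    svm = {
      pr <- stats::predict(fitted, X, probability = TRUE)
      attr(pr, "probabilities")
    },
    xgb = {
      raw <- stats::predict(fitted, X)
      lev <- attr(fitted, "levels")
      if (is.matrix(raw)) raw
      else {            # binary: vector of second-level probabilities
        M <- cbind(1 - raw, raw)
        colnames(M) <- lev
        M
      }
    })
  P <- P[, levels, drop = FALSE]                 # fixed column order
  P / rowSums(P)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- one-class screen -----------------------------------------------------

# per-breed smoothed panel allele frequencies (add-one on alleles) and the
# mean per-SNP binomial log-likelihood score
one_class_fit <- function(X, y) {
  freqs <- lapply(levels(y), function(b) {
    Xb <- X[y == b, , drop = FALSE]
    nalle <- 2 * colSums(!is.na(Xb))
    alt <- colSums(Xb, na.rm = TRUE)
    (alt + 1) / (nalle + 2)
  })
  names(freqs) <- levels(y)
  freqs
}

one_class_score <- function(dosages, freqs) {
  ok <- !is.na(dosages)
  if (!any(ok)) return(-Inf)
  mean(stats::dbinom(dosages[ok], 2, freqs[ok], log = TRUE))
}

#' One-class validation of a genotype against the model's breeds
#'
#' Scores a dosage vector under the predicted breed's smoothed panel allele
#' frequencies (mean per-SNP binomial log-likelihood) and compares it with
#' the breed's threshold — the 1st percentile of the breed's own training
#' scores. Rows with more than 50% missing panel SNPs fail automatically
#' with reason `"low-quality"`.
#'
#' @param model a `classifier_model` from [train_classifier()]
#' @param dosages numeric vector of panel dosages (NA = missing), in panel
#'   SNP order
#' @param breed breed whose threshold to test against
#' @return list with `pass`, `score`, `threshold`, `reason`
#' @export
one_class_check <- function(model, dosages, breed) {
  if (!breed %in% names(model$one_class$freqs)) stop("unknown breed: ", breed)
  if (mean(is.na(dosages)) > 0.5)
    return(list(pass = FALSE, score = NA_real_,
                threshold = model$one_class$thresholds[[breed]],
                reason = "low-quality"))
  sc <- one_class_score(dosages, model$one_class$freqs[[breed]])
  th <- model$one_class$thresholds[[breed]]
  list(pass = sc >= th, score = sc, threshold = th,
       reason = if (sc >= th) "" else "unlike-training-breed")
}

# ---- training -------------------------------------------------------------

panel_matrix <- function(G, panel_ids) {
  missing_snps <- setdiff(panel_ids, snp_ids(G))
  have <- intersect(panel_ids, snp_ids(G))
  if (!length(have)) stop("no panel SNPs present in the genotype matrix")
  X <- matrix(NA_real_, nrow(G$dosages), length(panel_ids),
              dimnames = list(individual_ids(G), panel_ids))
  X[, have] <- G$dosages[, have, drop = FALSE]
  X
}

impute_with_means <- function(X, means) {
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- means[idx[, 2]]
  X
}

#' Train a breed classifier on a SNP panel
#'
#' Fits one of four classifiers (KNN, random forest, RBF SVM with
#' probability outputs, XGBoost) on the panel dosages, reports stratified
#' cross-validated performance (pooled accuracy, per-fold accuracies,
#' Cohen's kappa, macro one-vs-rest AUC, confusion matrix), then refits on
#' all data and calibrates the one-class thresholds. Missing dosages are
#' imputed with training-fold means inside CV and full-data means in the
#' final model.
#'
#' @param G training `genotype_matrix`
#' @param breeds breed table covering the individuals of `G`
#' @param panel a `snp_panel` (or character vector of SNP IDs)
#' @param algorithm `"knn"`, `"rf"`, `"svm"` or `"xgb"`
#' @param cv CV scheme string: `"kfold:5"`, `"repeated_kfold:5x5"`, `"loo"`
#' @param seed integer RNG seed
#' @param alpha z-score calibration tuning parameter (> 0, default 2)
#' @param hyperparams optional named list: `knn_k`, `rf_trees`, `svm_cost`,
#'   `xgb_rounds`, `xgb_depth`, `xgb_eta`
#' @return list with `model` (a `classifier_model`) and `cv` (a `cv_report`)
#' @export
train_classifier <- function(G, breeds, panel, algorithm = c("rf", "knn",
                             "svm", "xgb"), cv = "kfold:5", seed = 1,
                             alpha = 2, hyperparams = list()) {
  algorithm <- match.arg(algorithm)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  panel_ids <- if (inherits(panel, "snp_panel")) panel$snp_ids
               else as.character(panel)
  if (!length(panel_ids)) stop("empty SNP panel")
  missing_snps <- setdiff(panel_ids, snp_ids(G))
  if (length(missing_snps))
    stop("panel SNP(s) absent from training genotypes: ",
         paste(utils::head(missing_snps, 5), collapse = ", "),
         if (length(missing_snps) > 5) ", ...")
  y <- breed_factor(G, breeds)
  X <- panel_matrix(G, panel_ids)
  n <- nrow(X)
  scheme <- parse_cv_scheme(cv)
  if (scheme$scheme == "loo" && n > 10000)
    stop("leave-one-out with n = ", n, " individuals is impractical; ",
         "use kfold:5 or repeated_kfold:5x5 instead")

  fold_sets <- switch(scheme$scheme,
    loo = list(seq_len(n)),
    kfold = list(stratified_folds(y, scheme$k, seed)),
    repeated_kfold = lapply(seq_len(scheme$times), function(r)
      stratified_folds(y, scheme$k, seed + r - 1L)))

  pooled_truth <- character(0); pooled_pred <- character(0)
  pooled_prob <- NULL
  fold_acc <- numeric(0)
  for (rep_i in seq_along(fold_sets)) {
    fold <- fold_sets[[rep_i]]
    for (f in sort(unique(fold))) {
      test <- which(fold == f); train <- which(fold != f)
      mu <- colMeans(X[train, , drop = FALSE], na.rm = TRUE)
      mu[!is.finite(mu)] <- 1                  # all-missing column fallback
      Xtr <- impute_with_means(X[train, , drop = FALSE], mu)
      Xte <- impute_with_means(X[test, , drop = FALSE], mu)
      fit <- fit_algorithm(Xtr, droplevels(y[train]), algorithm, hyperparams,
                           seed + 7919L * rep_i + f)
      P <- predict_prob(fit, algorithm, Xte, levels(droplevels(y[train])))
      full <- matrix(0, nrow(P), nlevels(y),
                     dimnames = list(NULL, levels(y)))
      full[, colnames(P)] <- P
      pred <- colnames(full)[max.col(full, ties.method = "first")]
      pooled_truth <- c(pooled_truth, as.character(y[test]))
      pooled_pred <- c(pooled_pred, pred)
      pooled_prob <- rbind(pooled_prob, full)
      fold_acc <- c(fold_acc, mean(pred == as.character(y[test])))
    }
  }
  met <- evaluate_metrics(pooled_truth, pooled_pred, pooled_prob)
  cv_report <- structure(list(
    scheme = scheme, fold_accuracy = fold_acc,
    accuracy = met$accuracy, kappa = met$kappa, macro_auc = met$macro_auc,
    confusion = met$confusion, seed = seed), class = "cv_report")

  mu <- colMeans(X, na.rm = TRUE)
  mu[!is.finite(mu)] <- 1
  Xall <- impute_with_means(X, mu)
  fit <- fit_algorithm(Xall, y, algorithm, hyperparams, seed)
  freqs <- one_class_fit(X, y)
  # training scores are jackknifed (each individual's alleles removed from
  # its breed's frequency estimate) so the threshold calibrated on them
  # transfers to genuinely new individuals instead of inheriting the
  # in-sample bias of the full-sample frequencies
  scores <- vapply(seq_len(n), function(i) {
    b <- as.character(y[i])
    Xb <- X[y == y[i], , drop = FALSE]
    alt <- colSums(Xb, na.rm = TRUE)
    nalle <- 2 * colSums(!is.na(Xb))
    gi <- X[i, ]
    ok <- !is.na(gi)
    floo <- (alt[ok] - gi[ok] + 1) / (nalle[ok] - 2 + 2)
    one_class_score(gi[ok], floo)
  }, numeric(1))
  thresholds <- vapply(levels(y), function(b)   # inverse-ECDF 1st percentile:
    stats::quantile(scores[y == b], 0.01, names = FALSE, type = 1), numeric(1))
  model <- structure(list(
    algorithm = algorithm, panel = panel_ids, fitted = fit,
    breed_levels = levels(y), impute_means = mu, alpha = alpha,
    hyperparams = hyperparams, seed = seed,
    one_class = list(freqs = freqs,
                     thresholds = as.list(thresholds))),
    class = "classifier_model")
  list(model = model, cv = cv_report)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%s): accuracy %.4f | kappa %.4f | macro AUC %.4f\n",
              x$scheme$scheme, x$accuracy, x$kappa, x$macro_auc))
  invisible(x)
}

#' @export
print.classifier_model <- function(x, ...) {
  cat("classifier_model:", x$algorithm, "|", length(x$panel), "panel SNPs |",
      length(x$breed_levels), "breeds | alpha =", x$alpha, "\n")
  invisible(x)
}

#' Predict breeds for new individuals
#'
#' Applies a trained model to new genotypes: panel SNPs absent from the new
#' data count as missing (and against the one-class quality check); missing
#' entries are imputed with the training means for classification. Per
#' individual the result carries the predicted breed, the raw top-class
#' probability P, the calibrated z-score, the one-class outcome, and the
#' full probability vector; when a geography table is given its coordinates
#' are joined on the predicted breed.
#'
#' @param model a `classifier_model`
#' @param G_new `genotype_matrix` of query individuals
#' @param geo optional geography table (see [read_geo_table()])
#' @return a `prediction_result` data frame: `ID`, `breed`, `P`, `z_score`,
#'   `one_class_pass`, `one_class_score`, `one_class_reason`, per-breed
#'   `prob.*` columns, and geo columns when joined
#' @export
predict_new <- function(model, G_new, geo = NULL) {
  X <- panel_matrix(G_new, model$panel)
  Xi <- impute_with_means(X, model$impute_means)
  P <- predict_prob(model$fitted, model$algorithm, Xi, model$breed_levels)
  pred <- model$breed_levels[max.col(P, ties.method = "first")]
  top <- P[cbind(seq_len(nrow(P)), max.col(P, ties.method = "first"))]
  z <- as.numeric(calibrate_zscore(top, model$alpha))
  oc <- lapply(seq_len(nrow(X)), function(i)
    one_class_check(model, X[i, ], pred[i]))
  out <- data.frame(
    ID = individual_ids(G_new), breed = pred, P = top, z_score = z,
    one_class_pass = vapply(oc, `[[`, logical(1), "pass"),
    one_class_score = vapply(oc, `[[`, numeric(1), "score"),
    one_class_reason = vapply(oc, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  prob <- as.data.frame(P)
  names(prob) <- paste0("prob.", model$breed_levels)
  out <- cbind(out, prob)
  if (!is.null(geo)) {
    idx <- match(out$breed, geo$breed)
    out$Latitude <- geo$Latitude[idx]
    out$Longitude <- geo$Longitude[idx]
    out$Location <- geo$Location[idx]
  }
  rownames(out) <- NULL
  class(out) <- c("prediction_result", "data.frame")
  out
}
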