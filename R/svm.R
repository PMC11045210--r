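# RBF-SVM classification gate: stratified 80/20 split, decade-spaced grid
# tuning of (gamma, C) by stratified 10-fold cross-validation, and a
# confusion-matrix report with kappa / specificity / no-information-rate
# acceptance gates. Plus ROC-AUC and PCA variance-coverage diagnostics.

#' Stratified train/test split
#'
#' Per class, `round(train_frac * class size)` samples go to training; the
#' split is reproducible for a fixed seed and leaves the caller's RNG state
#' untouched.
#'
#' @param labels Class label per sample (each class needs >= 5 samples).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed) {
  labels <- as.character(labels)
  tabs <- table(labels)
  if (any(tabs < 5)) stop("every class needs >= 5 samples to split")
  train <- with_seed(seed, {
    unlist(lapply(names(tabs), function(cl) {
      idx <- which(labels == cl)
      sample(idx, round(train_frac * length(idx)))
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' RBF-SVM tuning grid
#'
#' Decade-spaced defaults: gamma over 1e-6..1e6 and cost over 1e-5..1e5,
#' one point per decade.
#'
#' @param gamma,cost Positive numeric grids.
#' @param cv_folds Cross-validation folds (default 10).
#' @return List of class `tune_grid`.
#' @export
tune_grid <- function(gamma = 10^(-6:6), cost = 10^(-5:5), cv_folds = 10) {
  stopifnot(all(gamma > 0), all(cost > 0), cv_folds >= 2)
  structure(list(gamma = sort(gamma), cost = sort(cost), cv_folds = cv_folds),
            class = "tune_grid")
}

# Standardize train columns; zero-SD columns pass through unscaled.
std_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
std_apply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

#' Fit an RBF-SVM at fixed hyperparameters
#'
#' Features are standardized with training-set mean/SD before fitting (RBF
#' distances on raw FPKM scales are otherwise dominated by the
#' highest-expressed gene).
#'
#' @param X Numeric matrix, samples x features. @param y tumor/normal labels.
#' @param gamma,cost RBF kernel width and soft-margin penalty.
#' @return A `dosig_svm` model usable with [predict()].
#' @export
fit_rbf_svm <- function(X, y, gamma, cost) {
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = c("normal", "tumor"))
  if (nlevels(droplevels(y)) < 2) stop("training data must contain both classes")
  st <- std_fit(X)
  fit <- e1071::svm(std_apply(X, st), y, type = "C-classification",
                    kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  structure(list(fit = fit, std = st, gamma = gamma, cost = cost,
                 features = colnames(X)),
            class = "dosig_svm")
}

#' Predict classes (and decision scores) from a fitted RBF-SVM
#'
#' @param object A `dosig_svm`. @param newdata Samples x features matrix.
#' @param ... Unused.
#' @return Factor of predicted labels with a `"scores"` attribute: signed
#'   decision values oriented so larger means more tumor-like.
#' @export
predict.dosig_svm <- function(object, newdata, ...) {
  Xs <- std_apply(as.matrix(newdata)[, object$features, drop = FALSE], object$std)
  pr <- stats::predict(object$fit, Xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  scores <- dv[, 1]
  if (!startsWith(colnames(dv)[1], "tumor")) scores <- -scores
  attr(pr, "decision.values") <- NULL
  attr(pr, "scores") <- unname(scores)
  pr
}

#' Grid-tune an RBF-SVM by stratified cross-validation
#'
#' Evaluates mean stratified k-fold CV accuracy for every (gamma, cost) pair
#' and returns the maximizer; ties break toward smaller cost, then smaller
#' gamma. Fold assignment derives from the seed and is identical across grid
#' points.
#'
#' @param X Samples x features matrix. @param y tumor/normal labels.
#' @param grid A [tune_grid()]. @param seed Integer seed for fold assignment.
#' @return List with `best_gamma`, `best_cost`, `cv_accuracy`, and the full
#'   `grid_accuracy` data.frame.
#' @export
tune_rbf_svm <- function(X, y, grid = tune_grid(), seed = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  tabs <- table(y)
  if (length(tabs) < 2) stop("training data must contain both classes")
  if (any(tabs < grid$cv_folds))
    stop("each class needs >= cv_folds samples for stratified CV")
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cl in names(tabs)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(grid$cv_folds), length(idx))
    }
    f
  })
  pairs <- expand.grid(cost = grid$cost, gamma = grid$gamma,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[order(pairs$cost, pairs$gamma), ]
  acc <- vapply(seq_len(nrow(pairs)), function(i) {
    correct <- 0L
    for (k in seq_len(grid$cv_folds)) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2) next
      fit <- fit_rbf_svm(X[tr, , drop = FALSE], y[tr],
                         pairs$gamma[i], pairs$cost[i])
      pr <- predict(fit, X[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pr) == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  best <- which.max(acc)  # first max: smaller cost, then smaller gamma
  list(best_gamma = pairs$gamma[best], best_cost = pairs$cost[best],
       cv_accuracy = acc[best],
       grid_accuracy = cbind(pairs, accuracy = acc))
}

#' Confusion-matrix report with acceptance gates
#'
#' Tumor is the positive class. Reports raw counts, accuracy, sensitivity,
#' specificity, Cohen's kappa, the no-information rate (NIR: majority-class
#' proportion in the test set), and the exact one-sided binomial p-value for
#' accuracy exceeding the NIR. The signature is accepted when kappa and
#' specificity both exceed their cutoffs and the binomial p is below its
#' cutoff.
#'
#' @param model A `dosig_svm`. @param X_test,y_test Held-out data (both
#'   classes must be present).
#' @param kappa_cut,spec_cut Gate thresholds (default 0.8).
#' @param p_cut Binomial significance threshold (default 0.05).
#' @return List of class `classifier_report`.
#' @export
evaluate_classifier <- function(model, X_test, y_test, kappa_cut = 0.8,
                                spec_cut = 0.8, p_cut = 0.05) {
  y_test <- as.character(y_test)
  if (length(unique(y_test)) < 2) stop("test set must contain both classes")
  pr <- predict(model, X_test)
  pred <- as.character(pr)
  counts <- list(TP = sum(pred == "tumor" & y_test == "tumor"),
                 FP = sum(pred == "tumor" & y_test == "normal"),
                 TN = sum(pred == "normal" & y_test == "normal"),
                 FN = sum(pred == "normal" & y_test == "tumor"))
  rep <- classifier_report(counts, kappa_cut, spec_cut, p_cut)
  rep$best_gamma <- model$gamma
  rep$best_cost <- model$cost
  rep$scores <- attr(pr, "scores")
  rep
}

#' Build a classifier report from raw confusion counts
#'
#' @param counts List or vector with elements `TP`, `FP`, `TN`, `FN`
#'   (tumor = positive).
#' @inheritParams evaluate_classifier
#' @return List of class `classifier_report` with the derived metrics and
#'   the `accepted` flag.
#' @export
classifier_report <- function(counts, kappa_cut = 0.8, spec_cut = 0.8,
                              p_cut = 0.05) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  TN <- counts[["TN"]]; FN <- counts[["FN"]]
  n <- TP + FP + TN + FN
  acc <- (TP + TN) / n
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  # chance agreement from marginal products
  pe <- ((TP + FP) * (TP + FN) + (TN + FN) * (TN + FP)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  nir <- max(TP + FN, TN + FP) / n
  p_acc <- stats::pbinom(TP + TN - 1, n, nir, lower.tail = FALSE)  # P(X >= correct)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN, n_test = n,
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 kappa = kappa, NIR = nir, p_acc_vs_nir = p_acc,
                 accepted = isTRUE(kappa > kappa_cut && spec > spec_cut &&
                                     p_acc < p_cut)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report (tumor positive): n=%d  acc=%.3f  sens=%.3f  spec=%.3f\n",
              x$n_test, x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  kappa=%.3f  NIR=%.3f  P(acc>NIR)=%.3g  accepted=%s\n",
              x$kappa, x$NIR, x$p_acc_vs_nir, x$accepted))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midranks for tied scores; equals
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric classifier scores (larger = more tumor-like).
#' @param y Labels; `positive` marks the positive class.
#' @param positive Positive-class label (default `"tumor"`).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.35, 0.8, 0.1, 0.4), c("tumor", "tumor", "normal", "normal"))
#' @export
roc_auc <- function(scores, y, positive = "tumor") {
  y <- as.character(y)
  pos <- y == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cumulative PCA variance coverage
#'
#' Fraction of total variance captured by the top `k` principal components
#' of the column-centered matrix. The downstream reproducibility gate
#' passes when the fraction reaches 0.80.
#'
#' @param X Samples x features matrix. @param k Number of components.
#' @return List with `fraction` (cumulative variance fraction) and `pass`
#'   (`fraction >= 0.80`).
#' @export
pca_variance_check <- function(X, k) {
  X <- as.matrix(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot == 0) stop("zero total variance")
  k <- min(k, length(pc$sdev))
  frac <- sum(pc$sdev[seq_len(k)]^2) / tot
  list(fraction = frac, pass = frac >= 0.80)
}
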