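#' Classifier specification
#'
#' Deterministic Gaussian discriminant classifiers: `linear` (shared
#' pooled covariance), `quadratic` (per-class covariance) and
#' `naive_bayes` (per-class independent Gaussians per feature). A
#' ridge `regularisation` is added to every covariance diagonal
#' (default `1e-3 * trace / P`) so that small-sample fits stay
#' invertible.
#'
#' @param family One of `"linear"`, `"quadratic"`, `"naive_bayes"`.
#' @param regularisation Nonnegative ridge weight, as a fraction of
#'   `trace(cov) / P` added to the covariance diagonal.
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("linear", "quadratic", "naive_bayes"),
                            regularisation = 1e-3,
                            priors = c("empirical", "uniform")) {
  family <- match.arg(family)
  priors <- match.arg(priors)
  stopifnot(regularisation >= 0)
  structure(list(family = family, regularisation = regularisation,
                 priors = priors), class = "classifier_spec")
}

#' Fit a deterministic two-class Gaussian discriminant
#'
#' @param train N x P numeric matrix or feature data frame.
#' @param labels Two-class labels; the second factor level is scored
#'   as the positive class.
#' @param spec A [classifier_spec()].
#' @return Object of class `gaussian_classifier` with a
#'   [predict()][predict.gaussian_classifier] method returning
#'   positive-class posterior probabilities.
#' @export
fit_classifier <- function(train, labels, spec = classifier_spec()) {
  X <- feature_matrix(train)
  g <- as_group_factor(labels)
  if (nlevels(g) != 2) stop("need exactly 2 classes", call. = FALSE)
  if (any(table(g) < 2))
    stop("each class needs at least 2 training samples", call. = FALSE)
  P <- ncol(X)
  prior <- if (spec$priors == "empirical") as.numeric(table(g)) / length(g)
           else c(0.5, 0.5)
  mus <- lapply(levels(g), function(lv) colMeans(X[g == lv, , drop = FALSE]))
  covs <- lapply(levels(g), function(lv) stats::cov(X[g == lv, , drop = FALSE]))
  ridge <- function(S) {
    lam <- spec$regularisation * sum(diag(S)) / P
    S + diag(rep(max(lam, 1e-12 * (spec$regularisation > 0)), P), P)
  }
  if (spec$family == "linear") {
    ns <- as.numeric(table(g))
    Sp <- Reduce(`+`, Map(function(S, n) S * (n - 1), covs, ns)) /
      (length(g) - 2)
    Sp <- ridge(Sp)
    covs <- list(Sp, Sp)
  } else if (spec$family == "quadratic") {
    covs <- lapply(covs, ridge)
  } else {
    covs <- lapply(covs, function(S) ridge(diag(diag(S), P)))
  }
  for (S in covs)
    if (rcond_psd(S) < 1e-14)
      stop("singular class covariance; increase `regularisation`",
           call. = FALSE)
  structure(list(spec = spec, levels = levels(g), prior = prior,
                 means = mus, covs = covs, feature_names = colnames(X)),
            class = "gaussian_classifier")
}

rcond_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) 0 else max(min(ev), 0) / max(ev)
}

#' @describeIn fit_classifier Positive-class posterior probabilities
#'   for new data.
#' @param object A `gaussian_classifier`.
#' @param newdata N x P matrix or data frame.
#' @param ... Unused.
#' @export
predict.gaussian_classifier <- function(object, newdata, ...) {
  X <- feature_matrix(newdata, feature_names =
                        if (is.data.frame(newdata)) object$feature_names
                        else NULL)
  ll <- vapply(1:2, function(k) {
    gaussian_loglik(X, object$means[[k]], object$covs[[k]]) +
      log(object$prior[k])
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, 1)
  m <- pmax(ll[, 1], ll[, 2])
  p <- exp(ll[, 2] - m) / (exp(ll[, 1] - m) + exp(ll[, 2] - m))
  unname(p)
}

gaussian_loglik <- function(X, mu, S) {
  L <- chol(S)
  z <- forwardsolve(t(L), t(sweep(X, 2, mu)))
  -0.5 * colSums(z^2) - sum(log(diag(L))) - 0.5 * ncol(X) * log(2 * pi)
}

#' Rank features by univariate group separation
#'
#' Scores every feature by a per-feature two-sample criterion between
#' the two groups — the Kolmogorov-Smirnov statistic (default,
#' matching the projection-based hypothesis testing) or the univariate
#' AUROC folded about 0.5 — and returns the top `k` names. Ties are
#' broken by registry (column) order.
#'
#' @param table Feature tibble or matrix.
#' @param groups Two-group labels.
#' @param k Number of features to keep.
#' @param criterion `"ks"` or `"auc"`.
#' @return Character vector of `k` feature names, best first.
#' @export
select_features <- function(table, groups, k = 5,
                            criterion = c("ks", "auc")) {
  criterion <- match.arg(criterion)
  X <- feature_matrix(table)
  g <- as_group_factor(groups)
  if (nlevels(g) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  k <- min(k, ncol(X))
  score <- vapply(seq_len(ncol(X)), function(j) {
    a <- X[g == levels(g)[1], j]; b <- X[g == levels(g)[2], j]
    if (criterion == "ks") ks_statistic(a, b)
    else abs(auroc_mw(c(a, b), rep(c(FALSE, TRUE), c(length(a),
                                                     length(b)))) - 0.5)
  }, numeric(1))
  ord <- order(-score, seq_along(score))   # stable: ties keep column order
  colnames(X)[ord[seq_len(k)]]
}

# Mann-Whitney AUROC with half weight for score ties
auroc_mw <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

roc_points <- function(scores, positive) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  purrr::map_dfr(ths, function(t) {
    tibble::tibble(threshold = t,
                   fpr = mean(scores[!positive] >= t),
                   tpr = mean(scores[positive] >= t))
  })
}

new_cv_report <- function(scheme, scores, labels, selected = NULL,
                          spec = NULL) {
  pos <- labels == levels(labels)[2]
  roc <- roc_points(scores, pos)
  structure(list(scheme = scheme,
                 per_sample_scores = scores,
                 labels = labels,
                 roc_points = roc,
                 auroc = auroc_mw(scores, pos),
                 selected_features = selected,
                 spec = spec),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, N = %d, AUROC = %.4f\n", x$scheme,
              length(x$per_sample_scores), x$auroc))
  if (!is.null(x$selected_features))
    cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-out cross-validated ROC
#'
#' Scores every sample with a classifier trained on all other samples,
#' sweeps every threshold (including the `(0,0)` and `(1,1)`
#' endpoints) for the ROC curve, and computes the AUROC with the
#' Mann-Whitney convention (score ties count one half). Folds whose
#' training half collapses to one class are skipped with a message.
#'
#' @param table N x P features (N >= 4).
#' @param labels Two-class labels; second level is positive.
#' @param spec A [classifier_spec()].
#' @return A `cv_report`.
#' @export
loocv_roc <- function(table, labels, spec = classifier_spec()) {
  X <- feature_matrix(table)
  g <- as_group_factor(labels)
  if (nlevels(g) != 2) stop("need exactly 2 classes", call. = FALSE)
  if (nrow(X) < 4) stop("LOOCV needs at least 4 samples", call. = FALSE)
  scores <- rep(NA_real_, nrow(X))
  for (i in seq_len(nrow(X))) {
    gi <- g[-i]
    if (nlevels(droplevels(gi)) < 2 || any(table(gi) < 2)) {
      message("skipping LOOCV fold ", i, ": single-class training set")
      next
    }
    fit <- fit_classifier(X[-i, , drop = FALSE], gi, spec)
    scores[i] <- predict(fit, X[i, , drop = FALSE])
  }
  ok <- !is.na(scores)
  new_cv_report("loocv", scores[ok], droplevels(g[ok]), spec = spec)
}

#' Three-dataset cross-validation
#'
#' The triplicate-dish validation scheme: features are selected on
#' dataset 1 only, the classifier is trained on dataset 2 only, and
#' scores, ROC and AUROC are computed on dataset 3 only.
#'
#' @param tables List of three feature tibbles sharing the same
#'   feature columns, each with a `group` column (or supply `groups`
#'   as a list of three label vectors).
#' @param k Number of features to select on dataset 1.
#' @param spec A [classifier_spec()].
#' @param criterion Selection criterion, see [select_features()].
#' @param groups Optional list of three label vectors.
#' @return A `cv_report` with `scheme = "three_dataset"` and the
#'   selected feature names.
#' @export
three_dataset_cv <- function(tables, k = 5, spec = classifier_spec(),
                             criterion = "ks", groups = NULL) {
  stopifnot(length(tables) == 3)
  if (is.null(groups)) {
    if (!all(purrr::map_lgl(tables, ~ "group" %in% names(.x))))
      stop("each table needs a `group` column (or pass `groups`)",
           call. = FALSE)
    groups <- purrr::map(tables, ~ .x$group)
  }
  mats <- purrr::map(tables, feature_matrix)
  schemas <- purrr::map(mats, colnames)
  if (length(unique(purrr::map_chr(schemas, paste, collapse = "|"))) != 1)
    stop("the three tables must share an identical feature schema",
         call. = FALSE)
  sel <- select_features(mats[[1]], groups[[1]], k = k,
                         criterion = criterion)
  fit <- fit_classifier(mats[[2]][, sel, drop = FALSE], groups[[2]], spec)
  g3 <- as_group_factor(groups[[3]])
  scores <- predict(fit, mats[[3]][, sel, drop = FALSE])
  rep <- new_cv_report("three_dataset", scores, g3, selected = sel,
                       spec = spec)
  rep
}
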