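test_that("feature selection ranks an informative feature first", {
  set.seed(1)
  n <- 30
  X <- matrix(rnorm(2 * n * 6), 2 * n, 6)
  X[(n + 1):(2 * n), 4] <- X[(n + 1):(2 * n), 4] + 20   # disjoint support
  colnames(X) <- paste0("f", 1:6)
  g <- rep(c("a", "b"), each = n)
  sel <- select_features(X, g, k = 3)
  expect_equal(sel[1], "f4")
  # per-feature KS oracle agrees with the ranking criterion
  ks4 <- ks_statistic(X[1:n, 4], X[-(1:n), 4])
  expect_equal(ks4, 1)
  expect_equal(select_features(X, g, k = 6), c("f4", setdiff(paste0("f", 1:6), "f4")[
    order(-sapply(setdiff(1:6, 4), function(j)
      ks_statistic(X[1:n, j], X[-(1:n), j])))]))
  expect_error(select_features(X, g, k = 0), "positive")
})

test_that("all-tied features fall back to registry order", {
  X <- matrix(rep(c(1, 2), each = 10), 20, 5)
  colnames(X) <- paste0("f", 1:5)
  g <- rep(c("a", "b"), 10)
  expect_equal(select_features(X, g, k = 5), paste0("f", 1:5))
})

test_that("the linear discriminant splits symmetric classes at the midpoint", {
  set.seed(2)
  x <- matrix(c(rnorm(60), rnorm(60, 10)), ncol = 1)
  g <- rep(c("a", "b"), each = 60)
  fit <- fit_classifier(x, g, classifier_spec("linear"))
  p5 <- predict(fit, matrix(5))
  expect_equal(p5, 0.5, tolerance = 0.15)
  expect_lt(predict(fit, matrix(0)), 0.01)
  expect_gt(predict(fit, matrix(10)), 0.99)
})

test_that("naive Bayes equals the product of per-feature likelihood ratios", {
  X <- rbind(c(0, 1), c(1, 0), c(0.5, 0.5), c(3, 4), c(4, 3), c(3.5, 3.5))
  g <- rep(c("a", "b"), each = 3)
  fit <- fit_classifier(X, g, classifier_spec("naive_bayes",
                                              regularisation = 0))
  xq <- c(2, 2)
  hand <- function(x, cls) {
    i <- if (cls == "a") 1:3 else 4:6
    prod(sapply(1:2, function(j)
      stats::dnorm(x[j], mean(X[i, j]), stats::sd(X[i, j]))))
  }
  expect_equal(predict(fit, matrix(xq, 1)),
               hand(xq, "b") / (hand(xq, "a") + hand(xq, "b")),
               tolerance = 1e-10)
})

test_that("quadratic equals linear when class covariances match", {
  set.seed(3)
  base <- matrix(rnorm(200), 100, 2)
  X <- rbind(base, sweep(base, 2, c(2, 1), "+"))  # identical covariances
  g <- rep(c("a", "b"), each = 100)
  fl <- fit_classifier(X, g, classifier_spec("linear"))
  fq <- fit_classifier(X, g, classifier_spec("quadratic"))
  grid <- matrix(rnorm(100), 50, 2)
  expect_lt(max(abs(predict(fl, grid) - predict(fq, grid))), 1e-6)
})

test_that("singular covariances error with guidance at zero regularisation", {
  X <- cbind(rep(c(1, 2), 10), rep(c(1, 2), 10))   # perfectly collinear
  g <- rep(c("a", "b"), 10)
  expect_error(fit_classifier(X, g, classifier_spec("quadratic",
                                                    regularisation = 0)),
               "regularisation")
})

test_that("held-out AUROC equals the brute-force concordant-pair count", {
  set.seed(4)
  d <- make_feature_dataset(20, 3, effect = c(1.5, 0, 0), seed = 11)
  rep <- loocv_roc(dplyr::select(d, -cell_id, -group), d$group)
  s <- rep$per_sample_scores
  pos <- d$group == "B"
  conc <- 0
  for (i in which(pos)) for (j in which(!pos))
    conc <- conc + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  expect_equal(rep$auroc, conc / (sum(pos) * sum(!pos)), tolerance = 1e-12)
  # pROC as an independent cross-check
  skip_if_not_installed("pROC")
  expect_equal(rep$auroc,
               as.numeric(suppressMessages(pROC::auc(pos, s))),
               tolerance = 1e-10)
})

test_that("ROC curves span (0,0) to (1,1) and are monotone", {
  set.seed(5)
  d <- make_feature_dataset(15, 2, effect = c(1, 0), seed = 12)
  rep <- loocv_roc(dplyr::select(d, -cell_id, -group), d$group)
  roc <- tidy(rep)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(rep$auroc >= 0 && rep$auroc <= 1)
})

test_that("swapping the positive class reflects the AUROC exactly", {
  set.seed(6)
  d <- make_feature_dataset(15, 3, effect = c(1, 0.5, 0), seed = 13)
  X <- dplyr::select(d, -cell_id, -group)
  a <- loocv_roc(X, d$group)
  pos <- a$labels == levels(a$labels)[2]
  expect_equal(specell:::auroc_mw(a$per_sample_scores, !pos),
               1 - a$auroc, tolerance = 1e-12)
})

test_that("AUROC is invariant under strictly increasing score transforms", {
  set.seed(7)
  s <- rnorm(40); pos <- rep(c(TRUE, FALSE), 20)
  expect_equal(specell:::auroc_mw(s, pos),
               specell:::auroc_mw(exp(2 * s) + 1, pos))
})

test_that("perfect separation and permuted labels bracket the AUROC", {
  set.seed(8)
  d <- make_feature_dataset(25, 2, effect = c(50, 0), seed = 14)
  X <- dplyr::select(d, -cell_id, -group)
  expect_equal(loocv_roc(X, d$group)$auroc, 1.0)
  d0 <- make_feature_dataset(50, 2, effect = c(0, 0), seed = 15)
  g0 <- sample(d0$group)
  a0 <- loocv_roc(dplyr::select(d0, -cell_id, -group), g0)$auroc
  expect_gt(a0, 0.3); expect_lt(a0, 0.7)
})

test_that("LOOCV is deterministic for deterministic classifiers", {
  d <- make_feature_dataset(12, 3, effect = c(1, 0, 0), seed = 16)
  X <- dplyr::select(d, -cell_id, -group)
  expect_identical(loocv_roc(X, d$group)$per_sample_scores,
                   loocv_roc(X, d$group)$per_sample_scores)
})

test_that("the three-dataset scheme selects, trains and tests separately", {
  mk <- function(seed) {
    d <- make_feature_dataset(40, 14, effect = c(3, rep(0, 13)),
                              seed = seed)
    names(d)[-(1:2)] <- paste0("f", 1:14)
    d
  }
  tabs <- list(mk(21), mk(22), mk(23))
  rep <- three_dataset_cv(tabs, k = 3)
  expect_equal(rep$selected_features[1], "f1")
  expect_gt(rep$auroc, 0.95)
  expect_equal(rep$scheme, "three_dataset")
  # identical group distributions: AUROC inside the permutation null
  mk0 <- function(seed) {
    d <- make_feature_dataset(40, 5, effect = rep(0, 5), seed = seed)
    names(d)[-(1:2)] <- paste0("f", 1:5)
    d
  }
  rep0 <- three_dataset_cv(list(mk0(31), mk0(32), mk0(33)), k = 3)
  null_aurocs <- replicate(200, {
    specell:::auroc_mw(rep0$per_sample_scores,
                       sample(rep0$labels) == levels(rep0$labels)[2])
  })
  qs <- quantile(null_aurocs, c(0.005, 0.995))
  expect_gt(rep0$auroc, qs[1]); expect_lt(rep0$auroc, qs[2])
  # schema mismatch errors
  bad <- mk(24); names(bad)[3] <- "zz"
  expect_error(three_dataset_cv(list(mk(21), mk(22), bad), k = 2),
               "schema")
})

test_that("linear LOOCV AUROC approaches the Gaussian optimum", {
  # two classes at Mahalanobis separation Delta have Bayes AUROC
  # pnorm(Delta / sqrt(2)); at Delta = 2 that is ~0.921
  d <- make_feature_dataset(200, 4, effect = c(2, 0, 0, 0), seed = 42)
  rep <- loocv_roc(dplyr::select(d, -cell_id, -group), d$group,
                   classifier_spec("linear"))
  expect_lt(abs(rep$auroc - pnorm(sqrt(2))), 0.03)
})
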