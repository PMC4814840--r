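#' Principal component analysis of a feature or pixel table
#'
#' PCA is a unitary rotation of the feature space onto the
#' eigenvectors of the data covariance matrix; the first few canonical
#' variables explain most of the variability and decorrelate the
#' features ahead of discriminant analysis. The sign of each component
#' is fixed so that its largest-magnitude loading is positive.
#'
#' @param table N x P numeric matrix or data frame of features (N > 1).
#' @param standardise If `TRUE`, divide each column by its standard
#'   deviation before rotation (errors on constant columns).
#' @return A `projection_model` with `kind = "PCA"`: `mean_vector`,
#'   `scale_vector`, `basis` (P x R, orthonormal columns),
#'   `axis_scores` (explained-variance ratios, non-increasing),
#'   `feature_names`.
#' @export
pca_fit <- function(table, standardise = FALSE) {
  X <- feature_matrix(table)
  if (nrow(X) < 2) stop("PCA needs at least 2 observations", call. = FALSE)
  mu <- colMeans(X)
  sc <- rep(1, ncol(X))
  if (standardise) {
    sc <- apply(X, 2, stats::sd)
    if (any(sc == 0))
      stop("cannot standardise constant feature(s): ",
           paste(colnames(X)[sc == 0], collapse = ", "), call. = FALSE)
  }
  Xc <- sweep(sweep(X, 2, mu), 2, sc, "/")
  cv <- stats::cov(Xc)
  if (all(cv == 0)) stop("zero-variance data: PCA undefined", call. = FALSE)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  keep <- which(vals > max(vals) * 1e-12)
  basis <- eg$vectors[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(basis))) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  rownames(basis) <- colnames(X)
  new_projection_model("PCA", mu, sc, basis, vals[keep] / sum(vals),
                       colnames(X))
}

new_projection_model <- function(kind, mean_vector, scale_vector, basis,
                                 axis_scores, feature_names,
                                 degenerate = FALSE, objective = NULL) {
  structure(list(kind = kind, mean_vector = mean_vector,
                 scale_vector = scale_vector, basis = basis,
                 axis_scores = axis_scores, feature_names = feature_names,
                 degenerate = degenerate, objective = objective),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model> %s: %d features -> %d canonical variables\n",
              x$kind, length(x$feature_names), ncol(x$basis)))
  if (isTRUE(x$degenerate)) cat("  (degenerate: no between-group scatter)\n")
  invisible(x)
}

#' Project data onto a fitted model's canonical variables
#'
#' Centres (and scales, if the model was fitted so) the data and
#' multiplies by the basis columns.
#'
#' @param model A `projection_model`.
#' @param table N x P data with the model's features (matching names if
#'   named).
#' @param n_components Number of leading canonical variables (defaults
#'   to all).
#' @return N x R numeric matrix of scores (columns `CV1`, `CV2`, ...).
#' @export
pca_transform <- function(model, table, n_components = NULL) {
  stopifnot(inherits(model, "projection_model"))
  X <- feature_matrix(table, feature_names =
                        if (!is.null(colnames(table)) || is.data.frame(table))
                          model$feature_names else NULL)
  if (ncol(X) != length(model$feature_names))
    stop("table has ", ncol(X), " features, model expects ",
         length(model$feature_names), call. = FALSE)
  R <- ncol(model$basis)
  if (is.null(n_components)) n_components <- R
  if (n_components > R)
    stop("model has only ", R, " components", call. = FALSE)
  Xc <- sweep(sweep(X, 2, model$mean_vector), 2, model$scale_vector, "/")
  sc <- Xc %*% model$basis[, seq_len(n_components), drop = FALSE]
  colnames(sc) <- paste0("CV", seq_len(n_components))
  sc
}

#' @rdname pca_transform
#' @export
project_features <- pca_transform

#' Linear discriminant canonical variables
#'
#' Fits the discriminant projection returning `n - 1` canonical
#' variables for `n` groups: eigenvectors of the shrunk
#' within-group-scatter inverse times between-group scatter
#' (`Sw^-1 Sb`, the Mahalanobis between-class distance form). Because
#' correlated features require decorrelation prior to multivariate
#' analysis, the data is standardised and rotated by PCA (retaining
#' components covering at least `pca_var` of variance) before the
#' discriminant eigenproblem; the returned basis maps the original
#' features directly to canonical variables.
#'
#' @param table N x P numeric features.
#' @param groups Vector (or factor) of group labels, each group with
#'   at least 2 members.
#' @param shrinkage Shrinkage of `Sw` toward its diagonal in `[0, 1]`
#'   (default 0.05), guaranteeing invertibility on small N.
#' @param pca_var Variance fraction retained by the decorrelation PCA.
#' @param standardise Standardise features before PCA (default `TRUE`).
#' @return A `projection_model` with `kind = "LDA"`; `axis_scores` are
#'   the discriminant eigenvalues. If the between-group scatter is
#'   zero the model is returned with `degenerate = TRUE` and zero
#'   eigenvalues.
#' @export
lda_fit <- function(table, groups, shrinkage = 0.05, pca_var = 0.99,
                    standardise = TRUE) {
  X <- feature_matrix(table)
  g <- as_group_factor(groups)
  stopifnot(length(g) == nrow(X))
  if (nlevels(g) < 2) stop("LDA needs at least 2 groups", call. = FALSE)
  if (any(table(g) < 2))
    stop("every group needs at least 2 members", call. = FALSE)
  if (shrinkage < 0 || shrinkage > 1)
    stop("shrinkage must be in [0, 1]", call. = FALSE)

  # decorrelate: standardise (constant features dropped) then PCA
  sds <- apply(X, 2, stats::sd)
  keep_f <- if (standardise) sds > 0 else rep(TRUE, ncol(X))
  Xk <- X[, keep_f, drop = FALSE]
  pca <- pca_fit(Xk, standardise = standardise)
  cs <- cumsum(pca$axis_scores)
  r <- if (any(cs >= pca_var - 1e-12)) min(which(cs >= pca_var - 1e-12))
       else length(cs)
  Z <- pca_transform(pca, Xk, n_components = r)

  n <- nlevels(g)
  mu <- colMeans(Z)
  Sw <- matrix(0, r, r); Sb <- matrix(0, r, r)
  for (lv in levels(g)) {
    Zi <- Z[g == lv, , drop = FALSE]
    mi <- colMeans(Zi)
    Sw <- Sw + crossprod(sweep(Zi, 2, mi))
    Sb <- Sb + nrow(Zi) * tcrossprod(mi - mu)
  }
  Sw_s <- (1 - shrinkage) * Sw + shrinkage * diag(diag(Sw), r)
  if (max(abs(Sb)) < 1e-12 * max(1, max(abs(Sw)))) {
    basis0 <- matrix(0, r, n - 1)
    W <- compose_basis(pca, basis0, keep_f, ncol(X), colnames(X))
    return(new_projection_model("LDA", colMeans(X), rep(1, ncol(X)), W,
                                rep(0, n - 1), colnames(X),
                                degenerate = TRUE))
  }
  L <- tryCatch(chol(Sw_s), error = function(e)
    stop("within-group scatter is singular; increase shrinkage",
         call. = FALSE))
  Li <- backsolve(L, diag(r))              # Sw_s^{-1/2} (upper-tri inverse)
  M <- t(Li) %*% Sb %*% Li
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  R <- min(n - 1, r)
  vecs <- Li %*% eg$vectors[, seq_len(R), drop = FALSE]
  # normalise canonical directions to unit within-group variance
  for (j in seq_len(R)) {
    s <- sqrt(drop(t(vecs[, j]) %*% Sw_s %*% vecs[, j]) /
                max(nrow(Z) - n, 1))
    if (s > 0) vecs[, j] <- vecs[, j] / s
  }
  W <- compose_basis(pca, vecs, keep_f, ncol(X), colnames(X))
  # sign convention as in PCA
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  m <- new_projection_model("LDA", colMeans(X), rep(1, ncol(X)), W,
                            pmax(eg$values[seq_len(R)], 0), colnames(X))
  m
}

# fold the standardise+PCA preprocessing into a single P x R basis on
# the original (unscaled) features
compose_basis <- function(pca, vecs, keep_f, P, feature_names) {
  B <- sweep(pca$basis[, seq_len(nrow(vecs)), drop = FALSE],
             1, pca$scale_vector, "/") %*% vecs
  W <- matrix(0, P, ncol(vecs))
  W[keep_f, ] <- B
  rownames(W) <- feature_names
  W
}

#' Targeted projection pursuit
#'
#' Finds an orthonormal basis whose projection of the (centred) data
#' best matches a user-supplied target configuration in the least
#' squares (Frobenius) sense, up to a free per-axis scale (so targets
#' such as group indicators need not share the data's units). The
#' closed-form orthogonal-Procrustes polar factor of `X' T` seeds a
#' projected-gradient refinement on the Stiefel manifold, restarted
#' from seeded random perturbations to guard against local optima.
#'
#' @param table N x P numeric features.
#' @param target N x R numeric target configuration, `R < P`.
#' @param max_iter Gradient iterations per start.
#' @param tol Relative objective-improvement tolerance.
#' @param n_restarts Perturbed restarts beyond the Procrustes start.
#' @param seed Seed for the restarts.
#' @return A `projection_model` with `kind = "TPP"`, orthonormal basis
#'   and the final objective in `$objective`; `axis_scores` hold the
#'   per-axis share of projected variance.
#' @export
tpp_fit <- function(table, target, max_iter = 500, tol = 1e-12,
                    n_restarts = 3, seed = 1) {
  X <- feature_matrix(table)
  target <- as.matrix(target)
  stopifnot(nrow(target) == nrow(X))
  if (ncol(target) >= ncol(X))
    stop("target dimension must be below the feature dimension",
         call. = FALSE)
  qrT <- qr(scale(target, scale = FALSE))
  if (qrT$rank < ncol(target)) {
    warning("rank-deficient target: reducing to ", qrT$rank,
            " dimension(s)")
    target <- qr.Q(qrT)[, seq_len(qrT$rank), drop = FALSE] * sqrt(nrow(X))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  Tc <- scale(target, scale = FALSE)
  polar <- function(M) {
    sv <- svd(M)
    sv$u %*% t(sv$v)
  }
  # the projected configuration is matched to the target up to a free
  # per-axis scale, so targets need not share the data's units
  objective <- function(B) {
    P <- Xc %*% B
    d <- colSums(P * Tc) / pmax(colSums(P^2), 1e-300)
    sum((sweep(P, 2, d, "*") - Tc)^2)
  }
  refine <- function(B) {
    lip <- max(svd(crossprod(Xc))$d)
    step <- 1 / lip
    ob <- objective(B)
    for (it in seq_len(max_iter)) {
      P <- Xc %*% B
      d <- colSums(P * Tc) / pmax(colSums(P^2), 1e-300)
      Gr <- crossprod(Xc, sweep(sweep(P, 2, d, "*") - Tc, 2, d, "*"))
      B2 <- polar(B - step * Gr)
      ob2 <- objective(B2)
      if (ob2 < ob) {
        done <- (ob - ob2) <= tol * max(ob, 1e-300)
        B <- B2; ob <- ob2
        if (done) break
      } else {
        step <- step / 2
        if (step < 1e-18) break
      }
    }
    list(B = B, objective = ob)
  }
  B0 <- polar(crossprod(Xc, Tc))
  best <- refine(B0)
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    Bp <- polar(B0 + matrix(stats::rnorm(length(B0), sd = 0.1), nrow(B0)))
    cand <- refine(Bp)
    if (cand$objective < best$objective) best <- cand
  }
  B <- best$B
  rownames(B) <- colnames(X)
  sc <- Xc %*% B
  v <- apply(sc, 2, stats::var)
  m <- new_projection_model("TPP", mu, rep(1, ncol(X)), B,
                            if (sum(v) > 0) v / sum(v) else v,
                            colnames(X), objective = best$objective)
  m
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum of the absolute difference between the two empirical
#' cumulative distribution functions, evaluated at all pooled points.
#'
#' @param x,y Numeric samples.
#' @return The KS statistic `D` in `[0, 1]`.
#' @export
ks_statistic <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  pool <- sort(unique(c(x, y)))
  Fx <- vapply(pool, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pool, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

#' Optimal 1-D discrimination with hypothesis test
#'
#' Projects the two groups onto the single optimised discriminant
#' direction (LDA with two groups returns one canonical variable) and
#' applies the two-sample Kolmogorov-Smirnov test to the projected
#' scores. Significance is conventionally declared at p < 0.05. Note
#' the optimism caveat: when the projection is optimised on the same
#' cells that are tested, the test is anti-conservative; for a
#' calibrated test fit the projection on one half of the cells and
#' test the other (see `split` argument).
#'
#' @param table N x P numeric features.
#' @param groups Two-group labels.
#' @param split Optional logical vector (length N): `TRUE` rows train
#'   the projection, `FALSE` rows are projected and tested. Default
#'   `NULL` trains and tests on all cells (exploratory use).
#' @param shrinkage Passed to [lda_fit()].
#' @return A list with `scores` (length N, or length of the test half),
#'   `ks_statistic`, `p_value`, `model`, and the group factor used.
#' @export
discriminate_1d <- function(table, groups, split = NULL, shrinkage = 0.05) {
  X <- feature_matrix(table)
  g <- as_group_factor(groups)
  if (nlevels(g) != 2)
    stop("discriminate_1d requires exactly 2 groups", call. = FALSE)
  if (is.null(split)) {
    model <- lda_fit(X, g, shrinkage = shrinkage)
    sc <- drop(pca_transform(model, X, n_components = 1))
    gt <- g
  } else {
    stopifnot(length(split) == nrow(X))
    model <- lda_fit(X[split, , drop = FALSE], g[split],
                     shrinkage = shrinkage)
    sc <- drop(pca_transform(model, X[!split, , drop = FALSE],
                             n_components = 1))
    gt <- g[!split]
  }
  a <- sc[gt == levels(gt)[1]]
  b <- sc[gt == levels(gt)[2]]
  D <- ks_statistic(a, b)
  exact <- length(a) + length(b) < 25
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(scores = sc, groups = gt, ks_statistic = D,
       p_value = unname(kt$p.value), model = model)
}

#' False-colour rendering from the top three principal components
#'
#' Assigns red, green and blue to the per-pixel scores on the first
#' three principal components of the pixel spectra, each channel
#' independently rescaled to `[0, 1]` by its robust 1st-99th
#' percentiles. Pixels with zero total intensity (or outside the valid
#' mask) render black.
#'
#' @param stack A `hyper_stack`.
#' @param pixel_model A `projection_model` fitted on pixel spectra with
#'   at least 3 components.
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
render_rgb <- function(stack, pixel_model) {
  stopifnot(inherits(stack, "hyper_stack"),
            inherits(pixel_model, "projection_model"))
  if (ncol(pixel_model$basis) < 3)
    stop("RGB rendering needs at least 3 components", call. = FALSE)
  d <- dim(stack$data)
  V <- matrix(stack$data, d[1] * d[2], d[3])
  colnames(V) <- pixel_model$feature_names
  sc <- pca_transform(pixel_model, V, n_components = 3)
  rgb <- array(0, dim = c(d[1], d[2], 3))
  black <- rowSums(V) == 0 | !as.vector(stack$valid_mask)
  for (j in 1:3) {
    v <- sc[, j]
    qs <- stats::quantile(v[!black], c(0.01, 0.99), names = FALSE)
    v <- (v - qs[1]) / max(qs[2] - qs[1], .Machine$double.eps)
    v <- pmin(pmax(v, 0), 1)
    v[black] <- 0
    rgb[, , j] <- matrix(v, d[1], d[2])
  }
  rgb
}
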