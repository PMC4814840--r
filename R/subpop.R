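#' Detect cell subpopulations
#'
#' Transparent unsupervised cluster detection in feature or
#' canonical-variable space: k-means with seeded restarts for every
#' candidate K, model selection by maximum mean silhouette width, and
#' a single-population fallback. A candidate K is only accepted when
#' its silhouette exceeds both `silhouette_min` and the best
#' silhouette obtained by force-splitting matched single-Gaussian
#' reference data into K clusters (a gap-statistic-style null, since
#' even one Gaussian cloud yields sizeable silhouettes when split).
#' Candidates containing a cluster smaller
#' than `min_cluster_size` are discarded. Labels are renumbered
#' `0..K-1` in order of first appearance, so the assignment is
#' equivariant under row permutation and stable under duplication of
#' the data.
#'
#' @param points N x D numeric matrix (D intended small, e.g. the
#'   first canonical variables).
#' @param min_cluster_size Minimum cluster occupancy (default 5).
#' @param k_range Candidate cluster counts (default `1:5`).
#' @param seed Integer seed; the result is deterministic given it.
#' @param n_restarts k-means restarts per K (default 10).
#' @param silhouette_min Mean-silhouette floor below which a single
#'   population is reported (default 0.25).
#' @param noise_sd If non-`NULL`, points farther than this many
#'   within-cluster standard deviations from their centroid get the
#'   noise label `-1`.
#' @return A list of class `cluster_assignment`: `labels` (length N,
#'   `0..K-1`, `-1` = noise), `K`, `centroids`, `silhouette`.
#' @export
detect_clusters <- function(points, min_cluster_size = 5, k_range = 1:5,
                            seed = 1, n_restarts = 10,
                            silhouette_min = 0.25, noise_sd = NULL) {
  points <- as.matrix(points)
  stopifnot(is.numeric(points), all(is.finite(points)))
  N <- nrow(points)
  if (N < 2 * min_cluster_size)
    stop("need at least 2 * min_cluster_size points", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1) || min(k_range) * min_cluster_size > N ||
      max(k_range) >= N)
    stop("k_range infeasible for N = ", N, call. = FALSE)
  dmat <- stats::dist(points)
  kfit <- function(pts, k, sd_offset = 0) {
    set.seed(seed + k + sd_offset)
    stats::kmeans(pts, centers = k, nstart = n_restarts, iter.max = 100)
  }
  # null calibration: the silhouette a single Gaussian population of the
  # same shape would produce when force-split into k clusters
  mu <- colMeans(points)
  cv <- stats::cov(points)
  L <- tryCatch(chol(cv + diag(1e-10, ncol(points))),
                error = function(e) NULL)
  null_sil <- function(k) {
    if (is.null(L)) return(-Inf)
    sils <- vapply(1:8, function(b) {
      set.seed(seed + 7919 * b + k)
      ref <- sweep(matrix(stats::rnorm(N * ncol(points)), N) %*% L, 2,
                   mu, "+")
      km <- kfit(ref, k, sd_offset = 1000 * b)
      mean(cluster::silhouette(km$cluster,
                               stats::dist(ref))[, "sil_width"])
    }, numeric(1))
    mean(sils) + 4 * stats::sd(sils)
  }
  best <- list(k = 1L, sil = -Inf, cluster = rep(1L, N))
  evaluated <- FALSE
  for (k in k_range[k_range >= 2]) {
    km <- kfit(points, k)
    if (any(tabulate(km$cluster, k) < min_cluster_size)) next
    sil <- mean(cluster::silhouette(km$cluster, dmat)[, "sil_width"])
    if (sil <= null_sil(k) + 0.02) next   # no better than one Gaussian
    evaluated <- TRUE
    if (sil > best$sil) best <- list(k = k, sil = sil, cluster = km$cluster)
  }
  if (!evaluated || best$sil < silhouette_min) {
    if (!(1L %in% k_range) && evaluated) {
      # caller excluded K = 1; keep the best multi-cluster solution
    } else {
      best <- list(k = 1L, sil = if (evaluated) best$sil else 0,
                   cluster = rep(1L, N))
    }
  }
  cl <- best$cluster
  # canonical label order: first appearance in row order, 0-based
  uniq <- unique(cl)
  labels <- match(cl, uniq) - 1L
  K <- length(uniq)
  centroids <- t(vapply(seq_len(K) - 1L, function(l)
    colMeans(points[labels == l, , drop = FALSE]), numeric(ncol(points))))
  if (!is.null(noise_sd) && K >= 1) {
    for (l in seq_len(K) - 1L) {
      i <- which(labels == l)
      d <- sqrt(rowSums(sweep(points[i, , drop = FALSE], 2,
                              centroids[l + 1L, ])^2))
      s <- stats::sd(d)
      if (is.finite(s) && s > 0) labels[i[d > noise_sd * s]] <- -1L
    }
  }
  structure(list(labels = labels, K = K, centroids = centroids,
                 silhouette = if (is.finite(best$sil)) best$sil else 0),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> K = %d, mean silhouette %.3f\n",
              x$K, x$silhouette))
  print(table(labels = x$labels))
  invisible(x)
}

#' Canonical-variable projection of detected subpopulations
#'
#' Fits the discriminant projection using the detected cluster labels
#' as groups, returning `min(K - 1, 2)` canonical variables for
#' visualising the subpopulation structure.
#'
#' @param table Feature tibble or matrix for the same cells.
#' @param assignment A `cluster_assignment` with `K >= 2`.
#' @param shrinkage Passed to [lda_fit()].
#' @return A `projection_model` whose basis has `min(K - 1, 2)`
#'   columns.
#' @export
subpop_projection <- function(table, assignment, shrinkage = 0.05) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (assignment$K < 2)
    stop("need at least 2 subpopulations to project", call. = FALSE)
  keep <- assignment$labels >= 0
  X <- feature_matrix(table)
  stopifnot(nrow(X) == length(assignment$labels))
  m <- lda_fit(X[keep, , drop = FALSE], assignment$labels[keep],
               shrinkage = shrinkage)
  r <- min(assignment$K - 1L, 2L)
  m$basis <- m$basis[, seq_len(r), drop = FALSE]
  m$axis_scores <- m$axis_scores[seq_len(r)]
  m
}
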