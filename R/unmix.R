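#' Unsupervised spectral unmixing by nonnegative matrix factorisation
#'
#' Factorises the masked pixel-by-channel matrix `V` (pixels with zero
#' total intensity are excluded) into nonnegative abundances `W` and
#' endmember spectra `S`, `V ~ W S`, by Frobenius multiplicative
#' updates with several seeded random restarts (best final objective
#' kept). Endmember spectra are row-normalised to unit sum and ordered
#' by total abundance, descending. Final per-pixel abundance maps are
#' recomputed for every pixel by exact nonnegative least squares
#' against the fitted spectra, so excluded zero pixels get zero
#' abundance.
#'
#' @param stack A `hyper_stack`.
#' @param k Number of endmembers, `1 <= k <= C`.
#' @param seed Integer seed; the factorisation is bit-reproducible for
#'   a given seed.
#' @param max_iter Maximum multiplicative-update iterations.
#' @param tol Relative objective-change convergence tolerance.
#' @param n_restarts Number of seeded random restarts.
#' @param sum_to_one If `TRUE`, renormalise each pixel's abundances to
#'   sum to one (where the sum is positive).
#' @return An object of class `endmember_set`: `spectra` (k x C,
#'   rows sum to 1), `abundances` (H x W x k), `residual_rms`, `k`,
#'   `objective_trace` (list per restart), and `channels`.
#' @export
unmix_stack <- function(stack, k = 3, seed = 1, max_iter = 500, tol = 1e-7,
                        n_restarts = 5, sum_to_one = FALSE) {
  stopifnot(inherits(stack, "hyper_stack"))
  C <- n_channels(stack)
  if (k < 1 || k > C)
    stop("k must be between 1 and the number of channels (", C, ")",
         call. = FALSE)
  d <- dim(stack$data)
  V_all <- matrix(stack$data, d[1] * d[2], C)
  tot <- rowSums(V_all)
  fit_idx <- which(tot > 0 & as.vector(stack$valid_mask))
  if (length(fit_idx) == 0)
    stop("all-zero stack: nothing to unmix", call. = FALSE)
  V <- V_all[fit_idx, , drop = FALSE]

  best <- NULL
  traces <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    fit <- nmf_multiplicative(V, k, max_iter = max_iter, tol = tol)
    traces[[r]] <- fit$objective
    if (is.null(best) || utils::tail(fit$objective, 1) <
          utils::tail(best$objective, 1))
      best <- fit
  }

  S <- best$H                              # k x C spectra
  rs <- rowSums(S)
  rs[rs == 0] <- 1
  S <- S / rs
  A_fit <- nnls_smallk(V, S)               # exact NNLS per pixel
  ord <- order(colSums(A_fit), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A_fit <- A_fit[, ord, drop = FALSE]

  A_all <- matrix(0, d[1] * d[2], k)
  A_all[fit_idx, ] <- A_fit
  if (sum_to_one) {
    s <- rowSums(A_all)
    pos <- s > 0
    A_all[pos, ] <- A_all[pos, , drop = FALSE] / s[pos]
  }
  resid <- V - A_fit %*% S
  structure(list(
    spectra = S,
    abundances = array(A_all, dim = c(d[1], d[2], k)),
    residual_rms = sqrt(mean(resid^2)),
    k = as.integer(k),
    objective_trace = traces,
    channels = stack$channels),
    class = "endmember_set")
}

#' @export
print.endmember_set <- function(x, ...) {
  cat(sprintf("<endmember_set> k = %d, residual RMS %.4g\n",
              x$k, x$residual_rms))
  invisible(x)
}

# Lee-Seung multiplicative updates for || V - W H ||_F^2
nmf_multiplicative <- function(V, k, max_iter = 500, tol = 1e-7) {
  n <- nrow(V); C <- ncol(V)
  mx <- mean(V)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  # seed spectra from sampled pixel spectra: a data-driven start that is
  # equivariant under channel permutation (row choice ignores channels)
  H <- V[sample.int(n, k), , drop = FALSE] + 0.1 * mx
  eps <- .Machine$double.eps
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) + eps) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H) + eps) / (W %*% tcrossprod(H) + eps)
    o <- sum((V - W %*% H)^2)
    obj <- c(obj, o)
    if (is.finite(prev) && (prev - o) <= tol * max(prev, eps)) break
    prev <- o
  }
  list(W = W, H = H, objective = obj)
}

# Exact nonnegative least squares for each row of V against spectra S
# (k x C), by enumeration of the 2^k - 1 possible active sets. For each
# support the unconstrained LS solution is computed for all pixels at
# once; the best feasible (all-nonnegative) support wins per pixel.
nnls_smallk <- function(V, S) {
  k <- nrow(S)
  if (k > 8) stop("active-set enumeration supports k <= 8", call. = FALSE)
  n <- nrow(V)
  best_res <- rep(Inf, n)
  best_A <- matrix(0, n, k)
  base_res <- rowSums(V^2)                 # empty support
  best_res <- base_res
  for (m in seq_len(2^k - 1)) {
    sup <- which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
    Ss <- S[sup, , drop = FALSE]
    G <- tcrossprod(Ss)                    # |sup| x |sup|
    Gi <- tryCatch(solve(G), error = function(e) NULL)
    if (is.null(Gi)) next
    A_s <- V %*% t(Ss) %*% Gi              # n x |sup|
    feasible <- rowSums(A_s < -1e-12) == 0
    if (!any(feasible)) next
    A_s[A_s < 0] <- 0
    fit <- A_s %*% Ss
    res <- rowSums((V - fit)^2)
    upd <- feasible & (res < best_res - 1e-15)
    if (any(upd)) {
      best_res[upd] <- res[upd]
      best_A[upd, ] <- 0
      best_A[upd, sup] <- A_s[upd, , drop = FALSE]
    }
  }
  best_A
}

#' Similarity of a measured spectrum to a reference fluorophore
#'
#' Captures how close a pixel or cell spectrum is to a known
#' fluorophore signature. `cosine` is the normalised dot product (in
#' `[0, 1]` for nonnegative spectra), `sam_angle` the spectral angle
#' `acos(cosine)` in radians, and `euclidean` the distance between the
#' two sum-normalised spectra.
#'
#' @param spectrum Length-C nonnegative numeric.
#' @param reference Length-C nonnegative numeric (a reference spectrum).
#' @param metric One of `"cosine"`, `"sam_angle"`, `"euclidean"`.
#' @return A single numeric value.
#' @export
spectral_similarity <- function(spectrum, reference,
                                metric = c("cosine", "sam_angle",
                                           "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(length(spectrum) == length(reference),
            all(is.finite(spectrum)), all(is.finite(reference)))
  if (metric %in% c("cosine", "sam_angle")) {
    na <- sqrt(sum(spectrum^2)); nb <- sqrt(sum(reference^2))
    if (na == 0 || nb == 0)
      stop("angular similarity is undefined for a zero spectrum",
           call. = FALSE)
    cosv <- min(max(sum(spectrum * reference) / (na * nb), -1), 1)
    if (metric == "cosine") cosv else acos(cosv)
  } else {
    a <- spectrum / max(sum(spectrum), .Machine$double.eps)
    b <- reference / max(sum(reference), .Machine$double.eps)
    sqrt(sum((a - b)^2))
  }
}

#' Co-localisation of two abundance maps
#'
#' Pearson correlation of two unmixed component (abundance) images over
#' a pixel mask; a standard co-localisation score in `[-1, 1]`.
#'
#' @param abundance_a,abundance_b H x W numeric matrices.
#' @param mask H x W logical; defaults to all pixels.
#' @return Pearson correlation, or `NaN` (with a message) if either map
#'   has zero variance on the mask.
#' @export
colocalisation <- function(abundance_a, abundance_b, mask = NULL) {
  stopifnot(identical(dim(abundance_a), dim(abundance_b)),
            all(is.finite(abundance_a)), all(is.finite(abundance_b)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(abundance_a),
                                    ncol(abundance_a))
  stopifnot(identical(dim(mask), dim(abundance_a)))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  a <- abundance_a[mask]; b <- abundance_b[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    message("colocalisation undefined: zero-variance map on mask")
    return(NaN)
  }
  stats::cor(a, b)
}

#' Read reference fluorophore spectra from CSV
#'
#' CSV layout: column `name` plus one column per channel (in channel
#' order). Spectra are normalised to unit sum on read.
#'
#' @param path CSV path.
#' @return A tibble with columns `name` and `values` (list of numeric
#'   vectors summing to 1).
#' @export
read_reference_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot("name" %in% names(df))
  vals <- as.matrix(df[, setdiff(names(df), "name"), drop = FALSE])
  tibble::tibble(
    name = as.character(df$name),
    values = purrr::map(seq_len(nrow(vals)), function(i) {
      v <- as.numeric(vals[i, ])
      if (any(v < 0) || sum(v) == 0)
        stop("reference spectra must be nonnegative and nonzero",
             call. = FALSE)
      v / sum(v)
    }))
}
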