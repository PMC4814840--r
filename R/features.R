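#' Per-cell feature primitives
#'
#' Building blocks for the per-cell feature vectors: mean channel
#' intensity, excitation band ratios (the redox-fluorometry surrogate
#' relating NADH-like to flavin-like emission), statistics of
#' principal-component scores, inter-channel correlation, and the mean
#' spectral-angle variation of pixel spectra across the cell.
#'
#' @param cell M x C matrix of cell pixel spectra (see
#'   [cell_pixels()]).
#' @param channel 1-based channel column index.
#' @return A single numeric value.
#' @export
mean_channel_intensity <- function(cell, channel) {
  stopifnot(is.matrix(cell), nrow(cell) >= 1)
  if (channel < 1 || channel > ncol(cell))
    stop("channel ", channel, " out of range", call. = FALSE)
  mean(cell[, channel])
}

#' @rdname mean_channel_intensity
#' @param num_channel,den_channel 1-based numerator / denominator
#'   channel indices.
#' @param epsilon Small positive stabiliser added to the denominator
#'   mean.
#' @export
band_ratio <- function(cell, num_channel, den_channel,
                       epsilon = 1e-9 * mean(cell)) {
  stopifnot(epsilon > 0)
  mean_channel_intensity(cell, num_channel) /
    (mean_channel_intensity(cell, den_channel) + epsilon)
}

#' @rdname mean_channel_intensity
#' @param channel_a,channel_b Channel indices for the correlation.
#' @export
channel_correlation <- function(cell, channel_a, channel_b) {
  stopifnot(is.matrix(cell))
  a <- cell[, channel_a]; b <- cell[, channel_b]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NaN)
  stats::cor(a, b)
}

#' @rdname mean_channel_intensity
#' @export
spectral_variation <- function(cell) {
  stopifnot(is.matrix(cell), nrow(cell) >= 2)
  norms <- sqrt(rowSums(cell^2))
  keep <- norms > 0
  if (!any(keep)) stop("all cell pixels are zero", call. = FALSE)
  m <- colMeans(cell)
  nm <- sqrt(sum(m^2))
  cosv <- (cell[keep, , drop = FALSE] %*% m) / (norms[keep] * nm)
  mean(acos(pmin(pmax(cosv, -1), 1)))
}

#' Statistics of per-pixel principal-component scores within a cell
#'
#' The paper-style PCA abundance features: mean, variance (denominator
#' M - 1), skewness (biased `m3 / m2^1.5`) or kurtosis (biased
#' `m4 / m2^2`) of one component's scores over the cell's pixels.
#'
#' @param cell_scores M x R matrix of per-pixel PCA scores.
#' @param component 1-based component index.
#' @param statistic One of `"mean"`, `"variance"`, `"skewness"`,
#'   `"kurtosis"`.
#' @return A single numeric value.
#' @export
pca_abundance_stat <- function(cell_scores,
                               component,
                               statistic = c("mean", "variance",
                                             "skewness", "kurtosis")) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(cell_scores))
  if (component < 1 || component > ncol(cell_scores))
    stop("component out of range", call. = FALSE)
  x <- cell_scores[, component]
  M <- length(x)
  if (statistic %in% c("skewness", "kurtosis") && M < 3)
    stop("need at least 3 pixels for higher moments", call. = FALSE)
  if (statistic == "mean") return(mean(x))
  if (statistic == "variance") return(stats::var(x))
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0)
    stop("zero-variance scores: ", statistic, " undefined", call. = FALSE)
  if (statistic == "skewness") mean((x - mean(x))^3) / m2^1.5
  else mean((x - mean(x))^4) / m2^2
}

#' Grey-level co-occurrence texture of a cell image
#'
#' Quantises the in-mask intensities to `levels` grey bins over the
#' cell's own min-max range, accumulates the symmetric co-occurrence
#' matrix of pixel pairs at the given distance for the four
#' orientations (0, 45, 90, 135 degrees; pairs involving out-of-mask
#' pixels are excluded), and averages the requested statistic over
#' orientations. Degenerate single-level cells return contrast 0,
#' energy 1, homogeneity 1.
#'
#' @param cell_image 2-D numeric matrix (cell bounding box).
#' @param mask Logical matrix, `TRUE` for pixels belonging to the cell.
#' @param metric One of `"glcm_contrast"`, `"glcm_homogeneity"`,
#'   `"glcm_energy"`.
#' @param levels Number of grey levels (default 16).
#' @param distance_px Pair offset in pixels (default 1).
#' @return A single numeric value.
#' @export
texture_feature <- function(cell_image, mask = NULL,
                            metric = c("glcm_contrast", "glcm_homogeneity",
                                       "glcm_energy"),
                            levels = 16, distance_px = 1) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(cell_image), levels >= 2, distance_px >= 1)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(cell_image), ncol(cell_image))
  stopifnot(identical(dim(mask), dim(cell_image)))
  if (sum(mask) < 4)
    stop("texture needs at least a 2x2 in-mask neighbourhood",
         call. = FALSE)
  v <- cell_image[mask]
  rng <- range(v)
  if (rng[2] == rng[1]) {
    return(switch(metric, glcm_contrast = 0, glcm_homogeneity = 1,
                  glcm_energy = 1))
  }
  q <- matrix(NA_integer_, nrow(cell_image), ncol(cell_image))
  q[mask] <- pmin(as.integer((cell_image[mask] - rng[1]) /
                               (rng[2] - rng[1]) * levels) + 1L, levels)
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1)) # 0,45,90,135 deg
  vals <- vapply(offsets, function(off) {
    P <- glcm_matrix(q, off * distance_px, levels)
    if (sum(P) == 0) return(NA_real_)
    P <- P / sum(P)
    i <- row(P); j <- col(P)
    switch(metric,
           glcm_contrast = sum(P * (i - j)^2),
           glcm_homogeneity = sum(P / (1 + abs(i - j))),
           glcm_energy = sum(P^2))
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# symmetric co-occurrence counts of quantised image q at offset (dr, dc)
glcm_matrix <- function(q, off, levels) {
  H <- nrow(q); W <- ncol(q)
  dr <- off[1]; dc <- off[2]
  r0 <- max(1, 1 - dr):min(H, H - dr)
  c0 <- max(1, 1 - dc):min(W, W - dc)
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + dr, c0 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  P <- matrix(0, levels, levels)
  if (any(ok)) {
    tab <- table(factor(a[ok], levels = seq_len(levels)),
                 factor(b[ok], levels = seq_len(levels)))
    P <- unclass(tab) + t(unclass(tab))
  }
  P
}

#' Morphology of a segmented cell
#'
#' Standard region properties of the labelled mask: pixel area,
#' boundary-face perimeter (count of 4-neighbour faces between cell
#' and non-cell pixels), eccentricity from the second central moments
#' of the pixel coordinates, and solidity (area over the pixel count
#' of the convex hull of the cell).
#'
#' @param seg A `segmentation`.
#' @param cell_id Cell label.
#' @return Named list with `area_px`, `perimeter_px`, `eccentricity`,
#'   `solidity`.
#' @export
morphology_features <- function(seg, cell_id) {
  stopifnot(inherits(seg, "segmentation"))
  if (!(cell_id %in% seq_len(seg$n_cells)))
    stop("unknown cell_id ", cell_id, call. = FALSE)
  H <- nrow(seg$labels)
  idx <- which(seg$labels == cell_id)
  r <- (idx - 1L) %% H + 1L
  cl <- (idx - 1L) %/% H + 1L
  area <- length(idx)
  incell <- matrix(FALSE, H, ncol(seg$labels))
  incell[idx] <- TRUE
  per <- perimeter_faces(incell)
  ecc <- if (area < 2) 0 else {
    cv <- stats::cov(cbind(r, cl)) * (area - 1) / area
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
  }
  sol <- area / convex_pixel_count(r, cl)
  list(area_px = area, perimeter_px = per, eccentricity = ecc,
       solidity = min(sol, 1))
}

perimeter_faces <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  up <- mask & !rbind(FALSE, mask[-H, , drop = FALSE])
  down <- mask & !rbind(mask[-1, , drop = FALSE], FALSE)
  left <- mask & !cbind(FALSE, mask[, -W, drop = FALSE])
  right <- mask & !cbind(mask[, -1, drop = FALSE], FALSE)
  sum(up) + sum(down) + sum(left) + sum(right)
}

# number of pixel centres inside (or on) the convex hull of the cell
convex_pixel_count <- function(r, cl) {
  if (length(r) < 3) return(length(r))
  pts <- unique(cbind(r, cl))
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  if (n < 3) return(length(r))
  # force counter-clockwise vertex order
  s <- sum(hull[, 1] * hull[c(2:n, 1), 2] - hull[c(2:n, 1), 1] * hull[, 2])
  if (s < 0) hull <- hull[n:1, , drop = FALSE]
  rr <- range(r); cc <- range(cl)
  grid <- expand.grid(r = rr[1]:rr[2], c = cc[1]:cc[2])
  inside <- rep(TRUE, nrow(grid))
  for (i in seq_len(n)) {
    p1 <- hull[i, ]; p2 <- hull[(i %% n) + 1, ]
    cross <- (p2[1] - p1[1]) * (grid$c - p1[2]) -
      (p2[2] - p1[2]) * (grid$r - p1[1])
    inside <- inside & (cross >= -1e-9)
  }
  max(sum(inside), length(r))
}
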