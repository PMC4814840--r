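#' Smooth pseudo-fluorophore endmember spectra
#'
#' Generates `k` discretised Gaussian excitation bumps over
#' `c_channels` channels with distinct, jittered centres, each
#' row-normalised to unit sum, and verifies that no pair is more
#' similar than cosine 0.95.
#'
#' @param c_channels Number of channels.
#' @param k Number of endmembers (`k <= c_channels`).
#' @param seed Integer seed (same seed, same matrix).
#' @param width Bump standard deviation in channel units.
#' @return K x C nonnegative matrix with rows summing to 1.
#' @export
make_endmembers <- function(c_channels, k, seed = 1, width = NULL) {
  stopifnot(k >= 1)
  if (k > c_channels)
    stop("cannot place more endmembers than channels", call. = FALSE)
  if (is.null(width)) width <- c_channels / (2.5 * k)
  set.seed(seed)
  for (attempt in 1:50) {
    centres <- seq(1, c_channels, length.out = k + 2)[2:(k + 1)] +
      stats::runif(k, -c_channels / (4 * k), c_channels / (4 * k))
    S <- t(vapply(centres, function(m)
      exp(-((seq_len(c_channels) - m)^2) / (2 * width^2)),
      numeric(c_channels)))
    S <- S / rowSums(S)
    if (k == 1) return(S)
    cosmax <- max(vapply(utils::combn(k, 2, simplify = FALSE), function(p) {
      a <- S[p[1], ]; b <- S[p[2], ]
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }, numeric(1)))
    if (cosmax < 0.95) return(S)
    width <- width * 0.8
  }
  stop("could not generate ", k, " sufficiently distinct endmembers for ",
       c_channels, " channels", call. = FALSE)
}

#' Synthetic multispectral scene description
#'
#' Defines the ground-truth model from which [render_scene()] samples
#' an image stack: non-overlapping disc-shaped cells with
#' spatially varying mixtures of endmember spectra, an optional
#' perinuclear ring of elevated short-wavelength abundance (emulating
#' the bright rings of protein-bound mitochondrial NADH), additive
#' background and Poisson shot noise.
#'
#' @param seed Integer seed driving all randomness of the scene.
#' @param image_size `c(H, W)` in pixels.
#' @param n_cells Number of cells.
#' @param cell_radius_px Length-2 interval of cell radii (px).
#' @param n_channels Number of spectral channels.
#' @param endmember_spectra K x C row-normalised matrix; default
#'   `make_endmembers(n_channels, 3, seed)`.
#' @param group_abundance_profiles Named list of groups, each a list
#'   with `mean` (length-K nonnegative) and `sd` (length-K); cells are
#'   assigned to groups round-robin.
#' @param background_level Additive background (counts).
#' @param photon_scale Expected counts of a unit-abundance cell pixel.
#' @param min_gap_px Minimum empty gap between cell rims in pixels.
#' @param perinuclear_ring If `TRUE`, boost the first endmember inside
#'   an annulus at ~60 percent of each cell radius.
#' @param ring_contrast Multiplicative boost inside the ring.
#' @param noise If `FALSE`, [render_scene()] returns the noiseless
#'   expectation.
#' @return A list of class `synth_scene`.
#' @export
synth_scene <- function(seed = 1, image_size = c(256, 256), n_cells = 12,
                        cell_radius_px = c(9, 14), n_channels = 18,
                        endmember_spectra = NULL,
                        group_abundance_profiles = NULL,
                        background_level = 2, photon_scale = 200,
                        min_gap_px = 2,
                        perinuclear_ring = TRUE, ring_contrast = 1.8,
                        noise = TRUE) {
  if (is.null(endmember_spectra))
    endmember_spectra <- make_endmembers(n_channels, 3, seed)
  K <- nrow(endmember_spectra)
  stopifnot(ncol(endmember_spectra) == n_channels,
            all(endmember_spectra >= 0))
  if (is.null(group_abundance_profiles))
    group_abundance_profiles <- list(
      A = list(mean = 2^(-(seq_len(K) - 1)), sd = 0.05))
  for (g in group_abundance_profiles) {
    stopifnot(length(g$mean) == K, all(g$mean >= 0))
  }
  structure(list(seed = as.integer(seed), image_size = image_size,
                 n_cells = as.integer(n_cells),
                 cell_radius_px = cell_radius_px,
                 n_channels = as.integer(n_channels),
                 endmember_spectra = endmember_spectra,
                 group_abundance_profiles = group_abundance_profiles,
                 background_level = background_level,
                 photon_scale = photon_scale,
                 min_gap_px = min_gap_px,
                 perinuclear_ring = isTRUE(perinuclear_ring),
                 ring_contrast = ring_contrast,
                 noise = isTRUE(noise)),
            class = "synth_scene")
}

#' Render a synthetic scene to a stack with ground truth
#'
#' Places the scene's cells without overlap (gap >= 2 px, fully inside
#' the image), builds the per-pixel expected intensity
#' `background + photon_scale * sum_k abundance_k(x) * spectrum_k`,
#' and draws seeded Poisson counts (unless the scene disables noise).
#'
#' @param scene A [synth_scene()].
#' @return A list: `stack` (a `hyper_stack`), `labels` (ground-truth
#'   H x W label matrix), `cells` (tibble: `cell_id`, `group`,
#'   `centre_row`, `centre_col`, `radius`, abundance columns `ab_1..`),
#'   `expectation` (H x W x C array), `group_of_cell` (factor).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "synth_scene"))
  set.seed(scene$seed)
  H <- scene$image_size[1]; W <- scene$image_size[2]
  K <- nrow(scene$endmember_spectra); C <- scene$n_channels
  rmax <- scene$cell_radius_px[2]
  centres <- matrix(NA_real_, scene$n_cells, 3) # row, col, radius
  for (i in seq_len(scene$n_cells)) {
    placed <- FALSE
    for (att in 1:1000) {
      rad <- stats::runif(1, scene$cell_radius_px[1],
                          scene$cell_radius_px[2])
      gap <- scene$min_gap_px %||% 2
      pos <- c(stats::runif(1, rad + 2, H - rad - 1),
               stats::runif(1, rad + 2, W - rad - 1))
      if (i == 1 || all(sqrt((centres[seq_len(i - 1), 1] - pos[1])^2 +
                               (centres[seq_len(i - 1), 2] - pos[2])^2) >=
                          centres[seq_len(i - 1), 3] + rad + gap)) {
        centres[i, ] <- c(pos, rad)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", scene$n_cells, " non-overlapping cells in ",
           H, "x", W, " px after 1000 attempts", call. = FALSE)
  }
  groups <- names(scene$group_abundance_profiles)
  group_of_cell <- factor(groups[((seq_len(scene$n_cells) - 1) %%
                                    length(groups)) + 1], levels = groups)
  labels <- matrix(0L, H, W)
  ab_maps <- array(0, dim = c(H, W, K))
  cell_ab <- matrix(0, scene$n_cells, K)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(scene$n_cells)) {
    prof <- scene$group_abundance_profiles[[as.character(group_of_cell[i])]]
    sd <- if (length(prof$sd) == 1) rep(prof$sd, K) else prof$sd
    ab <- pmax(stats::rnorm(K, prof$mean, sd), 0)
    cell_ab[i, ] <- ab
    d2 <- (rows - centres[i, 1])^2 + (cols - centres[i, 2])^2
    inside <- d2 <= centres[i, 3]^2
    labels[inside] <- i
    boost <- rep(1, sum(inside))
    if (scene$perinuclear_ring) {
      dd <- sqrt(d2[inside]) / centres[i, 3]
      boost <- ifelse(dd > 0.45 & dd < 0.75, scene$ring_contrast, 1)
    }
    for (k in seq_len(K)) {
      add <- ab[k] * (if (k == 1) boost else 1)
      ab_maps[, , k][inside] <- add
    }
  }
  expectation <- array(scene$background_level, dim = c(H, W, C))
  A <- matrix(ab_maps, H * W, K)
  E <- A %*% scene$endmember_spectra * scene$photon_scale
  expectation <- expectation + array(E, dim = c(H, W, C))
  data <- if (scene$noise)
    array(stats::rpois(length(expectation), expectation),
          dim = dim(expectation))
  else expectation
  ch <- channel_table(C)
  cells <- tibble::tibble(cell_id = seq_len(scene$n_cells),
                          group = as.character(group_of_cell),
                          centre_row = centres[, 1],
                          centre_col = centres[, 2],
                          radius = centres[, 3])
  for (k in seq_len(K)) cells[[paste0("ab_", k)]] <- cell_ab[, k]
  list(stack = hyper_stack(data, ch),
       labels = labels, cells = cells, expectation = expectation,
       group_of_cell = group_of_cell)
}

#' Synthetic two-group Gaussian feature dataset
#'
#' Draws `n_per_group` cells per group from `N(0, cov)` (group A) and
#' `N(effect, cov)` (group B). With equal covariances the optimal
#' (Bayes) AUROC is `pnorm(Delta / sqrt(2))` where `Delta` is the
#' Mahalanobis norm of `effect`, a useful closed-form reference for
#' classifier tests.
#'
#' @param n_per_group Cells per group.
#' @param p Number of features.
#' @param effect Length-p mean shift of group B.
#' @param cov P x P symmetric positive-definite covariance (default
#'   identity).
#' @param seed Integer seed.
#' @return A tibble with `cell_id`, `group` (`"A"`/`"B"`) and features
#'   `f01..`.
#' @export
make_feature_dataset <- function(n_per_group, p, effect = rep(0, p),
                                 cov = diag(p), seed = 1) {
  stopifnot(length(effect) == p, all(dim(cov) == p))
  if (!isSymmetric(unname(cov), tol = 1e-8))
    stop("cov must be symmetric positive definite", call. = FALSE)
  L <- tryCatch(chol(cov), error = function(e)
    stop("cov must be symmetric positive definite", call. = FALSE))
  set.seed(seed)
  Z <- matrix(stats::rnorm(2 * n_per_group * p), 2 * n_per_group, p) %*% L
  Z[(n_per_group + 1):(2 * n_per_group), ] <-
    sweep(Z[(n_per_group + 1):(2 * n_per_group), , drop = FALSE], 2,
          effect, "+")
  colnames(Z) <- sprintf("f%02d", seq_len(p))
  out <- tibble::tibble(cell_id = seq_len(2 * n_per_group),
                        group = rep(c("A", "B"), each = n_per_group))
  dplyr::bind_cols(out, tibble::as_tibble(Z))
}
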