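#' Feature registries
#'
#' A registry declares which per-cell features an experiment computes:
#' one row per feature with a unique `name`, a `family` (one of
#' `mean_intensity`, `band_ratio`, `pca_stat`, `channel_correlation`,
#' `similarity_stat`, `spectral_variation`, `texture`, `morphology`),
#' and family-specific `params`. Registries can be built in code,
#' loaded from YAML, or taken from a shipped preset.
#'
#' `default18` is the 18-channel preset: the mean intensities of the
#' channels nearest 360 and 460 nm excitation, four canonical band
#' ratios (360/460 and the channel-3/15, 5/6 and 8/14 pairs), the
#' variance of PC1, skewness of PC2 and mean of PC3 of the per-pixel
#' PCA scores, three channel correlations, the mean spectral-angle
#' variation, co-occurrence contrast in channels 4 and 6, and four
#' morphology features. `minimal` keeps just the 360/460 redox
#' surrogate, the 360 nm mean intensity and the cell area.
#'
#' @param preset `"default18"` or `"minimal"`.
#' @param channels Channel tibble used to resolve wavelength-named
#'   bands onto concrete channel indices.
#' @return A tibble with columns `name`, `family`, `params`
#'   (list-column).
#' @export
feature_registry <- function(preset = c("default18", "minimal"),
                             channels = channel_table(18)) {
  preset <- match.arg(preset)
  i360 <- nearest_channel(channels, 360) + 1L   # 1-based
  i460 <- nearest_channel(channels, 460) + 1L
  C <- nrow(channels)
  ch <- function(i) min(i, C)
  spec <- function(name, family, ...)
    tibble::tibble(name = name, family = family, params = list(list(...)))
  reg <- dplyr::bind_rows(
    spec("mean_ex360", "mean_intensity", channel = i360),
    spec("mean_ex460", "mean_intensity", channel = i460),
    spec("ratio_360_460", "band_ratio", num_channel = i360,
         den_channel = i460),
    spec("ratio_ch3_ch15", "band_ratio", num_channel = ch(3L),
         den_channel = ch(15L)),
    spec("ratio_ch5_ch6", "band_ratio", num_channel = ch(5L),
         den_channel = ch(6L)),
    spec("ratio_ch8_ch14", "band_ratio", num_channel = ch(8L),
         den_channel = ch(14L)),
    spec("pc1_variance", "pca_stat", component = 1L,
         statistic = "variance"),
    spec("pc2_skewness", "pca_stat", component = 2L,
         statistic = "skewness"),
    spec("pc3_mean", "pca_stat", component = 3L, statistic = "mean"),
    spec("corr_360_460", "channel_correlation", channel_a = i360,
         channel_b = i460),
    spec("corr_ch3_ch15", "channel_correlation", channel_a = ch(3L),
         channel_b = ch(15L)),
    spec("corr_ch5_ch6", "channel_correlation", channel_a = ch(5L),
         channel_b = ch(6L)),
    spec("spectral_variation", "spectral_variation"),
    spec("texture_ch4_contrast", "texture", channel = ch(4L),
         metric = "glcm_contrast", levels = 16L, distance_px = 1L),
    spec("texture_ch6_contrast", "texture", channel = ch(6L),
         metric = "glcm_contrast", levels = 16L, distance_px = 1L),
    spec("area", "morphology", property = "area_px"),
    spec("perimeter", "morphology", property = "perimeter_px"),
    spec("eccentricity", "morphology", property = "eccentricity"),
    spec("solidity", "morphology", property = "solidity")
  )
  if (preset == "minimal")
    reg <- reg[reg$name %in% c("ratio_360_460", "mean_ex360", "area"), ]
  validate_registry(reg, C)
  reg
}

validate_registry <- function(registry, n_channels = NULL) {
  stopifnot(is.data.frame(registry),
            all(c("name", "family", "params") %in% names(registry)))
  if (nrow(registry) == 0) stop("empty feature registry", call. = FALSE)
  if (anyDuplicated(registry$name))
    stop("duplicate feature names in registry", call. = FALSE)
  fams <- c("mean_intensity", "band_ratio", "pca_stat",
            "channel_correlation", "similarity_stat", "spectral_variation",
            "texture", "morphology")
  bad <- setdiff(registry$family, fams)
  if (length(bad) > 0)
    stop("unknown feature families: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(n_channels)) {
    for (i in seq_len(nrow(registry))) {
      p <- registry$params[[i]]
      chs <- unlist(p[grep("channel", names(p))])
      if (length(chs) > 0 && any(chs < 1 | chs > n_channels))
        stop("feature '", registry$name[i],
             "' references a channel outside 1..", n_channels,
             call. = FALSE)
    }
  }
  invisible(registry)
}

#' @rdname feature_registry
#' @param path YAML registry path: a list of records with keys `name`,
#'   `family` and the family parameters.
#' @export
read_feature_registry <- function(path) {
  doc <- yaml::read_yaml(path)
  recs <- doc$features %||% doc
  reg <- purrr::map_dfr(recs, function(r) {
    tibble::tibble(name = r$name, family = r$family,
                   params = list(r[setdiff(names(r), c("name", "family"))]))
  })
  validate_registry(reg)
  reg
}

#' @rdname feature_registry
#' @param registry A registry tibble to write.
#' @export
write_feature_registry <- function(registry, path) {
  validate_registry(registry)
  recs <- purrr::pmap(registry, function(name, family, params)
    c(list(name = name, family = family), params))
  yaml::write_yaml(list(features = recs), path)
  invisible(path)
}

#' Pixel-level PCA shared across groups
#'
#' Fits the PCA used for per-pixel principal-component score features.
#' When cell groups are compared, fit this model once on the pooled
#' pixels of every stack under comparison so that all cells share one
#' basis.
#'
#' @param stack_or_pixels A `hyper_stack`, a list of them, or an
#'   N_px x C pixel matrix.
#' @param seg Optional `segmentation` (or list of them, matching the
#'   stacks): restricts pooling to segmented cell pixels.
#' @return A `projection_model` (see [pca_fit()]).
#' @export
pixel_pca <- function(stack_or_pixels, seg = NULL) {
  px <- pool_pixels(stack_or_pixels, seg)
  if (nrow(px) <= ncol(px))
    stop("need more pixels than channels for a pixel PCA", call. = FALSE)
  pca_fit(px, standardise = FALSE)
}

pool_pixels <- function(stack_or_pixels, seg = NULL) {
  if (is.matrix(stack_or_pixels)) return(stack_or_pixels)
  stacks <- if (inherits(stack_or_pixels, "hyper_stack"))
    list(stack_or_pixels) else stack_or_pixels
  segs <- if (is.null(seg)) vector("list", length(stacks))
          else if (inherits(seg, "segmentation")) list(seg) else seg
  px <- purrr::map2(stacks, segs, function(st, sg) {
    d <- dim(st$data)
    V <- matrix(st$data, d[1] * d[2], d[3])
    keep <- as.vector(st$valid_mask)
    if (!is.null(sg)) keep <- keep & as.vector(sg$labels > 0)
    V[keep, , drop = FALSE]
  })
  out <- do.call(rbind, px)
  colnames(out) <- stacks[[1]]$channels$label
  out
}

#' Extract a per-cell feature table
#'
#' Computes every registry feature for every segmented cell that is
#' wholly contained in the image (border-touching cells are excluded).
#' Cells for which any feature is undefined (for example a zero
#' variance correlation) are dropped with a message. Column order
#' follows the registry.
#'
#' @param stack A `hyper_stack` (typically denoised and
#'   background-subtracted).
#' @param seg A `segmentation` of that stack.
#' @param registry Feature registry tibble (see [feature_registry()]).
#' @param shared_pca Optional `projection_model` from [pixel_pca()];
#'   required semantics for group comparisons is one shared model. If
#'   `NULL` and `pca_stat` features are requested, a model is fitted on
#'   this stack's cell pixels (a message notes this).
#' @param endmembers Optional `endmember_set` (reserved for
#'   similarity-to-endmember features).
#' @param refs Optional reference spectra tibble from
#'   [read_reference_spectra()]; required for `similarity_stat`
#'   features.
#' @param group Optional single group label attached to all cells.
#' @param stack_id Provenance string recorded in the table.
#' @return A tibble: `cell_id`, optional `group`, one column per
#'   feature.
#' @export
extract_features <- function(stack, seg, registry = feature_registry(
                               channels = stack$channels),
                             shared_pca = NULL, endmembers = NULL,
                             refs = NULL, group = NULL,
                             stack_id = "stack") {
  stopifnot(inherits(stack, "hyper_stack"), inherits(seg, "segmentation"))
  validate_registry(registry, n_channels = n_channels(stack))
  need_pca <- any(registry$family == "pca_stat")
  if (need_pca && is.null(shared_pca)) {
    message("fitting pixel PCA on this stack only; pass `shared_pca` ",
            "for cross-group comparisons")
    shared_pca <- pixel_pca(stack, seg)
  }
  if (any(registry$family == "similarity_stat") && is.null(refs))
    stop("registry requests similarity_stat features but no reference ",
         "spectra were supplied", call. = FALSE)
  if (need_pca && ncol(shared_pca$basis) <
        max(purrr::map_int(registry$params[registry$family == "pca_stat"],
                           ~ as.integer(.x$component))))
    stop("shared PCA has too few components for the registry",
         call. = FALSE)

  keep_ids <- seg$cells$cell_id[!seg$cells$border_touching]
  rows <- purrr::map(keep_ids, function(id) {
    cell <- cell_pixels(stack, seg, id)
    scores <- if (need_pca) pca_transform(shared_pca, cell) else NULL
    vals <- purrr::map_dbl(seq_len(nrow(registry)), function(i) {
      fam <- registry$family[i]; p <- registry$params[[i]]
      tryCatch(switch(fam,
        mean_intensity = mean_channel_intensity(cell, p$channel),
        band_ratio = band_ratio(cell, p$num_channel, p$den_channel),
        pca_stat = pca_abundance_stat(scores, p$component, p$statistic),
        channel_correlation = channel_correlation(cell, p$channel_a,
                                                  p$channel_b),
        similarity_stat = similarity_stat(cell, refs, p),
        spectral_variation = spectral_variation(cell),
        texture = texture_cell(stack, seg, id, p),
        morphology = morphology_features(seg, id)[[p$property]]
      ), error = function(e) NaN)
    })
    vals
  })
  mat <- do.call(rbind, rows)
  if (is.null(mat)) mat <- matrix(numeric(0), 0, nrow(registry))
  colnames(mat) <- registry$name
  ok <- rowSums(!is.finite(mat)) == 0
  if (any(!ok))
    message("dropping ", sum(!ok), " cell(s) with undefined features: ",
            paste(keep_ids[!ok], collapse = ", "))
  out <- tibble::tibble(cell_id = keep_ids[ok])
  if (!is.null(group)) out$group <- group
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat[ok, , drop = FALSE]))
  attr(out, "stack_id") <- stack_id
  out
}

similarity_stat <- function(cell, refs, p) {
  ref <- refs$values[[match(p$reference_name, refs$name)]]
  if (is.null(ref) || anyNA(ref))
    stop("unknown reference spectrum: ", p$reference_name, call. = FALSE)
  metric <- p$metric %||% "sam_angle"
  statf <- match.fun(p$statistic %||% "mean")
  norms <- sqrt(rowSums(cell^2))
  vals <- apply(cell[norms > 0, , drop = FALSE], 1, spectral_similarity,
                reference = ref, metric = metric)
  statf(vals)
}

texture_cell <- function(stack, seg, id, p) {
  H <- nrow(seg$labels)
  idx <- which(seg$labels == id)
  r <- (idx - 1L) %% H + 1L
  cl <- (idx - 1L) %/% H + 1L
  rr <- range(r); cc <- range(cl)
  sub <- stack$data[rr[1]:rr[2], cc[1]:cc[2], p$channel, drop = TRUE]
  if (!is.matrix(sub)) sub <- matrix(sub, rr[2] - rr[1] + 1)
  msk <- seg$labels[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == id
  texture_feature(sub, msk, metric = p$metric %||% "glcm_contrast",
                  levels = p$levels %||% 16L,
                  distance_px = p$distance_px %||% 1L)
}
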