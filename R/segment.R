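#' Composite intensity image
#'
#' Collapses a stack to a single intensity image by a nonnegative
#' weighted sum over channels, rescaled to `[0, 1]`. This is the image
#' the segmenter thresholds.
#'
#' @param stack A `hyper_stack`.
#' @param channel_weights Length-C nonnegative weights, not all zero.
#'   Defaults to uniform weights.
#' @return H x W numeric matrix in `[0, 1]`.
#' @export
composite_intensity <- function(stack, channel_weights = NULL) {
  stopifnot(inherits(stack, "hyper_stack"))
  C <- n_channels(stack)
  if (is.null(channel_weights)) channel_weights <- rep(1, C)
  stopifnot(length(channel_weights) == C, all(is.finite(channel_weights)))
  if (any(channel_weights < 0))
    stop("channel weights must be nonnegative", call. = FALSE)
  if (all(channel_weights == 0))
    stop("channel weights must not all be zero", call. = FALSE)
  d <- dim(stack$data)
  comp <- matrix(0, d[1], d[2])
  for (c in seq_len(C))
    comp <- comp + channel_weights[c] * stack$data[, , c]
  rng <- range(comp)
  if (rng[2] > rng[1]) (comp - rng[1]) / (rng[2] - rng[1]) else comp * 0
}

# 4-connected labelling of a logical mask via the pixel adjacency graph
label_4connected <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, H, W)
  if (length(idx) == 0) return(labels)
  row <- (idx - 1L) %% H + 1L
  col <- (idx - 1L) %/% H + 1L
  pos <- integer(H * W); pos[idx] <- seq_along(idx)
  right <- idx[col < W][mask[idx[col < W] + H]]
  down <- idx[row < H][mask[idx[row < H] + 1L]]
  edges <- rbind(cbind(pos[right], pos[right + H]),
                 cbind(pos[down], pos[down + 1L]))
  if (nrow(edges) == 0) {
    labels[idx] <- seq_along(idx)
    return(labels)
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # relabel 1..N in raster order of first occurrence (deterministic)
  uniq <- unique(comp)
  remap <- integer(max(comp))
  remap[uniq] <- seq_along(uniq)
  labels[idx] <- remap[comp]
  labels
}

#' Segment individual cells from a multispectral stack
#'
#' Standard robust pipeline: Gaussian smoothing of the composite
#' intensity image, Otsu threshold, hole filling, optional marker-based
#' watershed split of touching cells (markers come from the smoothed
#' distance transform), area filter, and 4-connected labelling. Cells
#' touching the image border are kept in the label image but flagged,
#' so downstream feature extraction can restrict itself to cells wholly
#' contained in the field of view.
#'
#' @param stack A `hyper_stack` (denoised or raw).
#' @param min_area_px Minimum region area in pixels (default 50, to
#'   reject debris).
#' @param split_touching If `TRUE`, split touching cells by watershed.
#' @param channel_weights Weights for [composite_intensity()].
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @return A list of class `segmentation` with elements `labels`
#'   (H x W integer matrix, 0 = background, 1..n = cells), `n_cells`,
#'   `min_area_px`, `channel_weights`, and `cells`, a tibble with one
#'   row per cell: `cell_id`, `area`, `centroid_row`, `centroid_col`,
#'   `border_touching`.
#' @export
segment_cells <- function(stack, min_area_px = 50, split_touching = TRUE,
                          channel_weights = NULL, smooth_sigma = 2) {
  stopifnot(inherits(stack, "hyper_stack"), min_area_px >= 1)
  C <- n_channels(stack)
  if (is.null(channel_weights)) channel_weights <- rep(1, C)
  comp <- composite_intensity(stack, channel_weights)
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(comp), ncol(comp)), n_cells = 0L,
                   min_area_px = as.integer(min_area_px),
                   channel_weights = channel_weights,
                   cells = tibble::tibble(cell_id = integer(),
                                          area = integer(),
                                          centroid_row = numeric(),
                                          centroid_col = numeric(),
                                          border_touching = logical())),
              class = "segmentation")
  }
  if (max(comp) == 0) return(empty())
  sm <- as.matrix(EBImage::gblur(EBImage::Image(comp), sigma = smooth_sigma))
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  fg <- sm > thr
  fg <- as.matrix(EBImage::fillHull(EBImage::Image(fg))) > 0
  if (!any(fg)) return(empty())
  if (split_touching) {
    dm <- EBImage::distmap(EBImage::Image(fg))
    dm <- EBImage::gblur(dm, sigma = 2)
    ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    wsm <- as.matrix(EBImage::imageData(ws))
    # re-run 4-connected labelling inside each watershed region
    labels <- matrix(0L, nrow(fg), ncol(fg))
    nxt <- 0L
    for (w in sort(unique(wsm[wsm > 0]))) {
      sub <- label_4connected(wsm == w & fg)
      k <- max(sub)
      if (k > 0) {
        labels[sub > 0] <- sub[sub > 0] + nxt
        nxt <- nxt + k
      }
    }
  } else {
    labels <- label_4connected(fg)
  }
  # area filter, then contiguous relabel in raster order
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0], nbins = max(labels))
    keep <- which(areas >= min_area_px)
    labels[!(labels %in% keep)] <- 0L
    labels <- relabel_raster(labels)
  }
  n <- max(labels)
  if (n == 0) return(empty())
  H <- nrow(labels); W <- ncol(labels)
  cells <- purrr::map_dfr(seq_len(n), function(i) {
    idx <- which(labels == i)
    r <- (idx - 1L) %% H + 1L
    cl <- (idx - 1L) %/% H + 1L
    tibble::tibble(cell_id = i, area = length(idx),
                   centroid_row = mean(r), centroid_col = mean(cl),
                   border_touching = any(r == 1L | r == H | cl == 1L |
                                           cl == W))
  })
  structure(list(labels = labels, n_cells = n,
                 min_area_px = as.integer(min_area_px),
                 channel_weights = channel_weights, cells = cells),
            class = "segmentation")
}

# relabel positive labels contiguously 1..N by raster order of first pixel
relabel_raster <- function(labels) {
  ids <- labels[labels > 0]
  if (length(ids) == 0) return(labels)
  uniq <- unique(ids[order(which(labels > 0))])
  remap <- integer(max(labels))
  remap[uniq] <- seq_along(uniq)
  labels[labels > 0] <- remap[ids]
  labels
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d cells (min area %d px), %d border-touching\n",
              x$n_cells, x$min_area_px, sum(x$cells$border_touching)))
  invisible(x)
}

#' Pixel-by-channel matrix of one segmented cell
#'
#' Extracts the spectra of all pixels belonging to a cell: one row per
#' pixel (raster order), one column per spectral channel.
#'
#' @param stack A `hyper_stack`.
#' @param seg A `segmentation` from [segment_cells()].
#' @param cell_id Cell label in `1..n_cells`.
#' @return M x C numeric matrix, M the cell's pixel count.
#' @export
cell_pixels <- function(stack, seg, cell_id) {
  stopifnot(inherits(stack, "hyper_stack"), inherits(seg, "segmentation"))
  if (!(cell_id %in% seq_len(seg$n_cells)))
    stop("unknown cell_id ", cell_id, " (stack has ", seg$n_cells,
         " cells)", call. = FALSE)
  idx <- which(seg$labels == cell_id)
  d <- dim(stack$data)
  m <- matrix(0, length(idx), d[3])
  for (c in seq_len(d[3]))
    m[, c] <- stack$data[idx + (c - 1L) * d[1] * d[2]]
  colnames(m) <- stack$channels$label
  m
}

#' Write a label image as a single-page 16-bit TIFF
#'
#' @param seg A `segmentation`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  tiff::writeTIFF(seg$labels / (2^16 - 1), path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}
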