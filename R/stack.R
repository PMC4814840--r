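#' Multispectral image stack container
#'
#' A `hyper_stack` holds an H x W x C cube of nonnegative fluorescence
#' intensities (camera counts), the channel metadata describing each of
#' the C excitation/emission bands, an optional per-channel background
#' estimate, and a mask of valid pixels (saturated pixels are excluded
#' via the mask rather than clipped).
#'
#' @param data Numeric H x W x C array (a matrix is treated as C = 1).
#'   Values must be finite; negative values are clamped to zero.
#' @param channels Channel tibble (see [channel_table()]) with C rows.
#' @param background Optional length-C nonnegative numeric, the
#'   per-channel background that has been (or will be) subtracted.
#' @param valid_mask Optional H x W logical matrix; defaults to all
#'   `TRUE`.
#' @return An object of class `hyper_stack`.
#' @examples
#' st <- hyper_stack(array(1, dim = c(4, 4, 3)), channel_table(3))
#' dim(st)
#' @export
hyper_stack <- function(data, channels, background = NULL, valid_mask = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(is.finite(data)))
    stop("stack intensities must be finite", call. = FALSE)
  data[data < 0] <- 0
  validate_channels(channels)
  C <- dim(data)[3]
  if (nrow(channels) != C)
    stop("channel metadata has ", nrow(channels), " rows but the stack has ",
         C, " channels", call. = FALSE)
  if (is.null(background)) background <- rep(0, C)
  stopifnot(length(background) == C, all(is.finite(background)),
            all(background >= 0))
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  }
  stopifnot(is.logical(valid_mask),
            identical(dim(valid_mask), dim(data)[1:2]))
  structure(
    list(data = data, channels = channels,
         background_per_channel = as.numeric(background),
         valid_mask = valid_mask),
    class = "hyper_stack")
}

#' @export
dim.hyper_stack <- function(x) dim(x$data)

#' Number of spectral channels of a stack
#' @param stack A `hyper_stack`.
#' @return Integer channel count.
#' @export
n_channels <- function(stack) dim(stack$data)[3]

#' @export
print.hyper_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_stack> %d x %d px, %d channels (ex %.0f-%.0f nm)\n",
              d[1], d[2], d[3],
              min(x$channels$ex_center_nm), max(x$channels$ex_center_nm)))
  cat(sprintf("  intensity range [%.3g, %.3g], %d/%d valid px\n",
              min(x$data), max(x$data), sum(x$valid_mask),
              length(x$valid_mask)))
  invisible(x)
}

# Map doubles onto the nearest float32 value (used to make the 32-bit
# TIFF round trip exact on float32-representable inputs).
as_float32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.vector(x), raw(), size = 4L),
                 "numeric", n = length(x), size = 4L)
  dim(out) <- d
  out
}

#' Read and write multispectral stacks
#'
#' Stacks are stored as a multi-page TIFF (one page per channel, in
#' channel-index order) plus a YAML sidecar holding the channel
#' metadata and the intensity scale. Integer-valued stacks with a
#' maximum below 2^16 are stored as 16-bit pages and round-trip
#' bit-exactly; other data is stored as 32-bit samples under a
#' power-of-two scale and is recovered on the float32 grid.
#'
#' @param tiff_path Path to the multi-page TIFF.
#' @param channel_config_path Path to the YAML sidecar; defaults to the
#'   TIFF path with extension `.yaml`.
#' @param stack A `hyper_stack` to write.
#' @return `read_stack()` returns a `hyper_stack` (valid mask
#'   all-`TRUE`); `write_stack()` returns `tiff_path` invisibly.
#' @export
read_stack <- function(tiff_path, channel_config_path = NULL) {
  if (is.null(channel_config_path))
    channel_config_path <- default_sidecar(tiff_path)
  doc <- yaml::read_yaml(channel_config_path)
  channels <- read_channel_config(channel_config_path)
  scale <- doc$intensity_scale %||% 1
  storage <- doc$storage %||% "uint16"
  # as.is only for integer pages: 32-bit samples overflow signed int
  pages <- tiff::readTIFF(tiff_path, all = TRUE,
                          as.is = (storage == "uint16"))
  if (length(pages) != nrow(channels))
    stop("TIFF has ", length(pages), " pages but the channel config lists ",
         nrow(channels), " channels", call. = FALSE)
  dims <- unique(purrr::map(pages, dim))
  if (length(dims) != 1)
    stop("all TIFF pages must share the same height and width", call. = FALSE)
  cube <- array(0, dim = c(dims[[1]], nrow(channels)))
  for (i in seq_along(pages)) {
    page <- pages[[i]]
    cube[, , i] <- if (storage == "uint16") as.numeric(page)
                   else as_float32(as.numeric(page) * scale)
  }
  hyper_stack(cube, channels)
}

#' @rdname read_stack
#' @export
write_stack <- function(stack, tiff_path, channel_config_path = NULL) {
  stopifnot(inherits(stack, "hyper_stack"))
  if (is.null(channel_config_path))
    channel_config_path <- default_sidecar(tiff_path)
  x <- stack$data
  mx <- max(x)
  integerish <- all(x == round(x)) && mx < 2^16
  if (integerish) {
    storage <- "uint16"; scale <- 1
    pages <- purrr::map(seq_len(dim(x)[3]), ~ x[, , .x] / (2^16 - 1))
    bits <- 16L
  } else {
    storage <- "float32"
    scale <- 2^ceiling(log2(max(mx, 1)))
    pages <- purrr::map(seq_len(dim(x)[3]), ~ x[, , .x] / scale)
    bits <- 32L
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  write_channel_config(stack$channels, channel_config_path)
  doc <- yaml::read_yaml(channel_config_path)
  doc$storage <- storage
  doc$intensity_scale <- scale
  yaml::write_yaml(doc, channel_config_path)
  invisible(tiff_path)
}

default_sidecar <- function(tiff_path) {
  paste0(tools::file_path_sans_ext(tiff_path), ".yaml")
}

#' Estimate per-channel background level
#'
#' When no dark frame is available the background is estimated in-image
#' as a low percentile of each channel over the valid pixels (default:
#' 5th percentile of the field).
#'
#' @param stack A `hyper_stack`.
#' @param percentile Percentile in `[0, 100]`.
#' @return Length-C numeric vector of background levels.
#' @export
estimate_background <- function(stack, percentile = 5) {
  stopifnot(inherits(stack, "hyper_stack"),
            percentile >= 0, percentile <= 100)
  if (!any(stack$valid_mask))
    stop("cannot estimate background: no valid pixels", call. = FALSE)
  apply(stack$data, 3, function(ch)
    stats::quantile(ch[stack$valid_mask], probs = percentile / 100,
                    names = FALSE, type = 7))
}

#' Subtract per-channel background
#'
#' Subtracts a background level from every pixel of each channel and
#' clamps at zero. If `background` is omitted it is estimated with
#' [estimate_background()].
#'
#' @param stack A `hyper_stack`.
#' @param background Length-C nonnegative numeric, or `NULL` to
#'   estimate in-image.
#' @param percentile Percentile used when estimating.
#' @return A `hyper_stack` with the background removed and recorded in
#'   `background_per_channel`.
#' @export
subtract_background <- function(stack, background = NULL, percentile = 5) {
  stopifnot(inherits(stack, "hyper_stack"))
  if (is.null(background)) background <- estimate_background(stack, percentile)
  C <- n_channels(stack)
  if (length(background) != C)
    stop("background has length ", length(background),
         " but the stack has ", C, " channels", call. = FALSE)
  stopifnot(all(is.finite(background)), all(background >= 0))
  out <- stack$data
  for (c in seq_len(C)) out[, , c] <- pmax(out[, , c] - background[c], 0)
  hyper_stack(out, stack$channels, background = background,
              valid_mask = stack$valid_mask)
}

#' Flag saturated pixels as invalid
#'
#' Pixels at or above the camera full-well value in any channel are
#' removed from the valid mask (not clipped), so they are excluded from
#' background estimation and feature extraction.
#'
#' @param stack A `hyper_stack`.
#' @param full_well Saturation threshold in camera counts.
#' @return The stack with an updated `valid_mask`.
#' @export
flag_saturated <- function(stack, full_well) {
  stopifnot(inherits(stack, "hyper_stack"), full_well > 0)
  sat <- apply(stack$data >= full_well, c(1, 2), any)
  stack$valid_mask <- stack$valid_mask & !sat
  stack
}
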