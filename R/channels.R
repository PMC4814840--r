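#' Build a channel metadata table
#'
#' Describes the excitation/emission layout of a multispectral
#' autofluorescence acquisition as one row per spectral channel. The
#' default layout follows a wide-field multispectral microscope with
#' excitation bands 10 nm wide spread between 334 and 495 nm and a
#' single long-pass emission window of 450-700 nm.
#'
#' @param n_channels Number of spectral channels.
#' @param ex_range Length-2 numeric, lowest and highest excitation band
#'   centre in nanometres. Centres are spaced evenly across this range.
#' @param ex_bandwidth_nm Excitation band width (nm), identical for all
#'   channels.
#' @param em_range Length-2 numeric, emission detection window (nm).
#' @return A tibble with columns `index` (0-based, contiguous),
#'   `ex_center_nm`, `ex_bw_nm`, `em_low_nm`, `em_high_nm`, `label`.
#' @examples
#' channel_table(18)
#' @export
channel_table <- function(n_channels = 18, ex_range = c(334, 495),
                          ex_bandwidth_nm = 10, em_range = c(450, 700)) {
  stopifnot(n_channels >= 1, length(ex_range) == 2, length(em_range) == 2)
  centres <- if (n_channels == 1) mean(ex_range) else
    seq(ex_range[1], ex_range[2], length.out = n_channels)
  ch <- tibble::tibble(
    index = seq_len(n_channels) - 1L,
    ex_center_nm = centres,
    ex_bw_nm = rep(ex_bandwidth_nm, n_channels),
    em_low_nm = rep(em_range[1], n_channels),
    em_high_nm = rep(em_range[2], n_channels),
    label = sprintf("ex%03.0f", centres)
  )
  validate_channels(ch)
  ch
}

validate_channels <- function(channels) {
  req <- c("index", "ex_center_nm", "ex_bw_nm", "em_low_nm", "em_high_nm", "label")
  missing <- setdiff(req, names(channels))
  if (length(missing) > 0)
    stop("channel config is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- as.integer(channels$index)
  if (!identical(idx, seq_along(idx) - 1L))
    stop("channel indices must be unique and contiguous from 0, in order",
         call. = FALSE)
  if (any(channels$em_low_nm >= channels$em_high_nm))
    stop("emission window must satisfy em_low_nm < em_high_nm", call. = FALSE)
  if (any(channels$ex_bw_nm <= 0))
    stop("excitation bandwidth must be positive", call. = FALSE)
  invisible(channels)
}

#' Read or write a channel configuration file
#'
#' Channel metadata travels with a stack as a YAML sidecar: a list of
#' records with keys `index`, `ex_center_nm`, `ex_bw_nm`, `em_low_nm`,
#' `em_high_nm`, `label`. Extra top-level keys (such as the intensity
#' scale recorded by [write_stack()]) are preserved by the stack IO and
#' ignored here.
#'
#' @param path Path to the YAML file.
#' @param channels A channel tibble as produced by [channel_table()].
#' @return `read_channel_config()` returns the channel tibble;
#'   `write_channel_config()` returns `path` invisibly.
#' @export
read_channel_config <- function(path) {
  doc <- yaml::read_yaml(path)
  recs <- if (!is.null(doc$channels)) doc$channels else doc
  if (!is.list(recs) || length(recs) == 0)
    stop("no channel records found in ", path, call. = FALSE)
  ch <- purrr::map_dfr(recs, function(r) {
    tibble::tibble(
      index = as.integer(r$index),
      ex_center_nm = as.numeric(r$ex_center_nm),
      ex_bw_nm = as.numeric(r$ex_bw_nm),
      em_low_nm = as.numeric(r$em_low_nm),
      em_high_nm = as.numeric(r$em_high_nm),
      label = as.character(r$label %||% sprintf("ch%02d", as.integer(r$index)))
    )
  })
  ch <- dplyr::arrange(ch, .data$index)
  validate_channels(ch)
  ch
}

#' @rdname read_channel_config
#' @export
write_channel_config <- function(channels, path) {
  validate_channels(channels)
  recs <- purrr::pmap(channels, function(index, ex_center_nm, ex_bw_nm,
                                         em_low_nm, em_high_nm, label, ...) {
    list(index = as.integer(index), ex_center_nm = ex_center_nm,
         ex_bw_nm = ex_bw_nm, em_low_nm = em_low_nm,
         em_high_nm = em_high_nm, label = label)
  })
  yaml::write_yaml(list(channels = recs), path)
  invisible(path)
}

#' Find the channel nearest a given excitation centre
#'
#' Used to resolve named band-ratio features such as the classic
#' 360 nm / 460 nm excitation redox surrogate onto concrete channel
#' indices of a particular acquisition.
#'
#' @param channels A channel tibble.
#' @param ex_nm Target excitation centre (nm).
#' @return The 0-based `index` of the nearest channel.
#' @export
nearest_channel <- function(channels, ex_nm) {
  validate_channels(channels)
  channels$index[which.min(abs(channels$ex_center_nm - ex_nm))]
}
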