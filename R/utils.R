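`%||%` <- function(a, b) if (is.null(a)) b else a

#' Peak signal-to-noise ratio
#'
#' PSNR of an image against a reference, in decibels:
#' `10 log10(peak^2 / mse)` where `mse` is the mean squared error and
#' `peak` defaults to the dynamic range of the reference.
#'
#' @param image,reference Numeric arrays of identical shape.
#' @param peak Peak signal value; defaults to `max(reference)`.
#' @return PSNR in dB (`Inf` for identical inputs).
#' @export
psnr <- function(image, reference, peak = max(reference)) {
  stopifnot(identical(dim(image), dim(reference)), peak > 0)
  mse <- mean((image - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# numeric matrix from a data frame of features (keeps non-numeric ids out)
feature_matrix <- function(table, feature_names = NULL) {
  if (is.matrix(table)) {
    m <- table
    if (is.null(colnames(m)))
      colnames(m) <- sprintf("f%02d", seq_len(ncol(m)))
  } else {
    df <- as.data.frame(table)
    num <- vapply(df, is.numeric, logical(1))
    drop <- intersect(names(df), c("cell_id", "stack_id"))
    num[drop] <- FALSE
    m <- as.matrix(df[, num, drop = FALSE])
  }
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, colnames(m))
    if (length(missing) > 0)
      stop("features absent from table: ", paste(missing, collapse = ", "),
           call. = FALSE)
    m <- m[, feature_names, drop = FALSE]
  }
  m
}

# group labels as a factor with >= 2 observations checkable by callers
as_group_factor <- function(groups) {
  if (is.list(groups) && !is.null(groups$labels)) groups <- groups$labels
  f <- factor(groups)
  droplevels(f)
}
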