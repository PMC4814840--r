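#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a projection model
#'
#' One row per (feature, canonical variable) loading.
#'
#' @param x A `projection_model`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `component`, `loading`.
#' @method tidy projection_model
#' @export
tidy.projection_model <- function(x, ...) {
  B <- x$basis
  tibble::tibble(
    feature = rep(x$feature_names, ncol(B)),
    component = rep(paste0("CV", seq_len(ncol(B))), each = nrow(B)),
    loading = as.vector(B))
}

#' @rdname tidy.projection_model
#' @method glance projection_model
#' @export
glance.projection_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_features = length(x$feature_names),
                 n_components = ncol(x$basis),
                 leading_score = x$axis_scores[1],
                 degenerate = isTRUE(x$degenerate))
}

#' @rdname tidy.projection_model
#' @param data Feature table to project.
#' @method augment projection_model
#' @export
augment.projection_model <- function(x, data, ...) {
  sc <- pca_transform(x, data)
  dplyr::bind_cols(tibble::as_tibble(data), tibble::as_tibble(sc))
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return `tidy()`: the ROC points (threshold, fpr, tpr);
#'   `glance()`: one row with scheme, n, AUROC.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$roc_points

#' @rdname tidy.cv_report
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, n = length(x$per_sample_scores),
                 auroc = x$auroc,
                 n_features = length(x$selected_features %||% character(0)))
}

#' Tidy an endmember set
#'
#' @param x An `endmember_set`.
#' @param ... Unused.
#' @return One row per (endmember, channel) with the spectrum weight.
#' @method tidy endmember_set
#' @export
tidy.endmember_set <- function(x, ...) {
  K <- nrow(x$spectra); C <- ncol(x$spectra)
  tibble::tibble(
    endmember = rep(seq_len(K), C),
    channel = rep(seq_len(C), each = K),
    ex_center_nm = rep(x$channels$ex_center_nm, each = K),
    weight = as.vector(x$spectra))
}

#' @rdname tidy.endmember_set
#' @method glance endmember_set
#' @export
glance.endmember_set <- function(x, ...) {
  tibble::tibble(k = x$k, residual_rms = x$residual_rms)
}

#' ROC curve plot
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr,
                                                  y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%s ROC, AUROC = %.3f", object$scheme,
                                  object$auroc)) +
    ggplot2::theme_minimal()
}

#' Endmember spectra plot
#'
#' @param object An `endmember_set`.
#' @param ... Unused.
#' @return A ggplot of each endmember's excitation profile.
#' @method autoplot endmember_set
#' @export
autoplot.endmember_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ex_center_nm,
                                   y = .data$weight,
                                   colour = factor(.data$endmember))) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Excitation centre (nm)", y = "Normalised weight",
                  colour = "Endmember") +
    ggplot2::theme_minimal()
}

#' Canonical-variable scatter plot
#'
#' Projects a feature table onto the first two canonical variables of
#' a fitted model and colours points by group.
#'
#' @param model A `projection_model` with >= 2 components (for 1-D
#'   models a jittered strip is drawn).
#' @param table Feature table.
#' @param groups Optional group labels.
#' @return A ggplot.
#' @export
plot_scores <- function(model, table, groups = NULL) {
  r <- min(2, ncol(model$basis))
  sc <- pca_transform(model, table, n_components = r)
  df <- tibble::as_tibble(sc)
  if (!is.null(groups)) df$group <- as_group_factor(groups)
  if (r == 1) df$CV2 <- stats::runif(nrow(df), -0.2, 0.2)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$CV1, y = .data$CV2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "Canonical variable 1",
                  y = if (r == 1) "jitter" else "Canonical variable 2")
  if (is.null(df$group)) p + ggplot2::geom_point(alpha = 0.8)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group),
                               alpha = 0.8)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
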