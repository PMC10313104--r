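# ggplot2 displays: Bull's eye polar maps and embedding scatter panels.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bull's eye polar display
#'
#' Renders the ring/segment grid as a polar heatmap: the apex at the center,
#' the base outermost, segment 1 anchored at the junction and proceeding
#' anticlockwise. Metrics flagged `log_scale` (p-values) use a logarithmic
#' color scale.
#'
#' @param object a `myo_bullseye`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot myo_bullseye
#' @export
autoplot.myo_bullseye <- function(object, ...) {
  df <- tidy.myo_bullseye(object)
  n_c <- max(df$segment)
  df$start <- (df$segment - 1) / n_c * 360
  df$end <- df$segment / n_c * 360
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = .data$ring - 1, ymax = .data$ring,
                                    fill = .data$value), color = NA) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = attr(object, "metric"))
  if (isTRUE(attr(object, "log_scale"))) {
    p <- p + ggplot2::scale_fill_viridis_c(trans = "log10", direction = -1,
                                           na.value = "grey85")
  } else {
    p <- p + ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85")
  }
  p
}

#' Embedding scatter colored by clinical covariates
#'
#' One panel per requested covariate: continuous covariates use a sequential
#' colormap, categorical ones a discrete palette; missing values are gray.
#'
#' @param embedding a `myo_embedding`.
#' @param covariates data frame with `subject_id` and covariate columns.
#' @param vars covariate names to display (default: all shared columns).
#' @return a ggplot (faceted over covariates via long format).
#' @export
plot_colored <- function(embedding, covariates, vars = NULL) {
  pts <- embedding$points
  df <- dplyr::left_join(pts, covariates, by = "subject_id")
  if (is.null(vars)) vars <- setdiff(names(covariates), "subject_id")
  panels <- lapply(vars, function(v) {
    vals <- df[[v]]
    if (all(is.na(vals))) {
      rlang::warn(paste0("covariate '", v, "' is entirely missing; gray panel"))
      return(ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
               ggplot2::geom_point(color = "grey60") +
               ggplot2::labs(title = v) + ggplot2::theme_minimal())
    }
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
      ggplot2::labs(title = v) + ggplot2::theme_minimal()
    if (is.numeric(vals)) {
      p + ggplot2::geom_point(ggplot2::aes(color = .data[[v]])) +
        ggplot2::scale_color_viridis_c(na.value = "grey60")
    } else {
      p + ggplot2::geom_point(ggplot2::aes(color = factor(.data[[v]]))) +
        ggplot2::scale_color_brewer(palette = "Set1", na.value = "grey60") +
        ggplot2::labs(color = v)
    }
  })
  if (length(panels) == 1) return(panels[[1]])
  panels
}

#' @rdname plot_colored
#' @param object a `myo_embedding`.
#' @param ... unused.
#' @method autoplot myo_embedding
#' @export
autoplot.myo_embedding <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "t-SNE dimension 1 (a.u.)", y = "t-SNE dimension 2 (a.u.)") +
    ggplot2::theme_minimal()
}
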