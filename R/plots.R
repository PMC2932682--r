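#' Plot an LD decay profile
#'
#' Binned mean r-squared against distance with the isotonic fit and,
#' when defined, the 0.5-crossing decay radius.
#'
#' @param object an [ld_decay()] object.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ld_decay
#' @export
autoplot.ld_decay <- function(object, ...) {
  pr <- object$profile
  p <- ggplot2::ggplot(pr, ggplot2::aes(x = .data$bin_mid_bp / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_r2,
                                     size = .data$n_pairs),
                        alpha = 0.6) +
    ggplot2::geom_step(ggplot2::aes(y = .data$smoothed_r2),
                       colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "distance (Mb)", y = expression(mean ~ r^2),
                  size = "pairs") +
    ggplot2::theme_minimal()
  if (object$status == "ok") {
    p <- p + ggplot2::geom_vline(xintercept = object$radius_bp / 1e6,
                                 colour = "firebrick", linetype = "dotted")
  }
  p
}

#' Plot an association scan
#'
#' logP along the region; a permutation threshold is drawn when passed
#' or attached as the `threshold` attribute.
#'
#' @param object a `scan_result` tibble.
#' @param threshold optional threshold logP.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, threshold = attr(object, "threshold"),
                                 ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$pos_bp / 1e6, y = .data$logP)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE, alpha = 0.4) +
    ggplot2::labs(x = "position (Mb)", y = "logP") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = as.numeric(threshold),
                                 colour = "firebrick", linetype = "dashed")
  }
  p
}

#' Plot admixture proportions
#'
#' Stacked per-individual ancestry fractions, the standard structure
#' bar plot.
#'
#' @param object an [admixture_em()] fit.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot admixture_fit
#' @export
autoplot.admixture_fit <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$proportion,
                                 fill = .data$population)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot founder contribution profiles
#'
#' @param contributions tibble from [founder_contributions()] (several
#'   colonies may be stacked).
#' @return A ggplot (colony x founder tile map).
#' @export
plot_founder_contributions <- function(contributions) {
  ggplot2::ggplot(contributions,
                  ggplot2::aes(x = .data$founder, y = .data$colony_id,
                               fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10") +
    ggplot2::labs(x = "founder strain", y = NULL, fill = "fraction") +
    ggplot2::theme_minimal()
}

#' Plot MDS coordinates
#'
#' @param coords tibble from [mds_coordinates()].
#' @param colour optional vector (e.g. colony labels) to colour points.
#' @return A ggplot.
#' @export
plot_mds <- function(coords, colour = NULL) {
  p <- ggplot2::ggplot(coords, ggplot2::aes(x = .data$mds1, y = .data$mds2))
  if (is.null(colour)) {
    p <- p + ggplot2::geom_point()
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = colour)) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::labs(x = "MDS 1", y = "MDS 2") + ggplot2::theme_minimal()
}
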