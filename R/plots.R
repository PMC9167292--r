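# Quick-look ggplot2 figures for the main result types.

#' @method autoplot abd_series
#' @export
autoplot.abd_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = "value (nm or degrees)") +
    ggplot2::theme_minimal()
}

#' @method autoplot abd_density
#' @export
autoplot.abd_density <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$grid, y = .data$density)) +
    ggplot2::geom_col(width = object$bin_width, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$peak, linetype = 2) +
    ggplot2::labs(x = object$label, y = "probability density") +
    ggplot2::theme_minimal()
}

#' @method autoplot abd_ed
#' @export
autoplot.abd_ed <- function(object, n_components = 10, ...) {
  df <- head(tidy(object), n_components)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "principal component", y = expression(eigenvalue ~ (nm^2))) +
    ggplot2::theme_minimal()
}

#' Bound-state heat map of hydrogen bonds over frames
#'
#' One row per bond, shaded where the bond is bound (the heat-map view of
#' long-lived interface bonds).
#'
#' @param states an `abd_hbond_states` tibble.
#' @return a ggplot object.
#' @export
plot_bound_states <- function(states) {
  df <- dplyr::bind_rows(lapply(seq_len(nrow(states)), function(b) {
    tibble(bond_key = states$bond_key[b],
           frame = seq_along(states$bound[[b]]),
           bound = states$bound[[b]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$bond_key,
                                   fill = .data$bound)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey95", `TRUE` = "grey20")) +
    ggplot2::labs(x = "frame", y = NULL, fill = "bound") +
    ggplot2::theme_minimal()
}

#' @method autoplot abd_langevin
#' @export
autoplot.abd_langevin <- function(object, ...) {
  w <- object$spec$well
  if (!is.null(w)) {
    df <- langevin_pair_distance(object, w$i, w$j)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$distance)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = well_cutoff(w), linetype = 2) +
      ggplot2::labs(x = "time (ps)", y = "well-pair separation (nm)") +
      ggplot2::theme_minimal()
  } else {
    tidy(object) |>
      ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$x,
                                   colour = factor(.data$bead))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (ps)", y = "x (nm)", colour = "bead") +
      ggplot2::theme_minimal()
  }
}
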