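#' Plot group decoding accuracy across layers
#'
#' Bar chart of mean decoding accuracy per (area, layer, stereo) with
#' Cousineau-Morey within-subject error bars and the 50% chance line.
#'
#' @param object A `laminar_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.laminar_experiment <- function(object, ...) {
  acc <- object$accuracy |>
    dplyr::mutate(cell = paste(.data$area, .data$layer, .data$stereo, sep = "."))
  sem <- cousineau_morey_sem(acc, subject = "subject", condition = "cell",
                             value = "accuracy") |>
    tidyr::separate_wider_delim("condition", ".", names = c("area", "layer", "stereo")) |>
    dplyr::mutate(layer = factor(.data$layer,
                                 levels = c("deeper", "middle", "superficial")))
  ggplot2::ggplot(sem, ggplot2::aes(x = .data$layer, y = .data$mean,
                                    fill = .data$stereo)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7,
                      colour = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$area)) +
    ggplot2::scale_fill_manual(values = c(correlated = "grey40",
                                          anticorrelated = "white")) +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::labs(x = "cortical depth", y = "decoding accuracy (near vs far)",
                  fill = NULL) +
    ggplot2::theme_classic()
}

#' Plot layer response profiles before and after correction
#'
#' @param profile A [layer_profile()] table (optionally with `area` and
#'   `subject` columns, which are averaged over).
#' @return A ggplot object showing the relative depth profile per state.
#' @export
plot_layer_profile <- function(profile) {
  tab <- profile |>
    dplyr::group_by(.data$state, .data$layer) |>
    dplyr::summarise(rel_response = mean(.data$rel_response), .groups = "drop")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$layer, y = .data$rel_response,
                                    colour = .data$state,
                                    group = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "cortical depth", y = "relative response",
                  colour = NULL) +
    ggplot2::theme_classic()
}

#' Plot informational connectivity per pathway
#'
#' @param connectivity A [pathway_contrast()] table (optionally pooled over
#'   subjects).
#' @return A ggplot object: Fisher-z connectivity per area pair and
#'   condition, faceted by pathway.
#' @export
plot_connectivity <- function(connectivity) {
  tab <- connectivity |>
    dplyr::group_by(.data$pathway, .data$area_pair, .data$stereo) |>
    dplyr::summarise(z = mean(.data$z, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$area_pair, y = .data$z,
                                    fill = .data$stereo)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7,
                      colour = "black") +
    ggplot2::facet_wrap(ggplot2::vars(.data$pathway)) +
    ggplot2::scale_fill_manual(values = c(correlated = "grey40",
                                          anticorrelated = "white")) +
    ggplot2::labs(x = "area pair", y = "informational connectivity (Fisher z)",
                  fill = NULL) +
    ggplot2::theme_classic()
}
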