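#' Build classifier-distance series per (area, layer, stereo) cell
#'
#' Converts the per-test-block hyperplane distances stored by
#' [crossval_decode()] into discriminability time courses: distances are
#' oriented toward the correct class (distance times +1 for near, -1 for far
#' blocks, so larger = more discriminable) and concatenated across
#' leave-one-run-out folds in block-onset order. Series from different cells
#' of one dataset are aligned block-for-block.
#'
#' @param decodes Tibble with columns `area`, `layer`, `stereo` and a
#'   list-column `fit` of `decoding_result`s (one per cell).
#' @return A `distance_series` tibble: `area`, `layer`, `stereo`, `run`,
#'   `onset_tr`, `block_id`, `value` (oriented distance).
#' @export
build_distance_series <- function(decodes) {
  tab <- as_tibble(decodes)
  need <- c("area", "layer", "stereo", "fit")
  if (!all(need %in% names(tab))) {
    abort("`decodes` needs columns area, layer, stereo and a `fit` list-column.")
  }
  out <- purrr::pmap(tab, function(area, layer, stereo, fit, ...) {
    stopifnot(inherits(fit, "decoding_result"))
    fit$distances |>
      dplyr::mutate(
        value = .data$distance * ifelse(.data$disparity == "near", 1, -1),
        area = .env$area, layer = .env$layer, stereo = .env$stereo
      ) |>
      dplyr::arrange(.data$run, .data$onset_tr) |>
      dplyr::select("area", "layer", "stereo", "run", "onset_tr", "block_id", "value")
  }) |>
    dplyr::bind_rows()
  # all series of one dataset must cover identical block sets per stereo level
  chk <- out |>
    dplyr::group_by(.data$stereo, .data$area, .data$layer) |>
    dplyr::summarise(key = paste(.data$block_id, collapse = ","), .groups = "drop") |>
    dplyr::group_by(.data$stereo) |>
    dplyr::summarise(n_keys = dplyr::n_distinct(.data$key), .groups = "drop")
  if (any(chk$n_keys > 1)) {
    abort("Mismatched block sets across layers: distance series are not aligned.")
  }
  structure(out, class = c("distance_series", class(out)))
}

#' Informational connectivity between two distance series
#'
#' Spearman rank correlation (average ranks for ties) between two aligned
#' classifier-distance series, plus its Fisher z transform
#' `z = arctanh(rho)` (with `|rho|` clamped just below 1). Correlated
#' block-wise fluctuations in pattern discriminability indicate that the two
#' sites share stimulus-specific information.
#'
#' @param a,b Numeric vectors (aligned, equal length >= 5).
#' @return List: `rho`, `z`, `n`. For a constant series both are `NA` with a
#'   `reason` element.
#' @export
informational_connectivity <- function(a, b) {
  if (length(a) != length(b)) abort("Series must have equal length.")
  if (length(a) < 5) abort("Need >= 5 blocks to correlate.")
  if (sd(a) == 0 || sd(b) == 0) {
    return(list(rho = NA_real_, z = NA_real_, n = length(a),
                reason = "constant series: correlation undefined"))
  }
  rho <- cor(a, b, method = "spearman")
  rho_c <- sign(rho) * min(abs(rho), 1 - 1e-12)
  list(rho = rho, z = atanh(rho_c), n = length(a))
}

#' Feedforward and feedback pathway connectivity tables
#'
#' Computes informational connectivity for the two laminar pathway motifs
#' between every ordered pair of visual areas, per stereo condition:
#' \describe{
#'   \item{feedforward}{superficial layer of the lower area with the middle
#'     layer of the higher area (output layers 2/3 project to input layer 4).}
#'   \item{feedback}{deeper layer with deeper layer (layers 5/6 exchange
#'     feedback).}
#' }
#' Superficial-to-deeper pairs are never emitted: that motif cannot separate
#' feedforward from feedback processing.
#'
#' @param series A [build_distance_series()] tibble covering the required
#'   layers of all areas.
#' @param area_order Areas ordered low to high in the visual hierarchy.
#' @return Tibble: `pathway`, `area_pair`, `lower`, `higher`, `stereo`,
#'   `rho`, `z`, `n`.
#' @export
pathway_contrast <- function(series, area_order = c("A1", "A3A", "A7")) {
  stopifnot(inherits(series, "distance_series") || is.data.frame(series))
  pairs <- utils::combn(area_order, 2, simplify = FALSE)
  stereo_levels <- unique(series$stereo)
  get_series <- function(a, l, s) {
    v <- series |>
      dplyr::filter(.data$area == a, .data$layer == l, .data$stereo == s) |>
      dplyr::arrange(.data$run, .data$onset_tr)
    if (nrow(v) == 0) abort(sprintf("Missing distance series for %s/%s/%s.", a, l, s))
    v$value
  }
  rows <- list()
  for (p in pairs) {
    for (s in stereo_levels) {
      ff <- informational_connectivity(get_series(p[1], "superficial", s),
                                       get_series(p[2], "middle", s))
      fb <- informational_connectivity(get_series(p[1], "deeper", s),
                                       get_series(p[2], "deeper", s))
      rows[[length(rows) + 1]] <- tibble(
        pathway = c("feedforward", "feedback"),
        area_pair = paste(p[1], p[2], sep = "-"),
        lower = p[1], higher = p[2], stereo = s,
        rho = c(ff$rho, fb$rho), z = c(ff$z, fb$z), n = c(ff$n, fb$n)
      )
    }
  }
  dplyr::bind_rows(rows)
}
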