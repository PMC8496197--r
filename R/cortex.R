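#' Generate a synthetic cortical patch
#'
#' Creates a column-parameterised grey-matter ribbon for one or more visual
#' areas. Each cortical column is a normal through the ribbon carrying
#' `voxels_per_column` voxels at true depth fractions equally spaced in (0, 1)
#' (depth 0 = white-matter boundary, 1 = pial boundary). Curvature is encoded
#' per column by its inner (white) and outer (pial) boundary patch areas, drawn
#' from `curvature_range`; these drive the equi-volume depth grids. Columns are
#' laid out on a regular `spacing_mm` 2-D grid per area, mimicking a flattened
#' 0.8 mm acquisition patch.
#'
#' @param n_columns Columns per area (>= 1).
#' @param voxels_per_column Voxels along each column (>= 3).
#' @param curvature_range Interval from which boundary areas are drawn
#'   (mm^2, both endpoints > 0). `c(1, 1)` gives a flat (zero-curvature) patch.
#' @param areas Character vector of area labels; defaults to analogues of
#'   V1, V3A and V7.
#' @param thickness_mm Cortical thickness (mm).
#' @param spacing_mm In-plane column spacing (mm).
#' @param seed Integer seed; fixed seed gives an identical model.
#' @return A `cortical_model` tibble with one row per voxel: `voxel_id`,
#'   `area`, `column_id`, `x`, `y`, `z` (mm), `i`, `j`, `k` (voxel array
#'   indices), `true_depth`, `true_layer` (equi-volume band of `true_depth`),
#'   `inner_area`, `outer_area`, `vein_flag` (filled by the simulator).
#'   Attributes: `areas`, `thickness_mm`, `spacing_mm`, `voxels_per_column`,
#'   `grid_dim`.
#' @examples
#' m <- generate_cortical_patch(n_columns = 4, voxels_per_column = 3,
#'                              curvature_range = c(1, 1), areas = "A1", seed = 1)
#' m$true_depth # 0.25 / 0.5 / 0.75 per column
#' @export
generate_cortical_patch <- function(n_columns = 84, voxels_per_column = 9,
                                    curvature_range = c(0.5, 2),
                                    areas = c("A1", "A3A", "A7"),
                                    thickness_mm = 2, spacing_mm = 0.8,
                                    seed = 1) {
  if (!is.numeric(n_columns) || n_columns < 1) abort("`n_columns` must be >= 1.")
  if (!is.numeric(voxels_per_column) || voxels_per_column < 3) {
    abort("`voxels_per_column` must be >= 3 (one voxel per layer).")
  }
  if (length(curvature_range) != 2 || any(!is.finite(curvature_range)) ||
      any(curvature_range <= 0)) {
    abort("`curvature_range` must be a positive finite interval (boundary areas > 0).")
  }
  n_columns <- as.integer(n_columns)
  voxels_per_column <- as.integer(voxels_per_column)
  set.seed(derive_seed(seed, "cortex"))

  nx <- ceiling(sqrt(n_columns))
  depth <- seq_len(voxels_per_column) / (voxels_per_column + 1)

  per_area <- purrr::imap(setNames(areas, areas), function(a, idx) {
    cid0 <- (match(a, areas) - 1L) * n_columns
    cols <- tibble(
      column_id = cid0 + seq_len(n_columns),
      area = a,
      col_ix = (seq_len(n_columns) - 1L) %% nx + 1L,
      col_iy = (seq_len(n_columns) - 1L) %/% nx + 1L,
      inner_area = stats::runif(n_columns, curvature_range[1], curvature_range[2]),
      outer_area = stats::runif(n_columns, curvature_range[1], curvature_range[2])
    )
    tidyr::expand_grid(cols, k = seq_len(voxels_per_column)) |>
      dplyr::mutate(
        true_depth = depth[.data$k],
        x = (.data$col_ix - 1L) * spacing_mm,
        y = (.data$col_iy - 1L) * spacing_mm,
        z = .data$true_depth * thickness_mm,
        i = .data$col_ix, j = .data$col_iy
      )
  })
  model <- dplyr::bind_rows(per_area) |>
    dplyr::mutate(voxel_id = dplyr::row_number(), vein_flag = FALSE) |>
    dplyr::select("voxel_id", "area", "column_id", "x", "y", "z", "i", "j", "k",
                  "true_depth", "inner_area", "outer_area", "vein_flag")

  # true layer: band true_depth by the column's own interior equi-volume grids
  f1 <- equivolume_fraction(1 / 3, model$inner_area, model$outer_area)
  f2 <- equivolume_fraction(2 / 3, model$inner_area, model$outer_area)
  model$true_layer <- factor(
    ifelse(model$true_depth < f1, "deeper",
           ifelse(model$true_depth < f2, "middle", "superficial")),
    levels = c("deeper", "middle", "superficial")
  )

  structure(
    model,
    class = c("cortical_model", class(model)),
    areas = areas,
    thickness_mm = thickness_mm,
    spacing_mm = spacing_mm,
    voxels_per_column = voxels_per_column,
    grid_dim = c(nx, ceiling(n_columns / nx), voxels_per_column)
  )
}

#' @export
print.cortical_model <- function(x, ...) {
  cat(sprintf(
    "<cortical_model> %d voxels, %d columns, areas: %s\n",
    nrow(x), dplyr::n_distinct(x$column_id),
    paste(attr(x, "areas"), collapse = ", ")
  ))
  NextMethod()
}
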