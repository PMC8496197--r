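#' Select top-t voxels per layer for pattern analysis
#'
#' Ranks voxels within each cortical layer by the (label-agnostic) stimulus-
#' vs-baseline t statistic and keeps the top `n` per layer, fixing the pattern
#' size across layers and subjects. Ties are broken deterministically by voxel
#' id. Because the ranking contrast does not involve the near/far label, the
#' selection introduces no decoding leakage.
#'
#' @param glm A [fit_glm()] result (fitted on the matched, z-scored data).
#' @param layers Layer assignment covering the GLM's voxels, or a dataset
#'   voxel table with a `layer` column.
#' @param n Voxels per layer (default 175).
#' @return Tibble: `layer`, `voxel_id`, `t`, `rank`.
#' @export
select_voxels <- function(glm, layers, n = 175) {
  stopifnot(inherits(glm, "laminar_glm"))
  lay <- if ("layer" %in% names(glm$voxels)) {
    glm$voxels |> dplyr::select("voxel_id", "layer")
  } else {
    as_tibble(layers) |> dplyr::select("voxel_id", "layer")
  }
  tab <- tibble(voxel_id = glm$voxels$voxel_id, t = glm$t_map) |>
    dplyr::inner_join(lay, by = "voxel_id")
  counts <- table(tab$layer)
  if (any(counts < n)) {
    short <- names(counts)[counts < n]
    abort(sprintf(
      "Layer(s) %s have fewer than %d voxels (min %d); choose a smaller `n`.",
      paste(short, collapse = ", "), n, min(counts)))
  }
  tab |>
    dplyr::group_by(.data$layer) |>
    dplyr::arrange(dplyr::desc(.data$t), .data$voxel_id, .by_group = TRUE) |>
    dplyr::slice_head(n = n) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

# Fit a linear soft-margin classifier and return signed distances for test
# patterns with the convention positive = "near".
svm_fold <- function(x_train, y_train, x_test, C) {
  y_train <- factor(y_train, levels = c("near", "far"))
  fit <- e1071::svm(x = x_train, y = y_train, kernel = "linear", cost = C,
                    scale = FALSE)
  pred <- stats::predict(fit, x_test, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # e1071 labels the decision column "<pos>/<neg>"; orient so positive = near
  orient <- if (identical(colnames(dv)[1], "near/far")) 1 else -1
  drop(dv) * orient
}

#' Leave-one-run-out cross-validated near-vs-far decoding
#'
#' Trains a linear maximum-margin classifier (soft margin, cost `C`) on all
#' runs but one and tests on the held-out run, for every run in turn.
#' Accuracy is the fold-average fraction of correctly classified test blocks;
#' the signed distance to the hyperplane (positive = "near" side) is stored
#' for every test block. A test block exactly on the hyperplane (distance 0)
#' counts as incorrect. Call once per stereo condition: the patterns supplied
#' should all share one (area, layer, stereo) cell.
#'
#' @param patterns A [block_responses()] `block_patterns` object whose blocks
#'   all belong to one stereo condition.
#' @param C Soft-margin cost (default 1).
#' @return A `decoding_result`: `accuracy`, `folds` tibble (`run`,
#'   `accuracy`), `distances` tibble (`block_id`, `run`, `onset_tr`, `label`,
#'   `distance`, `correct`), `n_voxels`, `C`.
#' @export
crossval_decode <- function(patterns, C = 1) {
  stopifnot(inherits(patterns, "block_patterns"))
  blocks <- patterns$blocks
  runs <- sort(unique(blocks$run))
  if (length(runs) < 2) abort("Need >= 2 runs for leave-one-run-out cross-validation.")
  for (r in runs) {
    tr_lab <- blocks$disparity[blocks$run != r]
    if (length(unique(tr_lab)) < 2) {
      abort(sprintf("Training fold (run %d held out) is missing a class.", r))
    }
  }
  dist_rows <- purrr::map(runs, function(r) {
    train <- blocks$run != r
    d <- svm_fold(patterns$responses[train, , drop = FALSE],
                  blocks$disparity[train],
                  patterns$responses[!train, , drop = FALSE], C)
    blocks[!train, ] |>
      dplyr::mutate(distance = d,
                    correct = (.data$distance > 0 & .data$disparity == "near") |
                      (.data$distance < 0 & .data$disparity == "far"))
  })
  distances <- dplyr::bind_rows(dist_rows)
  folds <- distances |>
    dplyr::group_by(run = .data$run) |>
    dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop")
  structure(
    list(accuracy = mean(folds$accuracy), folds = folds, distances = distances,
         n_voxels = ncol(patterns$responses), C = C,
         area = patterns$area,
         layer = if ("layer" %in% names(patterns$voxels)) {
           as.character(patterns$voxels$layer[1])
         } else NA_character_),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> accuracy %.3f over %d folds (%d voxels, C = %g)\n",
              x$accuracy, nrow(x$folds), x$n_voxels, x$C))
  invisible(x)
}

#' Tidy a decoding result
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return The per-test-block distance tibble.
#' @export
tidy.decoding_result <- function(x, ...) x$distances

#' One-line summary of a decoding result
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return One-row tibble: `accuracy`, `n_folds`, `n_voxels`, `C`.
#' @export
glance.decoding_result <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_folds = nrow(x$folds),
         n_voxels = x$n_voxels, C = x$C)
}

#' Permutation null distribution for decoding accuracy
#'
#' Re-runs the full leave-one-run-out cross-validation with disparity labels
#' shuffled within run, `n_perm` times, and returns the null accuracy
#' distribution together with the permutation p-value
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param patterns A `block_patterns` object (one stereo condition).
#' @param n_perm Number of label permutations (default 5000).
#' @param seed Integer seed for the shuffles.
#' @param C Soft-margin cost.
#' @return List: `observed` accuracy, `null` (numeric vector length `n_perm`),
#'   `p`.
#' @export
permutation_null <- function(patterns, n_perm = 5000, seed = 1, C = 1) {
  stopifnot(inherits(patterns, "block_patterns"))
  if (n_perm < 100) warn("Fewer than 100 permutations gives unstable p-values.")
  observed <- crossval_decode(patterns, C = C)$accuracy
  blocks <- patterns$blocks
  runs <- sort(unique(blocks$run))
  set.seed(derive_seed(seed, "permutation"))
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- patterns
    for (r in runs) {
      idx <- which(blocks$run == r)
      perm$blocks$disparity[idx] <- blocks$disparity[sample(idx)]
    }
    crossval_decode(perm, C = C)$accuracy
  }, numeric(1))
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_perm))
}

#' Remove the univariate component from block patterns
#'
#' Subtracts, for each block, the across-voxel mean response, leaving only
#' the multivoxel pattern component. Decoding after this control cannot be
#' driven by overall activation differences between conditions.
#'
#' @param patterns A `block_patterns` object (>= 2 voxels).
#' @return The mean-removed `block_patterns`.
#' @export
regress_mean_pattern <- function(patterns) {
  stopifnot(inherits(patterns, "block_patterns"))
  if (ncol(patterns$responses) < 2) {
    abort("Need >= 2 voxels to remove the across-voxel mean.")
  }
  patterns$responses <- patterns$responses - rowMeans(patterns$responses)
  patterns
}
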