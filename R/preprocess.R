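#' High-pass filter and detrend a laminar dataset
#'
#' Per run, regresses out an intercept, a linear trend, and sine/cosine pairs
#' at 1..`n_cycles` cycles per run (a GLM with a Fourier basis set), returning
#' the residual time courses. This removes slow scanner drift while leaving
#' the block-frequency condition structure intact.
#'
#' @param ds A `laminar_dataset`.
#' @param n_cycles Highest Fourier frequency removed, in cycles per run.
#' @return The filtered `laminar_dataset` (step `highpass` appended).
#' @export
highpass_and_detrend <- function(ds, n_cycles = 2) {
  stopifnot(inherits(ds, "laminar_dataset"))
  n_tr <- ds$n_tr_per_run
  rank_needed <- 2 + 2 * n_cycles
  if (n_tr < max(8, rank_needed + 1)) {
    abort(sprintf("Run too short for the Fourier basis: %d TRs < %d.",
                  n_tr, max(8, rank_needed + 1)))
  }
  tt <- seq_len(n_tr)
  X <- cbind(1, scale(tt, scale = FALSE))
  for (k in seq_len(n_cycles)) {
    X <- cbind(X, sin(2 * pi * k * tt / n_tr), cos(2 * pi * k * tt / n_tr))
  }
  Q <- qr.Q(qr(X))
  for (r in seq_len(ds$n_runs)) {
    idx <- (r - 1) * n_tr + tt
    Y <- t(ds$data[, idx, drop = FALSE])
    ds$data[, idx] <- t(Y - Q %*% crossprod(Q, Y))
  }
  ds$applied_steps <- c(ds$applied_steps, "highpass")
  ds
}

# Condition design matrix: HRF-convolved boxcar per condition (4 columns),
# concatenated across runs, plus per-run intercepts. Returns list(X, cond_cols).
condition_design_matrix <- function(design, n_tr, tr, nuisance = NULL) {
  conds <- sort(unique(design$condition))
  n_runs <- max(design$run)
  block_tr <- design_attr(design, "block_tr")
  Xc <- matrix(0, n_tr * n_runs, length(conds))
  colnames(Xc) <- conds
  for (r in seq_len(n_runs)) {
    dr <- design[design$run == r, ]
    Xb <- block_regressor_matrix(dr$onset_tr, rep(block_tr, nrow(dr)), n_tr, tr)
    for (ci in seq_along(conds)) {
      sel <- dr$condition == conds[ci]
      if (any(sel)) {
        Xc[(r - 1) * n_tr + seq_len(n_tr), ci] <-
          rowSums(Xb[, sel, drop = FALSE])
      }
    }
  }
  run_int <- matrix(0, n_tr * n_runs, n_runs)
  for (r in seq_len(n_runs)) run_int[(r - 1) * n_tr + seq_len(n_tr), r] <- 1
  colnames(run_int) <- paste0("run", seq_len(n_runs))
  X <- cbind(Xc, run_int)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nrow(X)) abort("`nuisance` must have one row per TR.")
    colnames(nuisance) <- colnames(nuisance) %||% paste0("nuis", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  list(X = X, cond_cols = seq_along(conds), conds = conds)
}

#' Fit a condition GLM to a laminar dataset
#'
#' Ordinary least squares per voxel on HRF-convolved condition boxcars (one
#' regressor per stimulus condition), per-run intercepts, and optional
#' nuisance regressors. The t map tests the mean of the condition regressors
#' against baseline (stimulus vs fixation), the contrast used for voxel
#' preselection, vein detection, and top-t voxel ranking.
#'
#' @param ds A `laminar_dataset`.
#' @param design The matching [generate_design()] block design.
#' @param nuisance Optional TR x k matrix of nuisance regressors.
#' @return A `laminar_glm`: betas (voxel x regressor), `t_map` (stimulus vs
#'   baseline t per voxel), `residuals` (voxel x TR), `dof`, the design matrix
#'   and condition column indices, and the voxel table.
#' @export
fit_glm <- function(ds, design, nuisance = NULL) {
  stopifnot(inherits(ds, "laminar_dataset"))
  dm <- condition_design_matrix(design, ds$n_tr_per_run, ds$tr, nuisance)
  X <- dm$X
  if (nrow(X) != ncol(ds$data)) {
    abort(sprintf("Design spans %d TRs but the dataset has %d.",
                  nrow(X), ncol(ds$data)))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Rank-deficient design matrix; collinear columns: ",
                 paste(dropped, collapse = ", ")))
  }
  Y <- t(ds$data)
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  dof <- nrow(X) - qrX$rank
  sigma2 <- colSums(resid^2) / dof
  cvec <- numeric(ncol(X))
  cvec[dm$cond_cols] <- 1 / length(dm$cond_cols)
  XtXinv <- chol2inv(qr.R(qrX))
  cvar <- drop(t(cvec) %*% XtXinv %*% cvec)
  cb <- drop(crossprod(cvec, beta))
  t_map <- cb / sqrt(sigma2 * cvar)
  structure(
    list(betas = t(beta), t_map = t_map, contrast_estimate = cb,
         residuals = t(resid), dof = dof, X = X, cond_cols = dm$cond_cols,
         conditions = dm$conds, voxels = ds$voxels, area = ds$area,
         n_runs = ds$n_runs, n_tr_per_run = ds$n_tr_per_run),
    class = "laminar_glm"
  )
}

#' @export
print.laminar_glm <- function(x, ...) {
  cat(sprintf("<laminar_glm> area %s: %d voxels, %d regressors, dof %d\n",
              x$area, nrow(x$betas), ncol(x$betas), x$dof))
  invisible(x)
}

#' Tidy a fitted condition GLM
#' @param x A `laminar_glm`.
#' @param ... Unused.
#' @return Tibble with one row per voxel: `voxel_id`, condition betas,
#'   `contrast_estimate` and `t` (stimulus vs baseline).
#' @export
tidy.laminar_glm <- function(x, ...) {
  out <- as_tibble(x$betas[, x$cond_cols, drop = FALSE])
  dplyr::bind_cols(
    tibble(voxel_id = x$voxels$voxel_id), out,
    tibble(contrast_estimate = x$contrast_estimate, t = x$t_map)
  )
}

#' Preselect stimulus-responsive voxels
#'
#' Retains voxels whose stimulus-vs-baseline t exceeds `t_threshold`. The
#' default 1.53 corresponds to p = 0.125 (one-sided) at the dof typical of a
#' single run's GLM and mirrors a liberal activation screen applied before
#' pattern analysis.
#'
#' @param glm A [fit_glm()] result.
#' @param t_threshold Liberal activation threshold.
#' @return Integer vector of retained voxel ids.
#' @export
roi_voxel_preselect <- function(glm, t_threshold = 1.53) {
  stopifnot(inherits(glm, "laminar_glm"))
  keep <- glm$voxels$voxel_id[glm$t_map > t_threshold]
  if (length(keep) == 0) {
    abort("Voxel preselection returned an empty set; lower `t_threshold`.")
  }
  keep
}

#' Exclude vasculature-confounded voxels
#'
#' Flags voxels dominated by large veins using two distribution-based cuts,
#' both computed within the dataset's area: (1) temporal SNR (temporal mean /
#' temporal SD) lower than `mean(tsnr) - sd_mult * sd(tsnr)` - large veins
#' have low-intensity, high-variance signal; and (2) stimulus-vs-baseline t
#' above the `t_percentile`-th percentile of the area's t distribution - the
#' strongest activations in gradient-echo BOLD sit on pial veins. A voxel with
#' zero temporal SD gets tSNR `+Inf` and is never excluded by the tSNR cut.
#'
#' @param ds The (uncorrected) `laminar_dataset` whose raw time courses define
#'   tSNR.
#' @param glm The matching [fit_glm()] result.
#' @param sd_mult Low-tSNR cut in SD units (default 2).
#' @param t_percentile Upper t percentile cut (default 90).
#' @return A `vascular_mask` tibble: `voxel_id`, `tsnr`, `t`, `keep`, with
#'   threshold attributes `tsnr_cut` and `t_cut`.
#' @export
vascular_exclusion <- function(ds, glm, sd_mult = 2, t_percentile = 90) {
  stopifnot(inherits(ds, "laminar_dataset"), inherits(glm, "laminar_glm"))
  if (nrow(ds$data) < 20) abort("Need >= 20 voxels for a meaningful percentile cut.")
  if (!identical(ds$voxels$voxel_id, glm$voxels$voxel_id)) {
    abort("Dataset and GLM cover different voxels.")
  }
  m <- rowMeans(ds$data)
  s <- apply(ds$data, 1, sd)
  tsnr <- ifelse(s == 0, Inf, m / s)
  fin <- is.finite(tsnr)
  tsnr_cut <- if (is.infinite(sd_mult)) -Inf else {
    mean(tsnr[fin]) - sd_mult * sd(tsnr[fin])
  }
  t_cut <- stats::quantile(glm$t_map, t_percentile / 100, names = FALSE, type = 7)
  low_tsnr <- tsnr < tsnr_cut
  high_t <- if (t_percentile >= 100) rep(FALSE, length(tsnr)) else glm$t_map > t_cut
  out <- tibble(
    voxel_id = ds$voxels$voxel_id,
    tsnr = tsnr,
    t = glm$t_map,
    low_tsnr = low_tsnr,
    high_t = high_t,
    keep = !(low_tsnr | high_t)
  )
  structure(out, class = c("vascular_mask", class(out)),
            tsnr_cut = tsnr_cut, t_cut = t_cut,
            sd_mult = sd_mult, t_percentile = t_percentile)
}

#' Match voxel counts across layers and z-score time courses
#'
#' Equalises the number of voxels across the three cortical layers of an area
#' (keeping, per layer, the voxels with the highest stimulus-vs-baseline t
#' among those surviving the vascular mask and any preselection), then
#' z-scores every surviving voxel's time course within run (mean 0, SD 1).
#' Matching plus within-layer normalisation removes depth-dependent signal
#' gain while preserving condition differences.
#'
#' @param ds A `laminar_dataset` (typically filtered).
#' @param layers A [assign_voxels()] layer assignment.
#' @param mask A [vascular_exclusion()] mask (provides the keep flags and the
#'   t ranking).
#' @param keep_ids Optional voxel ids from [roi_voxel_preselect()]; if given,
#'   only these voxels are eligible.
#' @return The matched, z-scored `laminar_dataset`; its voxel table gains a
#'   `layer` column.
#' @export
match_and_zscore <- function(ds, layers, mask, keep_ids = NULL) {
  stopifnot(inherits(ds, "laminar_dataset"), inherits(layers, "layer_assignment"),
            inherits(mask, "vascular_mask"))
  elig <- mask |>
    dplyr::filter(.data$keep) |>
    dplyr::inner_join(
      layers |> dplyr::select("voxel_id", "layer"), by = "voxel_id"
    )
  if (!is.null(keep_ids)) elig <- elig |> dplyr::filter(.data$voxel_id %in% keep_ids)
  counts <- table(elig$layer)
  empty <- setdiff(levels(layers$layer), names(counts)[counts > 0])
  if (length(empty) > 0) {
    abort(sprintf("Area %s: no voxels left in layer(s) %s after masking.",
                  ds$area, paste(empty, collapse = ", ")))
  }
  n_keep <- min(counts)
  chosen <- elig |>
    dplyr::group_by(.data$layer) |>
    dplyr::arrange(dplyr::desc(.data$t), .data$voxel_id, .by_group = TRUE) |>
    dplyr::slice_head(n = n_keep) |>
    dplyr::ungroup()
  ds2 <- subset_voxels(ds, chosen$voxel_id)
  ds2$voxels <- ds2$voxels |>
    dplyr::left_join(chosen |> dplyr::select("voxel_id", "layer"), by = "voxel_id")
  n_tr <- ds2$n_tr_per_run
  for (r in seq_len(ds2$n_runs)) {
    idx <- (r - 1) * n_tr + seq_len(n_tr)
    blk <- ds2$data[, idx, drop = FALSE]
    mu <- rowMeans(blk)
    sdv <- apply(blk, 1, sd)
    sdv[sdv == 0] <- 1
    ds2$data[, idx] <- (blk - mu) / sdv
  }
  ds2$applied_steps <- c(ds2$applied_steps, "match_zscore")
  ds2
}

#' Regress middle-layer signals out of superficial voxels
#'
#' Spatial-regression control for draining-vein leakage: for each superficial
#' voxel, the time courses of its `k_neighbors` nearest middle-layer voxels
#' (Euclidean distance, within area) are averaged and regressed out of the
#' superficial voxel (with an intercept). Deeper and middle voxels pass
#' through unchanged.
#'
#' @param ds A `laminar_dataset` whose voxel table has a `layer` column (i.e.
#'   after [match_and_zscore()]), or supply `layers`.
#' @param layers Optional [assign_voxels()] assignment if `ds` lacks layers.
#' @param k_neighbors Number of middle-layer neighbours to average.
#' @return The corrected `laminar_dataset` (step `spatial_regression`).
#' @export
regress_out_middle <- function(ds, layers = NULL, k_neighbors = 3) {
  stopifnot(inherits(ds, "laminar_dataset"))
  vox <- ds$voxels
  if (!"layer" %in% names(vox)) {
    if (is.null(layers)) abort("Provide `layers` or a dataset with a layer column.")
    vox <- vox |>
      dplyr::left_join(layers |> dplyr::select("voxel_id", "layer"), by = "voxel_id")
  }
  sup <- which(vox$layer == "superficial")
  mid <- which(vox$layer == "middle")
  if (length(sup) == 0 || length(mid) == 0) {
    abort("Both superficial and middle layers must be non-empty.")
  }
  k <- min(k_neighbors, length(mid))
  if (k < k_neighbors) {
    warn(sprintf("k_neighbors clamped from %d to %d (middle-layer count).",
                 k_neighbors, k))
  }
  P <- as.matrix(vox[, c("x", "y", "z")])
  for (v in sup) {
    d2 <- colSums((t(P[mid, , drop = FALSE]) - P[v, ])^2)
    nb <- mid[order(d2)[seq_len(k)]]
    ref <- colMeans(ds$data[nb, , drop = FALSE])
    X <- cbind(1, ref)
    y <- ds$data[v, ]
    ds$data[v, ] <- stats::lm.fit(X, y)$residuals
  }
  ds$applied_steps <- c(ds$applied_steps, "spatial_regression")
  ds
}

#' Extract per-block response patterns
#'
#' Averages each voxel's signal over a fixed post-onset TR window per block.
#' The default window `[3, 7]` (1-based, inclusive; 0-based offsets 2..6)
#' spans 4-14 s after block onset: shifted 2 TRs (4 s) for the haemodynamic
#' delay and extended 1 TR past the 12 s block to catch the response to the
#' final stimulus of the block.
#'
#' @param ds A `laminar_dataset` (typically matched and z-scored).
#' @param design The matching block design.
#' @param window Integer TR window, 1-based inclusive from block onset.
#' @return A `block_patterns`: `responses` (block x voxel matrix), `blocks`
#'   (tibble: `block_id`, `run`, `onset_tr`, `stereo`, `disparity`), `voxels`
#'   (the dataset's voxel table), `area`.
#' @export
block_responses <- function(ds, design, window = c(3, 7)) {
  stopifnot(inherits(ds, "laminar_dataset"), inherits(design, "block_design"))
  if (length(window) != 2 || window[1] < 1 || window[2] < window[1]) {
    abort("`window` must be an increasing 1-based TR interval.")
  }
  offsets <- (window[1] - 1):(window[2] - 1)
  n_tr <- ds$n_tr_per_run
  if (max(design$onset_tr) + max(offsets) > n_tr - 1) {
    abort("Block window exceeds the end of the run.")
  }
  B <- nrow(design)
  resp <- matrix(0, B, nrow(ds$data))
  for (b in seq_len(B)) {
    cols <- (design$run[b] - 1) * n_tr + design$onset_tr[b] + offsets + 1
    resp[b, ] <- rowMeans(ds$data[, cols, drop = FALSE])
  }
  blocks <- design |>
    as_tibble() |>
    dplyr::mutate(block_id = dplyr::row_number()) |>
    dplyr::select("block_id", "run", "onset_tr", "stereo", "disparity")
  structure(
    list(responses = resp, blocks = blocks, voxels = ds$voxels, area = ds$area),
    class = "block_patterns"
  )
}

#' @export
print.block_patterns <- function(x, ...) {
  cat(sprintf("<block_patterns> area %s: %d blocks x %d voxels\n",
              x$area %||% "?", nrow(x$responses), ncol(x$responses)))
  invisible(x)
}

#' Tidy block patterns
#' @param x A `block_patterns`.
#' @param ... Unused.
#' @return Long tibble: block metadata plus `voxel_id` and `response`.
#' @export
tidy.block_patterns <- function(x, ...) {
  nb <- nrow(x$responses)
  nv <- ncol(x$responses)
  dplyr::bind_cols(
    x$blocks[rep(seq_len(nb), times = nv), ],
    tibble(voxel_id = rep(x$voxels$voxel_id, each = nb),
           response = as.vector(x$responses))
  )
}

#' Subset block patterns by voxels and/or blocks
#'
#' @param patterns A `block_patterns` object.
#' @param voxel_ids Optional voxel ids to keep (order preserved as given).
#' @param block_keep Optional logical vector over blocks.
#' @return The subsetted `block_patterns`.
#' @export
filter_patterns <- function(patterns, voxel_ids = NULL, block_keep = NULL) {
  stopifnot(inherits(patterns, "block_patterns"))
  if (!is.null(voxel_ids)) {
    idx <- match(voxel_ids, patterns$voxels$voxel_id)
    if (anyNA(idx)) abort("Unknown voxel ids in pattern subset.")
    patterns$responses <- patterns$responses[, idx, drop = FALSE]
    patterns$voxels <- patterns$voxels[idx, ]
  }
  if (!is.null(block_keep)) {
    patterns$responses <- patterns$responses[block_keep, , drop = FALSE]
    patterns$blocks <- patterns$blocks[block_keep, ]
  }
  patterns
}

#' Layer response profiles before and after correction
#'
#' Summarises the mean block-window response per cortical layer for an
#' uncorrected dataset and its corrected counterpart. Before-state responses
#' are baseline-removed raw units (block-window mean minus the voxel's run
#' mean); after-state responses are in the corrected dataset's own units
#' (z-units after [match_and_zscore()]). `rel_response` rescales each state by
#' the mean over layers, making the depth profile shape comparable across
#' states with different units.
#'
#' @param before,after `laminar_dataset`s sharing geometry (the `after` voxels
#'   must be a subset of the `before` voxels).
#' @param layers A [assign_voxels()] layer assignment.
#' @param design The block design.
#' @param window TR window passed to [block_responses()].
#' @return Tibble: `state` (before/after), `layer`, `mean_response`,
#'   `rel_response`.
#' @export
layer_profile <- function(before, after, layers, design, window = c(3, 7)) {
  stopifnot(inherits(before, "laminar_dataset"), inherits(after, "laminar_dataset"))
  if (!all(after$voxels$voxel_id %in% before$voxels$voxel_id)) {
    abort("`after` voxels are not a subset of `before` voxels: mismatched geometry.")
  }
  demean <- function(ds) {
    n_tr <- ds$n_tr_per_run
    for (r in seq_len(ds$n_runs)) {
      idx <- (r - 1) * n_tr + seq_len(n_tr)
      ds$data[, idx] <- ds$data[, idx, drop = FALSE] - rowMeans(ds$data[, idx, drop = FALSE])
    }
    ds
  }
  one_state <- function(ds, state) {
    bp <- block_responses(demean(ds), design, window)
    tidy(bp) |>
      dplyr::inner_join(layers |> dplyr::select("voxel_id", "layer"), by = "voxel_id") |>
      dplyr::group_by(.data$layer) |>
      dplyr::summarise(mean_response = mean(.data$response), .groups = "drop") |>
      dplyr::mutate(state = state)
  }
  out <- dplyr::bind_rows(one_state(before, "before"), one_state(after, "after")) |>
    dplyr::group_by(.data$state) |>
    dplyr::mutate(rel_response = .data$mean_response / mean(.data$mean_response)) |>
    dplyr::ungroup() |>
    dplyr::select("state", "layer", "mean_response", "rel_response")
  out
}
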