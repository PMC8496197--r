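#' Specify the generative effects of a simulated laminar dataset
#'
#' Bundles every tunable of the laminar BOLD generator. The defaults encode
#' the scenario the analysis pipeline is designed to detect: a disparity
#' (near vs far) multivoxel signal confined to the superficial and middle
#' layers of the higher dorsal areas (A3A, A7) for correlated stereograms
#' only, on top of a stimulus-evoked univariate response everywhere, with
#' gradient-echo vascular confounds (superficial gain gradient, draining-vein
#' leakage into superficial voxels, sparse large-vein voxels) and AR(1)
#' physiological-plus-thermal noise.
#'
#' @param pattern_amplitude Tibble with columns `area`, `layer`, `stereo`,
#'   `amplitude` (arbitrary BOLD units; >= 0) giving the near-vs-far pattern
#'   amplitude per cell. Cells not listed have amplitude 0. `NULL` uses the
#'   default scenario with `signal_amplitude` in (A3A, A7) x
#'   (superficial, middle) x correlated.
#' @param signal_amplitude Amplitude used by the default `pattern_amplitude`
#'   scenario.
#' @param mean_amplitude Stimulus-evoked univariate response amplitude common
#'   to all stimulus blocks (drives the stimulus-vs-fixation t map).
#' @param superficial_gain_slope Unitless slope `b` of the superficial bias:
#'   evoked signals are scaled by `1 + b * true_depth`.
#' @param leak_fraction Fraction in `[0, 1)` of the mean deeper+middle column
#'   signal added to each superficial voxel (draining-vein leakage).
#' @param vein_fraction Fraction of voxels flagged as large-vein voxels.
#' @param vein_noise_mult,vein_amp_mult Noise-SD and evoked-amplitude
#'   multipliers for vein voxels.
#' @param noise_sd Thermal/physiological noise SD (marginal, per TR).
#' @param physio_ar1 Lag-1 autocorrelation of the noise in `[0, 1)`.
#' @param baseline Baseline signal level (sets the tSNR scale).
#' @param block_gain_sd Log-scale SD of the mean-1 log-normal per-block gain
#'   multiplier on the pattern amplitude (drives block-wise discriminability
#'   fluctuations; 0 disables them).
#' @param coupling Tibble with columns `source_area`, `source_layer`,
#'   `target_area`, `target_layer`, `stereo`, `rho` (each in `[0, 1]`):
#'   block-gain series of the target cell is correlated at `rho` with the
#'   source cell's, inducing shared discriminability fluctuations (the ground
#'   truth for informational connectivity). `NULL` = no coupling.
#' @param seed Integer seed; a fixed spec (including seed) reproduces the
#'   simulated dataset exactly.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(pattern_amplitude = NULL,
                        signal_amplitude = 0.08,
                        mean_amplitude = 2,
                        superficial_gain_slope = 1,
                        leak_fraction = 0.2,
                        vein_fraction = 0.05,
                        vein_noise_mult = 3,
                        vein_amp_mult = 2,
                        noise_sd = 1,
                        physio_ar1 = 0.3,
                        baseline = 100,
                        block_gain_sd = 0.8,
                        coupling = NULL,
                        seed = 1) {
  if (is.null(pattern_amplitude)) {
    pattern_amplitude <- tidyr::expand_grid(
      area = c("A3A", "A7"),
      layer = c("superficial", "middle"),
      stereo = "correlated"
    ) |>
      dplyr::mutate(amplitude = signal_amplitude)
  }
  req <- c("area", "layer", "stereo", "amplitude")
  if (!all(req %in% names(pattern_amplitude))) {
    abort("`pattern_amplitude` needs columns area, layer, stereo, amplitude.")
  }
  if (any(pattern_amplitude$amplitude < 0)) abort("Pattern amplitudes must be >= 0.")
  stopifnot(
    leak_fraction >= 0, leak_fraction < 1,
    vein_fraction >= 0, vein_fraction < 1,
    physio_ar1 >= 0, physio_ar1 < 1,
    noise_sd >= 0, mean_amplitude >= 0, block_gain_sd >= 0
  )
  if (!is.null(coupling)) {
    creq <- c("source_area", "source_layer", "target_area", "target_layer", "stereo", "rho")
    if (!all(creq %in% names(coupling))) {
      abort("`coupling` needs columns source_area, source_layer, target_area, target_layer, stereo, rho.")
    }
    if (any(coupling$rho < 0 | coupling$rho > 1)) abort("Coupling `rho` must lie in [0, 1].")
  }
  structure(
    list(
      pattern_amplitude = as_tibble(pattern_amplitude),
      mean_amplitude = mean_amplitude,
      superficial_gain_slope = superficial_gain_slope,
      leak_fraction = leak_fraction,
      vein_fraction = vein_fraction,
      vein_noise_mult = vein_noise_mult,
      vein_amp_mult = vein_amp_mult,
      noise_sd = noise_sd,
      physio_ar1 = physio_ar1,
      baseline = baseline,
      block_gain_sd = block_gain_sd,
      coupling = if (is.null(coupling)) NULL else as_tibble(coupling),
      seed = as.integer(seed)
    ),
    class = "effect_spec"
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("<effect_spec>\n")
  cat(sprintf("  mean amplitude %g, noise sd %g (AR1 %g), baseline %g\n",
              x$mean_amplitude, x$noise_sd, x$physio_ar1, x$baseline))
  cat(sprintf("  superficial slope %g, leak %g, veins %g%% (noise x%g, amp x%g)\n",
              x$superficial_gain_slope, x$leak_fraction, 100 * x$vein_fraction,
              x$vein_noise_mult, x$vein_amp_mult))
  cat(sprintf("  %d signal cell(s), %d coupling(s), seed %d\n",
              sum(x$pattern_amplitude$amplitude > 0),
              if (is.null(x$coupling)) 0L else nrow(x$coupling), x$seed))
  invisible(x)
}

new_laminar_dataset <- function(data, voxels, tr, n_runs, n_tr_per_run, area,
                                applied_steps = character()) {
  structure(
    list(data = data, voxels = voxels, tr = tr, n_runs = n_runs,
         n_tr_per_run = n_tr_per_run, area = area, applied_steps = applied_steps),
    class = "laminar_dataset"
  )
}

#' @export
print.laminar_dataset <- function(x, ...) {
  cat(sprintf("<laminar_dataset> area %s: %d voxels x %d TRs (%d runs, TR %gs)\n",
              x$area, nrow(x$data), ncol(x$data), x$n_runs, x$tr))
  if (length(x$applied_steps)) {
    cat("  steps:", paste(x$applied_steps, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Tidy a laminar dataset into a long tibble
#'
#' @param x A `laminar_dataset`.
#' @param ... Unused.
#' @return Tibble with columns `voxel_id`, `run`, `tr_index` (1-based within
#'   run) and `signal`.
#' @export
tidy.laminar_dataset <- function(x, ...) {
  tibble(
    voxel_id = rep(x$voxels$voxel_id, times = ncol(x$data)),
    run = rep(rep(seq_len(x$n_runs), each = x$n_tr_per_run), each = nrow(x$data)),
    tr_index = rep(rep(seq_len(x$n_tr_per_run), times = x$n_runs), each = nrow(x$data)),
    signal = as.vector(x$data)
  )
}

run_index <- function(ds) rep(seq_len(ds$n_runs), each = ds$n_tr_per_run)

# Subset a laminar_dataset to a set of voxel ids (order preserved as given).
subset_voxels <- function(ds, voxel_ids) {
  idx <- match(voxel_ids, ds$voxels$voxel_id)
  if (anyNA(idx)) abort("Unknown voxel ids in subset.")
  ds$data <- ds$data[idx, , drop = FALSE]
  ds$voxels <- ds$voxels[idx, ]
  ds
}

#' Simulate laminar BOLD time series with known ground truth
#'
#' Generates per-area voxel x TR datasets realising the generative model the
#' pipeline assumes. Per voxel `v` in area `a`, layer `l`, the evoked signal is
#' the HRF-convolved block boxcar carrying
#' `mean_amplitude * vein_mult_v + A(a, l, stereo_b) * (1 + g_b) * s_b * p_v`
#' where `p_v` is a fixed standard-normal near-vs-far pattern direction,
#' `s_b = +1/-1` for near/far blocks, and `g_b` is the latent per-block gain of
#' the cell (shared, via `coupling`, across coupled cells). The evoked signal
#' is scaled by the superficial gain `1 + b * true_depth_v`; superficial voxels
#' additionally receive `leak_fraction` times the mean evoked signal of the
#' deeper+middle voxels of their column. Vein voxels get amplitude and noise
#' multipliers. Additive noise is AR(1) Gaussian with marginal SD `noise_sd`,
#' independent across runs.
#'
#' @param model A [generate_cortical_patch()] cortical model.
#' @param design A [generate_design()] block design.
#' @param spec An [effect_spec()].
#' @return A `laminar_simulation`: list with `datasets` (named list of
#'   `laminar_dataset`, one per area) and `truth` (pattern directions, block
#'   gains per cell, vein voxel ids, signal-bearing cells, and the spec).
#' @export
simulate_bold <- function(model, design, spec) {
  if (!inherits(model, "cortical_model")) abort("`model` must be a cortical_model.")
  if (!inherits(design, "block_design")) abort("`design` must be a block_design.")
  if (!inherits(spec, "effect_spec")) abort("`spec` must be an effect_spec.")
  areas <- attr(model, "areas")
  layers <- c("deeper", "middle", "superficial")
  bad_cells <- spec$pattern_amplitude |>
    dplyr::filter(!(.data$area %in% areas) | !(.data$layer %in% layers))
  if (nrow(bad_cells) > 0) {
    abort(paste0("pattern_amplitude references unknown area/layer: ",
                 paste(unique(paste(bad_cells$area, bad_cells$layer)), collapse = ", ")))
  }
  if (!is.null(spec$coupling)) {
    cc <- spec$coupling
    known <- function(a, l) a %in% areas & l %in% layers
    if (any(!known(cc$source_area, cc$source_layer)) ||
        any(!known(cc$target_area, cc$target_layer))) {
      abort("`coupling` references an unknown area/layer.")
    }
  }

  tr <- design_attr(design, "tr")
  n_tr <- design_attr(design, "n_tr_per_run")
  n_runs <- max(design$run)
  block_tr <- design_attr(design, "block_tr")

  # --- seeded draws in a fixed order -----------------------------------------
  set.seed(derive_seed(spec$seed, "veins"))
  vein <- stats::runif(nrow(model)) < spec$vein_fraction

  set.seed(derive_seed(spec$seed, "patterns"))
  pattern <- stats::rnorm(nrow(model)) # fixed pattern direction per voxel

  # latent block gains per (area, layer, stereo) cell, coupling applied
  cells <- tidyr::expand_grid(area = areas, layer = layers,
                              stereo = c("correlated", "anticorrelated"))
  n_blocks_total <- nrow(design)
  set.seed(derive_seed(spec$seed, "gains"))
  u <- matrix(stats::rnorm(nrow(cells) * n_blocks_total), nrow(cells), n_blocks_total)
  rownames(u) <- paste(cells$area, cells$layer, cells$stereo, sep = ".")
  if (!is.null(spec$coupling)) {
    for (ci in seq_len(nrow(spec$coupling))) {
      cp <- spec$coupling[ci, ]
      src <- paste(cp$source_area, cp$source_layer, cp$stereo, sep = ".")
      tgt <- paste(cp$target_area, cp$target_layer, cp$stereo, sep = ".")
      u[tgt, ] <- cp$rho * u[src, ] + sqrt(1 - cp$rho^2) * u[tgt, ]
    }
  }
  # mean-1 log-normal gain multiplier; monotone in the latent normal, so the
  # coupling correlation transfers to the gain (and rank) scale unchanged
  gains <- exp(spec$block_gain_sd * u - spec$block_gain_sd^2 / 2)

  amp_tbl <- cells |>
    dplyr::left_join(
      spec$pattern_amplitude |>
        dplyr::group_by(.data$area, .data$layer, .data$stereo) |>
        dplyr::summarise(amplitude = sum(.data$amplitude), .groups = "drop"),
      by = c("area", "layer", "stereo")
    ) |>
    dplyr::mutate(amplitude = dplyr::coalesce(.data$amplitude, 0))
  amp_vec <- setNames(amp_tbl$amplitude,
                      paste(amp_tbl$area, amp_tbl$layer, amp_tbl$stereo, sep = "."))

  datasets <- list()
  model_tbl <- as_plain_tibble(model)
  for (a in areas) {
    vox <- model_tbl[model_tbl$area == a, ]
    v_idx <- vox$voxel_id
    nv <- nrow(vox)
    vein_a <- vein[v_idx]
    pat_a <- pattern[v_idx]
    amp_mult <- ifelse(vein_a, spec$vein_amp_mult, 1)
    noise_mult <- ifelse(vein_a, spec$vein_noise_mult, 1)
    depth_gain <- 1 + spec$superficial_gain_slope * vox$true_depth

    evoked <- matrix(0, nv, n_tr * n_runs)
    for (r in seq_len(n_runs)) {
      dr <- design[design$run == r, ]
      # per-block amplitude matrix: blocks x voxels
      amp <- matrix(0, nrow(dr), nv)
      for (b in seq_len(nrow(dr))) {
        s_b <- if (dr$disparity[b] == "near") 1 else -1
        key <- paste(a, vox$true_layer, dr$stereo[b], sep = ".")
        gidx <- which(design$run == dr$run[b] & design$block == dr$block[b])
        g_b <- gains[cbind(match(key, rownames(u)), gidx)]
        amp[b, ] <- spec$mean_amplitude * amp_mult +
          amp_vec[key] * g_b * s_b * pat_a
      }
      Xb <- block_regressor_matrix(dr$onset_tr, rep(block_tr, nrow(dr)), n_tr, tr)
      evoked[, (r - 1) * n_tr + seq_len(n_tr)] <- t(Xb %*% amp)
    }

    evoked <- evoked * depth_gain

    # draining-vein leakage into superficial voxels, column by column
    if (spec$leak_fraction > 0) {
      sup <- which(vox$true_layer == "superficial")
      if (length(sup) > 0) {
        deep_mid <- vox$true_layer != "superficial"
        col_means <- rowsum(evoked[deep_mid, , drop = FALSE],
                            group = vox$column_id[deep_mid]) /
          as.vector(table(vox$column_id[deep_mid]))
        src <- match(vox$column_id[sup], sort(unique(vox$column_id[deep_mid])))
        ok <- !is.na(src)
        evoked[sup[ok], ] <- evoked[sup[ok], , drop = FALSE] +
          spec$leak_fraction * col_means[src[ok], , drop = FALSE]
      }
    }

    set.seed(derive_seed(spec$seed, paste0("noise.", a)))
    noise <- matrix(0, nv, n_tr * n_runs)
    phi <- spec$physio_ar1
    innov_sd <- spec$noise_sd * sqrt(1 - phi^2)
    for (r in seq_len(n_runs)) {
      e <- matrix(stats::rnorm(nv * n_tr, sd = innov_sd), nv, n_tr)
      if (phi > 0) {
        e[, 1] <- stats::rnorm(nv, sd = spec$noise_sd) # stationary start
        for (tt in 2:n_tr) e[, tt] <- phi * e[, tt - 1] + e[, tt]
      }
      noise[, (r - 1) * n_tr + seq_len(n_tr)] <- e
    }
    noise <- noise * noise_mult

    data <- spec$baseline + evoked + noise
    vox_out <- vox |>
      dplyr::mutate(vein_flag = vein_a) |>
      dplyr::select("voxel_id", "area", "column_id", "x", "y", "z", "i", "j", "k",
                    "true_depth", "true_layer", "vein_flag")
    datasets[[a]] <- new_laminar_dataset(
      data = data, voxels = vox_out, tr = tr, n_runs = n_runs,
      n_tr_per_run = n_tr, area = a, applied_steps = "simulate"
    )
  }

  truth <- list(
    pattern = tibble(voxel_id = model$voxel_id, area = model$area,
                     layer = model$true_layer, pattern = pattern),
    gains = gains,
    gain_cells = cells,
    vein_voxels = model$voxel_id[vein],
    signal_cells = spec$pattern_amplitude |> dplyr::filter(.data$amplitude > 0),
    coupling = spec$coupling,
    spec = spec
  )
  structure(list(datasets = datasets, truth = truth, design = design),
            class = "laminar_simulation")
}

#' @export
print.laminar_simulation <- function(x, ...) {
  cat(sprintf("<laminar_simulation> %d areas x (%d voxels x %d TRs)\n",
              length(x$datasets), nrow(x$datasets[[1]]$data),
              ncol(x$datasets[[1]]$data)))
  invisible(x)
}
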