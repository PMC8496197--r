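#' Generate a counterbalanced block design
#'
#' Builds the run/block/condition structure of a 2 x 2 blocked stereoscopic
#' experiment: factors stereo (correlated vs anti-correlated random dot
#' stereograms) and disparity (near vs far), presented in stimulus blocks
#' flanked by lead and trail fixation blocks. With the defaults (TR 2 s, 10
#' blocks per condition, 12 s blocks and fixation) each run lasts
#' 12 + 40 x 12 + 12 = 504 s, i.e. 252 TRs.
#'
#' Counterbalancing: each run is a sequence of `blocks_per_condition` sweeps,
#' each sweep a seeded random permutation of the four conditions, so every
#' condition occurs exactly once per sweep and exactly `blocks_per_run / 4`
#' times per run.
#'
#' @param runs Number of runs (>= 2; leave-one-run-out needs at least two).
#' @param tr Repetition time, seconds.
#' @param blocks_per_condition Stimulus blocks per condition per run.
#' @param block_duration Stimulus block duration, seconds (multiple of `tr`).
#' @param fixation_duration Lead and trail fixation duration, seconds.
#' @param seed Integer seed; fixed seed gives an identical design.
#' @return A `block_design`: a tibble with one row per stimulus block
#'   (`run`, `block`, `onset_tr` 0-based, `onset_s`, `stereo`, `disparity`,
#'   `condition`) and attributes `tr`, `n_tr_per_run`, `run_duration_s`,
#'   `block_duration`, `fixation_duration`, `blocks_per_run`, plus stimulus
#'   timing metadata (`stimulus_duration_s` 0.9, `isi_s` 0.3,
#'   `disparity_arcmin` 10, `disparity_jitter_arcmin` 0.5) describing the
#'   per-stimulus events that are not simulated individually.
#' @examples
#' d <- generate_design(runs = 4, seed = 1)
#' attr(d, "run_duration_s") # 504
#' table(d$run, d$condition)
#' @export
generate_design <- function(runs = 4, tr = 2, blocks_per_condition = 10,
                            block_duration = 12, fixation_duration = 12,
                            seed = 1) {
  if (!is.numeric(runs) || runs < 2) {
    abort("`runs` must be >= 2 (leave-one-run-out cross-validation needs at least two runs).")
  }
  if (blocks_per_condition < 1 || block_duration <= 0 || fixation_duration < 0 || tr <= 0) {
    abort("Design parameters must be positive (and `blocks_per_condition` >= 1).")
  }
  if (abs(block_duration / tr - round(block_duration / tr)) > 1e-9 ||
      abs(fixation_duration / tr - round(fixation_duration / tr)) > 1e-9) {
    abort("`block_duration` and `fixation_duration` must be whole numbers of TRs.")
  }
  conditions <- tidyr::expand_grid(
    stereo = c("correlated", "anticorrelated"),
    disparity = c("near", "far")
  )
  blocks_per_run <- as.integer(4 * blocks_per_condition)
  block_tr <- as.integer(round(block_duration / tr))
  fix_tr <- as.integer(round(fixation_duration / tr))
  n_tr_per_run <- as.integer(2L * fix_tr + blocks_per_run * block_tr)

  set.seed(derive_seed(seed, "design"))
  per_run <- purrr::map(seq_len(runs), function(r) {
    order <- unlist(lapply(seq_len(blocks_per_condition), function(s) sample.int(4L)))
    conditions[order, ] |>
      dplyr::mutate(
        run = r,
        block = dplyr::row_number(),
        onset_tr = fix_tr + (dplyr::row_number() - 1L) * block_tr,
        onset_s = .data$onset_tr * tr
      )
  })
  design <- dplyr::bind_rows(per_run) |>
    dplyr::mutate(condition = paste(.data$stereo, .data$disparity, sep = "_")) |>
    dplyr::select("run", "block", "onset_tr", "onset_s", "stereo", "disparity", "condition")

  structure(
    design,
    class = c("block_design", class(design)),
    tr = tr,
    n_tr_per_run = n_tr_per_run,
    run_duration_s = n_tr_per_run * tr,
    block_duration = block_duration,
    block_tr = block_tr,
    fixation_duration = fixation_duration,
    blocks_per_run = blocks_per_run,
    stimulus_duration_s = 0.9,
    isi_s = 0.3,
    disparity_arcmin = 10,
    disparity_jitter_arcmin = 0.5
  )
}

design_attr <- function(design, what) attr(design, what, exact = TRUE)

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf(
    "<block_design> %d runs x %d blocks (TR %gs, run %gs = %d TRs)\n",
    max(x$run), design_attr(x, "blocks_per_run"), design_attr(x, "tr"),
    design_attr(x, "run_duration_s"), design_attr(x, "n_tr_per_run")
  ))
  NextMethod()
}
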