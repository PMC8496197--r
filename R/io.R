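#' Write a simulated dataset to NIfTI + TSV + JSON
#'
#' Serialises a [simulate_bold()] result in the standard neuroimaging layout:
#' one 4-D NIfTI time series per area (voxels placed at their array indices),
#' a 3-D integer NIfTI of layer labels (1 = deeper, 2 = middle,
#' 3 = superficial), BIDS-style events TSV files per run (`onset`,
#' `duration`, `trial_type`), and the ground truth as JSON.
#'
#' @param sim A `laminar_simulation`.
#' @param layers A [assign_voxels()] layer assignment for the label volumes.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, layers, dir) {
  stopifnot(inherits(sim, "laminar_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  design <- sim$design
  tr <- design_attr(design, "tr")
  for (a in names(sim$datasets)) {
    ds <- sim$datasets[[a]]
    vox <- ds$voxels
    dims <- c(max(vox$i), max(vox$j), max(vox$k))
    arr <- array(0, c(dims, ncol(ds$data)))
    lab <- array(0L, dims)
    lay <- layers$layer[match(vox$voxel_id, layers$voxel_id)]
    for (v in seq_len(nrow(vox))) {
      arr[vox$i[v], vox$j[v], vox$k[v], ] <- ds$data[v, ]
      lab[vox$i[v], vox$j[v], vox$k[v]] <- as.integer(lay[v])
    }
    bold_path <- file.path(dir, sprintf("%s_bold.nii.gz", a))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(0.8, 0.8, 0.8, tr)
    RNifti::writeNifti(img, bold_path)
    lab_path <- file.path(dir, sprintf("%s_layers.nii.gz", a))
    RNifti::writeNifti(RNifti::asNifti(lab), lab_path)
    files <- c(files, bold_path, lab_path)
  }
  for (r in sort(unique(design$run))) {
    ev <- design[design$run == r, ] |>
      as_tibble() |>
      dplyr::transmute(onset = .data$onset_s,
                       duration = design_attr(design, "block_duration"),
                       trial_type = .data$condition)
    ev_path <- file.path(dir, sprintf("run-%02d_events.tsv", r))
    utils::write.table(ev, ev_path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, ev_path)
  }
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- sim$truth
  jsonlite::write_json(
    list(
      vein_voxels = truth$vein_voxels,
      signal_cells = truth$signal_cells,
      coupling = truth$coupling,
      pattern = truth$pattern,
      seed = truth$spec$seed
    ),
    truth_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  files <- c(files, truth_path)
  invisible(files)
}

#' Read a 4-D NIfTI time series with events and layer labels
#'
#' Real-data entry point: builds a `laminar_dataset`, a `block_design`, and a
#' layer assignment from a 4-D BOLD NIfTI, a BIDS-style events TSV (columns
#' `onset`, `duration`, `trial_type` formatted `<stereo>_<disparity>`), and a
#' 3-D integer layer-label NIfTI (1 = deeper, 2 = middle, 3 = superficial;
#' 0 = outside mask).
#'
#' @param bold_files Character vector of per-run 4-D NIfTI paths (or one file
#'   for a single run).
#' @param events_files Matching per-run events TSV paths.
#' @param layer_file 3-D layer-label NIfTI path.
#' @param tr Repetition time in seconds (read from the NIfTI header when
#'   available; this argument overrides).
#' @param area Area label to record.
#' @return List: `dataset` (`laminar_dataset`), `design` (`block_design`),
#'   `layers` (`layer_assignment`).
#' @export
read_laminar_nifti <- function(bold_files, events_files, layer_file,
                               tr = NULL, area = "ROI") {
  if (length(bold_files) != length(events_files)) {
    abort("Need one events file per BOLD run.")
  }
  lab <- RNifti::readNifti(layer_file)
  mask <- which(lab > 0, arr.ind = TRUE)
  if (nrow(mask) == 0) abort("Layer-label volume contains no in-mask voxels.")
  layer_levels <- c("deeper", "middle", "superficial")

  runs <- list(); ev_all <- list()
  for (r in seq_along(bold_files)) {
    img <- RNifti::readNifti(bold_files[r])
    if (length(dim(img)) != 4) abort("BOLD image must be 4-D.")
    if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
    mat <- matrix(0, nrow(mask), dim(img)[4])
    for (v in seq_len(nrow(mask))) {
      mat[v, ] <- img[mask[v, 1], mask[v, 2], mask[v, 3], ]
    }
    runs[[r]] <- mat
    ev <- utils::read.delim(events_files[r])
    if (!all(c("onset", "duration", "trial_type") %in% names(ev))) {
      abort("Events TSV needs columns onset, duration, trial_type.")
    }
    ev$run <- r
    ev_all[[r]] <- ev
  }
  n_tr <- unique(vapply(runs, ncol, integer(1)))
  if (length(n_tr) != 1) abort("All runs must have the same number of TRs.")
  data <- do.call(cbind, runs)

  vox <- tibble(
    voxel_id = seq_len(nrow(mask)),
    area = area,
    i = mask[, 1], j = mask[, 2], k = mask[, 3],
    x = (mask[, 1] - 1) * 0.8, y = (mask[, 2] - 1) * 0.8, z = (mask[, 3] - 1) * 0.8,
    column_id = NA_integer_
  )
  ds <- new_laminar_dataset(data, vox, tr = tr, n_runs = length(runs),
                            n_tr_per_run = n_tr, area = area,
                            applied_steps = "read_nifti")

  ev <- dplyr::bind_rows(ev_all)
  parts <- strsplit(as.character(ev$trial_type), "_", fixed = TRUE)
  design <- tibble(
    run = ev$run,
    block = stats::ave(ev$run, ev$run, FUN = seq_along),
    onset_tr = as.integer(round(ev$onset / tr)),
    onset_s = ev$onset,
    stereo = vapply(parts, `[`, character(1), 1),
    disparity = vapply(parts, `[`, character(1), 2),
    condition = as.character(ev$trial_type)
  )
  dur_tr <- as.integer(round(unique(ev$duration)[1] / tr))
  design <- structure(
    design, class = c("block_design", class(design)),
    tr = tr, n_tr_per_run = n_tr, run_duration_s = n_tr * tr,
    block_duration = unique(ev$duration)[1], block_tr = dur_tr,
    fixation_duration = min(design$onset_s),
    blocks_per_run = sum(design$run == 1)
  )

  lay <- tibble(
    voxel_id = vox$voxel_id, area = area, column_id = NA_integer_,
    layer = factor(layer_levels[lab[mask]], levels = layer_levels),
    depth_fraction = NA_real_
  )
  counts <- lay |> dplyr::count(.data$area, .data$layer, .drop = FALSE)
  lay <- structure(lay, class = c("layer_assignment", class(lay)), counts = counts)

  list(dataset = ds, design = design, layers = lay)
}
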