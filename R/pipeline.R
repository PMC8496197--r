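#' Pipeline configuration
#'
#' Collects every threshold and parameter of the analysis chain in one list.
#' Defaults reproduce the standard settings: preselection t 1.53, tSNR cut at
#' 2 SD, t cut at the 90th percentile, 175 voxels per layer, linear classifier
#' cost C = 1, block-response TR window 3-7 (4-14 s after onset),
#' Greenhouse-Geisser applied for epsilon < 0.75, 5000 label permutations
#' when permutation testing is requested.
#'
#' @param ... Named overrides of any default (unknown names are rejected).
#' @return A `laminar_config` list.
#' @export
laminar_config <- function(...) {
  defaults <- list(
    # experiment / generator
    n_subjects = 7,
    runs_choices = c(4, 5, 6),
    tr = 2,
    blocks_per_condition = 10,
    block_duration = 12,
    fixation_duration = 12,
    n_columns = 84,
    voxels_per_column = 9,
    curvature_range = c(0.5, 2),
    areas = c("A1", "A3A", "A7"),
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
    pattern_amplitude = NULL,
    # preprocessing
    highpass_cycles = 2,
    t_preselect = 1.53,
    tsnr_sd_mult = 2,
    t_percentile = 90,
    window = c(3, 7),
    spatial_regression = FALSE,
    k_neighbors = 3,
    # decoding / ldc
    n_voxels = 175,
    svm_cost = 1,
    run_permutations = FALSE,
    n_perm = 5000,
    regress_mean = FALSE,
    # stats
    gg_threshold = 0.75,
    # bookkeeping
    seed = 1,
    out_dir = NULL
  )
  overrides <- list(...)
  # provenance fields written by write_report() are tolerated and dropped
  overrides <- overrides[setdiff(names(overrides),
                                 c("package_version", "config_hash"))]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides, keep.null = TRUE)
  validate_config(structure(cfg, class = "laminar_config"))
}

#' Validate a pipeline configuration
#'
#' Checks types and ranges, fills defaults, and rejects unknown keys. Accepts
#' a `laminar_config`, a plain named list, or a path to a YAML file.
#'
#' @param config A config list or YAML path; `NULL`/empty gives all defaults.
#' @return A validated `laminar_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("Config file not found: %s", config))
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
    for (nm in c("coupling", "pattern_amplitude")) {
      if (!is.null(config[[nm]]) && !is.data.frame(config[[nm]])) {
        config[[nm]] <- dplyr::bind_rows(lapply(config[[nm]], as_tibble))
      }
    }
    return(do.call(laminar_config, config))
  }
  if (is.null(config)) return(laminar_config())
  if (!inherits(config, "laminar_config")) {
    return(do.call(laminar_config, unclass(config)))
  }
  chk_pos <- function(key) {
    if (!is.numeric(config[[key]]) || any(config[[key]] <= 0)) {
      abort(sprintf("`%s` must be positive (got %s).", key,
                    paste(config[[key]], collapse = ", ")))
    }
  }
  for (key in c("n_subjects", "tr", "blocks_per_condition", "block_duration",
                "n_columns", "voxels_per_column", "n_voxels", "svm_cost",
                "n_perm", "baseline")) chk_pos(key)
  if (any(config$runs_choices < 2)) abort("`runs_choices` must all be >= 2.")
  if (config$t_percentile <= 0 || config$t_percentile > 100) {
    abort("`t_percentile` must lie in (0, 100].")
  }
  if (config$vein_fraction < 0 || config$vein_fraction >= 1) {
    abort("`vein_fraction` must lie in [0, 1).")
  }
  if (config$leak_fraction < 0 || config$leak_fraction >= 1) {
    abort("`leak_fraction` must lie in [0, 1).")
  }
  if (config$physio_ar1 < 0 || config$physio_ar1 >= 1) {
    abort("`physio_ar1` must lie in [0, 1).")
  }
  if (length(config$window) != 2 || config$window[1] < 1 ||
      config$window[2] < config$window[1]) {
    abort("`window` must be an increasing 1-based TR interval.")
  }
  structure(config, class = "laminar_config")
}

#' @export
print.laminar_config <- function(x, ...) {
  cat("<laminar_config>\n")
  utils::str(unclass(x), max.level = 1, give.attr = FALSE)
  invisible(x)
}

config_effect_spec <- function(config, seed) {
  effect_spec(
    pattern_amplitude = config$pattern_amplitude,
    signal_amplitude = config$signal_amplitude,
    mean_amplitude = config$mean_amplitude,
    superficial_gain_slope = config$superficial_gain_slope,
    leak_fraction = config$leak_fraction,
    vein_fraction = config$vein_fraction,
    vein_noise_mult = config$vein_noise_mult,
    vein_amp_mult = config$vein_amp_mult,
    noise_sd = config$noise_sd,
    physio_ar1 = config$physio_ar1,
    baseline = config$baseline,
    block_gain_sd = config$block_gain_sd,
    coupling = config$coupling,
    seed = seed
  )
}

#' Run the full analysis chain for one simulated subject
#'
#' Simulates one subject (geometry, design, BOLD) and runs the complete
#' pipeline per area: temporal filtering, condition GLM, voxel preselection,
#' vascular exclusion, equi-volume layer assignment, voxel-count matching
#' with z-scoring, optional spatial regression, block-response extraction,
#' per-(layer, stereo) decoding and LDC, and informational connectivity
#' between all layer pairs of different areas.
#'
#' @param config A [laminar_config()].
#' @param subject_seed Integer seed for this subject's randomness.
#' @param subject_id Label recorded in the output tables.
#' @return A `laminar_subject`: list of tidy tables `accuracy` (area, layer,
#'   stereo, accuracy, n_voxels), `ldc`, `profile` (per-area layer profiles
#'   before/after correction), `connectivity` (pathway table), plus `truth`
#'   and `meta`.
#' @export
run_subject <- function(config = laminar_config(), subject_seed = 1,
                        subject_id = "s1") {
  config <- validate_config(config)
  runs <- config$runs_choices[
    1 + (derive_seed(subject_seed, "runs") %% length(config$runs_choices))]
  model <- generate_cortical_patch(
    n_columns = config$n_columns, voxels_per_column = config$voxels_per_column,
    curvature_range = config$curvature_range, areas = config$areas,
    seed = derive_seed(subject_seed, "model")
  )
  design <- generate_design(
    runs = runs, tr = config$tr,
    blocks_per_condition = config$blocks_per_condition,
    block_duration = config$block_duration,
    fixation_duration = config$fixation_duration,
    seed = derive_seed(subject_seed, "design")
  )
  spec <- config_effect_spec(config, derive_seed(subject_seed, "effects"))
  sim <- simulate_bold(model, design, spec)
  grids <- build_grids(model)
  layers <- assign_voxels(model, grids)

  acc_rows <- list(); ldc_rows <- list(); prof_rows <- list(); decode_rows <- list()
  for (a in config$areas) {
    ds_raw <- sim$datasets[[a]]
    ds_f <- highpass_and_detrend(ds_raw, n_cycles = config$highpass_cycles)
    glm1 <- fit_glm(ds_f, design)
    pre <- roi_voxel_preselect(glm1, t_threshold = config$t_preselect)
    mask <- vascular_exclusion(ds_raw, glm1, sd_mult = config$tsnr_sd_mult,
                               t_percentile = config$t_percentile)
    ds_m <- match_and_zscore(ds_f, layers, mask, keep_ids = pre)
    if (isTRUE(config$spatial_regression)) {
      ds_m <- regress_out_middle(ds_m, k_neighbors = config$k_neighbors)
    }
    prof_rows[[a]] <- layer_profile(ds_f, ds_m, layers, design,
                                    window = config$window) |>
      dplyr::mutate(area = a)
    glm2 <- fit_glm(ds_m, design)
    n_vox <- min(config$n_voxels,
                 min(table(ds_m$voxels$layer)))
    sel <- select_voxels(glm2, ds_m$voxels, n = n_vox)
    bp_all <- block_responses(ds_m, design, window = config$window)
    for (l in levels(layers$layer)) {
      vox_l <- sel$voxel_id[sel$layer == l]
      for (s in c("correlated", "anticorrelated")) {
        keep <- bp_all$blocks$stereo == s
        bp <- filter_patterns(bp_all, voxel_ids = vox_l, block_keep = keep)
        if (isTRUE(config$regress_mean)) bp <- regress_mean_pattern(bp)
        dec <- crossval_decode(bp, C = config$svm_cost)
        ld <- ldc_crossvalidated(bp, glm2)
        acc_rows[[length(acc_rows) + 1]] <- tibble(
          area = a, layer = l, stereo = s, accuracy = dec$accuracy,
          n_voxels = dec$n_voxels)
        ldc_rows[[length(ldc_rows) + 1]] <- tibble(
          area = a, layer = l, stereo = s, ldc = ld$ldc)
        decode_rows[[length(decode_rows) + 1]] <- tibble(
          area = a, layer = l, stereo = s, fit = list(dec))
      }
    }
  }
  decodes <- dplyr::bind_rows(decode_rows)
  series <- build_distance_series(decodes)
  connectivity <- pathway_contrast(series, area_order = config$areas)

  structure(
    list(
      accuracy = dplyr::bind_rows(acc_rows) |> dplyr::mutate(subject = subject_id),
      ldc = dplyr::bind_rows(ldc_rows) |> dplyr::mutate(subject = subject_id),
      profile = dplyr::bind_rows(prof_rows) |> dplyr::mutate(subject = subject_id),
      connectivity = connectivity |> dplyr::mutate(subject = subject_id),
      decodes = decodes,
      truth = sim$truth,
      meta = list(subject_id = subject_id, seed = subject_seed, runs = runs)
    ),
    class = "laminar_subject"
  )
}

#' @export
print.laminar_subject <- function(x, ...) {
  cat(sprintf("<laminar_subject> %s (%d runs): mean accuracy %.3f\n",
              x$meta$subject_id, x$meta$runs, mean(x$accuracy$accuracy)))
  invisible(x)
}

#' Run a full simulated group experiment
#'
#' Simulates `n_subjects` independent subjects from one master seed, runs the
#' complete per-subject pipeline, and computes the group-level
#' repeated-measures statistics: the three-way condition x cortical depth x
#' area ANOVA on decoding accuracy, per-area two-way condition x depth
#' ANOVAs for accuracy and LDC, and per-pathway condition x area-pair ANOVAs
#' on Fisher-z informational connectivity.
#'
#' @param config A [laminar_config()]; `config$seed` is the master seed and
#'   `config$n_subjects` the group size.
#' @return A `laminar_experiment` with per-subject tables (`accuracy`, `ldc`,
#'   `profile`, `connectivity`), group ANOVA results (`anova_accuracy_3way`,
#'   `anova_accuracy_by_area`, `anova_ldc_by_area`, `anova_connectivity`),
#'   and `config`.
#' @export
run_experiment <- function(config = laminar_config()) {
  config <- validate_config(config)
  subjects <- purrr::map(seq_len(config$n_subjects), function(i) {
    run_subject(config, subject_seed = derive_seed(config$seed, paste0("subject", i)),
                subject_id = sprintf("s%02d", i))
  })
  accuracy <- purrr::map_dfr(subjects, "accuracy")
  ldc <- purrr::map_dfr(subjects, "ldc")
  profile <- purrr::map_dfr(subjects, "profile")
  connectivity <- purrr::map_dfr(subjects, "connectivity")

  anova_accuracy_3way <- rm_anova(accuracy, dv = "accuracy", subject = "subject",
                                  within = c("stereo", "layer", "area"),
                                  gg_threshold = config$gg_threshold)
  by_area <- function(tab, dv) {
    purrr::map(setNames(config$areas, config$areas), function(a) {
      rm_anova(tab[tab$area == a, ], dv = dv, subject = "subject",
               within = c("stereo", "layer"), gg_threshold = config$gg_threshold)
    })
  }
  anova_accuracy_by_area <- by_area(accuracy, "accuracy")
  anova_ldc_by_area <- by_area(ldc, "ldc")
  anova_connectivity <- purrr::map(
    setNames(c("feedforward", "feedback"), c("feedforward", "feedback")),
    function(p) {
      tab <- connectivity[connectivity$pathway == p, ]
      rm_anova(tab, dv = "z", subject = "subject",
               within = c("stereo", "area_pair"), gg_threshold = config$gg_threshold)
    })

  structure(
    list(accuracy = accuracy, ldc = ldc, profile = profile,
         connectivity = connectivity,
         anova_accuracy_3way = anova_accuracy_3way,
         anova_accuracy_by_area = anova_accuracy_by_area,
         anova_ldc_by_area = anova_ldc_by_area,
         anova_connectivity = anova_connectivity,
         config = config,
         subjects = purrr::map(subjects, "meta")),
    class = "laminar_experiment"
  )
}

#' @export
print.laminar_experiment <- function(x, ...) {
  cat(sprintf("<laminar_experiment> %d subjects, seed %d\n",
              x$config$n_subjects, x$config$seed))
  cat("\nGroup mean decoding accuracy:\n")
  print(
    x$accuracy |>
      dplyr::group_by(.data$area, .data$layer, .data$stereo) |>
      dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "stereo", values_from = "accuracy"),
    n = Inf
  )
  cat("\n3-way ANOVA on accuracy:\n")
  print(x$anova_accuracy_3way)
  invisible(x)
}

#' Write an experiment report bundle
#'
#' Writes the per-subject tables and group ANOVA tables as TSV, plus the
#' resolved configuration as YAML, to `dir`.
#'
#' @param experiment A [run_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(experiment, dir) {
  stopifnot(inherits(experiment, "laminar_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(tab, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(experiment$accuracy, "accuracy")
  wr(experiment$ldc, "ldc")
  wr(experiment$profile, "layer_profile")
  wr(experiment$connectivity, "connectivity")
  wr(tidy(experiment$anova_accuracy_3way), "anova_accuracy_3way")
  for (a in names(experiment$anova_accuracy_by_area)) {
    wr(tidy(experiment$anova_accuracy_by_area[[a]]), paste0("anova_accuracy_", a))
    wr(tidy(experiment$anova_ldc_by_area[[a]]), paste0("anova_ldc_", a))
  }
  for (p in names(experiment$anova_connectivity)) {
    wr(tidy(experiment$anova_connectivity[[p]]), paste0("anova_connectivity_", p))
  }
  cfg <- unclass(experiment$config)
  cfg$coupling <- if (!is.null(cfg$coupling)) as.data.frame(cfg$coupling)
  cfg$pattern_amplitude <- if (!is.null(cfg$pattern_amplitude)) {
    as.data.frame(cfg$pattern_amplitude)
  }
  cfg$package_version <- as.character(utils::packageVersion("laminar"))
  cfg$config_hash <- sum(utf8ToInt(paste(deparse(cfg), collapse = "")))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  files <- c(files, file.path(dir, "config.yaml"))
  invisible(files)
}
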