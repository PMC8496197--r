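make_ds <- function(data, tr = 2, n_runs = 1, area = "A1") {
  n_tr <- ncol(data) / n_runs
  structure(
    list(data = data, voxels = tibble::tibble(voxel_id = seq_len(nrow(data))),
         tr = tr, n_runs = n_runs, n_tr_per_run = n_tr, area = area,
         applied_steps = character()),
    class = "laminar_dataset"
  )
}

test_that("highpass removes trends and low-frequency sinusoids exactly", {
  n <- 100
  tt <- seq_len(n)
  data <- rbind(
    5 + 0.3 * tt,                      # pure linear trend
    sin(2 * pi * 2 * tt / n),          # 2-cycle sinusoid
    cos(2 * pi * 1 * tt / n)           # 1-cycle sinusoid
  )
  out <- highpass_and_detrend(make_ds(data))
  expect_lt(max(abs(out$data)), 1e-10 * max(abs(data)))
})

test_that("highpass residuals equal a brute-force OLS fit of the same basis", {
  set.seed(1)
  n <- 80
  data <- matrix(rnorm(3 * n), 3, n)
  out <- highpass_and_detrend(make_ds(data))
  tt <- seq_len(n)
  X <- cbind(1, tt, sin(2 * pi * tt / n), cos(2 * pi * tt / n),
             sin(4 * pi * tt / n), cos(4 * pi * tt / n))
  for (v in 1:3) {
    oracle <- stats::lm.fit(X, data[v, ])$residuals
    expect_lt(max(abs(out$data[v, ] - oracle)), 1e-10)
  }
  expect_error(highpass_and_detrend(make_ds(matrix(0, 2, 6))), "too short")
})

test_that("the GLM recovers a noiseless amplitude exactly", {
  m <- tiny_model(n_columns = 6, seed = 2)
  d <- tiny_design(runs = 2, seed = 2)
  sp <- effect_spec(
    pattern_amplitude = tibble::tibble(area = character(), layer = character(),
                                       stereo = character(), amplitude = numeric()),
    mean_amplitude = 1.7, noise_sd = 0, physio_ar1 = 0, leak_fraction = 0,
    vein_fraction = 0, superficial_gain_slope = 0, seed = 1
  )
  sim <- simulate_bold(m, d, sp)
  glm <- fit_glm(sim$datasets[["A3A"]], d)
  expect_lt(max(abs(glm$contrast_estimate - 1.7)), 1e-8)
  # residuals orthogonal to the design
  xr <- crossprod(glm$X, t(glm$residuals))
  expect_lt(max(abs(xr)), 1e-6)
})

test_that("GLM t equals the brute-force contrast formula on a small fixture", {
  set.seed(3)
  m <- tiny_model(n_columns = 4, voxels_per_column = 3, seed = 3)
  d <- tiny_design(runs = 2, seed = 3)
  sim <- simulate_bold(m, d, null_spec(seed = 3))
  ds <- sim$datasets[["A3A"]]
  ds$data <- ds$data[1:10, , drop = FALSE]
  ds$voxels <- ds$voxels[1:10, ]
  glm <- fit_glm(ds, d)
  X <- glm$X
  cvec <- numeric(ncol(X)); cvec[glm$cond_cols] <- 0.25
  XtXinv <- solve(crossprod(X))
  for (v in 1:10) {
    y <- ds$data[v, ]
    beta <- XtXinv %*% crossprod(X, y)
    r <- y - X %*% beta
    s2 <- sum(r^2) / (length(y) - ncol(X))
    t_hand <- drop(crossprod(cvec, beta)) / sqrt(s2 * drop(t(cvec) %*% XtXinv %*% cvec))
    expect_equal(glm$t_map[v], t_hand, tolerance = 1e-8)
  }
})

test_that("null GLM t-statistics are calibrated at the 5% level", {
  m <- generate_cortical_patch(n_columns = 360, voxels_per_column = 9,
                               areas = "A1", seed = 8)
  d <- tiny_design(runs = 2, seed = 8)
  sim <- simulate_bold(m, d, null_spec(seed = 8))
  glm <- fit_glm(sim$datasets[["A1"]], d)
  frac <- mean(glm$t_map > qt(0.95, glm$dof))
  expect_lt(abs(frac - 0.05), 0.012)
})

test_that("voxel preselection keeps strong responders and thresholds the null", {
  m <- generate_cortical_patch(n_columns = 360, voxels_per_column = 9,
                               areas = "A1", seed = 13)
  d <- tiny_design(runs = 2, seed = 13)
  sim <- simulate_bold(m, d, null_spec(seed = 13))
  glm <- fit_glm(sim$datasets[["A1"]], d)
  kept <- roi_voxel_preselect(glm, t_threshold = 1.53)
  # null retention at t > 1.53 is the upper tail: half of the two-sided
  # p = 0.125, i.e. ~6.3%
  expect_lt(abs(length(kept) / nrow(m) - pt(1.53, glm$dof, lower.tail = FALSE)),
            0.015)
  expect_identical(roi_voxel_preselect(glm, t_threshold = -Inf),
                   glm$voxels$voxel_id)
  expect_error(roi_voxel_preselect(glm, t_threshold = Inf), "empty")
})

test_that("vascular exclusion applies the percentile and tSNR rules", {
  m <- generate_cortical_patch(n_columns = 100, voxels_per_column = 9,
                               areas = "A1", seed = 21)
  d <- tiny_design(runs = 2, seed = 21)
  sim <- simulate_bold(m, d, null_spec(seed = 21))
  ds <- sim$datasets[["A1"]]
  glm <- fit_glm(ds, d)
  mask <- vascular_exclusion(ds, glm, sd_mult = 2, t_percentile = 90)
  # homogeneous noise: the t cut removes the top decile within rounding
  expect_equal(mean(mask$high_t), 0.10, tolerance = 0.005)
  # disabling both rules keeps everything
  mask_all <- vascular_exclusion(ds, glm, sd_mult = Inf, t_percentile = 100)
  expect_true(all(mask_all$keep))
  # constant voxel: tSNR sentinel +Inf, never excluded by the tSNR rule
  ds2 <- ds
  ds2$data[1, ] <- 42
  glm2 <- fit_glm(ds2, d)
  mask2 <- vascular_exclusion(ds2, glm2, sd_mult = 2, t_percentile = 100)
  expect_equal(mask2$tsnr[1], Inf)
  expect_false(mask2$low_tsnr[1])
})

test_that("simulated vein voxels are caught by the exclusion rules", {
  hits <- vapply(1:5, function(sd) {
    m <- tiny_model(n_columns = 40, seed = sd)
    d <- tiny_design(runs = 2, seed = sd)
    sim <- simulate_bold(m, d, tiny_spec(seed = sd))
    ds <- sim$datasets[["A3A"]]
    glm <- fit_glm(highpass_and_detrend(ds), d)
    mask <- vascular_exclusion(ds, glm)
    veins <- sim$truth$vein_voxels
    mean(!mask$keep[mask$voxel_id %in% veins])
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("voxel matching equalises layers by top-t and z-scores per run", {
  m <- tiny_model(n_columns = 30, seed = 6)
  d <- tiny_design(runs = 2, seed = 6)
  sim <- simulate_bold(m, d, tiny_spec(seed = 6))
  ds <- highpass_and_detrend(sim$datasets[["A3A"]])
  glm <- fit_glm(ds, d)
  la <- assign_voxels(m, build_grids(m))
  mask <- vascular_exclusion(sim$datasets[["A3A"]], glm)
  out <- match_and_zscore(ds, la, mask)
  counts <- table(out$voxels$layer)
  expect_true(all(counts == min(counts)))
  # kept voxels are the highest-t eligible voxels of each layer
  elig <- merge(as.data.frame(mask[mask$keep, ]), as.data.frame(la),
                by = "voxel_id")
  for (l in names(counts)) {
    top <- elig[elig$layer == l, ]
    top <- top[order(-top$t, top$voxel_id), "voxel_id"][seq_len(min(counts))]
    expect_setequal(out$voxels$voxel_id[out$voxels$layer == l], top)
  }
  n_tr <- out$n_tr_per_run
  for (r in 1:2) {
    blk <- out$data[, (r - 1) * n_tr + seq_len(n_tr)]
    expect_lt(max(abs(rowMeans(blk))), 1e-12)
    expect_lt(max(abs(apply(blk, 1, sd) - 1)), 1e-12)
  }
})

test_that("spatial regression removes a copied middle-layer signal", {
  m <- tiny_model(n_columns = 20, seed = 10)
  d <- tiny_design(runs = 2, seed = 10)
  sim <- simulate_bold(m, d, tiny_spec(seed = 10))
  ds <- sim$datasets[["A3A"]]
  la <- assign_voxels(m, build_grids(m))
  ds$voxels$layer <- la$layer[match(ds$voxels$voxel_id, la$voxel_id)]
  sup <- which(ds$voxels$layer == "superficial")[1]
  # make one superficial voxel an exact copy of its nearest middle voxel
  mid <- which(ds$voxels$layer == "middle")
  P <- as.matrix(ds$voxels[, c("x", "y", "z")])
  nb <- mid[which.min(colSums((t(P[mid, , drop = FALSE]) - P[sup, ])^2))]
  ds$data[sup, ] <- ds$data[nb, ]
  out <- regress_out_middle(ds, k_neighbors = 1)
  expect_lt(abs(cor(out$data[sup, ], ds$data[nb, ])), 1e-8)
  expect_warning(regress_out_middle(ds, k_neighbors = length(mid) + 5), "clamped")
})

test_that("spatial regression removes middle-layer spillover from superficial decoding", {
  decode_sup <- function(leak, sd, layers = "middle", mean_amp = 0) {
    m <- tiny_model(n_columns = 40, seed = sd)
    d <- tiny_design(runs = 2, seed = sd)
    pa <- tidyr::expand_grid(area = "A3A", layer = layers,
                             stereo = "correlated", amplitude = 0.3)
    # mean_amp 0 isolates the leakage pathway: with a shared univariate
    # response the regression mostly removes common-mode variance instead
    sim <- simulate_bold(m, d, effect_spec(
      pattern_amplitude = pa, leak_fraction = leak, vein_fraction = 0,
      superficial_gain_slope = 0, noise_sd = 0.3, mean_amplitude = mean_amp,
      block_gain_sd = 0, seed = sd))
    ds <- highpass_and_detrend(sim$datasets[["A3A"]])
    la <- assign_voxels(m, build_grids(m))
    ds$voxels$layer <- la$layer[match(ds$voxels$voxel_id, la$voxel_id)]
    acc <- function(dsx) {
      bp <- block_responses(dsx, d)
      bp <- filter_patterns(bp,
                            voxel_ids = dsx$voxels$voxel_id[dsx$voxels$layer == "superficial"],
                            block_keep = bp$blocks$stereo == "correlated")
      crossval_decode(bp)$accuracy
    }
    c(before = acc(ds), after = acc(regress_out_middle(ds)))
  }
  # signal only in the middle layer, leaking upward: the superficial layer
  # decodes via spillover, and the correction pushes it back toward chance
  leaky <- vapply(1:5, function(sd) decode_sup(0.5, sd), numeric(2))
  expect_gt(mean(leaky["before", ]), 0.9) # spillover alone decodes strongly
  expect_gt(mean(leaky["before", ] - leaky["after", ]), 0.05)
  # no leakage, genuine superficial signal: the correction is nearly a no-op
  clean <- vapply(1:5, function(sd) {
    decode_sup(0, sd + 50, layers = c("middle", "superficial"))
  }, numeric(2))
  expect_lt(mean(abs(clean["before", ] - clean["after", ])), 0.05)
})

test_that("block responses average the 3rd-7th TR window after onset", {
  d <- tiny_design(runs = 2, seed = 1)
  n_tr <- attr(d, "n_tr_per_run")
  # constant series: every block response equals the constant
  const <- make_ds(matrix(3.5, 2, 2 * n_tr), n_runs = 2)
  bp <- block_responses(const, d)
  expect_true(all(bp$responses == 3.5))
  expect_equal(nrow(bp$responses), 80)
  expect_true(all(table(bp$blocks$stereo, bp$blocks$disparity) == 20))
  # HRF delay: the shifted window catches more response than an unshifted one
  onset <- d$onset_tr[1]
  box <- numeric(n_tr); box[onset + 1:6] <- 1
  h <- laminar:::convolve_hrf(box, tr = 2)
  shifted <- mean(h[onset + 2:6 + 1])
  unshifted <- mean(h[onset + 0:4 + 1])
  expect_gt(shifted, unshifted)
  # window spans 4-14 s after onset: offsets 2..6 at TR 2 s
  expect_error(block_responses(const, d, window = c(3, 300)), "exceeds")
})

test_that("four runs give 160 block patterns, 40 per condition cell", {
  d <- generate_design(runs = 4, seed = 2)
  n_tr <- attr(d, "n_tr_per_run")
  ds <- make_ds(matrix(rnorm(5 * 4 * n_tr), 5), n_runs = 4)
  bp <- block_responses(ds, d)
  expect_equal(dim(bp$responses), c(160L, 5L))
  expect_true(all(table(bp$blocks$stereo, bp$blocks$disparity) == 40))
})

test_that("layer profiles show the superficial bias before but not after correction", {
  m <- tiny_model(n_columns = 40, seed = 12)
  d <- tiny_design(runs = 2, seed = 12)
  sim <- simulate_bold(m, d, tiny_spec(superficial_gain_slope = 1, seed = 12))
  ds_f <- highpass_and_detrend(sim$datasets[["A3A"]])
  glm <- fit_glm(ds_f, d)
  la <- assign_voxels(m, build_grids(m))
  mask <- vascular_exclusion(sim$datasets[["A3A"]], glm)
  ds_m <- match_and_zscore(ds_f, la, mask)
  prof <- layer_profile(ds_f, ds_m, la, d)
  before <- prof[prof$state == "before", ]
  before <- before[order(before$layer), ]
  expect_true(all(diff(before$mean_response) > 0)) # deeper < middle < superficial
  gap <- function(st) {
    p <- prof[prof$state == st, ]
    p$rel_response[p$layer == "superficial"] - p$rel_response[p$layer == "deeper"]
  }
  expect_lt(abs(gap("after")), abs(gap("before")))
})

test_that("without vascular effects the profile is flat before and after", {
  m <- tiny_model(n_columns = 40, seed = 14)
  d <- tiny_design(runs = 2, seed = 14)
  sim <- simulate_bold(m, d, tiny_spec(
    superficial_gain_slope = 0, leak_fraction = 0, vein_fraction = 0, seed = 14))
  ds_f <- highpass_and_detrend(sim$datasets[["A3A"]])
  glm <- fit_glm(ds_f, d)
  la <- assign_voxels(m, build_grids(m))
  mask <- vascular_exclusion(sim$datasets[["A3A"]], glm)
  ds_m <- match_and_zscore(ds_f, la, mask)
  prof <- layer_profile(ds_f, ds_m, la, d)
  rel <- tapply(prof$rel_response, prof$state, function(x) max(x) - min(x))
  expect_lt(max(rel), 0.12)
})
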