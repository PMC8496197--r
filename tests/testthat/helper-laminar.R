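# Shared fixtures, all generated in code.

tiny_model <- function(n_columns = 24, voxels_per_column = 9, areas = "A3A",
                       curvature_range = c(0.5, 2), seed = 1) {
  generate_cortical_patch(
    n_columns = n_columns, voxels_per_column = voxels_per_column,
    curvature_range = curvature_range, areas = areas, seed = seed
  )
}

tiny_design <- function(runs = 2, seed = 1) generate_design(runs = runs, seed = seed)

# EffectSpec restricted to one area, signal in superficial+middle / correlated.
tiny_spec <- function(area = "A3A", amplitude = 0.08, ..., seed = 1) {
  pa <- tidyr::expand_grid(area = area, layer = c("superficial", "middle"),
                           stereo = "correlated", amplitude = amplitude)
  effect_spec(pattern_amplitude = pa, ..., seed = seed)
}

null_spec <- function(..., seed = 1) {
  pa <- tibble::tibble(area = character(), layer = character(),
                       stereo = character(), amplitude = numeric())
  effect_spec(pattern_amplitude = pa, mean_amplitude = 0, physio_ar1 = 0,
              superficial_gain_slope = 0, leak_fraction = 0, vein_fraction = 0,
              ..., seed = seed)
}

# Hand-built block_patterns: two Gaussian classes separated along a random
# direction; `sep` = mean class separation per voxel (0 = label-independent).
synthetic_patterns <- function(n_runs = 4, blocks_per_class_run = 10,
                               n_vox = 40, sep = 0, noise = 1, seed = 1,
                               stereo = "correlated") {
  set.seed(seed)
  dir <- rnorm(n_vox)
  dir <- dir / sqrt(sum(dir^2))
  blocks <- tidyr::expand_grid(
    run = seq_len(n_runs),
    idx = seq_len(2 * blocks_per_class_run)
  )
  blocks$disparity <- rep(c("near", "far"), length.out = nrow(blocks))
  blocks$onset_tr <- blocks$idx * 6
  blocks$block_id <- seq_len(nrow(blocks))
  blocks$stereo <- stereo
  s <- ifelse(blocks$disparity == "near", 1, -1)
  resp <- outer(s, dir) * sep / 2 +
    matrix(rnorm(nrow(blocks) * n_vox, sd = noise), nrow(blocks))
  structure(
    list(responses = resp,
         blocks = blocks[, c("block_id", "run", "onset_tr", "stereo", "disparity")],
         voxels = tibble::tibble(voxel_id = seq_len(n_vox)),
         area = "FIX"),
    class = "block_patterns"
  )
}

# Residual matrix (voxels x TRs) whose per-run sample covariance is exactly
# `sigma` (empirically whitened noise recoloured by chol(sigma)).
exact_cov_residuals <- function(sigma, n_tr_per_run, n_runs, seed = 1) {
  set.seed(seed)
  p <- nrow(sigma)
  one_run <- function() {
    X <- matrix(rnorm(n_tr_per_run * p), n_tr_per_run, p)
    X <- scale(X, center = TRUE, scale = FALSE)
    W <- chol(crossprod(X) / (n_tr_per_run - 1))
    Z <- X %*% solve(W) # sample covariance exactly identity
    t(Z %*% chol(sigma))
  }
  run <- one_run()
  do.call(cbind, replicate(n_runs, run, simplify = FALSE))
}

# Minimal laminar_glm carrying just what ldc_crossvalidated() needs.
fake_glm <- function(residuals, voxel_ids, n_runs, n_tr_per_run) {
  structure(
    list(residuals = residuals,
         voxels = tibble::tibble(voxel_id = voxel_ids),
         n_runs = n_runs, n_tr_per_run = n_tr_per_run,
         area = "FIX", dof = n_tr_per_run - 2),
    class = "laminar_glm"
  )
}

# Numerical-inversion oracle for the equi-volume depth fraction: solve the
# linear-area wedge volume integral for x by root finding.
equivolume_oracle <- function(alpha, aw, ap) {
  total <- (aw + ap) / 2
  f <- function(x) aw * x + (ap - aw) * x^2 / 2 - alpha * total
  if (alpha <= 0) return(0)
  if (alpha >= 1) return(1)
  stats::uniroot(f, c(0, 1), tol = 1e-14)$root
}

# Independent closed-form oracle for a balanced within-subject effect:
# orthonormal-contrast scores Z = Y M give SS_E = n * sum(colMeans(Z)^2) and
# SS_error = sum((Z - colMeans)^2); also the Box epsilon from cov(Z).
oracle_effect <- function(Y, levs, effect_factors) {
  M <- matrix(1, 1, 1)
  for (f in names(levs)) {
    L <- length(levs[[f]])
    Mf <- if (f %in% effect_factors) stats::contr.poly(L) else
      matrix(rep(1 / sqrt(L), L), ncol = 1)
    M <- kronecker(M, Mf)
  }
  Z <- Y %*% M
  q <- ncol(Z)
  n <- nrow(Z)
  zbar <- colMeans(Z)
  ss_e <- n * sum(zbar^2)
  ss_err <- sum(sweep(Z, 2, zbar)^2)
  F_val <- (ss_e / q) / (ss_err / (q * (n - 1)))
  S <- stats::cov(Z)
  eps <- sum(diag(S))^2 / (q * sum(S^2))
  list(F = F_val, df1 = q, df2 = q * (n - 1), eps = eps)
}

balanced_table <- function(n_subj, levs, seed, effect_sd = 0.5) {
  set.seed(seed)
  cells <- do.call(tidyr::expand_grid, levs)
  tab <- tidyr::expand_grid(subject = paste0("s", seq_len(n_subj)), cells)
  tab$y <- rnorm(nrow(tab)) + rep(rnorm(n_subj), each = nrow(cells)) +
    rep(rnorm(nrow(cells), sd = effect_sd), times = n_subj)
  tab
}

wide_matrix <- function(tab, levs) {
  cells <- do.call(tidyr::expand_grid, levs)
  key <- do.call(paste, c(lapply(names(levs), function(f) tab[[f]]), sep = "."))
  ck <- do.call(paste, c(lapply(cells, as.character), sep = "."))
  subj <- sort(unique(tab$subject))
  Y <- matrix(NA_real_, length(subj), nrow(cells))
  Y[cbind(match(tab$subject, subj), match(key, ck))] <- tab$y
  Y
}
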