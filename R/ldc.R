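#' Shrinkage estimate of the noise covariance
#'
#' Analytic shrinkage of the sample covariance of GLM noise residuals toward
#' its diagonal: off-diagonal correlations are shrunk by a data-driven
#' intensity chosen to minimise the expected squared error (the
#' Schafer-Strimmer analytic formula; variances are kept as sampled). The
#' result is a sparse, well-conditioned noise covariance suitable for
#' inverting at pattern sizes comparable to the number of time points.
#'
#' @param residuals Time points x voxels matrix of noise residuals.
#' @param lambda Optional fixed shrinkage intensity in `[0, 1]`; `NULL`
#'   (default) uses the analytic estimate.
#' @return List: `sigma` (voxel x voxel shrunk covariance), `lambda` used.
#' @export
shrink_cov <- function(residuals, lambda = NULL) {
  X <- as.matrix(residuals)
  n <- nrow(X)
  if (n < 4) abort("Need >= 4 time points to estimate the noise covariance.")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / (n - 1)
  sds <- sqrt(diag(S))
  sds[sds == 0] <- 1
  R <- S / tcrossprod(sds)
  if (is.null(lambda)) {
    # analytic intensity: sum of sampling variances of the off-diagonal
    # correlations over the sum of their squares
    Z <- scale(X, center = TRUE, scale = TRUE)
    Z[is.na(Z)] <- 0
    w_bar <- crossprod(Z) / n
    w_ss <- crossprod(Z^2) # sum_k (z_ki z_kj)^2
    var_r <- (n / (n - 1)^3) * (w_ss - n * w_bar^2)
    r_hat <- (n / (n - 1)) * w_bar
    num <- sum(var_r[upper.tri(var_r)])
    den <- sum(r_hat[upper.tri(r_hat)]^2)
    lambda <- if (den <= 0) 1 else min(1, max(0, num / den))
  }
  R_shrunk <- (1 - lambda) * R
  diag(R_shrunk) <- 1
  sigma <- R_shrunk * tcrossprod(sds)
  list(sigma = sigma, lambda = lambda)
}

#' Cross-validated linear discriminant contrast (LDC)
#'
#' For each leave-one-run-out fold: the near-minus-far mean pattern difference
#' on the training runs is whitened by the inverse of the shrinkage noise
#' covariance of the training runs' GLM residuals to give a weights vector
#' `w = solve(Sigma, delta_train)`; the fold's LDC is the dot product of the
#' held-out run's near-minus-far difference with `w`. The statistic is the
#' cross-validated (squared) Mahalanobis contrast distance: because the two
#' difference estimates come from independent data, it is unbiased and centred
#' on zero when there is no reliable near/far difference.
#'
#' @param patterns A `block_patterns` object for one (area, layer, stereo)
#'   cell.
#' @param glm The [fit_glm()] result whose residuals estimate the noise
#'   covariance (must cover the patterns' voxels); residuals are restricted
#'   to the training runs of each fold.
#' @param lambda Optional fixed shrinkage intensity (see [shrink_cov()]).
#' @return An `ldc_result`: `ldc` (mean over folds), `folds` tibble (`run`,
#'   `ldc`, `lambda`), `n_voxels`.
#' @export
ldc_crossvalidated <- function(patterns, glm, lambda = NULL) {
  stopifnot(inherits(patterns, "block_patterns"), inherits(glm, "laminar_glm"))
  vox_idx <- match(patterns$voxels$voxel_id, glm$voxels$voxel_id)
  if (anyNA(vox_idx)) abort("GLM residuals do not cover the patterns' voxels.")
  blocks <- patterns$blocks
  runs <- sort(unique(blocks$run))
  if (length(runs) < 2) abort("Need >= 2 runs.")
  n_tr <- glm$n_tr_per_run
  resid <- glm$residuals[vox_idx, , drop = FALSE]
  fold_ldc <- numeric(length(runs))
  fold_lambda <- numeric(length(runs))
  for (fi in seq_along(runs)) {
    r <- runs[fi]
    train <- blocks$run != r
    delta_train <- colMeans(patterns$responses[train & blocks$disparity == "near", , drop = FALSE]) -
      colMeans(patterns$responses[train & blocks$disparity == "far", , drop = FALSE])
    delta_test <- colMeans(patterns$responses[!train & blocks$disparity == "near", , drop = FALSE]) -
      colMeans(patterns$responses[!train & blocks$disparity == "far", , drop = FALSE])
    train_trs <- which(rep(runs, each = n_tr) != r)
    sc <- shrink_cov(t(resid[, train_trs, drop = FALSE]), lambda = lambda)
    w <- tryCatch(solve(sc$sigma, delta_train), error = function(e) {
      abort(sprintf("Noise covariance singular after shrinkage (condition number %.3g).",
                    kappa(sc$sigma)))
    })
    fold_ldc[fi] <- sum(delta_test * w)
    fold_lambda[fi] <- sc$lambda
  }
  structure(
    list(ldc = mean(fold_ldc),
         folds = tibble(run = runs, ldc = fold_ldc, lambda = fold_lambda),
         n_voxels = ncol(patterns$responses),
         area = patterns$area,
         layer = if ("layer" %in% names(patterns$voxels)) {
           as.character(patterns$voxels$layer[1])
         } else NA_character_),
    class = "ldc_result"
  )
}

#' @export
print.ldc_result <- function(x, ...) {
  cat(sprintf("<ldc_result> LDC %.4f over %d folds (%d voxels)\n",
              x$ldc, nrow(x$folds), x$n_voxels))
  invisible(x)
}

#' Tidy an LDC result
#' @param x An `ldc_result`.
#' @param ... Unused.
#' @return The per-fold tibble.
#' @export
tidy.ldc_result <- function(x, ...) x$folds

#' One-line summary of an LDC result
#' @param x An `ldc_result`.
#' @param ... Unused.
#' @return One-row tibble: `ldc`, `n_folds`, `n_voxels`.
#' @export
glance.ldc_result <- function(x, ...) {
  tibble(ldc = x$ldc, n_folds = nrow(x$folds), n_voxels = x$n_voxels)
}

#' Assemble LDC results into a long analysis table
#'
#' @param results Tibble with columns `area`, `layer`, `stereo` and a
#'   list-column `fit` of `ldc_result`s, or a pre-summarised tibble with an
#'   `ldc` column.
#' @param areas,layers,stereo_levels Expected factor levels; the full
#'   factorial must be present.
#' @return Long tibble keyed by (`area`, `layer`, `stereo`) with `ldc`.
#' @export
ldc_table <- function(results,
                      areas = c("A1", "A3A", "A7"),
                      layers = c("deeper", "middle", "superficial"),
                      stereo_levels = c("correlated", "anticorrelated")) {
  tab <- as_tibble(results)
  if ("fit" %in% names(tab) && !("ldc" %in% names(tab))) {
    tab$ldc <- vapply(tab$fit, function(f) f$ldc, numeric(1))
    tab$fit <- NULL
  }
  need <- tidyr::expand_grid(area = areas, layer = layers, stereo = stereo_levels)
  missing <- dplyr::anti_join(need, tab, by = c("area", "layer", "stereo"))
  if (nrow(missing) > 0) {
    abort(paste0("Missing LDC cells: ",
                 paste(paste(missing$area, missing$layer, missing$stereo),
                       collapse = "; ")))
  }
  dplyr::inner_join(need, tab, by = c("area", "layer", "stereo"))
}
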