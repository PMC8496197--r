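#' Repeated-measures ANOVA with sphericity handling
#'
#' Within-subject ANOVA for up to three fully crossed within-subject factors
#' on a complete balanced subject x cell table. Sums of squares come from the
#' classical subject-by-effect partitioning (via [stats::aov()] error strata).
#' For every effect with more than one numerator df, the Greenhouse-Geisser
#' epsilon is computed from the covariance of the orthonormalised effect
#' contrasts, and Mauchly's W tests sphericity. Degrees of freedom and the
#' p-value are Greenhouse-Geisser-corrected when `epsilon < gg_threshold`
#' (default 0.75); both corrected and uncorrected values are always reported.
#' Two-level effects have epsilon 1 by definition and skip Mauchly.
#'
#' @param data Data frame with one row per subject x cell.
#' @param dv Name of the response column (string).
#' @param subject Name of the subject id column (string).
#' @param within Character vector (length 1-3) of within-subject factor
#'   columns.
#' @param gg_threshold Apply the Greenhouse-Geisser correction when epsilon
#'   falls below this value.
#' @return An `rm_anova_result`; `tidy()` returns the effects table with
#'   columns `effect`, `df1`, `df2`, `statistic` (F), `p.value`, `epsilon`,
#'   `mauchly_w`, `mauchly_p`, `df1_gg`, `df2_gg`, `p_gg`, `gg_applied`,
#'   `p_reported`.
#' @export
rm_anova <- function(data, dv, subject, within, gg_threshold = 0.75) {
  data <- as.data.frame(data)
  if (!all(c(dv, subject, within) %in% names(data))) {
    abort("`dv`, `subject` and `within` must name columns of `data`.")
  }
  if (length(within) < 1 || length(within) > 3) {
    abort("Between one and three within-subject factors are supported.")
  }
  d <- data.frame(
    y = as.numeric(data[[dv]]),
    subject = factor(data[[subject]])
  )
  for (f in within) d[[f]] <- factor(data[[f]])
  n_subj <- nlevels(d$subject)
  if (n_subj < 3) abort("Need >= 3 subjects.")
  levs <- lapply(within, function(f) levels(d[[f]]))
  names(levs) <- within
  cells <- do.call(tidyr::expand_grid, levs)
  # completeness / balance check: one observation per subject x cell
  tab <- d |> dplyr::count(dplyr::across(dplyr::all_of(c("subject", within))))
  if (nrow(tab) != n_subj * nrow(cells) || any(tab$n != 1)) {
    full <- tidyr::expand_grid(subject = levels(d$subject), cells)
    have <- d[, c("subject", within)]
    have$subject <- as.character(have$subject)
    for (f in within) have[[f]] <- as.character(have[[f]])
    miss <- dplyr::anti_join(full, have, by = c("subject", within))
    abort(paste0("Design is not complete/balanced; missing or duplicated cells",
                 if (nrow(miss) > 0) paste0(": ", paste(utils::head(
                   do.call(paste, miss), 5), collapse = "; ")) else "."))
  }

  rhs <- paste(within, collapse = " * ")
  form <- stats::as.formula(
    sprintf("y ~ %s + Error(subject/(%s))", rhs, rhs))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)

  # wide subject x cell matrix, cells ordered first-factor-slowest
  key <- do.call(paste, c(lapply(within, function(f) as.character(d[[f]])), sep = "."))
  cell_key <- do.call(paste, c(lapply(cells, as.character), sep = "."))
  Y <- matrix(NA_real_, n_subj, nrow(cells),
              dimnames = list(levels(d$subject), cell_key))
  Y[cbind(match(as.character(d$subject), levels(d$subject)), match(key, cell_key))] <- d$y

  effect_contrast <- function(effect_factors) {
    M <- matrix(1, 1, 1)
    for (f in within) {
      L <- length(levs[[f]])
      Mf <- if (f %in% effect_factors) {
        stats::contr.poly(L)
      } else {
        matrix(rep(1 / sqrt(L), L), ncol = 1)
      }
      M <- kronecker(M, Mf)
    }
    M
  }

  rows <- list()
  for (stratum in names(sm)) {
    df_tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(df_tab))
    for (i in which(rn != "Residuals")) {
      eff <- rn[i]
      eff_factors <- strsplit(eff, ":", fixed = TRUE)[[1]]
      ri <- which(rn == "Residuals")
      F_val <- df_tab[i, "F value"]
      df1 <- df_tab[i, "Df"]
      df2 <- df_tab[ri, "Df"]
      p_val <- df_tab[i, "Pr(>F)"]
      q <- prod(vapply(eff_factors, function(f) length(levs[[f]]) - 1L, integer(1)))
      if (q > 1) {
        M <- effect_contrast(eff_factors)
        Z <- Y %*% M
        S <- stats::cov(Z)
        eps <- sum(diag(S))^2 / (q * sum(S^2))
        W <- det(S) / (mean(diag(S)))^q
        dW <- 1 - (2 * q^2 + q + 2) / (6 * q * (n_subj - 1))
        chi2 <- -(n_subj - 1) * dW * log(max(W, .Machine$double.xmin))
        mauchly_p <- pchisq(chi2, df = q * (q + 1) / 2 - 1, lower.tail = FALSE)
      } else {
        eps <- 1
        W <- NA_real_
        mauchly_p <- NA_real_
      }
      p_gg <- pf(F_val, df1 * eps, df2 * eps, lower.tail = FALSE)
      gg_applied <- is.finite(eps) && eps < gg_threshold && q > 1
      rows[[length(rows) + 1]] <- tibble(
        effect = eff, df1 = df1, df2 = df2, statistic = F_val, p.value = p_val,
        epsilon = eps, mauchly_w = W, mauchly_p = mauchly_p,
        df1_gg = df1 * eps, df2_gg = df2 * eps, p_gg = p_gg,
        gg_applied = gg_applied,
        p_reported = if (gg_applied) p_gg else p_val
      )
    }
  }
  structure(
    list(effects = dplyr::bind_rows(rows), n_subjects = n_subj,
         within = within, dv = dv, gg_threshold = gg_threshold),
    class = "rm_anova_result"
  )
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("<rm_anova_result> %s over %s (n = %d subjects)\n",
              x$dv, paste(x$within, collapse = " x "), x$n_subjects))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-28s F(%.3g, %.3g) = %.3f, p = %.4f%s\n",
                eff$effect[i],
                if (eff$gg_applied[i]) eff$df1_gg[i] else eff$df1[i],
                if (eff$gg_applied[i]) eff$df2_gg[i] else eff$df2[i],
                eff$statistic[i], eff$p_reported[i],
                if (eff$gg_applied[i]) sprintf(" (GG, eps = %.3f)", eff$epsilon[i]) else ""))
  }
  invisible(x)
}

#' Tidy a repeated-measures ANOVA
#' @param x An `rm_anova_result`.
#' @param ... Unused.
#' @return The effects tibble.
#' @export
tidy.rm_anova_result <- function(x, ...) x$effects

#' One-line summary of a repeated-measures ANOVA
#' @param x An `rm_anova_result`.
#' @param ... Unused.
#' @return One-row tibble: `n_subjects`, `n_effects`, `gg_threshold`.
#' @export
glance.rm_anova_result <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_effects = nrow(x$effects),
         gg_threshold = x$gg_threshold)
}

#' Paired t-test on per-subject values
#'
#' @param a,b Numeric vectors of equal length (>= 2), paired by subject.
#' @return One-row tibble: `statistic` (t), `df`, `p.value`, `mean_diff`;
#'   a zero-variance difference yields `NA` statistics with a `reason`
#'   column.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 2) abort("Need >= 2 pairs.")
  diffs <- a - b
  if (sd(diffs) == 0) {
    if (all(diffs == 0)) {
      # identical vectors: no effect, by convention t = 0, p = 1
      return(tibble(statistic = 0, df = length(a) - 1, p.value = 1, mean_diff = 0))
    }
    return(tibble(statistic = NA_real_, df = length(a) - 1, p.value = NA_real_,
                  mean_diff = mean(diffs),
                  reason = "zero-variance differences: t undefined"))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, mean_diff = mean(diffs))
}

#' Cousineau-Morey within-subject SEM
#'
#' Normalises each observation by removing the subject mean and adding back
#' the grand mean, then computes the per-condition SEM of the normalised
#' values multiplied by the Morey bias correction `sqrt(C / (C - 1))` for `C`
#' conditions. The result is the within-subject error bar appropriate for
#' repeated-measures designs: it reflects condition differences, not stable
#' between-subject offsets.
#'
#' @param data Data frame with one row per subject x condition.
#' @param subject,condition,value Column names (strings).
#' @return Tibble: `condition`, `mean`, `sem`.
#' @export
cousineau_morey_sem <- function(data, subject = "subject",
                                condition = "condition", value = "value") {
  d <- as.data.frame(data)
  if (!all(c(subject, condition, value) %in% names(d))) {
    abort("`subject`, `condition` and `value` must name columns of `data`.")
  }
  d <- tibble(subject = factor(d[[subject]]), condition = factor(d[[condition]]),
              value = as.numeric(d[[value]]))
  C <- nlevels(d$condition)
  n <- nlevels(d$subject)
  if (C < 2) abort("Need >= 2 conditions.")
  if (n < 2) abort("Need >= 2 subjects.")
  if (nrow(d) != C * n || nrow(dplyr::distinct(d, .data$subject, .data$condition)) != C * n) {
    abort("Incomplete subject x condition table.")
  }
  grand <- mean(d$value)
  d <- d |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(norm = .data$value - mean(.data$value) + grand) |>
    dplyr::ungroup()
  d |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = sd(.data$norm) / sqrt(.env$n) * sqrt(.env$C / (.env$C - 1)),
      .groups = "drop"
    )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_bh <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  stats::p.adjust(pvals, method = "BH")
}
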