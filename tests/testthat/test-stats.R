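test_that("a 2-level factor gives F = t^2 and epsilon = 1", {
  set.seed(1)
  tab <- balanced_table(8, list(cond = c("a", "b")), seed = 1)
  fit <- rm_anova(tab, dv = "y", subject = "subject", within = "cond")
  eff <- tidy(fit)
  a <- tab$y[tab$cond == "a"][order(tab$subject[tab$cond == "a"])]
  b <- tab$y[tab$cond == "b"][order(tab$subject[tab$cond == "b"])]
  tt <- paired_t(a, b)
  expect_equal(eff$statistic, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(eff$p.value, tt$p.value, tolerance = 1e-10)
  expect_equal(eff$epsilon, 1)
  expect_true(is.na(eff$mauchly_w))
})

test_that("F, df and epsilon match the brute-force oracle on random balanced designs", {
  levs2 <- list(stereo = c("c", "a"), layer = c("d", "m", "s"))
  for (seed in 1:6) {
    tab <- balanced_table(6, levs2, seed = seed)
    fit <- rm_anova(tab, dv = "y", subject = "subject",
                    within = c("stereo", "layer"))
    Y <- wide_matrix(tab, levs2)
    for (eff_name in c("stereo", "layer", "stereo:layer")) {
      eff <- tidy(fit)[tidy(fit)$effect == eff_name, ]
      or <- oracle_effect(Y, levs2, strsplit(eff_name, ":")[[1]])
      expect_equal(eff$statistic, or$F, tolerance = 1e-8)
      expect_equal(eff$df1, or$df1)
      expect_equal(eff$df2, or$df2)
      expect_equal(eff$epsilon, or$eps, tolerance = 1e-8)
      expect_gte(or$eps + 1e-12, 1 / or$df1)
      expect_lte(or$eps - 1e-12, 1)
    }
  }
  # three-way design, one draw
  levs3 <- list(A = c("1", "2"), B = c("x", "y", "z"), C = c("p", "q", "r"))
  tab3 <- balanced_table(5, levs3, seed = 7)
  fit3 <- rm_anova(tab3, dv = "y", subject = "subject", within = c("A", "B", "C"))
  Y3 <- wide_matrix(tab3, levs3)
  for (eff_name in c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C")) {
    eff <- tidy(fit3)[tidy(fit3)$effect == eff_name, ]
    or <- oracle_effect(Y3, levs3, strsplit(eff_name, ":")[[1]])
    expect_equal(eff$statistic, or$F, tolerance = 1e-8)
    expect_equal(eff$epsilon, or$eps, tolerance = 1e-8)
  }
})

test_that("Mauchly's test matches the base-R multivariate implementation", {
  levs <- list(layer = c("d", "m", "s"))
  tab <- balanced_table(10, levs, seed = 3)
  fit <- rm_anova(tab, dv = "y", subject = "subject", within = "layer")
  Y <- wide_matrix(tab, levs)
  mlm <- stats::lm(Y ~ 1)
  ref <- stats::mauchly.test(mlm, X = ~1,
                             idata = data.frame(layer = factor(c("d", "m", "s"))))
  eff <- tidy(fit)
  expect_equal(eff$mauchly_w, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(eff$mauchly_p, ref$p.value, tolerance = 1e-6)
})

test_that("Greenhouse-Geisser correction is applied exactly when epsilon < 0.75", {
  # strongly non-spherical data: one contrast carries almost all variance
  set.seed(4)
  n <- 9
  base <- rnorm(n, sd = 3)
  tab <- tidyr::expand_grid(subject = paste0("s", 1:n),
                            cond = c("c1", "c2", "c3", "c4"))
  tab$y <- rnorm(nrow(tab), sd = 0.05)
  tab$y[tab$cond == "c1"] <- tab$y[tab$cond == "c1"] + base
  tab$y[tab$cond == "c2"] <- tab$y[tab$cond == "c2"] - base
  fit <- rm_anova(tab, dv = "y", subject = "subject", within = "cond")
  eff <- tidy(fit)
  expect_lt(eff$epsilon, 0.75)
  expect_true(eff$gg_applied)
  expect_equal(eff$df1_gg, eff$df1 * eff$epsilon)
  expect_equal(eff$p_reported,
               pf(eff$statistic, eff$df1 * eff$epsilon, eff$df2 * eff$epsilon,
                  lower.tail = FALSE))
  # spherical data: no correction
  tab2 <- balanced_table(9, list(cond = c("c1", "c2", "c3")), seed = 5)
  eff2 <- tidy(rm_anova(tab2, dv = "y", subject = "subject", within = "cond"))
  if (eff2$epsilon >= 0.75) expect_false(eff2$gg_applied)
})

test_that("incomplete designs are rejected with the missing cells named", {
  tab <- balanced_table(4, list(cond = c("a", "b", "c")), seed = 6)
  expect_error(rm_anova(tab[-1, ], dv = "y", subject = "subject", within = "cond"),
               "complete")
  expect_error(rm_anova(tab[tab$subject %in% c("s1", "s2"), ], dv = "y",
                        subject = "subject", within = "cond"), "subjects")
})

test_that("paired t matches the direct formula and handles degenerate input", {
  set.seed(7)
  a <- rnorm(7); b <- rnorm(7)
  res <- paired_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(7))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 6)
  expect_equal(res$p.value, 2 * pt(-abs(t_hand), 6), tolerance = 1e-12)
  same <- paired_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  const <- paired_t(a, a + 2)
  expect_true(is.na(const$statistic))
  expect_match(const$reason, "zero-variance")
})

test_that("Cousineau-Morey SEM matches the pencil-and-paper fixture", {
  tab <- tibble::tibble(subject = c("s1", "s1", "s2", "s2"),
                        condition = c("c1", "c2", "c1", "c2"),
                        value = c(1, 3, 2, 4))
  out <- cousineau_morey_sem(tab)
  # normalised rows are identical (1.5, 3.5): SEM exactly 0 in both conditions
  expect_equal(out$sem, c(0, 0))
  expect_equal(out$mean, c(1.5, 3.5))
  # subject offsets never change the SEM
  set.seed(8)
  tab2 <- tidyr::expand_grid(subject = paste0("s", 1:6), condition = c("a", "b", "c"))
  tab2$value <- rnorm(nrow(tab2))
  tab3 <- tab2
  tab3$value <- tab3$value + rep(rnorm(6) * 10, each = 3)
  expect_equal(cousineau_morey_sem(tab2)$sem, cousineau_morey_sem(tab3)$sem,
               tolerance = 1e-12)
  # hand computation on the random table
  C <- 3; n <- 6
  norm <- tab2 |>
    dplyr::group_by(subject) |>
    dplyr::mutate(norm = value - mean(value) + mean(tab2$value)) |>
    dplyr::ungroup()
  hand <- tapply(norm$norm, norm$condition, sd) / sqrt(n) * sqrt(C / (C - 1))
  expect_equal(cousineau_morey_sem(tab2)$sem, as.numeric(hand), tolerance = 1e-12)
  expect_error(cousineau_morey_sem(tab[-1, ]), "Incomplete")
})

test_that("Benjamini-Hochberg adjustment matches the step-up formula", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(fdr_bh(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # hand step-up: p_(i) * m / i, cumulative minimum from the largest rank
  m <- length(p)
  hand <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p)]
  expect_equal(fdr_bh(p), hand)
  # order preservation: adjustment is monotone in the raw p-values
  expect_true(all(diff(fdr_bh(p)[order(p)]) >= 0))
  expect_true(all(fdr_bh(p) >= p))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})
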