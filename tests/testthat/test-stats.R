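test_that("one-way ANOVA matches the F = t^2 identity and degenerates safely", {
  x <- c(4.1, 5.2, 6.3, 5.0, 4.4)
  y <- c(6.8, 7.1, 5.9, 7.4, 6.5)
  an <- one_way_anova(c(x, y), rep(c("a", "b"), each = 5))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(an$table$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$table$p[1], tt$p.value, tolerance = 1e-10)
  # identical groups: F = 0, p = 1
  an0 <- one_way_anova(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(an0$table$F[1], 0)
  expect_equal(an0$table$p[1], 1)
  # all values identical: flagged degenerate convention
  and <- one_way_anova(rep(5, 8), rep(c("a", "b"), each = 4))
  expect_equal(and$table$p[1], 1)
  expect_true("zero_variance" %in% and$flags)
  expect_error(one_way_anova(1:3, c("a", "a", "b")), ">= 2 observations")
})

test_that("Dunnett reduces to a t-test for one comparison and adjusts upward", {
  set.seed(12)
  v <- c(rnorm(8, 0), rnorm(8, 1))
  g <- rep(c("0", "2"), each = 8)
  d <- dunnett(v, g, control = "0", seed = 5)
  tt <- t.test(v[g == "2"], v[g == "0"], var.equal = TRUE)
  expect_equal(d$comparisons$p_adj[1], tt$p.value, tolerance = 1e-4)
  # many-to-one: adjusted p never below raw p
  v4 <- c(rnorm(6, 0), rnorm(6, 0.5), rnorm(6, 1), rnorm(6, 0.2))
  g4 <- rep(c("0", "1", "2", "3"), each = 6)
  d4 <- dunnett(v4, g4, control = "0", seed = 5)
  expect_equal(nrow(d4$comparisons), 3)
  expect_true(all(d4$comparisons$p_adj >= d4$comparisons$p_raw - 1e-12))
  expect_true(all(d4$comparisons$p_adj >= 0 & d4$comparisons$p_adj <= 1))
  expect_error(dunnett(v, g, control = "9"), "control")
  # gating flag when the omnibus was not significant
  expect_true(dunnett(v, g, control = "0", omnibus_p = 0.4)$gated)
})

test_that("factorial ANOVA uses Type II and reduces to the classical cases", {
  set.seed(3)
  f1 <- rep(c("lo", "hi"), each = 12)
  f2 <- rep(rep(c("s", "m", "l"), each = 4), 2)
  v <- rnorm(24) + (f1 == "hi") * 1 + (f2 == "l") * 0.5
  fa <- factorial_anova(v, data.frame(voltage = f1, size = f2))
  # balanced design: Type II equals the sequential (Type I) decomposition
  seq_an <- anova(lm(v ~ factor(f1) * factor(f2)))
  expect_equal(fa$table$ss, seq_an$`Sum Sq`[1:3], tolerance = 1e-10)
  expect_equal(fa$table$p, seq_an$`Pr(>F)`[1:3], tolerance = 1e-10)
  # single factor reduces to one-way ANOVA
  f_one <- factorial_anova(v, data.frame(voltage = f1))
  ow <- one_way_anova(v, f1)
  expect_equal(f_one$table$F[1], ow$table$F[1], tolerance = 1e-10)
  expect_equal(f_one$table$p[1], ow$table$p[1], tolerance = 1e-10)
  # empty cells are named in the error
  bad <- data.frame(voltage = c("lo", "lo", "hi", "hi"),
                    size = c("s", "s", "m", "m"))
  expect_error(factorial_anova(rnorm(4), bad), "empty design cells")
})

test_that("factorial ANOVA detects a programmed interaction but not an additive one", {
  set.seed(21)
  n_cell <- 10
  f1 <- rep(c("v0", "v2"), each = 2 * n_cell)
  f2 <- rep(rep(c("small", "large"), each = n_cell), 2)
  sigma <- 0.5
  additive <- rnorm(4 * n_cell, 0, sigma) + (f1 == "v2") * 1 +
    (f2 == "large") * 0.5
  fa_add <- factorial_anova(additive, data.frame(v = f1, s = f2))
  inter <- rnorm(4 * n_cell, 0, sigma) +
    (f1 == "v2") * (f2 == "large") * 2 * sigma * 2
  fa_int <- factorial_anova(inter, data.frame(v = f1, s = f2))
  expect_lt(fa_int$table$p[fa_int$table$term == "v:s"], 0.01)
  expect_gt(fa_add$table$p[fa_add$table$term == "v:s"], 0.01)
})

test_that("Tukey contrasts collapse to a t-test for two cells and respect bounds", {
  set.seed(31)
  v <- c(rnorm(7, 0), rnorm(7, 0.8))
  cells <- rep(c("a", "b"), each = 7)
  tk <- tukey(v, cells)
  tt <- t.test(v[cells == "b"], v[cells == "a"], var.equal = TRUE)
  expect_equal(tk$comparisons$p_adj[1], tt$p.value, tolerance = 1e-8)
  # equal cell means: adjusted p near 1
  v0 <- rep(c(1, 2, 3, 4), 3)
  tk0 <- tukey(v0, rep(c("a", "b", "c"), each = 4))
  expect_true(all(tk0$comparisons$p_adj > 0.95))
  # restricting to named pairs subsets the table; unknown labels error
  v6 <- rnorm(18)
  c6 <- rep(c("a", "b", "c"), each = 6)
  sub <- tukey(v6, c6, pairs = cbind("a", "b"))
  expect_equal(nrow(sub$comparisons), 1)
  expect_error(tukey(v6, c6, pairs = cbind("a", "z")), "unknown cell")
})

test_that("repeated measures detects a within-by-between interaction", {
  set.seed(44)
  n <- 10; days <- 3
  subj <- rep(sprintf("s%02d", 1:(2 * n)), each = days)
  grp <- rep(rep(c("g1", "g2"), each = n), each = days)
  day <- rep(paste0("d", 1:days), 2 * n)
  # group 2 recovers at day 3: a pure within-by-between interaction
  mu <- ifelse(grp == "g2" & day == "d3", 1.2, 0)
  v <- mu + rep(rnorm(2 * n, 0, 0.3), each = days) + rnorm(2 * n * days, 0, 0.3)
  rm <- repeated_measures(v, subj, day, grp)
  expect_lt(rm$table$p[rm$table$term == "within:between"], 0.05)
  # interaction SS matches the factorial decomposition (balanced design)
  fa <- factorial_anova(v, data.frame(between = grp, within = day))
  expect_equal(rm$table$ss[rm$table$term == "within:between"],
               fa$table$ss[fa$table$term == "between:within"],
               tolerance = 1e-8)
  # identical values: p = 1 convention
  rm0 <- repeated_measures(rep(2, 12), rep(1:4, each = 3),
                           rep(c("a", "b", "c"), 4), rep(c("x", "y"), each = 6))
  expect_true(all(rm0$table$p == 1))
  expect_error(repeated_measures(v[-1], subj[-1], day[-1], grp[-1]),
               "every within level")
})

test_that("Bonferroni-adjusted paired t-tests use alpha/m", {
  p6 <- paired_t_bonferroni(list(a = list(x = c(1, 2, 3, 4.5),
                                          y = c(2, 3, 4, 5))), m = 6)
  expect_equal(p6$adjusted_alpha, 0.008)
  p1 <- paired_t_bonferroni(list(list(x = rnorm(5), y = rnorm(5))), m = 1)
  expect_equal(p1$adjusted_alpha, 0.05)
  # identical paired vectors: degenerate, not significant
  same <- paired_t_bonferroni(list(list(x = 1:5, y = 1:5)), m = 2)
  expect_equal(same$comparisons$p_raw[1], 1)
  expect_false(same$comparisons$significant[1])
  expect_true(all(same$comparisons$p_adj >= same$comparisons$p_raw))
  expect_error(paired_t_bonferroni(list(list(x = 1:4, y = 1:5))), "unequal")
})

test_that("assumption checks flag heteroscedastic but not homoscedastic data", {
  set.seed(55)
  n <- 200
  x <- runif(n, 1, 5)
  # variance proportional to the predictor
  y_het <- 2 + x + rnorm(n, 0, 0.5 * x)
  ch_het <- assumption_checks(lm(y_het ~ x))
  expect_lt(ch_het$heteroscedasticity_p, 0.01)
  y_hom <- 2 + x + rnorm(n, 0, 0.8)
  ch_hom <- assumption_checks(lm(y_hom ~ x))
  expect_gt(ch_hom$heteroscedasticity_p, 0.01)
  expect_gt(ch_hom$normality_p, 0.001)
  # constant residuals: degenerate
  ch_deg <- assumption_checks(lm(rep(3, 10) ~ rep(c(1, 2), 5)))
  expect_true("degenerate" %in% ch_deg$flags)
  expect_true(is.na(ch_deg$normality_p))
})

test_that("randomization p-values respect the add-one bound and track parametric p", {
  set.seed(66)
  v <- c(rnorm(6), rnorm(6, 2))
  g <- rep(c("a", "b"), each = 6)
  p <- randomization_anova(v, g, n_perm = 199, seed = 3)
  expect_gte(p[[1]], 1 / 200)
  # calibration: permutation p correlates with parametric p under the null
  p_perm <- p_par <- numeric(60)
  for (r in 1:60) {
    vv <- rnorm(18)
    gg <- rep(c("a", "b", "c"), each = 6)
    p_perm[r] <- randomization_anova(vv, gg, n_perm = 499, seed = r)[[1]]
    p_par[r] <- one_way_anova(vv, gg)$table$p[1]
  }
  expect_gt(cor(p_perm, p_par), 0.95)
})

test_that("Freedman-Lane interaction permutation agrees with the parametric test on clear effects", {
  set.seed(77)
  f1 <- rep(c("v0", "v2"), each = 16)
  f2 <- rep(rep(c("s", "l"), each = 8), 2)
  v <- rnorm(32, 0, 0.4) + (f1 == "v2") * (f2 == "l") * 1.5
  ps <- randomization_anova(v, data.frame(v = f1, s = f2),
                            n_perm = 499, seed = 8)
  expect_lt(ps[["v:s"]], 0.02)
  v_null <- rnorm(32, 0, 0.4) + (f1 == "v2") * 0.5
  ps0 <- randomization_anova(v_null, data.frame(v = f1, s = f2),
                             n_perm = 499, seed = 9)
  expect_gt(ps0[["v:s"]], 0.05)
})

test_that("the full synthetic pipeline reproduces the size-dependence analysis skeleton", {
  # large worms electrotax at 2 V; head-fragment worms do not at either
  # voltage: the voltage-by-type interaction must be significant and
  # Tukey contrasts significant only within the large-worm level
  arena <- default_arena()
  design <- list()
  for (v in c(0, 2)) for (ty in c("large", "headfrag")) {
    bias <- if (v == 2 && ty == "large") 0.7 else 0
    design[[length(design) + 1]] <- list(
      n = 8, params = quick_worm(bias = bias),
      config = swap_config(duration_s = 60, voltage_V = v),
      label = paste0("v", v, "_", ty))
  }
  coh <- generate_cohort(design, arena, seed = 424)
  tab <- score_cohort(coh)
  tab$voltage <- sub("_.*", "", tab$label)
  tab$type <- sub(".*_", "", tab$label)
  fa <- factorial_anova(tab$f_mov_1, tab[, c("voltage", "type")])
  expect_lt(fa$table$p[fa$table$term == "voltage:type"], 0.01)
  cells <- interaction(tab$voltage, tab$type)
  tk <- tukey(tab$f_mov_1, cells,
              pairs = rbind(c("v0.large", "v2.large"),
                            c("v0.headfrag", "v2.headfrag")))
  p_large <- tk$comparisons$p_adj[grepl("large", tk$comparisons$comparison)]
  p_frag <- tk$comparisons$p_adj[grepl("headfrag", tk$comparisons$comparison)]
  expect_lt(p_large, 0.01)
  expect_gt(p_frag, 0.05)
})
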