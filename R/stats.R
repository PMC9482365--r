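#' Statistical battery for electrotaxis score tables
#'
#' Wrappers around the standard linear-model machinery, shaped for the
#' assay's analyses: one-way ANOVA over voltage levels with Dunnett
#' follow-ups against the 0 V control, factorial ANOVA (Type-II sums of
#' squares) with Tukey-adjusted cell contrasts, repeated-measures models
#' for successive-treatment designs, Bonferroni-adjusted paired t-tests,
#' normality/heteroscedasticity checks, and randomization tests used to
#' confirm parametric conclusions when proportions violate assumptions.
#'
#' Post hoc procedures are meant to follow a significant omnibus test;
#' when the caller supplies a non-significant omnibus p they still
#' compute, but the result is flagged (`gated = TRUE`).
#'
#' @name electrotaxis-statistics
NULL

anova_result <- function(table, residual_df, flags = character(),
                         checks = NULL, perm_p = NULL) {
  structure(list(table = table, residual_df = residual_df,
                 flags = flags, checks = checks, perm_p = perm_p),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  print(x$table)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

zero_variance <- function(values) stats::var(values) < .Machine$double.eps

#' One-way ANOVA
#'
#' Classical between/within decomposition with an F test. Degenerate
#' inputs in which every observation is identical return `p = 1` with a
#' `"zero_variance"` flag rather than failing, so synthetic edge cases
#' pass through pipelines.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor (>= 2 levels, >= 2 observations each).
#' @return An `anova_result` with per-term sum of squares, df, F and p.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 observations")
  if (zero_variance(values)) {
    tab <- data.frame(term = "groups", ss = 0, df = nlevels(groups) - 1L,
                      F = 0, p = 1)
    return(anova_result(tab, length(values) - nlevels(groups),
                        flags = "zero_variance"))
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tab <- data.frame(term = c("groups", "residual"),
                    ss = an[["Sum Sq"]], df = an[["Df"]],
                    F = c(an[["F value"]][1], NA),
                    p = c(an[["Pr(>F)"]][1], NA))
  anova_result(tab, an[["Df"]][2])
}

posthoc_result <- function(comparisons, method, gated = FALSE) {
  structure(list(comparisons = comparisons, method = method,
                 gated = gated),
            class = "posthoc_result")
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat("post hoc method:", x$method,
      if (x$gated) "(omnibus not significant - interpret with caution)",
      "\n")
  print(x$comparisons)
  invisible(x)
}

#' Dunnett many-to-one comparisons against a control group
#'
#' Compares every treatment group with the named control, with
#' family-wise adjustment from the multivariate-t reference distribution
#' (computed by seeded Monte-Carlo integration, so adjusted p-values are
#' reproducible to ~0.001).
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor.
#' @param control Label of the control group (e.g. `"0"` for the 0 V
#'   control).
#' @param omnibus_p Optional omnibus ANOVA p; if `>= alpha` the result is
#'   flagged as gated.
#' @param alpha Significance level used for gating (default 0.05).
#' @param seed Seed for the multivariate-t integration.
#' @return A `posthoc_result`; `comparisons` has columns `comparison`,
#'   `estimate`, `p_raw`, `p_adj`.
#' @export
dunnett <- function(values, groups, control, omnibus_p = NA,
                    alpha = 0.05, seed = 1) {
  groups <- factor(groups)
  if (!control %in% levels(groups)) stop("control group not present")
  groups <- stats::relevel(groups, ref = control)
  dat <- data.frame(values = values, groups = groups)
  fit <- stats::aov(values ~ groups, data = dat)
  set.seed(as.integer(seed))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(groups = "Dunnett"))
  sm <- summary(gl)
  # unadjusted per-comparison p for the monotonicity contract
  raw <- summary(gl, test = multcomp::adjusted("none"))$test$pvalues
  comp <- data.frame(comparison = names(sm$test$coefficients),
                     estimate = as.numeric(sm$test$coefficients),
                     p_raw = as.numeric(raw),
                     p_adj = pmax(as.numeric(sm$test$pvalues),
                                  as.numeric(raw)),
                     stringsAsFactors = FALSE)
  posthoc_result(comp, "dunnett",
                 gated = is.finite(omnibus_p) && omnibus_p >= alpha)
}

check_full_cross <- function(factors) {
  tab <- table(factors)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    labs <- apply(empty, 1, function(i)
      paste(mapply(function(d, k) dimnames(tab)[[d]][k],
                   seq_along(i), i), collapse = ":"))
    stop("empty design cells: ", paste(labs, collapse = ", "))
  }
}

#' Factorial ANOVA with Type-II sums of squares
#'
#' Fits all main effects and interactions of the supplied factors and
#' tests them with Type-II sums of squares, which for balanced designs
#' coincide with the classical sequential decomposition and remain
#' order-invariant when the design is unbalanced.
#'
#' @param values Numeric response vector.
#' @param factors A data frame of factors (one column per design factor),
#'   fully crossed (no empty cells).
#' @return An `anova_result`; the table has one row per model term plus
#'   the residual row.
#' @export
factorial_anova <- function(values, factors) {
  factors <- as.data.frame(lapply(as.data.frame(factors), factor))
  check_full_cross(factors)
  if (zero_variance(values)) {
    full <- attr(stats::terms(
      stats::as.formula(paste("~", paste(names(factors), collapse = "*")))),
      "term.labels")
    tab <- data.frame(term = full, ss = 0,
                      df = NA_integer_, F = 0, p = 1)
    return(anova_result(tab, NA_integer_, flags = "zero_variance"))
  }
  dat <- cbind(data.frame(.y = values), factors)
  form <- stats::as.formula(paste(".y ~", paste(names(factors), collapse = "*")))
  fit <- stats::lm(form, data = dat)
  an <- car::Anova(fit, type = 2)
  rows <- rownames(an) != "Residuals"
  tab <- data.frame(term = rownames(an)[rows],
                    ss = an[rows, "Sum Sq"], df = an[rows, "Df"],
                    F = an[rows, "F value"], p = an[rows, "Pr(>F)"])
  res <- anova_result(tab, an["Residuals", "Df"])
  res$model <- fit
  res
}

#' Tukey-adjusted pairwise cell contrasts
#'
#' Pairwise differences between design cells with studentized-range
#' (Tukey HSD) family-wise adjustment, optionally restricted to a given
#' set of cell pairs (the family-wise adjustment still uses the full
#' cell count, as when contrasting 0 V against 2 V within each level of
#' another factor).
#'
#' @param values Numeric response vector.
#' @param cells Factor (or interaction of factors, e.g.
#'   `interaction(voltage, size)`) labelling the design cells.
#' @param pairs Optional character matrix/data frame with two columns of
#'   cell labels selecting the comparisons to report; `NULL` reports all
#'   pairs.
#' @param omnibus_p,alpha Omnibus gating as in [dunnett()].
#' @return A `posthoc_result` with columns `comparison`, `estimate`,
#'   `p_adj`.
#' @export
tukey <- function(values, cells, pairs = NULL, omnibus_p = NA,
                  alpha = 0.05) {
  cells <- factor(cells)
  fit <- stats::aov(values ~ cells)
  th <- stats::TukeyHSD(fit)$cells
  comp <- data.frame(comparison = rownames(th),
                     estimate = th[, "diff"], p_adj = th[, "p adj"],
                     stringsAsFactors = FALSE)
  rownames(comp) <- NULL
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    bad <- !(pairs %in% levels(cells))
    if (any(bad)) stop("unknown cell labels: ",
                       paste(unique(pairs[bad]), collapse = ", "))
    want <- c(paste(pairs[, 1], pairs[, 2], sep = "-"),
              paste(pairs[, 2], pairs[, 1], sep = "-"))
    comp <- comp[comp$comparison %in% want, , drop = FALSE]
  }
  posthoc_result(comp, "tukey",
                 gated = is.finite(omnibus_p) && omnibus_p >= alpha)
}

#' Repeated-measures ANOVA with a between-subjects factor
#'
#' Univariate repeated-measures analysis for designs in which each
#' subject is measured at every level of a within-subjects treatment and
#' subjects belong to one of several groups. Subject enters as a
#' blocking factor; the within-by-between interaction tests whether the
#' groups differ in their response to the treatment sequence.
#'
#' @param values Numeric response vector.
#' @param subject Subject identifier.
#' @param within Within-subjects treatment factor (every subject observed
#'   at every level).
#' @param between Between-subjects group factor (constant within
#'   subject).
#' @return An `anova_result` with rows for the between effect, the
#'   within effect, and the within-by-between interaction.
#' @export
repeated_measures <- function(values, subject, within, between) {
  subject <- factor(subject); within <- factor(within)
  between <- factor(between)
  full <- table(subject, within)
  if (any(full == 0)) stop("each subject must be observed at every within level")
  if (zero_variance(values)) {
    tab <- data.frame(term = c("between", "within", "within:between"),
                      ss = 0, df = NA_integer_, F = 0, p = 1)
    return(anova_result(tab, NA_integer_, flags = "zero_variance"))
  }
  dat <- data.frame(values = values, subject = subject,
                    within = within, between = between)
  fit <- stats::aov(values ~ between * within + Error(subject / within),
                    data = dat)
  sm <- summary(fit)
  btw <- sm[["Error: subject"]][[1]]
  wth <- sm[["Error: subject:within"]][[1]]
  get_row <- function(an, name) {
    i <- match(name, trimws(rownames(an)))
    c(ss = an[["Sum Sq"]][i], df = an[["Df"]][i],
      F = an[["F value"]][i], p = an[["Pr(>F)"]][i])
  }
  b <- get_row(btw, "between")
  w <- get_row(wth, "within")
  iw <- get_row(wth, "between:within")
  tab <- data.frame(term = c("between", "within", "within:between"),
                    ss = c(b["ss"], w["ss"], iw["ss"]),
                    df = c(b["df"], w["df"], iw["df"]),
                    F = c(b["F"], w["F"], iw["F"]),
                    p = c(b["p"], w["p"], iw["p"]))
  res_df <- wth[["Df"]][match("Residuals", trimws(rownames(wth)))]
  anova_result(tab, res_df)
}

#' Paired t-tests with a Bonferroni-adjusted alpha
#'
#' Two-tailed paired t-tests for a family of `m` planned comparisons;
#' significance is assessed against `alpha / m` (e.g. 0.05/6 = 0.008).
#' Identical paired vectors are degenerate and return `p = 1` with a
#' flag instead of failing.
#'
#' @param pairs A list of comparisons; each element is a list or
#'   two-column structure with numeric vectors `x` and `y` of equal
#'   length (paired observations).
#' @param m Number of comparisons in the family; defaults to
#'   `length(pairs)`.
#' @param alpha Family-wise significance level.
#' @return A `posthoc_result` whose `comparisons` table has columns
#'   `comparison`, `estimate` (mean difference), `p_raw`, `p_adj`
#'   (Bonferroni), `significant`; the adjusted alpha (rounded to 3
#'   decimals) is attached as `adjusted_alpha`.
#' @export
paired_t_bonferroni <- function(pairs, m = length(pairs), alpha = 0.05) {
  stopifnot(m >= 1, length(pairs) >= 1)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    x <- pr$x %||% pr[[1]]; y <- pr$y %||% pr[[2]]
    if (length(x) != length(y)) stop("unequal pair lengths in comparison ", i)
    nm <- if (!is.null(names(pairs)[i]) && nzchar(names(pairs)[i]))
      names(pairs)[i] else paste0("comparison", i)
    d <- x - y
    if (stats::var(d) < .Machine$double.eps) {
      data.frame(comparison = nm, estimate = mean(d), p_raw = 1,
                 flag = "zero_variance", stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      data.frame(comparison = nm, estimate = unname(tt$estimate),
                 p_raw = tt$p.value, flag = "", stringsAsFactors = FALSE)
    }
  })
  comp <- do.call(rbind, rows)
  comp$p_adj <- pmin(1, comp$p_raw * m)
  comp$significant <- comp$p_raw < alpha / m
  out <- posthoc_result(comp, "bonferroni-paired-t")
  out$adjusted_alpha <- round(alpha / m, 3)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normality and homoscedasticity checks for a fitted model
#'
#' Shapiro-Wilk on the residuals and a (studentized) Breusch-Pagan
#' Lagrange-multiplier test of the residual variance against the model's
#' predictors. Proportion-valued responses frequently violate both
#' assumptions, which is what motivates the randomization fallback in
#' [randomization_anova()].
#'
#' @param model A fitted `lm`/`aov` model.
#' @return A list with `normality_p`, `heteroscedasticity_p`, and a
#'   `flags` character vector (`"degenerate"` when residuals are
#'   constant).
#' @export
assumption_checks <- function(model) {
  res <- stats::residuals(model)
  if (length(res) < 3 || stats::var(res) < .Machine$double.eps)
    return(list(normality_p = NA_real_, heteroscedasticity_p = NA_real_,
                flags = "degenerate"))
  sw <- stats::shapiro.test(res)
  bp <- lmtest::bptest(model)
  list(normality_p = sw$p.value, heteroscedasticity_p = bp$p.value,
       flags = character())
}

# One-way ANOVA F statistic from the classical decomposition (no model
# refit; used inside permutation loops).
one_way_F <- function(values, g) {
  n <- length(values)
  k <- nlevels(g)
  gs <- rowsum(values, g)
  gn <- tabulate(g, nbins = k)
  ssb <- sum(gs^2 / gn) - sum(values)^2 / n
  sst <- sum(values^2) - sum(values)^2 / n
  ssw <- sst - ssb
  (ssb / (k - 1)) / (ssw / (n - k))
}

# F statistics of all requested terms of a Type-II fit, as a named vector
type2_F <- function(form, data) {
  fit <- stats::lm(form, data = data)
  an <- car::Anova(fit, type = 2)
  rows <- rownames(an) != "Residuals"
  stats::setNames(an[rows, "F value"], rownames(an)[rows])
}

# Freedman-Lane permutation p for one model term: permute residuals of
# the reduced model (full model without the term), add them back to the
# reduced fit, and recompute the term's F on the reconstructed response.
freedman_lane_p <- function(full_form, term, data, n_perm, seed) {
  set.seed(as.integer(seed))
  F_obs <- type2_F(full_form, data)
  if (!term %in% names(F_obs)) stop("unknown model term: ", term)
  F_obs <- F_obs[[term]]
  resp <- all.vars(full_form)[1]
  full_terms <- attr(stats::terms(full_form), "term.labels")
  red_terms <- setdiff(full_terms, term)
  red_form <- if (length(red_terms))
    stats::reformulate(red_terms, response = resp)
  else stats::as.formula(paste(resp, "~ 1"))
  red_fit <- stats::lm(red_form, data = data)
  fitted_red <- stats::fitted(red_fit)
  res_red <- stats::residuals(red_fit)
  hits <- 0L
  dat <- data
  for (b in seq_len(n_perm)) {
    dat[[resp]] <- fitted_red + res_red[sample.int(length(res_red))]
    Fb <- type2_F(full_form, dat)[[term]]
    if (Fb >= F_obs) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Randomization (permutation) tests for ANOVA terms
#'
#' Non-parametric confirmation of parametric ANOVA conclusions. For a
#' single factor the response is permuted freely and the F statistic
#' recomputed; for multi-factor models each term uses the Freedman-Lane
#' residual-permutation scheme (residuals of the model without the term
#' are permuted, preserving the other effects). The p-value uses the
#' add-one estimator `(1 + #{F* >= F}) / (1 + n_perm)`, so it is never
#' smaller than `1/(1 + n_perm)`.
#'
#' With `exact = TRUE` (one-way, two groups only) all distinct
#' assignments of observations to groups are enumerated instead and the
#' p-value is the exact proportion with `F* >= F`.
#'
#' @param values Numeric response vector.
#' @param factors Data frame of design factors (or a single vector).
#' @param n_perm Number of permutations (>= 999 recommended).
#' @param seed Integer seed.
#' @param exact Enumerate all assignments exactly (two-group one-way
#'   designs only).
#' @return Named numeric vector of permutation p-values, one per model
#'   term.
#' @export
randomization_anova <- function(values, factors, n_perm = 999, seed = 1,
                                exact = FALSE) {
  if (!is.data.frame(factors)) factors <- data.frame(g = factors)
  factors <- as.data.frame(lapply(factors, factor))
  dat <- cbind(data.frame(.y = values), factors)
  form <- stats::as.formula(paste(".y ~",
                                  paste(names(factors), collapse = "*")))
  terms <- attr(stats::terms(form), "term.labels")
  if (zero_variance(values))
    return(stats::setNames(rep(1, length(terms)), terms))
  if (exact) {
    if (length(terms) != 1 || nlevels(factors[[1]]) != 2)
      stop("exact enumeration supports two-group one-way designs only")
    g <- factors[[1]]
    n1 <- sum(g == levels(g)[1])
    F_obs <- type2_F(form, dat)[[1]]
    combos <- utils::combn(length(values), n1)
    Fs <- apply(combos, 2, function(ix) {
      gg <- factor(ifelse(seq_along(values) %in% ix,
                          levels(g)[1], levels(g)[2]))
      d <- data.frame(.y = values); d[[names(factors)[1]]] <- gg
      type2_F(form, d)[[1]]
    })
    p <- mean(Fs >= F_obs - 1e-12)
    return(stats::setNames(p, terms))
  }
  if (length(terms) == 1) {
    set.seed(as.integer(seed))
    g <- factors[[1]]
    F_obs <- one_way_F(values, g)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (one_way_F(values[sample.int(length(values))], g) >= F_obs)
        hits <- hits + 1L
    }
    return(stats::setNames((1 + hits) / (1 + n_perm), terms))
  }
  out <- vapply(terms, function(tm)
    freedman_lane_p(form, tm, dat, n_perm = n_perm, seed = seed),
    numeric(1))
  out
}
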