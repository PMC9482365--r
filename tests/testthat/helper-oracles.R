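# Independent brute-force oracles. These deliberately re-derive the
# metrics with naive frame loops and no shared code with the package
# implementation (beyond the public geometry helpers they check against).

# Naive per-frame re-implementation of f_mov: loop over frames, track
# the distance to the cathode of the frame's phase, count strict
# approaches among visible pairs.
oracle_f_mov <- function(traj, config, arena) {
  n <- nrow(traj)
  out <- c(NA_real_, NA_real_)
  no_swap <- config$swap_s >= config$duration_s
  for (p in 1:2) {
    if (p == 2 && no_swap) break
    cat_pos <- if ((config$cathode1_end == "low") == (p == 1)) 0
               else arena$length_mm
    num <- 0L; denom <- 0L
    for (j in seq_len(n)) {
      in_p <- if (no_swap) TRUE
              else if (p == 1) traj$t_s[j] < config$swap_s
              else traj$t_s[j] >= config$swap_s
      if (!in_p) next
      if (traj$visible[j] && !is.na(traj$y_mm[j])) denom <- denom + 1L
      if (j == 1) next
      prev_in_p <- if (no_swap) TRUE
                   else if (p == 1) traj$t_s[j - 1] < config$swap_s
                   else traj$t_s[j - 1] >= config$swap_s
      if (!prev_in_p) next
      if (traj$visible[j] && traj$visible[j - 1] &&
          !is.na(traj$y_mm[j]) && !is.na(traj$y_mm[j - 1]) &&
          abs(traj$y_mm[j] - cat_pos) < abs(traj$y_mm[j - 1] - cat_pos))
        num <- num + 1L
    }
    out[p] <- if (denom > 0) num / denom else NA_real_
  }
  out
}

# Naive occupancy oracle with last-known-quadrant attribution.
oracle_f_cat <- function(traj, config, arena) {
  n <- nrow(traj)
  L <- arena$length_mm
  qw <- L / 4
  no_swap <- config$swap_s >= config$duration_s
  last_q <- NA_integer_
  qs <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    if (traj$visible[j] && !is.na(traj$y_mm[j])) {
      q <- floor(traj$y_mm[j] / qw)
      if (q > 3) q <- 3
      last_q <- as.integer(q)
    }
    qs[j] <- last_q
  }
  out <- c(NA_real_, NA_real_)
  for (p in 1:2) {
    if (p == 2 && no_swap) break
    in_p <- if (no_swap) rep(TRUE, n)
            else if (p == 1) traj$t_s < config$swap_s
            else traj$t_s >= config$swap_s
    attributable <- in_p & !is.na(qs)
    if (!any(attributable)) next
    cat_q <- if ((config$cathode1_end == "low") == (p == 1)) 0L else 3L
    out[p] <- sum(qs[attributable] == cat_q) / sum(attributable)
  }
  out
}

# Intensity-weighted centroid of a difference image, in mm. Independent
# of the tracker's mask-based centroid.
oracle_weighted_centroid <- function(frame, background, mm_per_px) {
  d <- abs(frame - background)
  d[d < max(d) / 2] <- 0    # suppress noise floor
  tot <- sum(d)
  rows <- matrix(seq_len(nrow(d)), nrow(d), ncol(d))
  cols <- matrix(seq_len(ncol(d)), nrow(d), ncol(d), byrow = TRUE)
  c(y = (sum(rows * d) / tot - 0.5) * mm_per_px,
    x = (sum(cols * d) / tot - 0.5) * mm_per_px)
}

# Exact permutation p for a two-group one-way design by exhaustive
# enumeration of group assignments, using t^2 as the statistic (F and
# t^2 are monotone-equivalent for two groups).
oracle_exact_perm_p <- function(values, groups) {
  g <- factor(groups)
  n1 <- sum(g == levels(g)[1])
  stat <- function(ix) {
    a <- values[ix]; b <- values[-ix]
    (mean(a) - mean(b))^2 /
      ((var(a) / length(a) + var(b) / length(b)) *
         0 + (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
         (length(values) - 2) * (1 / length(a) + 1 / length(b)))
  }
  obs <- stat(which(g == levels(g)[1]))
  combos <- combn(length(values), n1, simplify = FALSE)
  mean(vapply(combos, stat, 0) >= obs - 1e-12)
}
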