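#' Body size from a binary worm mask
#'
#' Area is the pixel count scaled by `mm_per_px^2`. Length is the maximum
#' Feret diameter — the largest caliper distance across the particle —
#' computed over the corners of the mask's boundary pixels (treating each
#' pixel as a unit square, as particle-analysis tools do), scaled by
#' `mm_per_px`. A single-pixel mask has length 0 by convention.
#'
#' @param mask A logical (or 0/1) matrix containing exactly one connected
#'   component.
#' @param mm_per_px Spatial scale.
#' @return A list with `body_length_mm` and `body_area_mm2`.
#' @export
body_metrics <- function(mask, mm_per_px) {
  mask <- mask > 0
  npix <- sum(mask)
  if (npix == 0) stop("empty mask")
  lab <- label_components(mask)
  if (length(unique(lab[lab > 0])) > 1)
    stop("mask has multiple connected components")
  area <- npix * mm_per_px^2
  if (npix == 1)
    return(list(body_length_mm = 0, body_area_mm2 = area))
  len <- max_feret_px(mask) * mm_per_px
  list(body_length_mm = len, body_area_mm2 = area)
}

# Maximum Feret diameter in px over pixel-square corners, via the convex
# hull of the corner point set (rotating-calipers scale is unnecessary at
# these particle sizes; the hull keeps the pairwise search small).
max_feret_px <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  corners <- rbind(px + rep(c(-0.5, -0.5), each = nrow(px)),
                   px + rep(c(-0.5, 0.5), each = nrow(px)),
                   px + rep(c(0.5, -0.5), each = nrow(px)),
                   px + rep(c(0.5, 0.5), each = nrow(px)))
  corners <- unique(corners)
  h <- grDevices::chull(corners[, 2], corners[, 1])
  pts <- corners[h, , drop = FALSE]
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2))
}

#' Head/body morphometric ratios from an annotated head boundary
#'
#' Projects the mask's pixels onto its principal (major) axis, takes the
#' head to be all pixels anterior to the annotated cut, and returns the
#' head:body length and area ratios. The anterior end is given by the
#' annotation — head position is a manual measurement in this assay, not
#' an inference.
#'
#' @param mask Binary worm mask (one component).
#' @param head_cut Position of the head/body boundary along the major
#'   axis. Interpreted as a fraction of the axial extent from the
#'   anterior end when `cut_unit = "fraction"`, or as mm when
#'   `cut_unit = "mm"`. Must fall strictly inside the mask's extent.
#' @param mm_per_px Spatial scale.
#' @param cut_unit `"fraction"` or `"mm"`.
#' @param anterior `"low"` or `"high"`: which end of the principal axis
#'   is the anterior end (for row-aligned masks from
#'   [synth_worm_mask()], `"low"` means the low-row end).
#' @return An object of class `worm_morphology`: a list with
#'   `body_length_mm`, `body_area_mm2`, `head_length_mm`,
#'   `head_area_mm2`, `ratio_len`, `ratio_area`.
#' @export
head_ratio <- function(mask, head_cut, mm_per_px,
                       cut_unit = c("fraction", "mm"),
                       anterior = c("low", "high")) {
  cut_unit <- match.arg(cut_unit)
  anterior <- match.arg(anterior)
  mask <- mask > 0
  body <- body_metrics(mask, mm_per_px)
  px <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(px)
  centred <- sweep(px, 2, ctr)
  ev <- eigen(stats::cov(centred), symmetric = TRUE)$vectors[, 1]
  proj <- centred %*% ev
  if (anterior == "high") proj <- -proj
  extent <- max(proj) - min(proj)
  if (extent <= 0) stop("degenerate mask: no axial extent")
  cut_px <- switch(cut_unit,
                   fraction = head_cut * extent,
                   mm = head_cut / mm_per_px)
  if (cut_px <= 0 || cut_px >= extent)
    stop("head_cut falls outside the mask's axial extent")
  is_head <- proj - min(proj) <= cut_px
  head_area <- sum(is_head) * mm_per_px^2
  head_len <- (max(proj[is_head]) - min(proj)) * mm_per_px
  structure(list(body_length_mm = body$body_length_mm,
                 body_area_mm2 = body$body_area_mm2,
                 head_length_mm = head_len,
                 head_area_mm2 = head_area,
                 ratio_len = head_len / (extent * mm_per_px),
                 ratio_area = head_area / body$body_area_mm2),
            class = "worm_morphology")
}

#' Interaction of head:body ratio and voltage on electrotaxis
#'
#' Tests whether the relationship between a worm's relative head size and
#' its post-swap electrotaxis (`f_mov_2`) differs between voltage levels,
#' by fitting `f_mov_2 ~ ratio * voltage` and examining the
#' ratio-by-voltage interaction. Reports the fitted ratio slope at each
#' voltage, the interaction F and parametric p (Type-II), and optionally
#' a Freedman-Lane permutation p for the interaction.
#'
#' @param data A data frame with columns `ratio` (head:body ratio, length
#'   or area based), `f_mov_2`, and `voltage` (two or more levels, e.g. 0
#'   and 2).
#' @param n_perm Number of permutations for the randomization p-value;
#'   `0` skips it.
#' @param seed Seed for the permutation draw.
#' @return A list with `slopes` (named per voltage level),
#'   `interaction_F`, `interaction_p`, `interaction_perm_p` (or `NA`),
#'   and the fitted `model`.
#' @export
ratio_response_model <- function(data, n_perm = 0, seed = 1) {
  stopifnot(all(c("ratio", "f_mov_2", "voltage") %in% names(data)))
  data$voltage <- factor(data$voltage)
  if (nlevels(data$voltage) < 2) stop("need at least two voltage levels")
  if (any(tapply(data$ratio, data$voltage, function(v) length(unique(v))) < 2))
    stop("degenerate design: a voltage level has a single ratio value")
  fit <- stats::lm(f_mov_2 ~ ratio * voltage, data = data)
  an <- car::Anova(fit, type = 2)
  irow <- grep("ratio:voltage", rownames(an))
  cf <- stats::coef(fit)
  lev <- levels(data$voltage)
  slopes <- stats::setNames(numeric(length(lev)), lev)
  slopes[1] <- cf[["ratio"]]
  for (k in seq_along(lev)[-1]) {
    term <- paste0("ratio:voltage", lev[k])
    slopes[k] <- cf[["ratio"]] + cf[[term]]
  }
  perm_p <- NA_real_
  if (n_perm > 0)
    perm_p <- freedman_lane_p(f_mov_2 ~ ratio * voltage, "ratio:voltage",
                              data, n_perm = n_perm, seed = seed)
  list(slopes = slopes,
       interaction_F = an[irow, "F value"],
       interaction_p = an[irow, "Pr(>F)"],
       interaction_perm_p = perm_p,
       model = fit)
}
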