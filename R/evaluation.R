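#' Masked voxel-wise Spearman correlation
#'
#' Spearman rank correlation between two volumes over the in-mask voxels
#' only, with average ranks for ties. A constant input within the mask makes
#' the correlation undefined and raises an error rather than returning 0.
#'
#' @param a,b [new_volume()] / [new_ventilation_image()] objects (or plain
#'   arrays) on the same grid.
#' @param mask a [new_mask()] with at least 3 foreground voxels.
#' @return `r_s` in `[-1, 1]`.
#' @export
spearman_masked <- function(a, b, mask) {
  av <- if (is.list(a)) a$values else a
  bv <- if (is.list(b)) b$values else b
  m <- mask$values
  if (!identical(dim(av), dim(m)) || !identical(dim(bv), dim(m)))
    vm_stop("inputs and mask must share a grid", "ventimap_geometry_error")
  if (sum(m) < 3L)
    vm_stop("mask must contain at least 3 voxels", "ventimap_data_error")
  x <- av[m]; y <- bv[m]
  if (min(x) == max(x) || min(y) == max(y))
    vm_stop("constant input within mask: Spearman correlation undefined",
            "ventimap_data_error")
  stats::cor(x, y, method = "spearman")
}

#' Tertile functional-lung segmentation
#'
#' Splits the in-mask ventilation distribution into low, medium and high
#' functional lung (LFL/MFL/HFL) at its 33.3 and 66.7 linear-interpolation
#' percentiles: `LFL = v < t_low`, `MFL = t_low <= v < t_high`,
#' `HFL = v >= t_high`; threshold ties therefore go to the higher region.
#'
#' @param vi a [new_ventilation_image()] (typically post-processed).
#' @param mask lung mask (defaults to `vi$mask`).
#' @return An object of class `ventimap_segmentation` with an integer label
#'   array (0 outside, 1 LFL, 2 MFL, 3 HFL) and the thresholds used.
#' @export
tertile_segmentation <- function(vi, mask = vi$mask) {
  v <- if (is.list(vi)) vi$values else vi
  m <- mask$values
  if (!identical(dim(v), dim(m)))
    vm_stop("image and mask must share a grid", "ventimap_geometry_error")
  if (!any(m)) vm_stop("empty mask", "ventimap_data_error")
  inm <- v[m]
  if (min(inm) == max(inm))
    vm_stop("constant ventilation within mask: tertiles are degenerate",
            "ventimap_segmentation_error")
  t_low <- vm_percentile(inm, 100 / 3)
  t_high <- vm_percentile(inm, 200 / 3)
  lab <- array(0L, dim = dim(v))
  lab[m] <- ifelse(inm >= t_high, 3L, ifelse(inm >= t_low, 2L, 1L))
  structure(list(labels = lab, t_low = t_low, t_high = t_high,
                 mask = mask),
            class = "ventimap_segmentation")
}

region_code <- function(region) {
  switch(match.arg(region, c("LFL", "MFL", "HFL")), LFL = 1L, MFL = 2L, HFL = 3L)
}

#' Dice similarity coefficient of one functional-lung region
#'
#' `DSC(A, B) = 2 |A intersect B| / (|A| + |B|)` between the same-named
#' tertile region of two segmentations. Two empty regions are defined as
#' DSC 1 (with a warning); this cannot occur for valid tertile maps.
#'
#' @param segA,segB [tertile_segmentation()] results on the same grid.
#' @param region `"LFL"`, `"MFL"` or `"HFL"`.
#' @return DSC in `[0, 1]`.
#' @export
dice_coefficient <- function(segA, segB, region) {
  if (!identical(dim(segA$labels), dim(segB$labels)))
    vm_stop("segmentations must share a grid", "ventimap_geometry_error")
  code <- region_code(region)
  a <- segA$labels == code
  b <- segB$labels == code
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) {
    warning("both regions empty; DSC defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Averaged Dice over the three functional-lung regions
#'
#' @inheritParams dice_coefficient
#' @return `(DSC_LFL + DSC_MFL + DSC_HFL) / 3`.
#' @export
averaged_dsc <- function(segA, segB) {
  mean(vapply(c("LFL", "MFL", "HFL"),
              function(r) dice_coefficient(segA, segB, r), numeric(1)))
}

#' One-way ANOVA with Tukey HSD across ventilation methods
#'
#' Compares per-subject averaged DSC values between methods: an overall
#' one-way ANOVA F test plus all pairwise Tukey honestly-significant-
#' difference adjusted p-values (studentized-range distribution).
#'
#' @param dsc_table data frame with columns `subject_id`, `method`, `dsc`.
#' @return A list with `f_statistic`, `p_overall`, and a data frame
#'   `pairwise` (`pair`, `diff`, `p_adj`).
#' @export
anova_tukey <- function(dsc_table) {
  stopifnot(all(c("subject_id", "method", "dsc") %in% names(dsc_table)))
  dsc_table$method <- factor(dsc_table$method)
  counts <- table(dsc_table$method)
  if (length(counts) < 2L)
    vm_stop("need at least 2 methods", "ventimap_data_error")
  if (any(counts < 2L))
    vm_stop("need at least 2 subjects per method", "ventimap_data_error")
  if (length(unique(counts)) != 1L)
    vm_stop("unbalanced method groups", "ventimap_data_error")
  fit <- stats::aov(dsc ~ method, data = dsc_table)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$method
  list(f_statistic = sm[["F value"]][1],
       p_overall = sm[["Pr(>F)"]][1],
       pairwise = data.frame(pair = rownames(tk),
                             diff = tk[, "diff"],
                             p_adj = tk[, "p adj"],
                             row.names = NULL))
}

#' Evaluate ventilation estimates of one subject against a reference
#'
#' For each estimate: masked voxel-wise Spearman correlation with the
#' reference, per-tertile-region Dice, and the averaged Dice. The reference
#' is resampled trilinearly onto the estimate grid first if the geometries
#' differ.
#'
#' @param estimates named list of [new_ventilation_image()] objects.
#' @param reference reference [new_ventilation_image()] (or volume).
#' @param mask evaluation mask (exhale lung mask).
#' @return A data frame with one row per method: `method`, `spearman`,
#'   `dsc_hfl`, `dsc_mfl`, `dsc_lfl`, `dsc_avg`.
#' @export
evaluate_subject <- function(estimates, reference, mask) {
  stopifnot(is.list(estimates), length(estimates) >= 1L)
  first <- estimates[[1]]
  ref_vol <- new_volume(reference$values, spacing = reference$spacing,
                        origin = reference$origin)
  if (!identical(dim(ref_vol$values), dim(first$values)) ||
      any(abs(ref_vol$spacing - first$spacing) > 1e-6) ||
      any(abs(ref_vol$origin - first$origin) > 1e-6)) {
    ref_vol <- resample_to_grid(ref_vol,
                                list(shape = dim(first$values),
                                     spacing = first$spacing,
                                     origin = first$origin),
                                "trilinear", fill = 0)
  }
  seg_ref <- tertile_segmentation(ref_vol, mask)
  rows <- lapply(names(estimates), function(nm) {
    est <- estimates[[nm]]
    seg_est <- tertile_segmentation(est, mask)
    data.frame(method = nm,
               spearman = spearman_masked(est, ref_vol, mask),
               dsc_hfl = dice_coefficient(seg_ref, seg_est, "HFL"),
               dsc_mfl = dice_coefficient(seg_ref, seg_est, "MFL"),
               dsc_lfl = dice_coefficient(seg_ref, seg_est, "LFL"),
               dsc_avg = averaged_dsc(seg_ref, seg_est))
  })
  do.call(rbind, rows)
}
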