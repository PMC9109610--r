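#' Ventilation image
#'
#' A dimensionless ventilation map on the peak-exhale (T50) grid, carrying
#' its lung mask and the method that produced it (`"HU"` density change,
#' `"JAC"` Jacobian, `"DL"` deep learning, `"REF"` reference). Values are
#' zero outside the mask after post-processing; when `normalized` the 90th
#' percentile of in-mask values equals 1.
#'
#' @param values numeric 3-D array.
#' @param mask a [new_mask()] on the same grid.
#' @param provenance one of `"HU"`, `"JAC"`, `"DL"`, `"REF"`.
#' @param spacing,origin grid geometry (mm); defaults taken from `mask`.
#' @param normalized has percentile normalisation been applied?
#' @return An object of class `ventimap_ventilation`.
#' @export
new_ventilation_image <- function(values, mask, provenance,
                                  spacing = mask$spacing, origin = mask$origin,
                                  normalized = FALSE) {
  stopifnot(inherits(mask, "ventimap_mask"))
  if (!is.array(values) || !identical(dim(values), dim(mask$values)))
    vm_stop("ventilation values must match the mask shape",
            "ventimap_geometry_error")
  provenance <- match.arg(provenance, c("HU", "JAC", "DL", "REF"))
  structure(list(values = values, mask = mask, provenance = provenance,
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 normalized = isTRUE(normalized)),
            class = "ventimap_ventilation")
}

#' @export
print.ventimap_ventilation <- function(x, ...) {
  inm <- x$values[x$mask$values]
  cat(sprintf("<ventimap_ventilation> %s, %s voxels, in-mask range [%.3g, %.3g]%s\n",
              x$provenance, paste(dim(x$values), collapse = "x"),
              min(inm), max(inm), if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Jacobian-based ventilation
#'
#' Local volume expansion `J - 1` from the Jacobian determinant of the
#' exhale-to-inhale displacement field, evaluated within the exhale lung
#' mask (zero elsewhere).
#'
#' @param dvf a [new_vector_field()] on the exhale grid.
#' @param exhale_mask exhale lung [new_mask()].
#' @return An unnormalised [new_ventilation_image()] with provenance `"JAC"`.
#' @export
ventilation_jacobian <- function(dvf, exhale_mask) {
  stopifnot(inherits(dvf, "ventimap_vector_field"),
            inherits(exhale_mask, "ventimap_mask"))
  if (!identical(dim(dvf$u)[1:3], dim(exhale_mask$values)))
    vm_stop("field and mask shapes differ", "ventimap_geometry_error")
  jac <- jacobian_determinant(dvf)
  v <- jac$values - 1
  v[!exhale_mask$values] <- 0
  new_ventilation_image(v, exhale_mask, provenance = "JAC",
                        spacing = dvf$spacing, origin = dvf$origin)
}

#' Mean inhale HU over the mapped volume of interest of one exhale voxel
#'
#' The exhale voxel's cell corners are mapped by `x + u(x)`; inhale-grid
#' voxel centres inside the bounding box of the mapped corners are averaged.
#' If the box captures no centre (local contraction), the inhale image is
#' sampled trilinearly at the mapped cell centre instead.
#'
#' @param inhale inhale-phase [new_volume()] (HU).
#' @param dvf exhale-grid [new_vector_field()].
#' @param exhale_voxel integer length-3 voxel index (1-based).
#' @param inhale_mask optional inhale lung [new_mask()]: restricts the
#'   averaged set to inhale lung voxels.
#' @return Mean inhale HU over the VOI.
#' @export
voi_mean_inhale <- function(inhale, dvf, exhale_voxel, inhale_mask = NULL) {
  d <- dim(dvf$u)[1:3]
  idx0 <- (exhale_voxel[1] - 1L) + (exhale_voxel[2] - 1L) * d[1] +
    (exhale_voxel[3] - 1L) * d[1] * d[2]
  .voi_mean_inhale(as.vector(inhale$values), dim(inhale$values),
                   inhale$spacing, inhale$origin,
                   as.vector(dvf$u), d, dvf$spacing, dvf$origin,
                   as.integer(idx0),
                   if (is.null(inhale_mask)) NULL else as.vector(inhale_mask$values))
}

#' Density-change ventilation
#'
#' Air-fraction change between exhale and registered inhale intensities:
#' at each masked exhale voxel with exhale value `HU_T50` and mean mapped
#' inhale value `H` (see [voi_mean_inhale()]),
#' `VI = 1000 * (H - HU_T50) / (HU_T50 * (1000 + H))`.
#' Voxels where a denominator vanishes (`HU_T50` near 0, `H` near -1000) are
#' set to zero and counted; more than 10 percent guarded voxels aborts with a
#' data error since that indicates broken masking or registration.
#'
#' @param inhale,exhale HU [new_volume()] objects (T00 and T50).
#' @param dvf exhale-grid [new_vector_field()] pointing into the inhale image.
#' @param exhale_mask exhale lung [new_mask()].
#' @param inhale_mask optional inhale lung [new_mask()]: when given, the VOI
#'   average is taken over inhale lung voxels only (the mapped bounding box
#'   of a boundary voxel otherwise mixes in chest-wall tissue).
#' @return An unnormalised [new_ventilation_image()] with provenance `"HU"`
#'   and attribute `"n_guarded"`.
#' @export
ventilation_density_change <- function(inhale, exhale, dvf, exhale_mask,
                                       inhale_mask = NULL) {
  stopifnot(inherits(inhale, "ventimap_volume"),
            inherits(exhale, "ventimap_volume"))
  if (inhale$intensity_kind != "HU" || exhale$intensity_kind != "HU")
    vm_stop("density-change ventilation requires HU volumes",
            "ventimap_format_error")
  d <- dim(dvf$u)[1:3]
  if (!identical(d, dim(exhale_mask$values)) ||
      !identical(d, dim(exhale$values)))
    vm_stop("exhale image, mask and field must share a grid",
            "ventimap_geometry_error")
  mi <- which(exhale_mask$values)
  if (length(mi) == 0L)
    vm_stop("empty exhale mask", "ventimap_data_error")
  h_voi <- .voi_mean_inhale(as.vector(inhale$values), dim(inhale$values),
                            inhale$spacing, inhale$origin,
                            as.vector(dvf$u), d, dvf$spacing, dvf$origin,
                            as.integer(mi - 1L),
                            if (is.null(inhale_mask)) NULL
                            else as.vector(inhale_mask$values))
  hu50 <- exhale$values[mi]
  guarded <- abs(hu50) < 1 | abs(1000 + h_voi) < 1
  vi_in <- numeric(length(mi))
  ok <- !guarded
  vi_in[ok] <- 1000 * (h_voi[ok] - hu50[ok]) / (hu50[ok] * (1000 + h_voi[ok]))
  if (mean(guarded) > 0.10)
    vm_stop(sprintf("%.1f%% of masked voxels hit a denominator guard",
                    100 * mean(guarded)), "ventimap_data_error")
  v <- array(0, dim = d)
  v[mi] <- vi_in
  out <- new_ventilation_image(v, exhale_mask, provenance = "HU",
                               spacing = dvf$spacing, origin = dvf$origin)
  attr(out, "n_guarded") <- sum(guarded)
  out
}

#' Post-process a ventilation image
#'
#' The shared chain applied to every ventilation map before comparison:
#' (1) zero outside the exhale lung mask, (2) divide by the
#' `norm_percentile`-th percentile of in-mask values (linear-interpolation
#' percentile over in-mask voxels only), (3) box median filter of edge
#' `filter_size` over the full grid with reflect padding, (4) re-zero outside
#' the mask. Scale invariance holds exactly: a positive rescaling of the
#' input leaves the result unchanged.
#'
#' @param vi a [new_ventilation_image()].
#' @param exhale_mask mask defining the lung region (defaults to `vi$mask`).
#' @param norm_percentile normalisation percentile (default 90).
#' @param filter_size odd box edge in voxels (default 9; 1 disables).
#' @return A normalised [new_ventilation_image()].
#' @export
postprocess <- function(vi, exhale_mask = vi$mask, norm_percentile = 90,
                        filter_size = 9L) {
  stopifnot(inherits(vi, "ventimap_ventilation"))
  filter_size <- as.integer(filter_size)
  if (filter_size < 1L || filter_size %% 2L == 0L)
    vm_stop("filter_size must be odd and >= 1", "ventimap_parameter_error")
  m <- exhale_mask$values
  if (!identical(dim(m), dim(vi$values)))
    vm_stop("mask shape differs from the ventilation image",
            "ventimap_geometry_error")
  v <- vi$values
  v[!m] <- 0
  norm <- vm_percentile(v[m], norm_percentile)
  if (!is.finite(norm) || norm <= 0)
    vm_stop("nonpositive normalisation constant", "ventimap_data_error")
  v <- v / norm
  if (filter_size > 1L) {
    # filtered values are only needed inside the mask, so run the filter on
    # the mask bounding box padded by the half window; where the padded box
    # is clipped by the volume edge the filter's reflect padding applies,
    # exactly as it would on the full grid
    h <- filter_size %/% 2L
    d <- dim(v)
    wi <- which(m, arr.ind = TRUE)
    lo <- pmax(apply(wi, 2, min) - h, 1L)
    hi <- pmin(apply(wi, 2, max) + h, d)
    sub <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    filt <- array(.median_filter_box(as.vector(sub), dim(sub), filter_size),
                  dim = dim(sub))
    v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- filt
  }
  v[!m] <- 0
  new_ventilation_image(v, exhale_mask, provenance = vi$provenance,
                        spacing = vi$spacing, origin = vi$origin,
                        normalized = TRUE)
}
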