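#' Per-voxel displacement field
#'
#' Displacements are stored in mm as a 4-D array `(nx, ny, nz, 3)` on a
#' stated reference grid — by convention in this package the fixed image's
#' grid (for ventilation work: the peak-exhale T50 grid), with the vector at
#' voxel `x` pointing to the corresponding position `x + u(x)` in the moving
#' (peak-inhale) image. Under this convention the Jacobian determinant of
#' `I + grad u` measures inhale/exhale local volume ratio, which is `>= 1` in
#' ventilated lung, so the Jacobian ventilation `J - 1` is nonnegative.
#'
#' @param u numeric 4-D array `(nx, ny, nz, 3)` of mm displacements.
#' @param spacing,origin grid geometry in mm.
#' @return An object of class `ventimap_vector_field`.
#' @export
new_vector_field <- function(u, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(u) || length(dim(u)) != 4L || dim(u)[4] != 3L)
    vm_stop("u must be a (nx, ny, nz, 3) array", "ventimap_format_error")
  if (any(!is.finite(u)))
    vm_stop("displacement components must be finite", "ventimap_format_error")
  structure(list(u = u, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ventimap_vector_field")
}

#' @export
print.ventimap_vector_field <- function(x, ...) {
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("<ventimap_vector_field> %s voxels, |u| mean %.2f / max %.2f mm\n",
              paste(dim(x$u)[1:3], collapse = "x"), mean(mag), max(mag)))
  invisible(x)
}

field_geometry <- function(dvf) list(shape = dim(dvf$u)[1:3],
                                     spacing = dvf$spacing, origin = dvf$origin)

#' Backward-warp a volume through a displacement field
#'
#' The output lives on the field's grid: the value at fixed-grid voxel `x` is
#' the moving image sampled at physical position `x + u(x)`.
#'
#' @param moving a [new_volume()].
#' @param dvf a [new_vector_field()] defining the output grid.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @param fill value for out-of-support sample positions (default: moving
#'   minimum).
#' @return A [new_volume()] on the field's grid.
#' @export
warp_volume <- function(moving, dvf, interpolation = c("trilinear", "nearest"),
                        fill = NULL) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(moving, "ventimap_volume"),
            inherits(dvf, "ventimap_vector_field"))
  if (is.null(fill)) fill <- min(moving$values)
  g <- field_geometry(dvf)
  ax <- grid_axes(g)
  n12 <- g$shape[1] * g$shape[2]
  px <- rep(ax[[1]], times = g$shape[2] * g$shape[3]) + as.vector(dvf$u[, , , 1])
  py <- rep(rep(ax[[2]], each = g$shape[1]), times = g$shape[3]) +
    as.vector(dvf$u[, , , 2])
  pz <- rep(ax[[3]], each = n12) + as.vector(dvf$u[, , , 3])
  ix <- (px - moving$origin[1]) / moving$spacing[1] + 1
  iy <- (py - moving$origin[2]) / moving$spacing[2] + 1
  iz <- (pz - moving$origin[3]) / moving$spacing[3] + 1
  vals <- if (interpolation == "trilinear")
    trilinear_sample(moving$values, ix, iy, iz, fill)
  else nearest_sample(moving$values, ix, iy, iz, fill)
  new_volume(array(vals, dim = g$shape), spacing = g$spacing, origin = g$origin,
             intensity_kind = moving$intensity_kind)
}

# Spacing-aware partial derivative of a 3-D array along one axis:
# central differences in the interior, one-sided at the two boundary planes.
grad_axis <- function(a, ax, h) {
  d <- dim(a)
  n <- d[ax]
  if (n == 1L) return(array(0, dim = d))
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(a, perm), nrow = n)
  g <- matrix(0, n, ncol(m))
  if (n > 2) g[2:(n - 1), ] <- (m[3:n, , drop = FALSE] -
                                  m[1:(n - 2), , drop = FALSE]) / (2 * h)
  g[1, ] <- (m[2, ] - m[1, ]) / h
  g[n, ] <- (m[n, ] - m[n - 1, ]) / h
  dim(g) <- d[perm]
  aperm(g, order(perm))
}

#' Jacobian determinant of a displacement field
#'
#' Per-voxel determinant of `I + grad u`, with the displacement gradient
#' computed by spacing-aware central differences (one-sided at the grid
#' boundary) and the 3x3 determinant expanded in closed form. Exact (to
#' floating-point round-off) for any field affine in the coordinates.
#'
#' @param dvf a [new_vector_field()].
#' @return A [new_volume()] of the determinant (dimensionless).
#' @export
jacobian_determinant <- function(dvf) {
  stopifnot(inherits(dvf, "ventimap_vector_field"))
  h <- dvf$spacing
  g <- vector("list", 9)
  k <- 1
  for (comp in 1:3) {
    ucomp <- dvf$u[, , , comp]
    for (ax in 1:3) {
      g[[k]] <- grad_axis(ucomp, ax, h[ax])
      k <- k + 1
    }
  }
  # g: ux_x ux_y ux_z uy_x uy_y uy_z uz_x uz_y uz_z
  a11 <- 1 + g[[1]]; a12 <- g[[2]]; a13 <- g[[3]]
  a21 <- g[[4]]; a22 <- 1 + g[[5]]; a23 <- g[[6]]
  a31 <- g[[7]]; a32 <- g[[8]]; a33 <- 1 + g[[9]]
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  new_volume(det, spacing = dvf$spacing, origin = dvf$origin,
             intensity_kind = "dimensionless")
}

#' Parameters of the demons registration
#'
#' @param n_levels number of multiresolution levels (coarsest factor
#'   `2^(n_levels - 1)`).
#' @param iterations maximum demons iterations per level (recycled to
#'   `n_levels`).
#' @param field_sigma_mm Gaussian smoothing of the accumulated field, mm.
#' @param update_sigma_mm Gaussian smoothing of each update, mm.
#' @param tol relative mean-squared intensity-difference change below which a
#'   level is considered converged.
#' @param diff_threshold intensity differences (HU) below this magnitude
#'   produce no force; suppresses spurious near-maximal steps in flat
#'   regions.
#' @param symmetric_forces use the mean of the fixed and warped-moving
#'   gradients in the demons force (faster, more accurate convergence than
#'   the fixed-gradient force).
#' @param density_match globally rescale `1000 + HU` of the moving image
#'   within the lung HU window so its mean matches the fixed image before
#'   registering. Inhale and exhale lung differ systematically in density
#'   (air content); without this the residual offset drives spurious
#'   deformation along lung texture gradients.
#' @return An object of class `ventimap_registration_params`.
#' @export
registration_params <- function(n_levels = 3L, iterations = 50L,
                                field_sigma_mm = 2.0, update_sigma_mm = 1.0,
                                tol = 1e-4, diff_threshold = 1.0,
                                symmetric_forces = TRUE,
                                density_match = TRUE) {
  if (n_levels < 1 || any(iterations < 1) || field_sigma_mm <= 0 ||
      update_sigma_mm <= 0 || tol <= 0 || diff_threshold <= 0)
    vm_stop("all registration parameters must be positive",
            "ventimap_parameter_error")
  structure(list(n_levels = as.integer(n_levels),
                 iterations = rep(as.integer(iterations), length.out = n_levels),
                 field_sigma_mm = field_sigma_mm,
                 update_sigma_mm = update_sigma_mm, tol = tol,
                 diff_threshold = diff_threshold,
                 symmetric_forces = isTRUE(symmetric_forces),
                 density_match = isTRUE(density_match)),
            class = "ventimap_registration_params")
}

# Smooth + subsample a volume by an integer factor (pyramid level).
downsample_volume <- function(vol, f) {
  if (f == 1L) return(vol)
  v <- gaussian_smooth_3d(vol$values, vol$spacing * f / 2, vol$spacing)
  d <- dim(v)
  sel <- lapply(1:3, function(ax) seq(1L, d[ax], by = f))
  new_volume(v[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
             spacing = vol$spacing * f, origin = vol$origin,
             intensity_kind = vol$intensity_kind)
}

resample_field <- function(dvf, geom) {
  d <- geom$shape
  u <- array(0, dim = c(d, 3))
  for (comp in 1:3) {
    v <- new_volume(dvf$u[, , , comp], spacing = dvf$spacing,
                    origin = dvf$origin)
    u[, , , comp] <- resample_to_grid(v, geom, "trilinear", fill = 0)$values
  }
  new_vector_field(u, spacing = geom$spacing, origin = geom$origin)
}

#' Multiresolution demons deformable registration
#'
#' Intensity-based demons registration: at each iteration the moving image is
#' backward-warped through the current field, the classical demons force
#' `(f - m(x+u)) * grad f / (|grad f|^2 + (f - m(x+u))^2 / s^2)` (with `s` the
#' mean voxel spacing, stabilising the denominator) is Gaussian-smoothed and
#' added to the field, and the accumulated field is Gaussian-smoothed again.
#' Levels run coarse to fine; the returned field lives on the fixed image's
#' grid and points from fixed positions to the corresponding moving
#' positions. The procedure is fully deterministic.
#'
#' @param fixed,moving [new_volume()] objects with HU intensities covering the
#'   same physical extent.
#' @param params a [registration_params()].
#' @param initial_field optional starting [new_vector_field()].
#' @param verbose print per-level convergence lines.
#' @return A [new_vector_field()] on the fixed grid.
#' @export
demons_register <- function(fixed, moving, params = registration_params(),
                            initial_field = NULL, verbose = FALSE) {
  stopifnot(inherits(fixed, "ventimap_volume"), inherits(moving, "ventimap_volume"))
  if (fixed$intensity_kind != "HU" || moving$intensity_kind != "HU")
    vm_stop("demons_register expects HU volumes", "ventimap_format_error")
  if (any(!is.finite(fixed$values)) || any(!is.finite(moving$values)))
    vm_stop("non-finite intensities", "ventimap_data_error")
  f_lo <- fixed$origin; f_hi <- fixed$origin + (dim(fixed$values) - 1) * fixed$spacing
  m_lo <- moving$origin; m_hi <- moving$origin + (dim(moving$values) - 1) * moving$spacing
  if (any(pmax(f_lo, m_lo) > pmin(f_hi, m_hi)))
    vm_stop("fixed and moving extents do not overlap", "ventimap_geometry_error")
  if (params$density_match) {
    in_win <- function(v) v >= -999 & v <= -250
    sf <- in_win(fixed$values)
    sm <- in_win(moving$values)
    if (any(sf) && any(sm)) {
      c_est <- mean(1000 + fixed$values[sf]) / mean(1000 + moving$values[sm])
      mv <- moving$values
      mv[sm] <- (1000 + mv[sm]) * c_est - 1000
      moving <- new_volume(mv, moving$spacing, moving$origin, "HU")
    }
  }
  dvf <- initial_field
  for (lev in seq(params$n_levels, 1)) {
    f <- 2L^(lev - 1L)
    fix_l <- downsample_volume(fixed, f)
    mov_l <- downsample_volume(moving, f)
    geom <- vol_geometry(fix_l)
    dvf <- if (is.null(dvf))
      new_vector_field(array(0, dim = c(geom$shape, 3)),
                       spacing = geom$spacing, origin = geom$origin)
    else resample_field(dvf, geom)
    s2 <- mean(geom$spacing)^2
    gx <- grad_axis(fix_l$values, 1, geom$spacing[1])
    gy <- grad_axis(fix_l$values, 2, geom$spacing[2])
    gz <- grad_axis(fix_l$values, 3, geom$spacing[3])
    gmag2 <- gx^2 + gy^2 + gz^2
    prev_mse <- Inf
    for (it in seq_len(params$iterations[params$n_levels - lev + 1L])) {
      mw <- warp_volume(mov_l, dvf)$values
      diff <- fix_l$values - mw
      mse <- mean(diff^2)
      if (is.finite(prev_mse) &&
          abs(prev_mse - mse) / max(prev_mse, .Machine$double.eps) < params$tol)
        break
      prev_mse <- mse
      if (params$symmetric_forces) {
        hx <- 0.5 * (gx + grad_axis(mw, 1, geom$spacing[1]))
        hy <- 0.5 * (gy + grad_axis(mw, 2, geom$spacing[2]))
        hz <- 0.5 * (gz + grad_axis(mw, 3, geom$spacing[3]))
        hmag2 <- hx^2 + hy^2 + hz^2
      } else {
        hx <- gx; hy <- gy; hz <- gz; hmag2 <- gmag2
      }
      # the normalised demons force is scale-invariant, so flat regions where
      # both the difference and the gradient are numerically tiny would still
      # produce near-maximal steps; gate them out (cf. the intensity
      # difference threshold of standard demons implementations)
      denom <- hmag2 + diff^2 / s2
      active <- denom > 1e-9 & abs(diff) > params$diff_threshold
      scale <- ifelse(active, diff / denom, 0)
      u <- dvf$u
      u[, , , 1] <- u[, , , 1] +
        gaussian_smooth_3d(scale * hx, params$update_sigma_mm, geom$spacing)
      u[, , , 2] <- u[, , , 2] +
        gaussian_smooth_3d(scale * hy, params$update_sigma_mm, geom$spacing)
      u[, , , 3] <- u[, , , 3] +
        gaussian_smooth_3d(scale * hz, params$update_sigma_mm, geom$spacing)
      for (comp in 1:3)
        u[, , , comp] <- gaussian_smooth_3d(u[, , , comp],
                                            params$field_sigma_mm, geom$spacing)
      dvf <- new_vector_field(u, spacing = geom$spacing, origin = geom$origin)
      if (verbose && it %% 10 == 0)
        message(sprintf("level %d it %d mse %.3f", lev, it, mse))
    }
    if (verbose) message(sprintf("level %d done, mse %.3f", lev, prev_mse))
  }
  dvf
}
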