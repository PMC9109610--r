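#' Specification of a synthetic breathing-lung phantom
#'
#' The phantom is a torso-like body (elliptic cylinder at soft-tissue HU)
#' containing two ellipsoidal lungs and a midline trachea. Breathing is
#' modelled by a dorsoventrally graded, z-directed expansion about a fixed
#' apex plane `z0`: at phase weight `w` the material point at exhale position
#' `z` moves to `z0 + (1 + w*a(x, y)) * (z - z0)`, where `a(x, y)` is the
#' regional specific-ventilation field (base level `a0`, dorsoventral gradient
#' `a1`, multiplicative Gaussian ventilation defects). Because the deformation
#' gradient is unit-lower-triangular, its Jacobian determinant is exactly
#' `1 + w*a(x, y)` inside the lungs, giving a closed-form ground-truth
#' ventilation of `a(x, y)` at peak inhale. Lung HU follows air-tissue mass
#' conservation across phases: `(1000 + HU_phase) = (1000 + HU_ex)/(1 + w*a)`.
#' A smooth vascular-like HU texture (amplitude `texture_amplitude`) is
#' attached to the lung tissue in material coordinates so that intensity-based
#' registration of the phases is well posed; the texture scales with density
#' so mass conservation continues to hold for the textured tissue.
#'
#' @param shape,spacing,origin grid geometry (voxels, mm, mm).
#' @param body_center,body_semiaxes torso ellipsoid (mm); the default z
#'   semi-axis is effectively infinite (cylinder).
#' @param lung_centers list of two length-3 centres (mm).
#' @param lung_semiaxes list of two length-3 semi-axes (mm).
#' @param trachea_center,trachea_radius,trachea_zmin midline airway cylinder
#'   (mm); it spans `z >= trachea_zmin`.
#' @param hu_body,hu_lung_ex,hu_trachea tissue HU values (exhale baseline).
#' @param a0,a1 base expansion and dorsoventral (y) gradient amplitude.
#' @param defects list of ventilation defects, each a list with `center`
#'   (length-2, mm, axial plane), `radius` (mm) and `depression` in `[0, 1]`.
#' @param z0 apex plane (mm): displacement is zero there and grows with
#'   distance below it.
#' @param texture_amplitude HU standard deviation of the smooth lung texture.
#' @param texture_sigma_mm correlation length of the texture.
#' @param texture_seed seed for the texture field; part of the anatomy, so it
#'   is deliberately separate from `seed`.
#' @param noise_sd additive Gaussian image noise (HU).
#' @param shading_amplitude amplitude of the smooth multiplicative shading
#'   field applied to `HU + 1000` (CBCT-like low-frequency nonuniformity).
#' @param seed master seed for the stochastic components (noise).
#' @return An object of class `ventimap_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 64), spacing = c(2, 2, 2),
                         origin = c(0, 0, 0),
                         body_center = NULL, body_semiaxes = c(88, 78, 1e6),
                         lung_centers = NULL, lung_semiaxes = NULL,
                         trachea_center = NULL, trachea_radius = 8,
                         trachea_zmin = NULL,
                         hu_body = 40, hu_lung_ex = -800, hu_trachea = -1000,
                         a0 = 0.15, a1 = 0.10,
                         defects = list(list(center = c(0.72, 0.58),
                                             radius = 16, depression = 0.7)),
                         z0 = NULL,
                         texture_amplitude = 50, texture_sigma_mm = 5,
                         texture_seed = 1L,
                         noise_sd = 20, shading_amplitude = 0.03,
                         seed = 1L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  extent <- (shape - 1) * spacing
  cen <- origin + extent / 2
  if (is.null(body_center)) body_center <- cen
  # defaults scale with the grid extent so that smaller grids hold the same
  # anatomy at coarser resolution
  sc <- extent / c(190, 190, 126)
  if (is.null(lung_centers))
    lung_centers <- list(cen + c(-42, 0, 0) * sc[c(1, 2, 3)] + c(0, 0, -1) * sc[3],
                         cen + c(42, 0, 0) * sc[c(1, 2, 3)] + c(0, 0, -1) * sc[3])
  if (is.null(lung_semiaxes))
    lung_semiaxes <- list(c(30, 42, 36) * sc, c(30, 42, 36) * sc)
  if (is.null(trachea_center)) trachea_center <- cen[1:2] + c(0, -15) * sc[1:2]
  if (is.null(trachea_zmin)) trachea_zmin <- cen[3]
  if (is.null(z0)) z0 <- max(vapply(1:2, function(i)
    lung_centers[[i]][3] + lung_semiaxes[[i]][3], numeric(1))) + 4 * sc[3]
  # defect centres given as fractions of the extent are resolved to mm
  defects <- lapply(defects, function(df) {
    if (all(df$center >= 0 & df$center <= 1))
      df$center <- origin[1:2] + df$center * extent[1:2]
    df
  })
  spec <- list(shape = shape, spacing = spacing, origin = as.numeric(origin),
               body_center = body_center, body_semiaxes = body_semiaxes,
               lung_centers = lung_centers, lung_semiaxes = lung_semiaxes,
               trachea_center = trachea_center, trachea_radius = trachea_radius,
               trachea_zmin = trachea_zmin,
               hu_body = hu_body, hu_lung_ex = hu_lung_ex, hu_trachea = hu_trachea,
               a0 = a0, a1 = a1, defects = defects, z0 = z0,
               texture_amplitude = texture_amplitude,
               texture_sigma_mm = texture_sigma_mm,
               texture_seed = as.integer(texture_seed),
               noise_sd = noise_sd, shading_amplitude = shading_amplitude,
               seed = as.integer(seed))
  class(spec) <- "ventimap_phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$hu_lung_ex <= -1000 || spec$hu_lung_ex >= -250)
    vm_stop("hu_lung_ex must lie in (-1000, -250)", "ventimap_parameter_error")
  a <- expansion_field(spec)
  if (any(1 + a <= 0))
    vm_stop("expansion field makes the deformation non-invertible",
            "ventimap_parameter_error")
  invisible(spec)
}

#' Regional expansion field of a phantom
#'
#' `a(x, y) = a0 + a1 * (y - y_min)/(y_max - y_min)`, multiplied by
#' `1 - depression * exp(-r^2 / (2 * (radius/2)^2))` for each ventilation
#' defect, then clipped so that `1 + a >= 0.05`.
#'
#' @param spec a [phantom_spec()].
#' @return An `nx` by `ny` matrix.
#' @export
expansion_field <- function(spec) {
  xs <- spec$origin[1] + (seq_len(spec$shape[1]) - 1) * spec$spacing[1]
  ys <- spec$origin[2] + (seq_len(spec$shape[2]) - 1) * spec$spacing[2]
  gy <- if (length(ys) > 1) (ys - min(ys)) / (max(ys) - min(ys)) else 0 * ys
  a <- matrix(spec$a0, length(xs), length(ys)) +
    spec$a1 * matrix(gy, length(xs), length(ys), byrow = TRUE)
  for (df in spec$defects) {
    r2 <- outer((xs - df$center[1])^2, (ys - df$center[2])^2, "+")
    a <- a * (1 - df$depression * exp(-r2 / (2 * (df$radius / 2)^2)))
  }
  pmax(a, -0.95)
}

#' Cosine phase-weight schedule over the 10 respiratory bins
#'
#' `w(p) = (1 + cos(2*pi*p/10))/2`: 1 at T00 (peak inhale), 0 at T50 (peak
#' exhale), symmetric between inhale and exhale limbs.
#'
#' @param phase_index integer in 0..9.
#' @return Phase weight in `[0, 1]`.
#' @export
phase_weight_schedule <- function(phase_index) {
  if (any(phase_index < 0 | phase_index > 9 | phase_index != round(phase_index)))
    vm_stop("phase_index must be an integer in 0..9", "ventimap_parameter_error")
  (1 + cos(2 * pi * phase_index / 10)) / 2
}

# Geometric (noise-free) membership arrays of the phantom at phase weight w.
# Lung membership is evaluated at the exactly inverse-mapped exhale
# coordinate z = z0 + (z' - z0)/(1 + w*a); body and trachea do not move.
phantom_membership <- function(spec, w, a = expansion_field(spec)) {
  d <- spec$shape
  xs <- spec$origin[1] + (seq_len(d[1]) - 1) * spec$spacing[1]
  ys <- spec$origin[2] + (seq_len(d[2]) - 1) * spec$spacing[2]
  zs <- spec$origin[3] + (seq_len(d[3]) - 1) * spec$spacing[3]
  denom <- 1 + w * a # (nx, ny)
  zin <- array(0, dim = d) # exhale-space z of each phase voxel
  for (k in seq_len(d[3]))
    zin[, , k] <- spec$z0 + (zs[k] - spec$z0) / denom
  lung <- array(FALSE, dim = d)
  for (l in 1:2) {
    c3 <- spec$lung_centers[[l]]; s3 <- spec$lung_semiaxes[[l]]
    q2 <- outer(((xs - c3[1]) / s3[1])^2, ((ys - c3[2]) / s3[2])^2, "+")
    lung <- lung | (array(q2, dim = d) + ((zin - c3[3]) / s3[3])^2 <= 1)
  }
  bq <- outer(((xs - spec$body_center[1]) / spec$body_semiaxes[1])^2,
              ((ys - spec$body_center[2]) / spec$body_semiaxes[2])^2, "+")
  body <- array(bq, dim = d) +
    rep(((zs - spec$body_center[3]) / spec$body_semiaxes[3])^2,
        each = d[1] * d[2]) <= 1
  tq <- outer((xs - spec$trachea_center[1])^2, (ys - spec$trachea_center[2])^2, "+")
  trachea <- array(tq <= spec$trachea_radius^2, dim = d) &
    rep(zs >= spec$trachea_zmin, each = d[1] * d[2])
  list(lung = lung, body = body, trachea = trachea, zin = zin, denom = denom)
}

# Smooth vascular-like HU texture in exhale (material) coordinates.
phantom_texture <- function(spec) {
  if (spec$texture_amplitude <= 0) return(array(0, dim = spec$shape))
  tex <- with_seed(derive_seed(spec$texture_seed, "phantom_texture"), {
    array(rnorm(prod(spec$shape)), dim = spec$shape)
  })
  tex <- gaussian_smooth_3d(tex, spec$texture_sigma_mm, spec$spacing)
  tex * (spec$texture_amplitude / sd(tex))
}

#' Analytic displacement field of a phantom
#'
#' Displacement on the exhale grid pointing to the corresponding inhale-ward
#' position at phase weight `w`: `u_x = u_y = 0`,
#' `u_z = w * a(x, y) * (z - z0)` inside the lungs, smoothly tapered to zero
#' over a 6 mm shell outside them. Inside the lungs the displacement-gradient
#' matrix is unit-lower-triangular, so the Jacobian determinant of `I + grad u`
#' is exactly `1 + w * a(x, y)`.
#'
#' @param spec a [phantom_spec()].
#' @param phase_weight `w` in `[0, 1]`.
#' @return A [new_vector_field()] on the exhale grid.
#' @export
analytic_dvf <- function(spec, phase_weight = 1) {
  if (phase_weight < 0 || phase_weight > 1)
    vm_stop("phase_weight must lie in [0, 1]", "ventimap_parameter_error")
  a <- expansion_field(spec)
  mem <- phantom_membership(spec, 0, a)
  d <- spec$shape
  zs <- spec$origin[3] + (seq_len(d[3]) - 1) * spec$spacing[3]
  # full displacement on the lungs plus a one-voxel margin (so that finite
  # differences at boundary lung voxels still see the affine field), then a
  # smooth taper to zero over a 6 mm shell
  taper <- array(0, dim = d)
  full <- dilate26(mem$lung)
  taper[full] <- 1
  shell_vox <- ceiling(6 / min(spec$spacing))
  prev <- full
  for (s in seq_len(shell_vox)) {
    cur <- dilate26(prev)
    taper[cur & !prev] <- cos(pi * s / (2 * (shell_vox + 1)))^2
    prev <- cur
  }
  uz <- phase_weight * array(a, dim = d) *
    rep(zs - spec$z0, each = d[1] * d[2]) * taper
  u <- array(0, dim = c(d, 3))
  u[, , , 3] <- uz
  new_vector_field(u, spacing = spec$spacing, origin = spec$origin)
}

#' Render one respiratory phase of a phantom
#'
#' The exhale anatomy (`w = 0`) is drawn from the ellipsoid model at the
#' stated HU; inhale-ward phases are rendered analytically on their own grid
#' through the exact inverse map, with lung HU obeying mass conservation
#' `(1000 + HU_phase) = (1000 + HU_ex + texture)/(1 + w*a)`. A smooth
#' multiplicative shading field and Gaussian noise are applied last (seeded;
#' noise differs between phases but is reproducible).
#'
#' @param spec a [phantom_spec()].
#' @param phase_weight `w` in `[0, 1]`.
#' @param phase_index optional integer tag entering the noise seed so each
#'   phase of a series gets independent noise.
#' @param texture precomputed texture array (internal reuse across phases).
#' @return A [new_volume()] with HU intensities.
#' @export
render_phase <- function(spec, phase_weight, phase_index = 0L,
                         texture = NULL) {
  if (phase_weight < 0 || phase_weight > 1)
    vm_stop("phase_weight must lie in [0, 1]", "ventimap_parameter_error")
  a <- expansion_field(spec)
  mem <- phantom_membership(spec, phase_weight, a)
  d <- spec$shape
  vals <- array(-1000, dim = d)
  vals[mem$body] <- spec$hu_body
  vals[mem$trachea] <- spec$hu_trachea
  denom3 <- array(1 + phase_weight * a, dim = d)
  tex <- if (is.null(texture)) phantom_texture(spec) else texture
  if (any(mem$lung)) {
    li <- which(mem$lung)
    # sample texture at the material coordinate (x, y, zin)
    fi <- (mem$zin[li] - spec$origin[3]) / spec$spacing[3] + 1
    fi <- pmin(pmax(fi, 1), d[3])
    k0 <- pmin(floor(fi), d[3] - 1); fr <- fi - k0
    xi <- ((li - 1) %% d[1]) + 1
    yi <- (((li - 1) %/% d[1]) %% d[2]) + 1
    tval <- tex[cbind(xi, yi, k0)] * (1 - fr) + tex[cbind(xi, yi, k0 + 1)] * fr
    vals[li] <- (1000 + spec$hu_lung_ex + tval) / denom3[li] - 1000
  }
  if (spec$shading_amplitude > 0) {
    ex <- (d - 1) * spec$spacing
    ax <- grid_axes(list(shape = d, spacing = spec$spacing, origin = spec$origin))
    sh <- spec$shading_amplitude *
      array(outer(cos(pi * (ax[[1]] - spec$origin[1]) / ex[1]),
                  cos(2 * pi * (ax[[2]] - spec$origin[2]) / ex[2]), "*"), dim = d) *
      rep(cos(pi * (ax[[3]] - spec$origin[3]) / ex[3]), each = d[1] * d[2])
    vals <- (vals + 1000) * (1 + sh) - 1000
  }
  if (spec$noise_sd > 0) {
    vals <- vals + with_seed(
      derive_seed(spec$seed, paste0("render_phase_", phase_index)),
      array(rnorm(prod(d), sd = spec$noise_sd), dim = d))
  }
  new_volume(vals, spacing = spec$spacing, origin = spec$origin,
             intensity_kind = "HU")
}

#' Degrade a ground-truth ventilation map into a SPECT-like reference
#'
#' Emulates the statistical structure of an aerosol-SPECT ventilation scan:
#' Gaussian blur at the tomograph's resolution, averaging onto a grid
#' coarsened by `coarsen_factor` (about 2 mm to about 8 mm by default),
#' count-statistics-like noise with variance proportional to the local mean,
#' clipping at zero, and trilinear interpolation back onto the fine grid.
#'
#' @param truth a [new_ventilation_image()] (nonnegative within its mask).
#' @param coarsen_factor integer grid coarsening factor.
#' @param blur_sigma_mm Gaussian blur in mm.
#' @param noise_scale relative noise level: the noise SD at a voxel with the
#'   in-mask mean intensity is `noise_scale` times that mean.
#' @param seed integer seed.
#' @return A [new_volume()] of kind `"counts"` on the fine grid.
#' @export
degrade_to_spect_like <- function(truth, coarsen_factor = 4L,
                                  blur_sigma_mm = 4, noise_scale = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(truth, "ventimap_ventilation"))
  v <- truth$values
  if (blur_sigma_mm > 0) {
    # normalised convolution: blur inside the lung support so that edge
    # voxels are not dragged toward the zero background
    m <- truth$mask$values + 0
    num <- gaussian_smooth_3d(v * m, blur_sigma_mm, truth$spacing)
    den <- gaussian_smooth_3d(m, blur_sigma_mm, truth$spacing)
    v <- ifelse(den > 1e-3, num / den, 0) * (den > 1e-3)
    dim(v) <- dim(truth$values)
  }
  f <- as.integer(coarsen_factor)
  if (f > 1L) {
    v <- block_average(v, f)
    spacing_c <- truth$spacing * f
    origin_c <- truth$origin + (f - 1) / 2 * truth$spacing
  } else {
    spacing_c <- truth$spacing; origin_c <- truth$origin
  }
  if (noise_scale > 0) {
    vbar <- mean(truth$values[truth$mask$values])
    v <- v + with_seed(derive_seed(seed, "spect_noise"),
                       array(rnorm(length(v)), dim = dim(v))) *
      noise_scale * sqrt(pmax(v, 0) * vbar)
  }
  v <- pmax(v, 0)
  coarse <- new_volume(v, spacing = spacing_c, origin = origin_c,
                       intensity_kind = "counts")
  resample_to_grid(coarse, list(shape = dim(truth$values),
                                spacing = truth$spacing, origin = truth$origin),
                   interpolation = "trilinear", fill = 0)
}

#' Generate a complete synthetic 4D subject
#'
#' Assembles the 10-phase series (cosine weight schedule), per-phase lung
#' masks from the noise-free geometry, the analytic peak-inhale displacement
#' field, the closed-form ground-truth ventilation `a(x, y)` on the exhale
#' lung mask, and the degraded SPECT-like reference.
#'
#' @param spec a [phantom_spec()].
#' @param id subject identifier string.
#' @param spect_args list of arguments passed to [degrade_to_spect_like()].
#' @return An object of class `ventimap_phantom_subject`.
#' @export
make_subject <- function(spec, id = "subject01", spect_args = list()) {
  a <- expansion_field(spec)
  weights <- phase_weight_schedule(0:9)
  phases <- vector("list", 10)
  masks <- vector("list", 10)
  tex <- phantom_texture(spec)
  for (p in 1:10) {
    phases[[p]] <- render_phase(spec, weights[p], phase_index = p - 1L,
                                texture = tex)
    mem <- phantom_membership(spec, weights[p], a)
    masks[[p]] <- new_mask(mem$lung, spacing = spec$spacing, origin = spec$origin)
  }
  names(phases) <- names(masks) <- sprintf("T%02d", seq(0, 90, by = 10))
  series <- new_phase_series(phases)
  exhale_mask <- masks[["T50"]]
  tv <- array(0, dim = spec$shape)
  tv[exhale_mask$values] <- array(a, dim = spec$shape)[exhale_mask$values]
  truth <- new_ventilation_image(tv, exhale_mask, provenance = "REF",
                                 spacing = spec$spacing, origin = spec$origin)
  spect <- do.call(degrade_to_spect_like,
                   c(list(truth = truth,
                          seed = derive_seed(spec$seed, "spect")), spect_args))
  structure(list(id = id, series = series, lung_masks = masks,
                 exhale_mask = exhale_mask,
                 true_dvf = analytic_dvf(spec, 1),
                 true_ventilation = truth, spect_like = spect, spec = spec),
            class = "ventimap_phantom_subject")
}

#' @export
print.ventimap_phantom_subject <- function(x, ...) {
  cat(sprintf("<ventimap_phantom_subject> %s: %s grid, %d lung voxels at exhale\n",
              x$id, paste(x$spec$shape, collapse = "x"),
              sum(x$exhale_mask$values)))
  invisible(x)
}

#' Generate a cohort of phantom subjects
#'
#' Per-subject anatomy and ventilation-pattern parameters are drawn by seeded
#' jitter around a base specification: lung positions and sizes, base and
#' gradient expansion, number/placement/depth of ventilation defects, and the
#' anatomical texture seed all vary between subjects; image noise seeds are
#' derived per subject.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param base_spec a [phantom_spec()] serving as the cohort template.
#' @param seed cohort master seed.
#' @param render if `FALSE`, return only the per-subject specs (cheap; useful
#'   for split/audit logic).
#' @param spect_args passed to [make_subject()].
#' @return A list of `ventimap_phantom_subject` (or of specs).
#' @export
make_cohort <- function(n_subjects, base_spec = phantom_spec(), seed = 1L,
                        render = TRUE, spect_args = list()) {
  if (n_subjects < 1)
    vm_stop("n_subjects must be >= 1", "ventimap_parameter_error")
  specs <- with_seed(derive_seed(seed, "cohort_jitter"), {
    lapply(seq_len(n_subjects), function(s) {
      sp <- base_spec
      ext <- (sp$shape - 1) * sp$spacing
      for (l in 1:2) {
        sp$lung_centers[[l]] <- sp$lung_centers[[l]] +
          runif(3, -3, 3) * ext / c(190, 190, 126)
        sp$lung_semiaxes[[l]] <- sp$lung_semiaxes[[l]] * runif(3, 0.92, 1.08)
      }
      sp$a0 <- runif(1, 0.10, 0.20)
      sp$a1 <- runif(1, 0.05, 0.15)
      nd <- sample(0:2, 1)
      sp$defects <- lapply(seq_len(nd), function(i) {
        l <- sample(1:2, 1)
        list(center = sp$lung_centers[[l]][1:2] +
               runif(2, -0.5, 0.5) * sp$lung_semiaxes[[l]][1:2],
             radius = runif(1, 10, 20), depression = runif(1, 0.4, 0.9))
      })
      sp$texture_seed <- sample.int(2^30, 1)
      sp$seed <- sample.int(2^30, 1)
      validate_phantom_spec(sp)
      sp
    })
  })
  if (!render) return(specs)
  lapply(seq_len(n_subjects), function(s)
    make_subject(specs[[s]], id = sprintf("subject%02d", s),
                 spect_args = spect_args))
}

#' Ordered 10-phase series of co-registered volumes
#'
#' @param phases named list of exactly 10 [new_volume()] objects labelled
#'   `T00` through `T90`; `T00` is peak inhale and `T50` peak exhale.
#' @return An object of class `ventimap_phase_series`.
#' @export
new_phase_series <- function(phases) {
  labels <- sprintf("T%02d", seq(0, 90, by = 10))
  if (length(phases) != 10L)
    vm_stop("a phase series has exactly 10 phases", "ventimap_format_error")
  if (is.null(names(phases))) names(phases) <- labels
  if (!identical(names(phases), labels))
    vm_stop("phases must be labelled T00..T90 in order", "ventimap_format_error")
  for (p in phases) {
    stopifnot(inherits(p, "ventimap_volume"))
    check_same_geometry(p, phases[[1]], "phases of a series")
  }
  structure(list(phases = phases,
                 geometry = vol_geometry(phases[[1]])),
            class = "ventimap_phase_series")
}
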