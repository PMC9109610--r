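test_that("Jacobian ventilation is J - 1 inside the mask and zero outside", {
  zf <- new_vector_field(array(0, dim = c(8, 8, 8, 3)), spacing = c(2, 2, 2))
  m <- array(FALSE, dim = c(8, 8, 8)); m[3:6, 3:6, 3:6] <- TRUE
  mask <- new_mask(m, spacing = c(2, 2, 2))
  vi <- ventilation_jacobian(zf, mask)
  expect_true(all(vi$values == 0))
  expect_identical(vi$provenance, "JAC")

  # componentwise affine expansion u = 0.1 x: J - 1 = 1.1^3 - 1 = 0.331
  u <- array(0, dim = c(8, 8, 8, 3))
  ax <- seq(0, 14, by = 2)
  u[, , , 1] <- 0.1 * rep(ax, times = 64)
  u[, , , 2] <- 0.1 * rep(rep(ax, each = 8), times = 8)
  u[, , , 3] <- 0.1 * rep(ax, each = 64)
  vi2 <- ventilation_jacobian(new_vector_field(u, spacing = c(2, 2, 2)), mask)
  expect_lt(max(abs(vi2$values[m] - (1.1^3 - 1))), 1e-9)
  expect_true(all(vi2$values[!m] == 0))
})

test_that("phantom closed form: VI_JAC from the true field equals a(x, y)", {
  sub <- clean_subject()
  a3 <- array(expansion_field(sub$spec), dim = sub$spec$shape)
  vi <- ventilation_jacobian(sub$true_dvf, sub$exhale_mask)
  expect_lt(max(abs(vi$values - a3)[sub$exhale_mask$values]), 1e-6)
  expect_gte(spearman_masked(vi, sub$true_ventilation, sub$exhale_mask), 0.999)
})

test_that("density-change ventilation reproduces the closed-form hand case", {
  # one masked voxel with HU_T50 = -800 and a field that lands the mapped
  # cell on inhale voxels of exactly -850 HU
  d <- c(5, 5, 5)
  ex <- new_volume(array(-800, dim = d), spacing = c(2, 2, 2),
                   intensity_kind = "HU")
  inh <- new_volume(array(-850, dim = d), spacing = c(2, 2, 2),
                    intensity_kind = "HU")
  zf <- new_vector_field(array(0, dim = c(d, 3)), spacing = c(2, 2, 2))
  m <- array(FALSE, dim = d); m[3, 3, 3] <- TRUE
  vi <- ventilation_density_change(inh, ex, zf, new_mask(m, c(2, 2, 2)))
  expect_equal(vi$values[3, 3, 3], 1000 * (-850 + 800) / (-800 * (1000 - 850)),
               tolerance = 1e-12)
  expect_equal(vi$values[3, 3, 3], 0.41667, tolerance = 1e-4)

  # no density change -> zero ventilation
  vi0 <- ventilation_density_change(ex, ex, zf, new_mask(m, c(2, 2, 2)))
  expect_equal(vi0$values[3, 3, 3], 0)
})

test_that("VOI mean matches exhaustive enumeration under uniform expansion", {
  # inhale grid at 1 mm; exhale voxel cell of edge 2 mm maps onto itself
  # (zero field), bounding box covers exactly 2x2x2 inhale voxel centres
  set.seed(8)
  iv <- array(rnorm(16^3), dim = c(16, 16, 16))
  inh <- new_volume(iv, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    intensity_kind = "HU")
  ex_geom <- list(shape = c(8L, 8L, 8L), spacing = c(2, 2, 2),
                  origin = c(0.5, 0.5, 0.5))
  zf <- new_vector_field(array(0, dim = c(8, 8, 8, 3)), spacing = c(2, 2, 2),
                         origin = c(0.5, 0.5, 0.5))
  got <- voi_mean_inhale(inh, zf, c(3, 3, 3))
  # exhale voxel (3,3,3) centre = 4.5 mm, cell [3.5, 5.5]; inhale centres at
  # 4 and 5 mm in each axis -> indices 5:6 (1-based)
  expect_equal(got, mean(iv[5:6, 5:6, 5:6]), tolerance = 1e-12)

  # matching grids, zero field: the VOI is the voxel itself
  inh2 <- new_volume(iv[1:8, 1:8, 1:8], spacing = c(2, 2, 2),
                     origin = c(0.5, 0.5, 0.5), intensity_kind = "HU")
  expect_equal(voi_mean_inhale(inh2, zf, c(4, 4, 4)), iv[4, 4, 4],
               tolerance = 1e-12)
})

test_that("mass-conserving phantom ties the HU estimate to 1.25 * (J - 1)", {
  sub <- clean_subject()
  vj <- ventilation_jacobian(sub$true_dvf, sub$exhale_mask)
  vh <- ventilation_density_change(sub$series$phases$T00,
                                   sub$series$phases$T50, sub$true_dvf,
                                   sub$exhale_mask,
                                   inhale_mask = sub$lung_masks$T00)
  core <- lung_core(sub, 2)
  rel <- abs(vh$values - 1.25 * vj$values)[core] /
    pmax(abs(1.25 * vj$values[core]), 1e-9)
  expect_lt(max(rel), 0.02)
  expect_gte(spearman_masked(vh, sub$true_ventilation, sub$exhale_mask), 0.99)
})

test_that("denominator guards zero offending voxels and flag bad runs", {
  d <- c(5, 5, 5)
  ex_vals <- array(-800, dim = d); ex_vals[3, 3, 3] <- 0  # vessel-like voxel
  ex <- new_volume(ex_vals, spacing = c(2, 2, 2), intensity_kind = "HU")
  inh <- new_volume(array(-850, dim = d), spacing = c(2, 2, 2),
                    intensity_kind = "HU")
  zf <- new_vector_field(array(0, dim = c(d, 3)), spacing = c(2, 2, 2))
  m <- array(TRUE, dim = d)
  vi <- ventilation_density_change(inh, ex, zf, new_mask(m, c(2, 2, 2)))
  expect_equal(vi$values[3, 3, 3], 0)
  expect_equal(attr(vi, "n_guarded"), 1L)

  # all-zero exhale HU: every voxel guarded -> data error
  ex0 <- new_volume(array(0, dim = d), spacing = c(2, 2, 2),
                    intensity_kind = "HU")
  expect_error(ventilation_density_change(inh, ex0, zf,
                                          new_mask(m, c(2, 2, 2))),
               class = "ventimap_data_error")
})

test_that("post-processing satisfies its contracts", {
  sub <- clean_subject()
  mask <- sub$exhale_mask
  vi <- ventilation_jacobian(sub$true_dvf, mask)

  # scale invariance (to floating-point round-off of the normalisation)
  pp1 <- postprocess(vi, mask, filter_size = 9)
  vi_k <- new_ventilation_image(vi$values * 7.25, mask, "JAC",
                                spacing = vi$spacing, origin = vi$origin)
  pp2 <- postprocess(vi_k, mask, filter_size = 9)
  expect_equal(pp1$values, pp2$values, tolerance = 1e-12)

  # normalisation: in-mask 90th percentile is exactly 1 before filtering
  pn <- postprocess(vi, mask, filter_size = 1)
  expect_equal(unname(quantile(pn$values[mask$values], 0.9, type = 7)), 1,
               tolerance = 1e-12)
  expect_true(pn$normalized)
  expect_true(all(pn$values[!mask$values] == 0))

  # median filter leaves a constant-in-mask image unchanged in the interior
  cv <- new_ventilation_image(array(3, dim = dim(mask$values)) *
                                (mask$values + 0), mask, "REF",
                              spacing = mask$spacing, origin = mask$origin)
  pc <- postprocess(cv, mask, filter_size = 9)
  core <- lung_core(sub, 5)  # window fully inside the mask: median of 1s
  expect_true(all(abs(pc$values[core] - 1) < 1e-12))

  expect_error(postprocess(vi, mask, filter_size = 4),
               class = "ventimap_parameter_error")
  neg <- new_ventilation_image(-abs(vi$values), mask, "JAC",
                               spacing = vi$spacing, origin = vi$origin)
  expect_error(postprocess(neg, mask), class = "ventimap_data_error")
})

test_that("normalisation happens before median filtering (pinned order)", {
  # an image whose 90th percentile changes under filtering: if filtering came
  # first, the in-mask p90 after postprocess would be exactly 1; with the
  # implemented order (normalise, then filter) it generally is not.
  set.seed(9)
  d <- c(24, 24, 24)
  m <- array(FALSE, dim = d); m[3:22, 3:22, 3:22] <- TRUE
  mask <- new_mask(m, c(2, 2, 2))
  vals <- array(0, dim = d)
  vals[m] <- rexp(sum(m))   # skewed so the filter moves the percentile
  vi <- new_ventilation_image(vals, mask, "REF", spacing = c(2, 2, 2))
  pp <- postprocess(vi, mask, filter_size = 9)
  p90 <- unname(quantile(pp$values[m], 0.9, type = 7))
  expect_gt(abs(p90 - 1), 1e-3)
  # while the unfiltered chain leaves it at exactly 1
  p90n <- unname(quantile(postprocess(vi, mask, filter_size = 1)$values[m],
                          0.9, type = 7))
  expect_equal(p90n, 1, tolerance = 1e-12)
})
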