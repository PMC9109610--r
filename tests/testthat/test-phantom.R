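test_that("expansion field follows its gradient + defect construction", {
  spec <- phantom_spec(a0 = 0.2, a1 = 0, defects = list())
  a <- expansion_field(spec)
  expect_true(all(abs(a - 0.2) < 1e-12))

  spec2 <- phantom_spec(a0 = 0.1, a1 = 0.2, defects = list())
  a2 <- expansion_field(spec2)
  expect_equal(a2[1, 1], 0.1, tolerance = 1e-12)
  expect_equal(a2[1, ncol(a2)], 0.3, tolerance = 1e-12)

  # full-depression defect takes the field to ~0 near the blob centre (the
  # nearest voxel centre sits within half a voxel of the exact minimum)
  spec3 <- phantom_spec(a0 = 0.2, a1 = 0,
                        defects = list(list(center = c(0.5, 0.5), radius = 20,
                                            depression = 1.0)))
  a3 <- expansion_field(spec3)
  expect_lt(min(abs(a3)), 0.005)
})

test_that("cosine phase weights peak at T00 and vanish at T50, symmetrically", {
  w <- phase_weight_schedule(0:9)
  expect_equal(w[1], 1)
  expect_equal(w[6], 0)
  expect_equal(w[3], w[9])   # p = 2 and p = 8
  expect_error(phase_weight_schedule(10), class = "ventimap_parameter_error")
  expect_error(phase_weight_schedule(-1), class = "ventimap_parameter_error")
})

test_that("analytic field is zero at w = 0 and affine in z inside the lungs", {
  spec <- phantom_spec(noise_sd = 0, shading_amplitude = 0,
                       texture_amplitude = 0, a0 = 0.2, a1 = 0,
                       defects = list())
  z <- analytic_dvf(spec, 0)
  expect_true(all(z$u == 0))
  expect_error(analytic_dvf(spec, 1.5), class = "ventimap_parameter_error")

  dvf <- analytic_dvf(spec, 1)
  # pick an interior lung voxel and check u_z = a * (z - z0)
  mem <- ventimap:::phantom_membership(spec, 0)
  core <- ventimap:::erode26(mem$lung, 3)
  idx <- which(core, arr.ind = TRUE)[1, ]
  zmm <- spec$origin[3] + (idx[3] - 1) * spec$spacing[3]
  expect_equal(dvf$u[idx[1], idx[2], idx[3], 3],
               unname(0.2 * (zmm - spec$z0)), tolerance = 1e-10)
  expect_true(all(dvf$u[, , , 1] == 0) && all(dvf$u[, , , 2] == 0))
})

test_that("numeric Jacobian of the analytic field matches 1 + w*a in the core", {
  sub <- clean_subject()
  spec <- sub$spec
  a3 <- array(expansion_field(spec), dim = spec$shape)
  for (w in c(0.4, 1)) {
    J <- jacobian_determinant(analytic_dvf(spec, w))$values
    core <- lung_core(sub, 2)
    expect_lt(max(abs(J - (1 + w * a3))[core]), 1e-6)
  }
})

test_that("rendered phases obey air-tissue mass conservation", {
  spec <- phantom_spec(noise_sd = 0, shading_amplitude = 0,
                       texture_amplitude = 0)
  a3 <- array(expansion_field(spec), dim = spec$shape)
  for (w in c(0, 0.5, 1)) {
    ph <- render_phase(spec, w)
    mem <- ventimap:::phantom_membership(spec, w)
    resid <- (1000 + ph$values[mem$lung]) * (1 + w * a3[mem$lung]) -
      (1000 + spec$hu_lung_ex)
    expect_lt(max(abs(resid)), 1e-9)
  }
  # hand case: w = 1, a = 0.25, HU_ex = -800 -> (1000-800)/1.25 - 1000 = -840
  spec2 <- phantom_spec(a0 = 0.25, a1 = 0, defects = list(), noise_sd = 0,
                        shading_amplitude = 0, texture_amplitude = 0)
  ph2 <- render_phase(spec2, 1)
  mem2 <- ventimap:::phantom_membership(spec2, 1)
  expect_lt(max(abs(ph2$values[mem2$lung] - (-840))), 1e-9)
})

test_that("rendering is deterministic given the seed and noise-only stochastic", {
  spec <- phantom_spec(seed = 42)
  p1 <- render_phase(spec, 0.5, phase_index = 2L)
  p2 <- render_phase(spec, 0.5, phase_index = 2L)
  expect_identical(p1$values, p2$values)

  spec_b <- phantom_spec(seed = 43)
  sub_a <- make_subject(phantom_spec(seed = 42,
                                     shape = c(48, 48, 32), spacing = c(4, 4, 4)))
  sub_b <- make_subject(phantom_spec(seed = 43,
                                     shape = c(48, 48, 32), spacing = c(4, 4, 4)))
  # anatomy/truth identical, noise different
  expect_identical(sub_a$exhale_mask$values, sub_b$exhale_mask$values)
  expect_identical(sub_a$true_ventilation$values, sub_b$true_ventilation$values)
  expect_false(identical(sub_a$series$phases$T00$values,
                         sub_b$series$phases$T00$values))
})

test_that("mass-compensated warp-back of peak inhale reproduces peak exhale", {
  sub <- clean_subject()
  a3 <- array(expansion_field(sub$spec), dim = sub$spec$shape)
  w <- warp_volume(sub$series$phases$T00, sub$true_dvf)
  recon <- (1000 + w$values) * (1 + a3) - 1000
  core <- lung_core(sub, 2)
  expect_lt(mean(abs(recon - sub$series$phases$T50$values)[core]), 2)
})

test_that("subject assembly ties truth, masks and the analytic field together", {
  spec <- phantom_spec(shape = c(48, 48, 32), spacing = c(4, 4, 4),
                       a0 = 0.2, a1 = 0, defects = list(), noise_sd = 0,
                       shading_amplitude = 0, texture_amplitude = 0)
  sub <- make_subject(spec)
  m <- sub$exhale_mask$values
  expect_true(all(abs(sub$true_ventilation$values[m] - 0.2) < 1e-12))
  expect_true(all(sub$true_ventilation$values[!m] == 0))
  # T50 is the exhale anatomy exactly
  expect_identical(sub$lung_masks$T50$values, m)
  expect_identical(sub$series$phases$T50$values,
                   render_phase(spec, 0, phase_index = 5L)$values)
  # segment_lungs on the noiseless exhale volume agrees with the geometry
  seg <- segment_lungs(sub$series$phases$T50)
  expect_gte(2 * sum(seg$values & m) / (sum(seg$values) + sum(m)), 0.99)
})

test_that("SPECT-like degradation keeps fidelity and its contracts", {
  sub <- clean_subject()
  tr <- sub$true_ventilation
  ident <- degrade_to_spect_like(tr, coarsen_factor = 1, blur_sigma_mm = 0,
                                 noise_scale = 0, seed = 1)
  expect_lt(max(abs(ident$values - tr$values)), 1e-12)
  deg <- degrade_to_spect_like(tr, seed = 7)
  expect_true(all(deg$values >= 0))
  expect_gte(spearman_masked(tr, deg, sub$exhale_mask), 0.8)
})

test_that("cohorts are reproducible and anatomically distinct", {
  base <- phantom_spec(shape = c(48, 48, 32), spacing = c(4, 4, 4))
  s1 <- make_cohort(28, base, seed = 17, render = FALSE)
  s2 <- make_cohort(28, base, seed = 17, render = FALSE)
  expect_identical(s1, s2)
  expect_error(make_cohort(0), class = "ventimap_parameter_error")

  subs <- make_cohort(4, base, seed = 17)
  for (i in 1:3) for (j in (i + 1):4) {
    a <- subs[[i]]$exhale_mask$values
    b <- subs[[j]]$exhale_mask$values
    expect_lt(2 * sum(a & b) / (sum(a) + sum(b)), 1)
  }
})
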