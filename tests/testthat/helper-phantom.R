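# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Clean noiseless phantom at full working resolution: closed-form checks.
clean_subject <- function() fixture("clean_subject", function()
  make_subject(phantom_spec(noise_sd = 0, shading_amplitude = 0,
                            texture_amplitude = 0)))

# Noiseless but textured phantom (registration needs intensity structure).
textured_subject <- function() fixture("textured_subject", function()
  make_subject(phantom_spec(noise_sd = 0, shading_amplitude = 0)))

# Small cohort for the learning tests.
small_cohort <- function() fixture("small_cohort", function()
  make_cohort(8, phantom_spec(shape = c(64, 64, 32), spacing = c(3, 3, 4)),
              seed = 11))

# Interior lung voxels: mask eroded so that finite-difference stencils and
# mapped-cell averages stay clear of the lung boundary.
lung_core <- function(subject, iter = 2L)
  ventimap:::erode26(subject$exhale_mask$values, iter)

expect_volume_equal <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a$values), dim(b$values))
  expect_lt(max(abs(a$values - b$values)), tol)
  expect_equal(a$spacing, b$spacing, tolerance = 1e-9)
  expect_equal(a$origin, b$origin, tolerance = 1e-9)
}
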