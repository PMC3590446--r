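test_that("rho estimation matches the gray calibration", {
  # independently: rho = R / sqrt(log(q_max / q_min))
  expect_equal(estimate_rho(5, 255, 61), 5 / sqrt(log(255 / 61)))
  expect_equal(estimate_rho(5, 255, 61), 4.18, tolerance = 0.01 / 4.18)
  expect_equal(estimate_rho(30, 255, 61), 25.08, tolerance = 0.01 / 25.08)
  # ln ratio = 1 collapses to R
  expect_equal(estimate_rho(10, exp(1) * 50, 50), 10)
  expect_error(estimate_rho(5, 61, 255), "q_min < q_max")
  expect_error(estimate_rho(-1, 255, 61), "positive")
})

test_that("radial profile interpolates q_max to q_min and decays monotonically", {
  spec <- template_spec("circle", R = 7)
  expect_equal(radial_profile(spec, 0), spec$q_max)
  expect_equal(radial_profile(spec, spec$R), spec$q_min,
               tolerance = 1e-9)
  expect_equal(radial_profile(spec, spec$rho), spec$q_max / exp(1))
  r <- seq(0, spec$R, length.out = 50)
  expect_true(all(diff(radial_profile(spec, r)) < 0))
  expect_error(radial_profile(spec, -0.1), "within")
  expect_error(radial_profile(spec, spec$R + 0.1), "within")
})

test_that("gray-level density has its closed-form boundary values", {
  spec <- template_spec("circle", R = 5)
  expect_equal(gray_level_density(spec, spec$q_max), 0)
  expect_equal(gray_level_density(spec, spec$q_min), 2 * pi * 5)
  # frozen from direct evaluation: 2*pi*5*sqrt(log(255/155)/log(255/61))
  expect_equal(gray_level_density(spec, 155), 18.5339, tolerance = 1e-4)
  expect_error(gray_level_density(spec, 60), "within")
  expect_error(gray_level_density(spec, 256), "within")
})

test_that("offset profile reduces to the radial profile and sets layer radii", {
  spec <- template_spec("sphere", R = 25, v = 7)
  r <- seq(0, 20, length.out = 9)
  expect_equal(offset_profile(spec, r, v = 0), radial_profile(spec, r))
  expect_equal(offset_profile(spec, 0, v = spec$rho), spec$q_max / exp(1))
  # the layer radius solves q_v(R_u) = q_min; root-find as the oracle
  root <- uniroot(function(x) offset_profile(spec, x, 7) - spec$q_min,
                  c(1, 25))$root
  expect_equal(root, sqrt(25^2 - 7^2), tolerance = 1e-6)
  expect_equal(root, 24, tolerance = 1e-6)
})

test_that("template spec enforces its geometric invariants", {
  expect_error(template_spec("circle", R = 5, q_max = 61, q_min = 255))
  expect_error(template_spec("sphere", R = 6, v = 7), "R > v")
  expect_error(template_spec("hollow_sphere", R = 20, hollow_fraction = 1.2))
  spec <- template_spec("circle", R = 12)
  expect_equal(spec$rho, estimate_rho(12, spec$q_max, spec$q_min))
})

test_that("rendered circle stencils have the right support and peak", {
  spec <- template_spec("circle", R = 5)
  tm <- build_template(spec)
  expect_equal(tm$values[tm$center[1], tm$center[2]], spec$q_max)
  expect_true(all(tm$values[tm$support] >= spec$q_min - 1e-9))
  # rasterized-disk area oracle
  expect_lt(abs(sum(tm$support) - pi * 25) / (pi * 25), 0.05)
  # monotone radial decay
  side <- nrow(tm$values)
  r <- sqrt(outer((seq_len(side) - tm$center[1])^2,
                  (seq_len(side) - tm$center[2])^2, "+"))
  o <- order(r[tm$support])
  vals <- tm$values[tm$support][o]
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("semicircle orientations mirror and rotate correctly", {
  s0 <- build_template(template_spec("semicircle", R = 10, angle = 0))
  s180 <- build_template(template_spec("semicircle", R = 10, angle = 180))
  expect_equal(sum(s0$support), sum(s180$support))
  expect_identical(s0$support[nrow(s0$support):1, ], s180$support)
  s90 <- build_template(template_spec("semicircle", R = 10, angle = 90))
  expect_identical(t(s0$support), s90$support)
})

test_that("3D templates stack per-layer profiles and hollow removes the core", {
  spec <- template_spec("sphere", R = 20, v = 7)
  tm <- build_template(spec)
  expect_equal(dim(tm$values)[3], 3L)
  # outer layers span radius sqrt(R^2 - v^2)
  R_u <- sqrt(20^2 - 7^2)
  side <- dim(tm$support)[1]
  r <- sqrt(outer((seq_len(side) - tm$center[1])^2,
                  (seq_len(side) - tm$center[2])^2, "+"))
  expect_true(all(r[tm$support[, , 1]] <= R_u))
  expect_true(any(r[tm$support[, , 2]] > R_u))
  hol <- build_template(template_spec("hollow_sphere", R = 20, v = 7))
  for (k in 1:3) expect_false(any(r[hol$support[, , k]] < 0.75 * 20))
})

test_that("template rendering is deterministic", {
  a <- build_template(template_spec("hollow_sphere", R = 16))
  b <- build_template(template_spec("hollow_sphere", R = 16))
  expect_identical(a, b)
})

test_that("analytic density matches the rendered gray histogram", {
  for (R in c(15, 25)) {
    spec <- template_spec("circle", R = R)
    tm <- build_template(spec)
    vals <- tm$values[tm$support]
    qs <- seq(spec$q_min, spec$q_max, length.out = 600)
    psi <- gray_level_density(spec, qs)
    cdf <- cumsum(psi) / sum(psi)
    ks <- max(abs(ecdf(vals)(qs) - cdf))
    expect_lt(ks, 0.1)
  }
})
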