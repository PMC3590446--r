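test_that("chromosome codec is an exact round trip with big-endian fields", {
  layout <- chromosome_layout("sphere")
  expect_equal(nodtemplate:::layout_total(layout), 28L)
  lay_semi <- chromosome_layout("semicircle")
  expect_equal(nodtemplate:::layout_total(lay_semi), 32L)

  dec <- decode_chromosome(rep(0L, 28), layout)
  expect_equal(dec$center, c(0, 0, 0))
  expect_equal(dec$R, 5)

  # x-field value 3 is the two lowest-order bits of the first 9
  bits <- encode_chromosome(c(3, 0, 0), 5, layout = layout)
  expect_equal(bits[1:9], c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L))

  set.seed(42)
  for (i in 1:100) {
    ctr <- c(sample(0:511, 1), sample(0:511, 1), sample(0:31, 1))
    R <- sample(5:30, 1)
    ang <- sample(0:15, 1) * 22.5
    b <- encode_chromosome(ctr, R, ang, lay_semi)
    d <- decode_chromosome(b, lay_semi)
    expect_equal(d$center, ctr)
    expect_equal(d$R, R)
    expect_equal(d$angle, ang)
    expect_equal(encode_chromosome(d$center, d$R, d$angle, lay_semi), b)
  }
  expect_error(encode_chromosome(c(600, 0, 0), 5, layout = layout), "bits")
  expect_error(encode_chromosome(c(0, 0, 0), 40, layout = layout), "range")
})

test_that("layout fields resize to the volume's axes", {
  expect_message(lay <- chromosome_layout("circle", dims = c(128, 128, 9)),
                 "narrowed")
  expect_equal(c(lay$x, lay$y, lay$z), c(7L, 7L, 4L))
  expect_message(lay2 <- chromosome_layout("circle", dims = c(512, 512, 182)),
                 "widened")
  expect_equal(lay2$z, 8L)
  expect_silent(lay3 <- chromosome_layout("circle", dims = c(512, 512, 32)))
  expect_equal(nodtemplate:::layout_total(lay3), 28L)
})

test_that("similarity is a normalized cross-correlation over the support", {
  a <- matrix(c(1, 3, 2, 4), 2)
  b <- matrix(c(1, 3, 2, 5), 2)
  # frozen hand evaluation: 6.5 / sqrt(5 * 8.75)
  expect_equal(similarity(a, b), 0.9827076, tolerance = 1e-6)
  expect_equal(similarity(a, b), similarity(b, a))

  set.seed(7)
  for (i in 1:50) {
    spec <- template_spec("circle", R = sample(5:20, 1))
    tm <- build_template(spec)
    expect_equal(similarity(tm$values, tm), 1.0)
    expect_equal(similarity(255 - tm$values, tm), -1.0)
    # affine gray rescaling with positive gain leaves the score unchanged
    gain <- runif(1, 0.1, 5); off <- runif(1, -40, 40)
    expect_equal(similarity(gain * tm$values + off, tm), 1.0)
  }
  expect_true(is.na(similarity(matrix(5, 2, 2), matrix(1:4, 2))))
  expect_error(similarity(matrix(1), matrix(1)), "2 support")
})

test_that("fitness scores planted templates and rejects degenerate windows", {
  spec <- template_spec("circle", R = 6)
  vol <- planted_template_volume(spec, c(100, 100, 5), c(50, 60, 2))
  cfg <- ga_config()
  expect_equal(fitness(vol, list(center = c(50, 60, 2), R = 6, angle = NULL),
                       "circle", cfg), 1.0)
  # uniform background window: undefined variance
  expect_identical(fitness(vol, list(center = c(15, 15, 2), R = 6,
                                     angle = NULL), "circle", cfg), -Inf)
  # window out of bounds
  expect_identical(fitness(vol, list(center = c(2, 2, 2), R = 6,
                                     angle = NULL), "circle", cfg), -Inf)
  # additive noise degrades the score gracefully
  set.seed(3)
  noisy <- vol
  noisy$data <- noisy$data + rnorm(length(noisy$data), 0, 5)
  expect_gt(fitness(noisy, list(center = c(50, 60, 2), R = 6, angle = NULL),
                    "circle", cfg), 0.9)
})

test_that("repair maps locations to the nearest search-space voxel", {
  space <- rbind(c(10L, 10L, 0L))
  expect_equal(repair_location(c(10, 10, 0), space), c(10L, 10L, 0L))
  expect_equal(repair_location(c(500, 3, 9), space), c(10L, 10L, 0L))
  space2 <- rbind(c(0L, 0L, 0L), c(4L, 0L, 0L))
  expect_equal(repair_location(c(1, 0, 0), space2), c(0L, 0L, 0L))
  # equidistant: lexicographic (x, y, z) tie-break
  expect_equal(repair_location(c(2, 0, 0), space2), c(0L, 0L, 0L))
  expect_error(repair_location(c(0, 0, 0), matrix(integer(), 0, 3)), "empty")
})

test_that("GA search recovers planted circles on a toy phantom", {
  nods <- data.frame(shape = "circle", x = c(14, 40), y = c(14, 40),
                     z = c(1, 1), R = c(6, 10), angle = NA)
  ph <- toy_phantom(nods, dims = c(56, 56, 3))
  sp <- space_from_threshold(ph$volume, 40)
  out <- suppressMessages(
    ga_search(ph$volume, sp, "circle", toy_ga_config(seed = 5)))
  expect_gt(nrow(out), 0)
  for (i in 1:2) {
    d <- sqrt((out$x - nods$x[i])^2 + (out$y - nods$y[i])^2 +
                (out$z - nods$z[i])^2)
    j <- which.min(d)
    expect_lte(d[j], 2)
    expect_lte(abs(out$R[j] - nods$R[i]), 2)
  }
  # all candidates exceed the threshold and sit inside the search space
  expect_true(all(out$similarity > 0.8))
  key <- paste(out$x, out$y, out$z)
  expect_true(all(key %in% paste(sp$voxels[, 1], sp$voxels[, 2],
                                 sp$voxels[, 3])))
})

test_that("GA search is a pure function of inputs and seed", {
  ph <- toy_phantom()
  sp <- space_from_threshold(ph$volume, 40)
  a <- suppressMessages(ga_search(ph$volume, sp, "circle",
                                  toy_ga_config(seed = 9)))
  b <- suppressMessages(ga_search(ph$volume, sp, "circle",
                                  toy_ga_config(seed = 9)))
  expect_identical(a, b)
})

test_that("pure noise below threshold yields no candidates", {
  set.seed(21)
  vol <- nod_volume(array(rnorm(32 * 32 * 3, 50, 3), c(32, 32, 3)))
  sp <- space_from_threshold(vol, 45)
  out <- suppressMessages(ga_search(vol, sp, "circle",
                                    toy_ga_config(seed = 2)))
  expect_equal(nrow(out), 0L)
})

test_that("every GA harvest appears in the exhaustive harvest", {
  ph <- toy_phantom(data.frame(shape = "circle", x = c(10, 22), y = c(10, 22),
                               z = c(1, 1), R = c(5, 7), angle = NA))
  sp <- space_from_threshold(ph$volume, 40)
  cfg <- toy_ga_config(seed = 4)
  ga_raw <- suppressMessages(ga_search(ph$volume, sp, "circle", cfg,
                                       dedup = FALSE))
  ex_raw <- exhaustive_match(ph$volume, sp, "circle",
                             radius_set = 5:12, config = cfg, dedup = FALSE)
  expect_gt(nrow(ga_raw), 0)
  expect_same_candidates(ga_raw, ex_raw)
})

test_that("exhaustive matching finds each planted template exactly once", {
  nods <- data.frame(shape = "circle", x = c(10, 22), y = c(10, 22),
                     z = c(1, 1), R = c(5, 7), angle = NA)
  ph <- toy_phantom(nods)
  sp <- space_from_threshold(ph$volume, 40)
  ex <- exhaustive_match(ph$volume, sp, "circle", radius_set = 5:12,
                         config = toy_ga_config())
  expect_equal(nrow(ex), 2L)
  got <- ex[order(ex$x), ]
  expect_equal(got$x, nods$x)
  expect_equal(got$R, nods$R)
  expect_equal(got$similarity, c(1, 1))
})
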