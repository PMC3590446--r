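# Fixtures are generated in code at test time.

# Phantom with a few solid circles on a small lattice, no noise unless asked.
toy_phantom <- function(nodules = data.frame(shape = "circle", x = 16, y = 16,
                                             z = 1, R = 6, angle = NA),
                        dims = c(32, 32, 3), noise_sigma = 0, seed = 1, ...) {
  make_phantom(dims = dims, nodules = nodules, noise_sigma = noise_sigma,
               seed = seed, ...)
}

# A rendered circle template embedded in a larger flat volume.
planted_template_volume <- function(spec, dims, center, background = 20) {
  tm <- build_template(spec)
  off <- nodtemplate:::template_offsets(tm)
  arr <- array(background, dims)
  idx <- cbind(center[1] + off$offx + 1L, center[2] + off$offy + 1L,
               center[3] + off$offz + 1L)
  arr[idx] <- off$values
  nod_volume(arr)
}

# Rasterized binary shapes for feature-geometry oracles.
raster_disk <- function(R, side = 2 * R + 11) {
  c0 <- (side + 1) / 2
  xy <- expand.grid(x = seq_len(side), y = seq_len(side))
  m <- matrix(sqrt((xy$x - c0)^2 + (xy$y - c0)^2) <= R, side, side)
  list(mask = m, center0 = c(c0 - 1, c0 - 1))
}

raster_ellipse <- function(a, b, side = 2 * max(a, b) + 11) {
  c0 <- (side + 1) / 2
  xy <- expand.grid(x = seq_len(side), y = seq_len(side))
  m <- matrix(((xy$x - c0) / a)^2 + ((xy$y - c0) / b)^2 <= 1, side, side)
  list(mask = m, center0 = c(c0 - 1, c0 - 1))
}

raster_square <- function(w, side = 2 * w + 11) {
  c0 <- (side + 1) / 2
  xy <- expand.grid(x = seq_len(side), y = seq_len(side))
  m <- matrix(abs(xy$x - c0) <= w & abs(xy$y - c0) <= w, side, side)
  list(mask = m, center0 = c(c0 - 1, c0 - 1))
}

# Fast config for GA tests on toys.
toy_ga_config <- function(...) {
  ga_config(population_size = 40, generations = 20, radius_range = c(5, 12),
            ...)
}

expect_same_candidates <- function(a, b) {
  key <- function(df) paste(df$x, df$y, df$z, df$shape, df$R, df$angle,
                            sep = "|")
  expect_true(all(key(a) %in% key(b)))
}
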