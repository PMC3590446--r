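test_that("ray-cast distances match geometry oracles", {
  d <- raster_disk(10)
  dist <- radial_distances(d$mask, d$center0)
  expect_length(dist, 8L)
  expect_true(all(abs(dist - 10) <= 0.5))
  expect_equal(radial_nonuniformity(dist), 0, tolerance = 0.5)

  sq <- raster_square(8)
  ds <- radial_distances(sq$mask, sq$center0)
  expect_true(all(abs(ds[c(1, 3, 5, 7)] - 8) <= 1))        # axis rays
  expect_true(all(abs(ds[c(2, 4, 6, 8)] - 8 * sqrt(2)) <= 1))  # diagonals

  el <- raster_ellipse(20, 10)
  de <- radial_distances(el$mask, el$center0)
  expect_equal(max(de), 20, tolerance = 1)
  expect_equal(min(de), 10, tolerance = 1)
  expect_equal(radial_nonuniformity(de), 10, tolerance = 1)

  expect_error(radial_distances(d$mask, c(0, 0)), "background")
})

test_that("radial nonuniformity is max minus min", {
  expect_equal(radial_nonuniformity(c(3, 5, 4, 7, 3, 4, 5, 6)), 4)
  expect_error(radial_nonuniformity(3), "at least 2")
})

test_that("gray features use the template support with a lower 10th percentile", {
  vol <- nod_volume(array(100, c(30, 30, 3)))
  cand <- list(shape = "circle", x = 14, y = 14, z = 1, R = 5, angle = NA)
  gf <- gray_features(vol, cand)
  expect_equal(unname(gf), c(100, 100))

  # the stated percentile convention on a 10-point support
  expect_equal(as.numeric(quantile(seq(10, 100, 10), 0.10, type = 1)), 10)

  spec <- template_spec("circle", R = 10)
  vol2 <- planted_template_volume(spec, c(40, 40, 1), c(20, 20, 0))
  gf2 <- gray_features(vol2, list(shape = "circle", x = 20, y = 20, z = 0,
                                  R = 10, angle = NA))
  tm <- build_template(spec)
  expect_equal(unname(gf2["q_ave"]), mean(tm$values[tm$support]))
  expect_error(gray_features(vol2, list(shape = "circle", x = 2, y = 2,
                                        z = 0, R = 10, angle = NA)),
               "outside")
})

test_that("feature extraction is driven by the mask, not the gray scores", {
  ph <- toy_phantom(data.frame(shape = "circle", x = 16, y = 16, z = 1,
                               R = 8, angle = NA), dims = c(36, 36, 3))
  cands <- candidate_table(x = 16L, y = 16L, z = 1L, shape = "circle",
                           R = 8, similarity = 0.95)
  f1 <- extract_features(ph$volume, ph$mask, cands)
  cands$similarity <- 0.5
  f2 <- extract_features(ph$volume, ph$mask, cands)
  expect_equal(f1[, c("U", "q_ave", "q_10")], f2[, c("U", "q_ave", "q_10")])
  expect_lt(f1$U, 1)
})

test_that("LCG fitting recovers known generators", {
  set.seed(101)
  x <- rnorm(2000, 5, 1)
  fit <- fit_lcg(x, n_pos = 1, n_neg = 0, seed = 1)
  expect_lt(abs(fit$means[1] - 5), 0.1)
  expect_lt(abs(fit$sds[1] - 1), 0.1)
  # single positive component reduces to the closed-form Gaussian MLE
  expect_equal(fit$means[1], mean(x), tolerance = 1e-6)
  expect_equal(fit$sds[1], sqrt(mean((x - mean(x))^2)), tolerance = 1e-4)

  y <- c(rnorm(2000, 2, 1), rnorm(2000, 8, 1))
  fit2 <- fit_lcg(y, n_pos = 2, n_neg = 0, seed = 1)
  expect_lt(abs(sort(fit2$means)[1] - 2), 0.2)
  expect_lt(abs(sort(fit2$means)[2] - 8), 0.2)

  expect_error(fit_lcg(rep(3, 50), 1, 0), "degenerate")
  expect_error(fit_lcg(rnorm(3), 2, 1), "samples")
})

test_that("fitted LCG densities are non-negative and normalized", {
  set.seed(55)
  x <- c(rnorm(300, 10, 2), rnorm(150, 18, 1.5))
  for (nn in 0:2) {
    fit <- fit_lcg(x, n_pos = 2, n_neg = nn, seed = 3)
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    grid <- seq(min(x) - 6, max(x) + 6, length.out = 2000)
    dens <- lcg_eval(fit, grid)
    expect_gt(min(dens), -1e-6)
    expect_equal(sum(dens) * diff(grid[1:2]), 1, tolerance = 0.02)
    expect_equal(fit$n_neg, nn)
    expect_length(fit$weights, 2 + nn)
  }
  # the positive-phase log-likelihood never decreases
  fit <- fit_lcg(x, n_pos = 2, n_neg = 1, seed = 3)
  expect_true(all(diff(fit$loglik) > -1e-8))
})

test_that("the positive-only fit agrees with a reference EM implementation", {
  skip_if_not_installed("mclust")
  set.seed(77)
  x <- c(rnorm(800, 0, 1), rnorm(800, 6, 1.5))
  fit <- fit_lcg(x, n_pos = 2, n_neg = 0, seed = 2)
  # my optimum must be a fixed point of mclust's EM for the same model
  w <- fit$weights
  ref <- mclust::emV(data = x,
                     parameters = list(pro = w / sum(w), mean = fit$means,
                                       variance = list(modelName = "V", d = 1,
                                                       G = 2,
                                                       sigmasq = fit$sds^2)))
  expect_lt(abs(ref$loglik - max(fit$loglik)), 1e-3 * abs(ref$loglik))
})

test_that("classifier training and Bayes rule behave as specified", {
  tr <- make_feature_training_set(n_per_class = 20, seed = 5)
  model <- train_classifier(tr, seed = 5)
  model2 <- train_classifier(tr, seed = 5)
  expect_identical(model, model2)

  # JSON round trip preserves the model exactly
  path <- tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  for (cl in c("TPN", "FPN"))
    for (f in model$features) {
      expect_equal(back$classes[[cl]][[f]]$weights,
                   model$classes[[cl]][[f]]$weights)
      expect_equal(back$classes[[cl]][[f]]$means,
                   model$classes[[cl]][[f]]$means)
    }

  expect_error(train_classifier(tr[tr$label == "TPN", ]), "2 training")
})

test_that("posterior arithmetic, tie-breaking and the wall path are exact", {
  gauss_model <- function(peaks_tpn, peaks_fpn) {
    dens <- function(peak) {
      # single Gaussian whose density at its mean is `peak`
      structure(list(weights = 1, means = 0, sds = 1 / (peak * sqrt(2 * pi)),
                     n_pos = 1L, n_neg = 0L, range = c(-1, 1), loglik = 0),
                class = "lcg_density")
    }
    structure(list(classes = list(
      TPN = list(U = dens(peaks_tpn[1]), q_ave = dens(peaks_tpn[2]),
                 q_10 = dens(peaks_tpn[3])),
      FPN = list(U = dens(peaks_fpn[1]), q_ave = dens(peaks_fpn[2]),
                 q_10 = dens(peaks_fpn[3]))),
      features = c("U", "q_ave", "q_10"), n_pos = 1L, n_neg = 0L, seed = 1L),
      class = "lcg_model")
  }
  feats <- list(U = 0, q_ave = 0, q_10 = 0)
  m <- gauss_model(c(0.2, 0.2, 0.2), c(0.05, 0.05, 0.05))
  res <- classify(feats, m)
  expect_equal(res$posterior, 0.2^3 / (0.2^3 + 0.05^3), tolerance = 1e-9)
  expect_equal(res$label, "TPN")

  # exact tie resolves to FPN
  tie <- classify(feats, gauss_model(c(0.1, 0.1, 0.1), c(0.1, 0.1, 0.1)))
  expect_equal(tie$posterior, 0.5)
  expect_equal(tie$label, "FPN")

  # the wall path ignores U: make U alone favor FPN overwhelmingly
  m2 <- gauss_model(c(1e-9, 0.2, 0.2), c(0.4, 0.05, 0.05))
  expect_equal(classify(feats, m2, wall_nodule = FALSE)$label, "FPN")
  expect_equal(classify(feats, m2, wall_nodule = TRUE)$label, "TPN")
})

test_that("swapping class labels in training flips posteriors", {
  tr <- make_feature_training_set(n_per_class = 20, seed = 8)
  sw <- tr
  sw$label <- ifelse(tr$label == "TPN", "FPN", "TPN")
  sw$group <- NULL; tr2 <- tr; tr2$group <- NULL
  m1 <- train_classifier(tr2, seed = 8)
  m2 <- train_classifier(sw, seed = 8)
  # swap the fitted class densities rather than refit: training is
  # per-class, so the swapped-model classes must mirror exactly
  expect_equal(m2$classes$TPN, m1$classes$FPN)
  feats <- list(U = 5, q_ave = 120, q_10 = 60)
  p1 <- classify(feats, m1)$posterior
  p2 <- classify(feats, m2)$posterior
  expect_equal(p2, 1 - p1, tolerance = 1e-9)
})

test_that("a separable synthetic test set is classified almost perfectly", {
  train <- make_feature_training_set(n_per_class = 20, seed = 31)
  model <- train_classifier(train, seed = 31)
  test <- make_feature_training_set(n_per_class = 200, seed = 32)
  correct <- 0L
  for (i in seq_len(nrow(test))) {
    res <- classify(test[i, ], model,
                    wall_nodule = test$group[i] == "wall_TPN")
    correct <- correct + (res$label == test$label[i])
  }
  expect_gte(correct / nrow(test), 0.95)
})
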