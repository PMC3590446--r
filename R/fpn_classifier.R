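#' Center-to-border distances along sampled directions
#'
#' Casts rays from the candidate center across a binary object mask and
#' measures, for each direction `theta_k = k * 360 / n_dirs` degrees, the
#' distance to the border of the segmented object: the ray advances in
#' steps of `step` pixels with bilinear mask interpolation and stops at
#' the first background crossing after the center.
#'
#' @param mask 2D logical or 0/1 numeric matrix (one slice).
#' @param center 0-based `(x, y)` position, must lie on foreground.
#' @param n_dirs number of directions (default 8).
#' @param step ray step in pixels.
#' @return numeric vector of `n_dirs` distances in pixels.
#' @export
radial_distances <- function(mask, center, n_dirs = 8, step = 0.25) {
  m <- as.matrix(mask) * 1
  lookup <- function(x, y) {
    # bilinear, 0-based coordinates; outside the slice counts as background
    x1 <- floor(x); y1 <- floor(y)
    fx <- x - x1; fy <- y - y1
    val <- 0
    for (dd in list(c(0, 0, (1 - fx) * (1 - fy)), c(1, 0, fx * (1 - fy)),
                    c(0, 1, (1 - fx) * fy), c(1, 1, fx * fy))) {
      xi <- x1 + dd[1] + 1; yi <- y1 + dd[2] + 1
      if (xi >= 1 && xi <= nrow(m) && yi >= 1 && yi <= ncol(m))
        val <- val + dd[3] * m[xi, yi]
    }
    val
  }
  if (lookup(center[1], center[2]) < 0.5)
    stop("candidate center lies on mask background")
  max_t <- sqrt(nrow(m)^2 + ncol(m)^2)
  vapply(seq_len(n_dirs) - 1, function(k) {
    th <- k * 2 * pi / n_dirs
    t <- step
    while (t <= max_t &&
           lookup(center[1] + t * cos(th), center[2] + t * sin(th)) >= 0.5)
      t <- t + step
    t - step
  }, numeric(1))
}

#' Radial nonuniformity
#'
#' `U = max(d) - min(d)` over the sampled center-to-border distances: 0
#' for a perfect disk centered on the candidate, large for elongated
#' (vessel-like) objects.
#'
#' @param distances vector of at least 2 distances.
#' @return U in pixels, `>= 0`.
#' @export
radial_nonuniformity <- function(distances) {
  if (length(distances) < 2) stop("need at least 2 distances")
  max(distances) - min(distances)
}

#' Gray-level features over a candidate's template support
#'
#' `q_ave` is the mean gray level of the volume over the candidate's
#' rendered template support; `q_10` is the 10th-percentile gray level
#' with lower-value interpolation (the threshold below which 10% of the
#' support voxels fall).
#'
#' @param vol a [nod_volume()].
#' @param candidate one-row candidate data frame or a list with `shape`,
#'   `x`, `y`, `z`, `R` and optionally `angle`.
#' @param config a [ga_config()] supplying the gray calibration.
#' @return named numeric `c(q_ave, q_10)`.
#' @export
gray_features <- function(vol, candidate, config = ga_config()) {
  spec <- template_spec(candidate$shape, R = candidate$R,
                        q_max = config$q_max, q_min = config$q_min,
                        v = config$v,
                        angle = if (is.na(candidate$angle %||% NA)) 0
                                else candidate$angle,
                        hollow_fraction = config$hollow_fraction)
  tm <- template_offsets(build_template(spec))
  xs <- candidate$x + tm$offx + 1L
  ys <- candidate$y + tm$offy + 1L
  zs <- candidate$z + tm$offz + 1L
  d <- dim(vol$data)
  if (any(xs < 1 | xs > d[1] | ys < 1 | ys > d[2] | zs < 1 | zs > d[3]))
    stop("candidate template support extends outside the volume")
  vals <- vol$data[cbind(xs, ys, zs)]
  c(q_ave = mean(vals),
    q_10 = as.numeric(stats::quantile(vals, 0.10, type = 1)))
}

#' Extract all three nodule features for a candidate table
#'
#' Fills the `U`, `q_ave` and `q_10` columns.  `U` is measured on the
#' candidate-space mask slice through each candidate's center; the gray
#' features are measured on the volume over the template support.
#'
#' @param vol a [nod_volume()].
#' @param mask binary [nod_volume()] (the segmented candidate tissue).
#' @param candidates candidate data frame.
#' @param config a [ga_config()].
#' @param n_dirs directions for [radial_distances()].
#' @return the candidate data frame with feature columns filled.
#' @export
extract_features <- function(vol, mask, candidates, config = ga_config(),
                             n_dirs = 8) {
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    gf <- gray_features(vol, cand, config)
    sl <- mask$data[, , cand$z + 1L] > 0
    d <- radial_distances(sl, c(cand$x, cand$y), n_dirs = n_dirs)
    candidates$U[i] <- radial_nonuniformity(d)
    candidates$q_ave[i] <- gf["q_ave"]
    candidates$q_10[i] <- gf["q_10"]
  }
  candidates
}

#' Fit a linear combination of Gaussians (LCG) to one feature
#'
#' Density model \eqn{f(x) = \sum_i p_i N(x; \mu_i, \sigma_i) - \sum_j
#' n_j N(x; \mu_j, \sigma_j)} with positive weights `p_i > 0`, negative
#' weights `n_j >= 0`, and `sum(p) - sum(n) = 1`.  Fitting is sequential:
#' (1) the positive components are fitted by standard univariate EM
#' (quantile-spread initialization, log-likelihood monotone, convergence
#' at relative change `< tol` or `max_iter` iterations); (2) negative
#' components are placed greedily on the largest lobes where the positive
#' mixture overshoots a kernel estimate of the empirical density, with
#' weights shrunk as needed so the total density stays non-negative over
#' the observed range.  With `n_neg = 0` the fit is a standard Gaussian
#' mixture.
#'
#' @param samples numeric feature samples, at least `2 * (n_pos + n_neg)`
#'   and not all identical.
#' @param n_pos,n_neg numbers of positive / negative components.
#' @param seed RNG seed for the EM initialization jitter.
#' @param max_iter,tol EM stopping rule.
#' @return object of class `lcg_density`: `weights` (signed, summing to
#'   1), `means`, `sds`, `n_pos`, `n_neg`, `range`, `loglik` (positive
#'   phase trace).
#' @export
fit_lcg <- function(samples, n_pos = 2, n_neg = 1, seed = 1,
                    max_iter = 500, tol = 1e-6) {
  x <- as.numeric(samples)
  if (length(x) < 2 * (n_pos + n_neg))
    stop("need at least 2*(n_pos + n_neg) samples")
  if (stats::sd(x) < 1e-12)
    stop("degenerate samples: all values identical")
  if (n_pos < 1) stop("need at least one positive component")

  n <- length(x)
  fit <- with_seed(seed, {
    mu <- as.numeric(stats::quantile(x, (seq_len(n_pos) - 0.5) / n_pos))
    mu <- mu + stats::rnorm(n_pos, 0, 1e-3 * stats::sd(x))
    sig <- rep(stats::sd(x) / n_pos + 1e-6, n_pos)
    w <- rep(1 / n_pos, n_pos)
    ll_trace <- numeric(0)
    var_floor <- max(1e-8, 1e-4 * stats::var(x))
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(n_pos),
                     function(j) w[j] * stats::dnorm(x, mu[j], sig[j]),
                     numeric(n))
      dens <- matrix(dens, nrow = n)
      tot <- pmax(rowSums(dens), 1e-300)
      ll <- sum(log(tot))
      ll_trace <- c(ll_trace, ll)
      if (it > 1 && abs(ll - ll_trace[it - 1]) <
          tol * (abs(ll_trace[it - 1]) + 1e-12)) break
      resp <- dens / tot
      nk <- pmax(colSums(resp), 1e-12)
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sig <- sqrt(pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk,
                       var_floor))
    }
    list(w = w, mu = mu, sig = sig, ll = ll_trace)
  })

  weights <- fit$w; means <- fit$mu; sds <- fit$sig
  if (n_neg > 0) {
    pad <- 3 * stats::sd(x)
    grid <- seq(min(x) - pad, max(x) + pad, length.out = 512)
    dg <- diff(grid[1:2])
    kde <- stats::density(x, from = grid[1], to = grid[length(grid)],
                          n = length(grid))
    femp <- kde$y
    for (j in seq_len(n_neg)) {
      fmod <- lcg_mix(grid, weights, means, sds)
      resid <- fmod - femp            # where the positive mixture overshoots
      if (max(resid) <= 0) { resid <- pmax(resid, 0) + 1e-12 }
      peak <- which.max(resid)
      # contiguous positive lobe around the peak
      lo <- peak; while (lo > 1 && resid[lo - 1] > 0) lo <- lo - 1
      hi <- peak; while (hi < length(grid) && resid[hi + 1] > 0) hi <- hi + 1
      lobe <- lo:hi
      rw <- pmax(resid[lobe], 0)
      mass <- sum(rw) * dg
      mu_n <- sum(grid[lobe] * rw) / sum(rw)
      sd_n <- sqrt(max(sum((grid[lobe] - mu_n)^2 * rw) / sum(rw), dg^2))
      w_n <- min(mass, 0.3)
      # rescale positives so signed weights still sum to 1, then guard
      # non-negativity of the total density by shrinking the new component
      repeat {
        cw <- c(weights / sum(weights) * (1 + w_n), -w_n)
        cm <- c(means, mu_n); cs <- c(sds, sd_n)
        if (min(lcg_mix(grid, cw, cm, cs)) >= -1e-9 || w_n < 1e-6) break
        w_n <- w_n / 2
      }
      weights <- cw; means <- cm; sds <- cs
    }
  }
  structure(list(weights = weights, means = means, sds = sds,
                 n_pos = n_pos, n_neg = n_neg,
                 range = range(x), loglik = fit$ll),
            class = "lcg_density")
}

lcg_mix <- function(x, weights, means, sds) {
  out <- numeric(length(x))
  for (j in seq_along(weights))
    out <- out + weights[j] * stats::dnorm(x, means[j], sds[j])
  out
}

#' Evaluate an LCG density
#'
#' @param model an `lcg_density`.
#' @param x evaluation points.
#' @return density values (may be a hair below 0 from numerics; the
#'   classifier clamps).
#' @export
lcg_eval <- function(model, x) {
  stopifnot(inherits(model, "lcg_density"))
  lcg_mix(x, model$weights, model$means, model$sds)
}

#' @export
print.lcg_density <- function(x, ...) {
  cat(sprintf("<lcg_density> %d positive + %d negative components, range [%.3g, %.3g]\n",
              x$n_pos, x$n_neg, x$range[1], x$range[2]))
  invisible(x)
}

classifier_features <- c("U", "q_ave", "q_10")

#' Train the TPN/FPN Bayes classifier
#'
#' Fits one LCG density per class (TPN, FPN) and per feature (`U`,
#' `q_ave`, `q_10`), treating the features as independent with
#' equiprobable class priors.  If the training frame carries a `group`
#' column distinguishing `lung_TPN` from `wall_TPN`, the TPN density of
#' `U` is fitted on lung TPNs only (wall nodules are classified without
#' `U`); all TPN samples contribute to the gray-feature densities.
#'
#' @param training data frame with columns `U`, `q_ave`, `q_10`, `label`
#'   (values `TPN` / `FPN`), optionally `group`.
#' @param n_pos,n_neg LCG component counts per density.
#' @param seed RNG seed for the EM initializations.
#' @return object of class `lcg_model`.
#' @export
train_classifier <- function(training, n_pos = 2, n_neg = 1, seed = 1) {
  stopifnot(all(c(classifier_features, "label") %in% names(training)))
  for (cl in c("TPN", "FPN"))
    if (sum(training$label == cl) < 2)
      stop("each class needs at least 2 training samples")
  classes <- list()
  for (cl in c("TPN", "FPN")) {
    cls <- training[training$label == cl, ]
    dens <- list()
    for (f in classifier_features) {
      sub <- cls
      if (f == "U" && cl == "TPN" && "group" %in% names(cls) &&
          any(cls$group == "lung_TPN"))
        sub <- cls[cls$group == "lung_TPN", ]
      dens[[f]] <- fit_lcg(sub[[f]], n_pos = n_pos, n_neg = n_neg,
                           seed = seed + match(f, classifier_features))
    }
    classes[[cl]] <- dens
  }
  structure(list(classes = classes, features = classifier_features,
                 n_pos = n_pos, n_neg = n_neg, seed = seed),
            class = "lcg_model")
}

#' Classify one feature vector as TPN or FPN
#'
#' Naive Bayes with equal priors: each class scores the product of its
#' per-feature LCG densities (clamped below at `1e-12`); the posterior is
#' `score_TPN / (score_TPN + score_FPN)`.  Lung-wall candidates
#' (`wall_nodule = TRUE`) use only the two gray features.  A posterior of
#' exactly 0.5 is resolved to FPN (favoring specificity).
#'
#' @param features list or one-row data frame with `U`, `q_ave`, `q_10`.
#' @param model an `lcg_model`.
#' @param wall_nodule use only `q_ave` and `q_10`.
#' @return list with `label` and `posterior` (probability of TPN).
#' @export
classify <- function(features, model, wall_nodule = FALSE) {
  stopifnot(inherits(model, "lcg_model"))
  feats <- if (wall_nodule) c("q_ave", "q_10") else model$features
  score <- function(cl) {
    s <- 1
    for (f in feats)
      s <- s * max(lcg_eval(model$classes[[cl]][[f]], features[[f]]), 1e-12)
    s
  }
  st <- score("TPN"); sf <- score("FPN")
  post <- st / (st + sf)
  list(label = if (post > 0.5) "TPN" else "FPN", posterior = post)
}

#' Classify a candidate table
#'
#' Applies [classify()] rowwise; semicircular candidates take the
#' lung-wall path (two gray features only).
#'
#' @param candidates candidate data frame with features filled.
#' @param model an `lcg_model`.
#' @return the table with `label` filled and a `posterior` column added.
#' @export
classify_candidates <- function(candidates, model) {
  post <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    res <- classify(candidates[i, ], model,
                    wall_nodule = candidates$shape[i] == "semicircle")
    candidates$label[i] <- res$label
    post[i] <- res$posterior
  }
  candidates$posterior <- post
  candidates
}

#' Serialize / load a trained classifier as JSON
#'
#' Weights, means and variances per class and feature are written at full
#' precision, so write-then-read reproduces the model exactly.
#'
#' @param model an `lcg_model`.
#' @param path JSON file path.
#' @return `write_model`: `path` invisibly; `read_model`: the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "lcg_model"))
  jsonlite::write_json(unclass_model(model), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

unclass_model <- function(model) {
  m <- unclass(model)
  m$classes <- lapply(m$classes, function(cl)
    lapply(cl, function(d) unclass(d)[c("weights", "means", "sds",
                                        "n_pos", "n_neg", "range", "loglik")]))
  m
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$classes <- lapply(m$classes, function(cl)
    lapply(cl, function(d) {
      d$n_pos <- as.integer(d$n_pos); d$n_neg <- as.integer(d$n_neg)
      structure(d, class = "lcg_density")
    }))
  m$n_pos <- as.integer(m$n_pos); m$n_neg <- as.integer(m$n_neg)
  m$seed <- as.integer(m$seed)
  structure(m, class = "lcg_model")
}
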