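#' Synthetic CT-like phantom with planted nodules
#'
#' Renders nodules of any of the four template shapes onto a uniform
#' background using the same analytic templates the matcher probes with,
#' adds vessel-like tubular distractors with the same Gaussian radial
#' gray profile, and finally additive Gaussian noise.  The returned mask
#' marks every voxel where the noiseless foreground exceeds the
#' background (the stand-in for the tissue segmentation), and the ground
#' truth lists the planted nodules.  Pure function of its arguments
#' including the seed.
#'
#' @param dims volume dimensions `(nx, ny, nz)`.
#' @param nodules data frame with columns `shape`, `x`, `y`, `z`
#'   (0-based centers), `R` and `angle` (`NA` except semicircles).
#'   Planted nodules may not overlap and must fit inside the volume.
#' @param n_vessels number of tubular distractors.
#' @param vessel_radius range of vessel radii in pixels.
#' @param background_gray background gray level.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param q_max,q_min,v,hollow_fraction template gray parameters.
#' @param seed RNG seed.
#' @return list with `volume` ([nod_volume()]), `mask` (binary
#'   [nod_volume()]) and `truth` (data frame).
#' @export
make_phantom <- function(dims = c(128, 128, 9), nodules = NULL,
                         n_vessels = 0, vessel_radius = c(2, 3),
                         background_gray = 20, noise_sigma = 0,
                         q_max = 255, q_min = 61, v = 7,
                         hollow_fraction = 0.75, seed = 1) {
  dims <- as.integer(dims)
  canvas <- array(background_gray, dims)
  if (is.null(nodules))
    nodules <- data.frame(shape = character(), x = integer(), y = integer(),
                          z = integer(), R = numeric(), angle = numeric())
  if (nrow(nodules) >= 2) {
    ctr <- as.matrix(nodules[, c("x", "y", "z")])
    for (i in 1:(nrow(nodules) - 1))
      for (j in (i + 1):nrow(nodules)) {
        d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
        if (d < nodules$R[i] + nodules$R[j])
          stop(sprintf("planted nodules %d and %d overlap (distance %.1f < R%d + R%d)",
                       i, j, d, i, j))
      }
  }
  for (i in seq_len(nrow(nodules))) {
    nd <- nodules[i, ]
    spec <- template_spec(nd$shape, R = nd$R, q_max = q_max, q_min = q_min,
                          v = v, angle = if (is.na(nd$angle)) 0 else nd$angle,
                          hollow_fraction = hollow_fraction)
    tm <- template_offsets(build_template(spec))
    xs <- nd$x + tm$offx + 1L; ys <- nd$y + tm$offy + 1L
    zs <- nd$z + tm$offz + 1L
    if (any(xs < 1 | xs > dims[1] | ys < 1 | ys > dims[2] |
            zs < 1 | zs > dims[3]))
      stop(sprintf("planted nodule %d does not fit inside the volume", i))
    idx <- cbind(xs, ys, zs)
    canvas[idx] <- pmax(canvas[idx], tm$values)
  }

  with_seed(seed, {
    for (vi in seq_len(n_vessels)) {
      for (try in 1:100) {
        r_v <- stats::runif(1, vessel_radius[1], vessel_radius[2])
        p0 <- c(stats::runif(1, 5, dims[1] - 5),
                stats::runif(1, 5, dims[2] - 5),
                stats::runif(1, 1, dims[3] - 1))
        dir <- c(stats::rnorm(2), 0.15 * stats::rnorm(1))
        dir <- dir / sqrt(sum(dir^2))
        len <- stats::runif(1, 30, 60)
        p1 <- p0 + dir * len
        ok <- TRUE
        for (i in seq_len(nrow(nodules))) {
          ndc <- as.numeric(nodules[i, c("x", "y", "z")])
          if (dist_point_segment(ndc, p0, p1) < nodules$R[i] + r_v + 2) {
            ok <- FALSE; break
          }
        }
        if (ok) {
          canvas <- stamp_tube(canvas, p0, p1, r_v, q_max, q_min)
          break
        }
      }
    }
    noiseless <- canvas
    if (noise_sigma > 0)
      canvas <- canvas + stats::rnorm(length(canvas), 0, noise_sigma)
    dim(canvas) <- dims
    truth <- data.frame(x = as.integer(nodules$x), y = as.integer(nodules$y),
                        z = as.integer(nodules$z),
                        shape = as.character(nodules$shape),
                        R = as.numeric(nodules$R),
                        angle = as.numeric(nodules$angle),
                        stringsAsFactors = FALSE)
    list(volume = nod_volume(canvas),
         mask = nod_volume((noiseless > background_gray) * 1),
         truth = truth)
  })
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- max(0, min(1, t))
  sqrt(sum((a + t * ab - p)^2))
}

# Render a tube between p0 and p1 with the template's Gaussian radial
# cross-section: gray q_max on the axis decaying to q_min at radius r_v.
stamp_tube <- function(canvas, p0, p1, r_v, q_max, q_min) {
  dims <- dim(canvas)
  rho_v <- estimate_rho(r_v, q_max, q_min)
  lo <- pmax(floor(pmin(p0, p1) - r_v - 1), c(0, 0, 0))
  hi <- pmin(ceiling(pmax(p0, p1) + r_v + 1), dims - 1)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  ab <- p1 - p0
  ap <- sweep(grid, 2, p0)
  t <- pmax(0, pmin(1, (ap %*% ab) / sum(ab^2)))
  proj <- sweep(t %*% t(ab), 2, -p0)
  d <- sqrt(rowSums((grid - proj)^2))
  sel <- d <= r_v
  if (any(sel)) {
    idx <- grid[sel, , drop = FALSE] + 1L
    vals <- q_max * exp(-(d[sel] / rho_v)^2)
    canvas[idx] <- pmax(canvas[idx], vals)
  }
  canvas
}

#' Canonical 10-nodule phantom layout
#'
#' A fixed arrangement of ten non-overlapping nodules covering all four
#' template shapes with radii spanning 5--20 pixels on a 128 x 128 x 9
#' lattice, used for end-to-end evaluation.
#'
#' @return nodule data frame suitable for [make_phantom()].
#' @export
default_nodule_layout <- function() {
  data.frame(
    shape = c("circle", "sphere", "circle", "sphere", "hollow_sphere",
              "semicircle", "hollow_sphere", "sphere", "circle",
              "semicircle"),
    x = c(24, 64, 104, 24, 64, 104, 24, 64, 104, 88),
    y = c(24, 24, 24, 64, 64, 64, 104, 104, 104, 88),
    z = c(2, 4, 6, 4, 4, 3, 4, 4, 5, 1),
    R = c(5, 12, 9, 20, 16, 10, 18, 14, 12, 7),
    angle = c(NA, NA, NA, NA, NA, 0, NA, NA, NA, 225),
    stringsAsFactors = FALSE)
}

#' Synthetic labeled feature training/test sets
#'
#' Draws `(U, q_ave, q_10)` feature vectors for three classes mirroring
#' the classifier's training design: vessel-like false positives (`FPN`),
#' lung true nodules (`lung_TPN`) and lung-wall true nodules
#' (`wall_TPN`).  Defaults place the TPN gray features at the analytic
#' template values (`q_ave` near 136, `q_10` near 70 for the 255/61 gray
#' calibration), give wall nodules slightly lower gray statistics, and
#' make FPNs elongated (high `U`) with lower gray levels; `U` is
#' truncated at 0.  Deterministic per seed.
#'
#' @param n_per_class draws per class (default 20, the training design).
#' @param seed RNG seed.
#' @param class_params optional override: named list per group of
#'   `list(U = c(mean, sd), q_ave = c(mean, sd), q_10 = c(mean, sd))`.
#' @return data frame with columns `U`, `q_ave`, `q_10`, `label`
#'   (`TPN`/`FPN`) and `group`.
#' @export
make_feature_training_set <- function(n_per_class = 20, seed = 1,
                                      class_params = NULL) {
  if (n_per_class < 2) stop("need at least 2 samples per class")
  defaults <- list(
    FPN      = list(U = c(14, 3),    q_ave = c(105, 8), q_10 = c(50, 7)),
    lung_TPN = list(U = c(1.5, 0.8), q_ave = c(136, 8), q_10 = c(70, 7)),
    wall_TPN = list(U = c(3, 1),     q_ave = c(133, 8), q_10 = c(68, 7)))
  params <- utils::modifyList(defaults, class_params %||% list())
  with_seed(seed, {
    out <- do.call(rbind, lapply(names(params), function(g) {
      p <- params[[g]]
      data.frame(
        U = pmax(stats::rnorm(n_per_class, p$U[1], p$U[2]), 0),
        q_ave = stats::rnorm(n_per_class, p$q_ave[1], p$q_ave[2]),
        q_10 = stats::rnorm(n_per_class, p$q_10[1], p$q_10[2]),
        label = if (g == "FPN") "FPN" else "TPN",
        group = g, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
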