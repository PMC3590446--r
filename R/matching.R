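#' GA matching configuration
#'
#' Parameters of the genetic-algorithm template search.  Defaults follow
#' the method's stated operating point: 75% crossover, 5% per-bit
#' mutation, similarity threshold 0.8, radius range 5--30 pixels, gray
#' calibration `q_max = 255`, `q_min = 61`, inter-slice offset `v = 7`.
#' Population size and generation count default to 100 and 50.
#'
#' @param population_size number of chromosomes per generation, `>= 2`.
#' @param generations number of generations.
#' @param crossover_rate probability of single-point crossover per pair.
#' @param mutation_rate per-bit mutation probability.
#' @param similarity_threshold NCC harvest threshold in `(-1, 1]`.
#' @param seed integer RNG seed; the search is a pure function of its
#'   inputs including this seed.
#' @param radius_range `(R_min, R_max)` in pixels.
#' @param q_max,q_min template gray calibration.
#' @param v inter-slice offset in pixels for 3D templates.
#' @param hollow_fraction cavity fraction for hollow spheres.
#' @param angle_bits width of the semicircle orientation gene.
#' @param selection generational scheme: `"crowding"` (deterministic
#'   crowding -- each child competes with its phenotypically nearest
#'   parent, preserving one niche per nodule, the default) or
#'   `"tournament"` (size-2 tournament, converges to the single best
#'   match).
#' @param restarts number of independent restarts sharing the generation
#'   budget; each restart draws a fresh uniform initial population, so
#'   weakly scoring nodules get repeated chances to seed a niche.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, generations = 50,
                      crossover_rate = 0.75, mutation_rate = 0.05,
                      similarity_threshold = 0.8, seed = 1,
                      radius_range = c(5, 30), q_max = 255, q_min = 61,
                      v = 7, hollow_fraction = 0.75, angle_bits = 4L,
                      selection = c("crowding", "tournament"),
                      restarts = 1L) {
  selection <- match.arg(selection)
  if (restarts < 1 || restarts > generations)
    stop("restarts must lie in [1, generations]")
  if (population_size < 2) stop("population_size must be >= 2")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1)
    stop("rates must lie in [0, 1]")
  if (similarity_threshold <= -1 || similarity_threshold > 1)
    stop("similarity_threshold must lie in (-1, 1]")
  if (radius_range[1] >= radius_range[2]) stop("require R_min < R_max")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 similarity_threshold = similarity_threshold,
                 seed = as.integer(seed),
                 radius_range = as.numeric(radius_range),
                 q_max = q_max, q_min = q_min, v = v,
                 hollow_fraction = hollow_fraction,
                 angle_bits = as.integer(angle_bits),
                 selection = selection, restarts = as.integer(restarts)),
            class = "ga_config")
}

int_to_bits <- function(v, n) {
  if (v < 0 || v >= 2^n) stop("value ", v, " does not fit in ", n, " bits")
  as.integer(rev((as.integer(v) %/% 2^(0:(n - 1))) %% 2L))  # big-endian
}

bits_to_int <- function(bits) sum(bits * 2^(rev(seq_along(bits)) - 1))

#' Chromosome layout for a given shape and volume
#'
#' Non-semicircular shapes use a 28-bit chromosome: 23 position bits split
#' 9/9/5 over `(x, y, z)` plus a 5-bit radius gene.  Semicircles append an
#' orientation gene (default 4 bits, 22.5-degree steps).  Given the
#' volume's dimensions, each position field is resized to the smallest
#' width covering its axis (widened for large volumes, narrowed for
#' small ones, with a message): mutations of a field that mostly decodes
#' off-lattice would otherwise be spent on repair instead of search.
#'
#' @param shape template shape.
#' @param dims optional volume dimensions used to widen fields.
#' @param x_bits,y_bits,z_bits,r_bits,angle_bits field widths.
#' @return list of field widths with the total, class `chrom_layout`.
#' @export
chromosome_layout <- function(shape, dims = NULL, x_bits = 9L, y_bits = 9L,
                              z_bits = 5L, r_bits = 5L, angle_bits = 4L) {
  widths <- c(x = x_bits, y = y_bits, z = z_bits)
  if (!is.null(dims)) {
    for (i in 1:3) {
      fit <- max(1L, as.integer(ceiling(log2(dims[i]))))
      if (fit != widths[i]) {
        message(sprintf("chromosome %s-field %s to %d bits for a %d-voxel axis",
                        names(widths)[i],
                        if (fit > widths[i]) "widened" else "narrowed",
                        fit, dims[i]))
        widths[i] <- fit
      }
    }
  }
  structure(list(x = as.integer(widths["x"]), y = as.integer(widths["y"]),
                 z = as.integer(widths["z"]), r = as.integer(r_bits),
                 angle = if (shape == "semicircle") as.integer(angle_bits) else 0L),
            class = "chrom_layout")
}

layout_total <- function(layout)
  layout$x + layout$y + layout$z + layout$r + layout$angle

#' Encode / decode a chromosome
#'
#' Fields are big-endian bit strings in the order x, y, z, radius and
#' (semicircle only) angle.  The radius gene `g` decodes to
#' `min(R_min + g, R_max)`; the angle gene `a` decodes to
#' `a * 360 / 2^angle_bits` degrees.
#'
#' @param center 0-based `(x, y, z)` voxel coordinates.
#' @param R radius in pixels within `radius_range`.
#' @param angle degrees, a multiple of the gene step (semicircle only).
#' @param layout a [chromosome_layout()].
#' @param radius_range `(R_min, R_max)`.
#' @return `encode_chromosome`: integer 0/1 vector; `decode_chromosome`:
#'   list with `center`, `R` and `angle` (`NULL` when absent).
#' @export
encode_chromosome <- function(center, R, angle = NULL, layout,
                              radius_range = c(5, 30)) {
  g <- as.integer(round(R - radius_range[1]))
  if (g < 0 || R > radius_range[2])
    stop("radius outside configured range")
  bits <- c(int_to_bits(center[1], layout$x),
            int_to_bits(center[2], layout$y),
            int_to_bits(center[3], layout$z),
            int_to_bits(g, layout$r))
  if (layout$angle > 0) {
    step <- 360 / 2^layout$angle
    a <- as.integer(round((angle %||% 0) / step)) %% 2^layout$angle
    bits <- c(bits, int_to_bits(a, layout$angle))
  }
  bits
}

#' @rdname encode_chromosome
#' @param bits integer 0/1 vector of width `layout_total(layout)`.
#' @export
decode_chromosome <- function(bits, layout, radius_range = c(5, 30)) {
  if (length(bits) != layout_total(layout))
    stop("chromosome width does not match layout")
  pos <- cumsum(c(0, layout$x, layout$y, layout$z, layout$r))
  x <- bits_to_int(bits[(pos[1] + 1):pos[2]])
  y <- bits_to_int(bits[(pos[2] + 1):pos[3]])
  z <- bits_to_int(bits[(pos[3] + 1):pos[4]])
  g <- bits_to_int(bits[(pos[4] + 1):pos[5]])
  R <- min(radius_range[1] + g, radius_range[2])
  ang <- NULL
  if (layout$angle > 0) {
    a <- bits_to_int(bits[(pos[5] + 1):(pos[5] + layout$angle)])
    ang <- a * 360 / 2^layout$angle
  }
  list(center = c(x, y, z), R = R, angle = ang)
}

#' Normalized cross-correlation of two images over a support mask
#'
#' Pearson correlation of the gray levels of `a` and `b` restricted to the
#' mask, the template-matching similarity score in `[-1, 1]`.  Invariant
#' to adding a constant or multiplying by a positive constant on either
#' input; symmetric in its arguments.  If either input has (near) zero
#' variance over the mask the score is undefined and `NA` is returned.
#'
#' @param a numeric array (image window).
#' @param b numeric array of the same shape, or a `template_image` (whose
#'   support becomes the mask).
#' @param mask optional logical array selecting the pixels compared.
#' @return NCC in `[-1, 1]`, or `NA` when undefined.
#' @export
similarity <- function(a, b, mask = NULL) {
  if (inherits(b, "template_image")) {
    mask <- mask %||% b$support
    b <- b$values
  }
  if (is.null(mask)) mask <- array(TRUE, dim(as.array(a)))
  av <- as.array(a)[mask]
  bv <- as.array(b)[mask]
  if (length(av) < 2) stop("similarity needs at least 2 support pixels")
  da <- av - mean(av); db <- bv - mean(bv)
  ssa <- sum(da^2); ssb <- sum(db^2)
  if (ssa <= 1e-12 || ssb <= 1e-12) return(NA_real_)
  max(-1, min(1, sum(da * db) / sqrt(ssa * ssb)))
}

# 3-layer templates only exist for R > v; a chromosome decoding to a
# smaller radius is an invalid individual, not an error.
valid_radius <- function(shape, R, config) {
  if (shape %in% c("sphere", "hollow_sphere")) R > config$v
  else rep(TRUE, length(R))
}

# Template cache: rendering is deterministic, so templates are memoized
# per (shape, R, angle, gray calibration) within a search run.
template_for <- function(cache, shape, R, angle, config) {
  key <- paste(shape, R, angle %||% "", sep = ":")
  tm <- cache[[key]]
  if (is.null(tm)) {
    spec <- template_spec(shape, R = R, q_max = config$q_max,
                          q_min = config$q_min, v = config$v,
                          angle = angle %||% 0,
                          hollow_fraction = config$hollow_fraction)
    tm <- template_offsets(build_template(spec))
    cache[[key]] <- tm
  }
  tm
}

# Batch NCC of one template at 0-based centers (matrix n x 3).
ncc_scores <- function(vol, tm, centers0) {
  if (!is.matrix(centers0)) centers0 <- matrix(centers0, ncol = 3)
  ncc_at_centers(vol$data, dim(vol$data), tm$offx, tm$offy, tm$offz,
                 tm$values, centers0 + 1L)
}

#' GA fitness: template similarity at a decoded chromosome
#'
#' Builds the template for the chromosome's radius (and angle), cuts the
#' congruent subvolume centered at its position, and returns the NCC.
#' Windows extending outside the volume, and zero-variance windows, score
#' `-Inf` (invalid individual).
#'
#' @param vol a [nod_volume()].
#' @param chromosome bit vector, or a decoded list as returned by
#'   [decode_chromosome()].
#' @param shape template shape.
#' @param config a [ga_config()].
#' @param layout layout used to decode a bit vector.
#' @return similarity, or `-Inf`.
#' @export
fitness <- function(vol, chromosome, shape, config = ga_config(),
                    layout = NULL) {
  dec <- if (is.list(chromosome)) chromosome else {
    layout <- layout %||% chromosome_layout(shape, dim(vol$data))
    decode_chromosome(chromosome, layout, config$radius_range)
  }
  if (!valid_radius(shape, dec$R, config)) return(-Inf)
  cache <- new.env(parent = emptyenv())
  tm <- template_for(cache, shape, dec$R, dec$angle, config)
  s <- ncc_scores(vol, tm, matrix(as.integer(dec$center), 1))
  if (is.na(s)) -Inf else s
}

#' Repair a chromosome's location onto the search space
#'
#' A location already in the search space is returned unchanged; otherwise
#' it is replaced by the Euclidean-nearest search-space voxel, ties broken
#' by lexicographic `(x, y, z)` order.  Radius and angle genes are never
#' touched.
#'
#' @param location 0-based `(x, y, z)`.
#' @param space a `search_space` or a 0-based n x 3 voxel matrix.
#' @return repaired 0-based `(x, y, z)`.
#' @export
repair_location <- function(location, space) {
  vox <- if (inherits(space, "search_space")) space$voxels else space
  if (!is.matrix(vox) || nrow(vox) == 0) stop("search space is empty")
  d2 <- (vox[, 1] - location[1])^2 + (vox[, 2] - location[2])^2 +
    (vox[, 3] - location[3])^2
  if (min(d2) == 0) return(as.integer(location))
  cand <- which(d2 == min(d2))
  if (length(cand) > 1) {
    sub <- vox[cand, , drop = FALSE]
    cand <- cand[order(sub[, 1], sub[, 2], sub[, 3])[1]]
  }
  as.integer(vox[cand, ])
}

# Greedy non-maximum suppression: scan by descending similarity, drop any
# candidate whose center lies within max(R_i, R_j) voxels of an accepted one.
nms_candidates <- function(df) {
  if (nrow(df) < 2) return(df)
  df <- df[order(-df$similarity, df$x, df$y, df$z), , drop = FALSE]
  keep <- logical(nrow(df))
  kx <- ky <- kz <- kr <- numeric(0)
  for (i in seq_len(nrow(df))) {
    if (length(kx)) {
      d <- sqrt((kx - df$x[i])^2 + (ky - df$y[i])^2 + (kz - df$z[i])^2)
      if (any(d <= pmax(kr, df$R[i]))) next
    }
    keep[i] <- TRUE
    kx <- c(kx, df$x[i]); ky <- c(ky, df$y[i]); kz <- c(kz, df$z[i])
    kr <- c(kr, df$R[i])
  }
  df[keep, , drop = FALSE]
}

harvest_frame <- function(shape, centers, R, angle, sim) {
  candidate_table(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                  shape = rep(shape, nrow(centers)), R = R,
                  angle = if (shape == "semicircle") angle else NA_real_,
                  similarity = sim)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Genetic-algorithm template search
#'
#' Evolves a population of chromosomes encoding template position, radius
#' and (semicircle) orientation.  The initial population draws locations
#' uniformly from the search space and radii uniformly from the radius
#' range; each generation applies single-point crossover, per-bit
#' mutation, and closest-location repair onto the search space, under
#' either deterministic-crowding replacement (default; one niche per
#' nodule survives) or size-2 tournament selection; each component's run
#' finishes with an exhaustive rescoring of the radius/angle codebook in
#' a small neighborhood of its best individual (memetic polish).  Every
#' individual ever evaluated whose
#' similarity exceeds the threshold is harvested across all restarts;
#' the harvest is deduplicated by non-maximum suppression and returned
#' sorted by descending similarity.  Deterministic for fixed inputs and
#' seed.
#'
#' @param vol a [nod_volume()].
#' @param space a `search_space` (see [space_from_mask()]).
#' @param shape template shape to match (one run per shape).
#' @param config a [ga_config()].
#' @param dedup apply non-maximum suppression (`TRUE`); `FALSE` returns
#'   the raw above-threshold harvest.
#' @return candidate data frame (see [candidate_table()]).
#' @export
ga_search <- function(vol, space, shape, config = ga_config(), dedup = TRUE) {
  vox <- if (inherits(space, "search_space")) space$voxels else space
  if (!is.matrix(vox) || nrow(vox) == 0)
    stop("search space is empty; nothing to match")
  layout <- chromosome_layout(shape, dim(vol$data),
                              angle_bits = config$angle_bits)
  cache <- new.env(parent = emptyenv())

  # one GA per segmented object: label the space's 26-connected
  # components and give each a population share, so a weakly scoring
  # object cannot be starved by a stronger one elsewhere
  m <- array(FALSE, dim(vol$data))
  m[vox + 1L] <- TRUE
  lab <- label_components_26(m, dim(m))
  comp <- lab[vox + 1L]
  harvest <- list()
  with_seed(config$seed, {
    for (ci in sort(unique(comp))) {
      vox_c <- vox[comp == ci, , drop = FALSE]
      pop_c <- max(20, round(config$population_size *
                               nrow(vox_c) / nrow(vox)))
      pop_c <- 2L * ceiling(pop_c / 2)
      harvest[[length(harvest) + 1L]] <-
        ga_evolve(vol, vox_c, shape, config, layout, cache, pop_c)
    }
  })

  out <- do.call(rbind, c(list(candidate_table()), harvest))
  if (dedup) out <- nms_candidates(out)
  out <- out[order(-out$similarity, out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  validate_candidates(out, dim(vol$data))
  out
}

# Evolve one population restricted to one component of the search space.
# Uses the ambient RNG stream (the caller seeds it); returns the
# above-threshold harvest of every evaluation.
ga_evolve <- function(vol, vox, shape, config, layout, cache, pop_n) {
  nbits <- layout_total(layout)
  rr <- config$radius_range
  in_space <- new.env(parent = emptyenv(), size = nrow(vox))
  for (i in seq_len(nrow(vox)))
    assign(paste(vox[i, ], collapse = ","), TRUE, envir = in_space)
  harvest <- list()

  draw_population <- function() {
    loc_idx <- sample.int(nrow(vox), pop_n, replace = TRUE)
    radii <- sample(seq(rr[1], rr[2]), pop_n, replace = TRUE)
    angles <- if (layout$angle > 0)
      sample(0:(2^layout$angle - 1), pop_n, replace = TRUE) *
        (360 / 2^layout$angle) else NULL
    lapply(seq_len(pop_n), function(i)
      encode_chromosome(vox[loc_idx[i], ], radii[i],
                        if (is.null(angles)) NULL else angles[i],
                        layout, rr))
  }

  evaluate <- function(pop) {
    dec <- lapply(pop, decode_chromosome, layout = layout,
                  radius_range = rr)
    fit <- rep(-Inf, length(pop))
    key <- vapply(dec, function(d)
      paste(d$R, d$angle %||% "", sep = ":"), "")
    for (k in unique(key)) {
      sel <- which(key == k)
      d1 <- dec[[sel[1]]]
      if (!valid_radius(shape, d1$R, config)) next
      tm <- template_for(cache, shape, d1$R, d1$angle, config)
      ctr <- do.call(rbind, lapply(dec[sel], `[[`, "center"))
      s <- ncc_scores(vol, tm, ctr)
      fit[sel] <- ifelse(is.na(s), -Inf, s)
      hit <- which(!is.na(s) & s > config$similarity_threshold)
      if (length(hit))
        harvest[[length(harvest) + 1L]] <<-
          harvest_frame(shape, ctr[hit, , drop = FALSE], d1$R,
                        d1$angle %||% NA_real_, s[hit])
    }
    fit
  }

  mutate_repair <- function(ch) {
    flip <- stats::runif(nbits) < config$mutation_rate
    ch[flip] <- 1L - ch[flip]
    dec <- decode_chromosome(ch, layout, rr)
    if (!exists(paste(dec$center, collapse = ","), envir = in_space,
                inherits = FALSE)) {
      loc <- repair_location(dec$center, vox)
      ch[1:(layout$x + layout$y + layout$z)] <-
        c(int_to_bits(loc[1], layout$x), int_to_bits(loc[2], layout$y),
          int_to_bits(loc[3], layout$z))
    }
    ch
  }
  cross <- function(p1, p2) {
    if (stats::runif(1) < config$crossover_rate) {
      cut <- sample.int(nbits - 1, 1)
      list(c(p1[1:cut], p2[(cut + 1):nbits]),
           c(p2[1:cut], p1[(cut + 1):nbits]))
    } else list(p1, p2)
  }
  # phenotype distance used to pair children with parents under crowding
  pheno_dist <- function(d1, d2)
    sqrt(sum((d1$center - d2$center)^2)) + abs(d1$R - d2$R)

  gens_per_run <- ceiling(config$generations / config$restarts)
  for (run in seq_len(config$restarts)) {
    pop <- draw_population()
    fit <- evaluate(pop)
    dec_pop <- lapply(pop, decode_chromosome, layout = layout,
                      radius_range = rr)
    for (gen in seq_len(gens_per_run)) {
      if (config$selection == "tournament") {
        tournament <- function() {
          i <- sample.int(pop_n, 2, replace = TRUE)
          if (fit[i[1]] >= fit[i[2]]) i[1] else i[2]
        }
        children <- vector("list", pop_n)
        for (i in seq(1, pop_n, by = 2)) {
          cc <- cross(pop[[tournament()]], pop[[tournament()]])
          children[[i]] <- cc[[1]]
          if (i + 1 <= pop_n) children[[i + 1]] <- cc[[2]]
        }
        pop <- lapply(children, mutate_repair)
        fit <- evaluate(pop)
        dec_pop <- lapply(pop, decode_chromosome, layout = layout,
                          radius_range = rr)
      } else {
        # deterministic crowding: each child competes against its
        # phenotypically nearest parent, keeping local niches alive
        perm <- sample.int(pop_n)
        for (i in seq(1, pop_n - 1, by = 2)) {
          i1 <- perm[i]; i2 <- perm[i + 1]
          cc <- cross(pop[[i1]], pop[[i2]])
          ch <- lapply(cc, mutate_repair)
          dch <- lapply(ch, decode_chromosome, layout = layout,
                        radius_range = rr)
          fch <- evaluate(ch)
          d11 <- pheno_dist(dch[[1]], dec_pop[[i1]])
          d12 <- pheno_dist(dch[[1]], dec_pop[[i2]])
          asg <- if (d11 <= d12) c(i1, i2) else c(i2, i1)
          for (k in 1:2) {
            tgt <- asg[k]
            if (fch[k] >= fit[tgt]) {
              pop[[tgt]] <- ch[[k]]
              fit[tgt] <- fch[k]
              dec_pop[[tgt]] <- dch[[k]]
            }
          }
        }
      }
    }
  }
  # memetic finish: exhaustively rescore the codebook around the
  # component's best individual, so a niche that climbed close to its
  # object's optimum is pinned to exact parameters
  best <- which.max(fit)
  if (length(best) && is.finite(fit[best])) {
    bd <- dec_pop[[best]]
    offs <- as.matrix(expand.grid(dx = -4:4, dy = -4:4, dz = -1:1))
    ctr <- cbind(bd$center[1] + offs[, 1], bd$center[2] + offs[, 2],
                 bd$center[3] + offs[, 3])
    keep <- vapply(seq_len(nrow(ctr)), function(i)
      exists(paste(ctr[i, ], collapse = ","), envir = in_space,
             inherits = FALSE), TRUE)
    ctr <- ctr[keep, , drop = FALSE]
    if (nrow(ctr)) {
      angs <- if (layout$angle > 0)
        (0:(2^layout$angle - 1)) * (360 / 2^layout$angle) else NA_real_
      for (R in seq(rr[1], rr[2])) {
        if (!valid_radius(shape, R, config)) next
        for (ang in angs) {
          a <- if (is.na(ang)) NULL else ang
          tm <- template_for(cache, shape, R, a, config)
          s <- ncc_scores(vol, tm, ctr)
          hit <- which(!is.na(s) & s > config$similarity_threshold)
          if (length(hit))
            harvest[[length(harvest) + 1L]] <-
              harvest_frame(shape, ctr[hit, , drop = FALSE], R,
                            a %||% NA_real_, s[hit])
        }
      }
    }
  }
  do.call(rbind, c(list(candidate_table()), harvest))
}

#' Exhaustive template matching (reference oracle)
#'
#' Evaluates the NCC fitness at every combination of search-space
#' location, radius (and orientation for semicircles), harvesting all
#' above-threshold combinations.  This is the definitive above-threshold
#' set against which the GA's recall is measured; it is only practical on
#' restricted search spaces.
#'
#' @param vol a [nod_volume()].
#' @param space a `search_space` or 0-based voxel matrix.
#' @param shape template shape.
#' @param radius_set radii to enumerate (default: all integer radii in
#'   the configured range).
#' @param config a [ga_config()].
#' @param angles orientations to enumerate for semicircles (default: the
#'   angle gene's codebook).
#' @param dedup apply non-maximum suppression.
#' @return candidate data frame sorted by descending similarity.
#' @export
exhaustive_match <- function(vol, space, shape,
                             radius_set = NULL, config = ga_config(),
                             angles = NULL, dedup = TRUE) {
  vox <- if (inherits(space, "search_space")) space$voxels else space
  if (!is.matrix(vox) || nrow(vox) == 0) stop("search space is empty")
  radius_set <- radius_set %||%
    seq(config$radius_range[1], config$radius_range[2])
  radius_set <- radius_set[valid_radius(shape, radius_set, config)]
  if (shape == "semicircle")
    angles <- angles %||% (0:(2^config$angle_bits - 1)) *
      (360 / 2^config$angle_bits)
  else angles <- NA_real_
  cache <- new.env(parent = emptyenv())
  harvest <- list()
  for (R in radius_set) {
    for (ang in angles) {
      a <- if (is.na(ang)) NULL else ang
      tm <- template_for(cache, shape, R, a, config)
      s <- ncc_scores(vol, tm, vox)
      hit <- which(!is.na(s) & s > config$similarity_threshold)
      if (length(hit))
        harvest[[length(harvest) + 1L]] <-
          harvest_frame(shape, vox[hit, , drop = FALSE], R,
                        a %||% NA_real_, s[hit])
    }
  }
  out <- if (length(harvest)) do.call(rbind, harvest) else candidate_table()
  if (dedup) out <- nms_candidates(out)
  out <- out[order(-out$similarity, out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Local refinement of matched candidates
#'
#' Polishes each candidate by exhaustively re-scoring its template over
#' the full radius codebook (same shape and angle) and over center
#' offsets of up to `offset` voxels, keeping the argmax-similarity
#' combination.  Deformable matching is only as fine as the GA's last
#' evaluations; this step pins radius and center before features are
#' measured on the template support.
#'
#' @param vol a [nod_volume()].
#' @param candidates candidate data frame.
#' @param config a [ga_config()].
#' @param offset maximum center perturbation in voxels (0 disables).
#' @param radius_set radii to scan (default: integer radii in range).
#' @return the candidate table with refined `x`, `y`, `z`, `R` and
#'   `similarity`.
#' @export
refine_candidates <- function(vol, candidates, config = ga_config(),
                              offset = 1L, radius_set = NULL) {
  if (!nrow(candidates)) return(candidates)
  radius_set <- radius_set %||%
    seq(config$radius_range[1], config$radius_range[2])
  cache <- new.env(parent = emptyenv())
  off <- expand.grid(dx = -offset:offset, dy = -offset:offset,
                     dz = -offset:offset)
  d <- dim(vol$data)
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, ]
    ctr <- cbind(cd$x + off$dx, cd$y + off$dy, cd$z + off$dz)
    ctr <- ctr[ctr[, 1] >= 0 & ctr[, 1] < d[1] & ctr[, 2] >= 0 &
                 ctr[, 2] < d[2] & ctr[, 3] >= 0 & ctr[, 3] < d[3], ,
               drop = FALSE]
    a <- if (is.na(cd$angle)) NULL else cd$angle
    best <- c(cd$similarity, cd$x, cd$y, cd$z, cd$R)
    for (R in radius_set) {
      if (!valid_radius(cd$shape, R, config)) next
      tm <- template_for(cache, cd$shape, R, a, config)
      s <- ncc_scores(vol, tm, ctr)
      j <- which.max(ifelse(is.na(s), -Inf, s))
      if (length(j) && !is.na(s[j]) && s[j] > best[1])
        best <- c(s[j], ctr[j, ], R)
    }
    candidates$similarity[i] <- best[1]
    candidates$x[i] <- best[2]; candidates$y[i] <- best[3]
    candidates$z[i] <- best[4]; candidates$R[i] <- best[5]
  }
  candidates
}
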