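#' Decay parameter of the Gaussian gray-level template
#'
#' A deformable nodule template has the central-symmetric profile
#' \deqn{q(r) = q_{max} \exp(-(r/\rho)^2), \quad 0 \le r \le R,}
#' with the boundary condition \eqn{q(R) = q_{min}}.  Solving for the decay
#' parameter gives
#' \deqn{\rho = R\,(\ln q_{max} - \ln q_{min})^{-1/2}.}
#' With the default gray calibration `q_max = 255`, `q_min = 61`, radii 5
#' and 30 pixels give \eqn{\rho \approx 4.18} and \eqn{25.08}.
#'
#' @param R template radius in pixels, `> 0`.
#' @param q_max peak gray level at the center.
#' @param q_min gray level at the template boundary, `0 < q_min < q_max`.
#' @return rho in pixels.
#' @export
estimate_rho <- function(R, q_max = 255, q_min = 61) {
  if (any(R <= 0)) stop("R must be positive")
  if (any(q_min <= 0) || any(q_min >= q_max))
    stop("gray levels must satisfy 0 < q_min < q_max")
  R / sqrt(log(q_max) - log(q_min))
}

#' Specification of a deformable nodule template
#'
#' Bundles the geometric and gray-level parameters of one template.  The
#' decay parameter `rho` is always derived from `(R, q_max, q_min)` via
#' [estimate_rho()], never free, so profile and boundary stay consistent.
#'
#' @param shape one of `"circle"`, `"semicircle"`, `"sphere"`,
#'   `"hollow_sphere"`.
#' @param R radius in pixels.
#' @param q_max,q_min peak / boundary gray levels.
#' @param v inter-slice offset in pixels for the 3-layer 3D shapes; the
#'   upper/lower layer radius is `sqrt(R^2 - v^2)`, so `R > v` is required.
#' @param angle orientation in degrees for the semicircle: the direction
#'   (counterclockwise from +x) of the outward normal of its flat edge.
#' @param hollow_fraction fraction of `R` removed from the interior of the
#'   hollow sphere (cavity), in `(0, 1)`.
#' @return object of class `template_spec`.
#' @export
template_spec <- function(shape = c("circle", "semicircle", "sphere",
                                    "hollow_sphere"),
                          R, q_max = 255, q_min = 61, v = 7, angle = 0,
                          hollow_fraction = 0.75) {
  shape <- match.arg(shape)
  if (R <= 0) stop("R must be positive")
  if (q_min <= 0 || q_min >= q_max)
    stop("gray levels must satisfy 0 < q_min < q_max")
  if (shape %in% c("sphere", "hollow_sphere") && R <= v)
    stop("3D templates require R > v (outer layer radius must be real)")
  if (hollow_fraction <= 0 || hollow_fraction >= 1)
    stop("hollow_fraction must lie in (0, 1)")
  structure(list(shape = shape, R = R, q_max = q_max, q_min = q_min,
                 rho = estimate_rho(R, q_max, q_min), v = v,
                 angle = if (shape == "semicircle") angle %% 360 else NA_real_,
                 hollow_fraction = if (shape == "hollow_sphere")
                   hollow_fraction else NA_real_),
            class = "template_spec")
}

#' @export
print.template_spec <- function(x, ...) {
  cat(sprintf("<template_spec> %s R=%g px, q in [%g, %g], rho=%.3f",
              x$shape, x$R, x$q_min, x$q_max, x$rho))
  if (!is.na(x$angle)) cat(sprintf(", angle=%g deg", x$angle))
  if (!is.na(x$hollow_fraction)) cat(sprintf(", hollow=%g", x$hollow_fraction))
  cat("\n")
  invisible(x)
}

#' Radial gray-level profile of a template
#'
#' Evaluates \eqn{q(r) = q_{max}\exp(-(r/\rho)^2)} on `0 <= r <= R`; by
#' construction of rho, `radial_profile(spec, R)` equals `q_min`.
#'
#' @param spec a [template_spec()].
#' @param r radii in pixels, within `[0, R]`.
#' @return gray levels, strictly decreasing in `r`.
#' @export
radial_profile <- function(spec, r) {
  stopifnot(inherits(spec, "template_spec"))
  if (any(r < 0 | r > spec$R))
    stop("r must lie within [0, R]")
  spec$q_max * exp(-(r / spec$rho)^2)
}

#' Analytic gray-level density of the 2D template
#'
#' The template's gray-level distribution, expressed in closed form over
#' its support:
#' \deqn{\psi(q \mid q_{min}, q_{max}) =
#'   2\pi R \sqrt{\frac{\ln q_{max} - \ln q}{\ln q_{max} - \ln q_{min}}}.}
#' It vanishes at `q_max` and equals `2*pi*R` at `q_min`, and is defined
#' only between the two.  It is an unnormalized profile; normalize it
#' numerically when comparing with an empirical gray histogram.
#'
#' @param spec a [template_spec()].
#' @param q gray levels within `[q_min, q_max]`.
#' @return density values.
#' @export
gray_level_density <- function(spec, q) {
  stopifnot(inherits(spec, "template_spec"))
  if (any(q < spec$q_min | q > spec$q_max))
    stop("q must lie within [q_min, q_max]")
  2 * pi * spec$R *
    sqrt((log(spec$q_max) - log(q)) / (log(spec$q_max) - log(spec$q_min)))
}

#' Gray-level profile of an offset (upper/lower) template layer
#'
#' For the 3-layer 3D templates the upper and lower cross-sections at
#' inter-slice offset `v` follow
#' \deqn{q_v(r) = q_{max} \exp(-(r^2 + v^2)/\rho^2),}
#' reducing to [radial_profile()] at `v = 0`.  The layer radius solving
#' `q_v(R_u) = q_min` is `sqrt(R^2 - v^2)`.
#'
#' @param spec a [template_spec()].
#' @param r in-plane radii, `>= 0`.
#' @param v inter-slice offset in pixels, `>= 0` (defaults to the spec's).
#' @return gray levels.
#' @export
offset_profile <- function(spec, r, v = spec$v) {
  stopifnot(inherits(spec, "template_spec"))
  if (any(r < 0) || any(v < 0)) stop("r and v must be non-negative")
  spec$q_max * exp(-(r^2 + v^2) / spec$rho^2)
}

#' Render a template to a gray-level stencil
#'
#' Rasterizes the analytic template onto an odd-sized square (2D) or
#' 3-layer cube (3D) stencil of side `2*ceiling(R) + 1`, so the center is
#' a single pixel.  A pixel belongs to the support if its center lies
#' within the shape; values over the support follow the radial (central
#' layer) and offset (outer layers) profiles.  The hollow sphere's
#' interior (in-plane radius below `hollow_fraction * R`, every layer) is removed
#' from the support mask, i.e. excluded from matching, not filled.
#'
#' @param spec a [template_spec()].
#' @return object of class `template_image`: list with `values` (numeric
#'   array, `NA` off support), `support` (logical array), `center`
#'   (1-based index of the center within the stencil) and the `spec`.
#' @export
build_template <- function(spec) {
  stopifnot(inherits(spec, "template_spec"))
  R <- spec$R
  side <- 2L * as.integer(ceiling(R)) + 1L
  c0 <- as.integer(ceiling(R)) + 1L
  xs <- seq_len(side) - c0
  r2 <- outer(xs^2, xs^2, "+")     # squared in-plane radius
  r <- sqrt(r2)

  layer_vals <- function(rad, v) {
    sup <- r <= rad
    vals <- matrix(NA_real_, side, side)
    vals[sup] <- spec$q_max * exp(-(r2[sup] + v^2) / spec$rho^2)
    list(values = vals, support = sup)
  }

  if (spec$shape == "circle" || spec$shape == "semicircle") {
    lay <- layer_vals(R, 0)
    if (spec$shape == "semicircle") {
      th <- spec$angle * pi / 180
      # keep the half-disk opposite the flat edge's outward normal; snap
      # near-zero trig values so axis-aligned flat edges are exact
      cs <- cos(th); sn <- sin(th)
      if (abs(cs) < 1e-12) cs <- 0
      if (abs(sn) < 1e-12) sn <- 0
      proj <- outer(xs * cs, xs * sn, "+")
      lay$support <- lay$support & proj <= 0
      lay$values[!lay$support] <- NA_real_
    }
    out <- list(values = lay$values, support = lay$support,
                center = c(c0, c0), spec = spec)
  } else {
    v <- spec$v
    if (R <= v) stop("3D template requires R > v")
    R_u <- sqrt(R^2 - v^2)
    mid <- layer_vals(R, 0)
    outer_l <- layer_vals(R_u, v)
    vals <- array(NA_real_, c(side, side, 3L))
    sup <- array(FALSE, c(side, side, 3L))
    vals[, , 1] <- outer_l$values; sup[, , 1] <- outer_l$support
    vals[, , 2] <- mid$values;     sup[, , 2] <- mid$support
    vals[, , 3] <- outer_l$values; sup[, , 3] <- outer_l$support
    if (spec$shape == "hollow_sphere") {
      hole <- r < spec$hollow_fraction * R
      for (k in 1:3) {
        sl <- sup[, , k]; sl[hole] <- FALSE; sup[, , k] <- sl
        vv <- vals[, , k]; vv[hole] <- NA_real_; vals[, , k] <- vv
      }
    }
    out <- list(values = vals, support = sup,
                center = c(c0, c0, 2L), spec = spec)
  }
  structure(out, class = "template_image")
}

#' @export
print.template_image <- function(x, ...) {
  d <- dim(x$support)
  cat(sprintf("<template_image> %s, stencil %s, %d support pixels\n",
              x$spec$shape, paste(d, collapse = " x "), sum(x$support)))
  invisible(x)
}

# Support offsets relative to the center plus gray values, the form the
# C++ NCC kernel consumes.
template_offsets <- function(tmpl) {
  stopifnot(inherits(tmpl, "template_image"))
  idx <- which(tmpl$support, arr.ind = TRUE)
  if (is.null(dim(tmpl$values)) || length(dim(tmpl$values)) == 2L) {
    offs <- cbind(idx[, 1] - tmpl$center[1], idx[, 2] - tmpl$center[2], 0L)
  } else {
    offs <- cbind(idx[, 1] - tmpl$center[1], idx[, 2] - tmpl$center[2],
                  idx[, 3] - tmpl$center[3])
  }
  list(offx = as.integer(offs[, 1]), offy = as.integer(offs[, 2]),
       offz = as.integer(offs[, 3]),
       values = tmpl$values[tmpl$support])
}

#' Write a rendered template to NIfTI for visual inspection
#'
#' Off-support pixels are written as 0.
#'
#' @param tmpl a `template_image`.
#' @param path destination `.nii`/`.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_template <- function(tmpl, path) {
  stopifnot(inherits(tmpl, "template_image"))
  vals <- tmpl$values
  vals[is.na(vals)] <- 0
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
  write_volume(nod_volume(vals), path, format = "nifti")
}
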