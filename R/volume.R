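#' Gray-level image volume
#'
#' A `nod_volume` wraps a 3D numeric array of gray levels (nominal range
#' 0--255) together with voxel spacing and origin in millimetres.  Voxel
#' coordinates throughout the package are 0-based `(x, y, z)` triples with
#' `z` the slice axis; the underlying R array is addressed 1-based as usual.
#'
#' @param data 3D numeric array of finite gray levels.
#' @param spacing numeric length-3, strictly positive, voxel size in mm.
#' @param origin numeric length-3, position of voxel (0, 0, 0) in mm.
#' @return An object of class `nod_volume` with elements `data`, `spacing`
#'   and `origin`.
#' @export
nod_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 2D or 3D array")
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  if (!all(is.finite(data))) stop("volume gray levels must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have three components")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "nod_volume")
}

#' @export
dim.nod_volume <- function(x) dim(x$data)

#' @export
print.nod_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nod_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm, gray [%g, %g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "raw"
}

#' Read a volume from disk
#'
#' Supports NIfTI-1 (`.nii` / `.nii.gz`) and a raw binary fallback whose
#' geometry lives in a YAML sidecar `<path>.yaml` with fields `dims`,
#' `dtype` (`double`, `float`, `uint8`, `int16`), `spacing` and optionally
#' `origin`.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"nifti"` or `"raw"`.
#' @param rescale if `TRUE`, linearly rescale gray levels to `[0, 255]`.
#' @return A [nod_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "raw"),
                        rescale = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    dat <- array(as.vector(img), dim(img))   # drop NIfTI attributes
    if (length(dim(dat)) == 2L) dim(dat) <- c(dim(dat), 1L)
    pix <- attr(img, "pixdim")
    if (is.null(pix) || length(pix) < 3L) pix <- c(1, 1, 1)
    vol <- nod_volume(dat, spacing = pix[1:3])
  } else {
    side <- paste0(path, ".yaml")
    if (!file.exists(side))
      stop("raw volume requires a sidecar metadata file: ", side)
    meta <- yaml::read_yaml(side)
    need <- c("dims", "dtype", "spacing")
    if (!all(need %in% names(meta)))
      stop("raw sidecar must define: ", paste(need, collapse = ", "))
    dims <- as.integer(meta$dims)
    n <- prod(dims)
    what <- switch(meta$dtype,
                   double = list("double", 8L, FALSE),
                   float  = list("double", 4L, FALSE),
                   uint8  = list("integer", 1L, FALSE),
                   int16  = list("integer", 2L, TRUE),
                   stop("unsupported raw dtype: ", meta$dtype))
    raw_n <- file.size(path)
    if (raw_n != n * what[[2]])
      stop(sprintf("raw volume size mismatch: sidecar implies %d bytes, file has %d",
                   n * what[[2]], raw_n))
    con <- file(path, "rb"); on.exit(close(con))
    dat <- readBin(con, what[[1]], n = n, size = what[[2]],
                   signed = what[[3]] || what[[2]] > 2L)
    dim(dat) <- dims
    vol <- nod_volume(dat, spacing = as.numeric(meta$spacing),
                      origin = as.numeric(meta$origin %||% c(0, 0, 0)))
  }
  if (rescale) {
    rng <- range(vol$data)
    if (diff(rng) > 0)
      vol$data <- (vol$data - rng[1]) / diff(rng) * 255
  }
  vol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume to disk
#'
#' @param vol a [nod_volume()].
#' @param path destination; `.nii`/`.nii.gz` writes NIfTI-1, anything else
#'   writes raw doubles plus a YAML sidecar.
#' @param format `"auto"`, `"nifti"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "nifti", "raw")) {
  stopifnot(inherits(vol, "nod_volume"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "nifti") {
    img <- RNifti::asNifti(vol$data, pixdim = vol$spacing)
    RNifti::writeNifti(img, path)
  } else {
    con <- file(path, "wb")
    writeBin(as.vector(vol$data), con, size = 8L)
    close(con)
    yaml::write_yaml(list(dims = dim(vol$data), dtype = "double",
                          spacing = vol$spacing, origin = vol$origin),
                     paste0(path, ".yaml"))
  }
  invisible(path)
}

candidate_columns <- c("x", "y", "z", "shape", "R", "angle", "similarity",
                       "U", "q_ave", "q_10", "label")

#' Create a candidate table
#'
#' Candidates are rows of a data frame with the fixed column set
#' `x, y, z, shape, R, angle, similarity, U, q_ave, q_10, label`.
#' Coordinates are 0-based voxel indices; `angle` (degrees) applies to
#' semicircular templates only and is `NA` otherwise; the feature columns
#' and `label` are `NA` until filled by the classifier stage.
#'
#' @param x,y,z 0-based integer voxel coordinates of the template centers.
#' @param shape character, each one of `"circle"`, `"semicircle"`,
#'   `"sphere"`, `"hollow_sphere"`.
#' @param R radii in pixels.
#' @param angle orientation in degrees (semicircle) or `NA`.
#' @param similarity NCC scores in `[-1, 1]`.
#' @param U,q_ave,q_10,label optional feature/label columns.
#' @return data frame with the candidate column set.
#' @export
candidate_table <- function(x = integer(), y = integer(), z = integer(),
                            shape = character(), R = numeric(),
                            angle = NA_real_, similarity = NA_real_,
                            U = NA_real_, q_ave = NA_real_,
                            q_10 = NA_real_, label = NA_character_) {
  n <- length(x)
  recycle <- function(v, as) {
    v <- as(v)
    if (length(v) == n) v else rep(v, length.out = n)
  }
  data.frame(x = as.integer(x), y = recycle(y, as.integer),
             z = recycle(z, as.integer),
             shape = recycle(shape, as.character),
             R = recycle(R, as.numeric),
             angle = recycle(angle, as.numeric),
             similarity = recycle(similarity, as.numeric),
             U = recycle(U, as.numeric), q_ave = recycle(q_ave, as.numeric),
             q_10 = recycle(q_10, as.numeric),
             label = recycle(label, as.character),
             stringsAsFactors = FALSE)
}

validate_candidates <- function(df, dims = NULL, radius_range = NULL) {
  miss <- setdiff(candidate_columns, names(df))
  if (length(miss))
    stop("candidate table missing columns: ", paste(miss, collapse = ", "))
  bad_shape <- setdiff(unique(df$shape),
                       c("circle", "semicircle", "sphere", "hollow_sphere"))
  if (length(bad_shape))
    stop("unknown template shape(s): ", paste(bad_shape, collapse = ", "))
  co <- as.matrix(df[, c("x", "y", "z")])
  if (nrow(df) && (any(co != floor(co)) || any(co < 0)))
    stop("candidate coordinates must be 0-based non-negative integers")
  if (!is.null(dims) && nrow(df)) {
    inb <- df$x < dims[1] & df$y < dims[2] & df$z < dims[3]
    if (!all(inb)) stop("candidate center outside volume bounds")
  }
  if (!is.null(radius_range) && nrow(df)) {
    if (any(df$R < radius_range[1] - 1e-9 | df$R > radius_range[2] + 1e-9))
      stop("candidate radius outside configured range")
  }
  invisible(df)
}

#' Write / read candidate lists as CSV
#'
#' The CSV dialect is comma-separated, "." decimal, UTF-8, with a header
#' row of the fixed candidate columns.  Round trips preserve all fields;
#' coordinates are checked to be 0-based integers on read.
#'
#' @param records candidate data frame (see [candidate_table()]).
#' @param path CSV file path.
#' @return `write_candidates`: `path` invisibly; `read_candidates`: the
#'   candidate data frame.
#' @export
write_candidates <- function(records, path) {
  validate_candidates(records)
  utils::write.csv(records[, candidate_columns], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) stop("no such candidate file: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(x = "integer", y = "integer",
                                   z = "integer", shape = "character",
                                   R = "numeric", angle = "numeric",
                                   similarity = "numeric", U = "numeric",
                                   q_ave = "numeric", q_10 = "numeric",
                                   label = "character")),
    error = function(e) stop("malformed candidate CSV '", path, "': ",
                             conditionMessage(e)))
  if (!nrow(df)) {
    df <- candidate_table()
  } else {
    df$label[!is.na(df$label) & df$label == ""] <- NA_character_
  }
  # locate first offending line for a useful parse error
  co <- as.matrix(df[, c("x", "y", "z")])
  if (nrow(df) && (anyNA(co) || any(co < 0))) {
    bad <- which(rowSums(is.na(co) | co < 0) > 0)[1]
    stop(sprintf("malformed candidate CSV '%s' at line %d: coordinates must be 0-based integers",
                 path, bad + 1L))
  }
  validate_candidates(df)
  df
}
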