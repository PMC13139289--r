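#' CT volumes and binary masks
#'
#' A `ct_volume` is a 3D scalar grid in Hounsfield units (HU) together with
#' its voxel geometry: isotropic or anisotropic voxel spacing in mm and the
#' world-mm position of voxel (1,1,1).  The geometry model is axis-aligned:
#' `world = origin + (index - 1) * spacing` per axis, the convention of an
#' axial scanning protocol.  Oblique affines are rejected on read.
#'
#' A `binary_mask` shares the same representation, with data restricted to
#' \{0, 1\}; masks are used for the manually labelled artery and for the
#' derived calcification segmentation.
#'
#' @param data numeric 3D array (HU for volumes, \{0,1\} for masks).
#' @param spacing positive numeric length-3, voxel edge length in mm.
#' @param origin numeric length-3, world-mm position of the first voxel.
#' @return A `ct_volume` (or `binary_mask`) object.
#' @examples
#' vol <- ct_volume(array(0, c(4, 4, 4)), spacing = c(0.625, 0.625, 0.625))
#' voxel_volume(vol)
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("not a 3D volume: `data` must be a 3D array", call. = FALSE)
  if (any(dim(data) == 0L)) stop("volume grid is empty", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  if (any(!is.finite(data)))
    stop("volume contains non-finite voxel values", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "ct_volume"
  )
}

#' @rdname ct_volume
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vol <- ct_volume(data, spacing, origin)
  d <- vol$data
  if (!all(d %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1; use `as_mask()` to binarise",
         call. = FALSE)
  storage.mode(vol$data) <- "integer"
  class(vol) <- c("binary_mask", "ct_volume")
  vol
}

#' @rdname ct_volume
#' @param x object to coerce or test.
#' @param reference optional `ct_volume` whose geometry the mask must match.
#' @export
as_mask <- function(x, reference = NULL) {
  if (inherits(x, "ct_volume")) {
    m <- binary_mask((x$data != 0) * 1L, x$spacing, x$origin)
  } else {
    m <- binary_mask((x != 0) * 1L)
  }
  if (!is.null(reference)) check_same_geometry(m, reference)
  m
}

#' @rdname ct_volume
#' @export
is_ct_volume <- function(x) inherits(x, "ct_volume")

#' @rdname ct_volume
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' @export
print.ct_volume <- function(x, ...) {
  kind <- if (inherits(x, "binary_mask")) "binary_mask" else "ct_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 6), collapse = "x"),
              paste(signif(x$origin, 6), collapse = ", ")))
  if (kind == "binary_mask") {
    cat(sprintf("  foreground voxels: %d (%.4g mm^3)\n",
                sum(x$data), sum(x$data) * voxel_volume(x)))
  } else {
    cat(sprintf("  HU range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

# Geometry agreement to within `tol` mm on spacing and origin, identical shape.
check_same_geometry <- function(a, b, tol = 1e-4) {
  if (!identical(dim(a$data), dim(b$data)) ||
      any(abs(a$spacing - b$spacing) > tol) ||
      any(abs(a$origin - b$origin) > tol)) {
    stop(sprintf(
      paste0("geometry mismatch: [%s voxels, spacing %s, origin %s] vs ",
             "[%s voxels, spacing %s, origin %s]"),
      paste(dim(a$data), collapse = "x"), paste(signif(a$spacing, 6), collapse = "x"),
      paste(signif(a$origin, 6), collapse = ","),
      paste(dim(b$data), collapse = "x"), paste(signif(b$spacing, 6), collapse = "x"),
      paste(signif(b$origin, 6), collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write volumes as NIfTI-1
#'
#' `read_volume()` loads a 3D single-channel NIfTI file as a [ct_volume],
#' taking spacing and origin from the header and applying the header's
#' intensity slope/intercept so that values are in HU.  Only axis-aligned
#' geometries are accepted.  `read_mask()` additionally binarises the data
#' (any nonzero label becomes 1) and checks that the file geometry matches
#' `reference` within 1e-4 mm.  `write_volume()` writes a `ct_volume` or
#' `binary_mask` back to NIfTI; the round trip preserves data, spacing, and
#' origin exactly.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param reference a [ct_volume] giving the expected geometry.
#' @param vol a [ct_volume] or [binary_mask].
#' @return `read_volume()` a `ct_volume`; `read_mask()` a `binary_mask`;
#'   `write_volume()` the path, invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("not a 3D volume: ", path, " has ", length(d), " dimensions",
         call. = FALSE)
  m <- RNifti::xform(img)
  sp <- abs(RNifti::pixdim(img))[1:3]
  rot <- m[1:3, 1:3]
  if (max(abs(rot - diag(sign(diag(rot)) * sp))) > 1e-4 || any(diag(rot) < 0))
    stop("oblique or flipped affine in ", path,
         "; only axis-aligned volumes are supported", call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  data <- array(as.vector(as.array(img), mode = "double"), dim = d)
  # RNifti applies scl_slope/scl_inter on access; guard against raw headers
  if (!is.null(attr(img, "scaled")) && identical(attr(img, "scaled"), FALSE) &&
      hdr$scl_slope != 0) {
    data <- data * hdr$scl_slope + hdr$scl_inter
  }
  storage.mode(data) <- "double"
  if (any(!is.finite(data)))
    stop("non-finite voxel values in ", path, call. = FALSE)
  ct_volume(data, spacing = sp, origin = m[1:3, 4])
}

#' @rdname read_volume
#' @export
read_mask <- function(path, reference = NULL) {
  vol <- read_volume(path)
  m <- as_mask(vol)
  if (!is.null(reference)) check_same_geometry(m, reference)
  m
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_ct_volume(vol))
  data <- vol$data
  storage.mode(data) <- "double"
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume to a new voxel spacing
#'
#' Resamples onto a grid aligned to the original origin, preserving the
#' world extent to within one target voxel.  HU volumes should use
#' `method = "linear"` (trilinear interpolation); masks use
#' `method = "nearest"`, which keeps them binary.  Resampling a
#' `binary_mask` with nearest-neighbour returns a `binary_mask`.
#'
#' @param vol a [ct_volume] or [binary_mask].
#' @param target_spacing positive numeric (length 1 or 3), new spacing in mm.
#' @param method `"linear"` or `"nearest"`.
#' @return a resampled [ct_volume] (or [binary_mask] under `"nearest"`).
#' @examples
#' v <- ct_volume(array(300, c(8, 8, 8)), spacing = rep(0.625, 3))
#' resample_volume(v, 1.25)
#' @export
resample_volume <- function(vol, target_spacing,
                            method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is_ct_volume(vol))
  ts <- as.numeric(target_spacing)
  if (length(ts) == 1L) ts <- rep(ts, 3L)
  if (length(ts) != 3L || any(!is.finite(ts)) || any(ts <= 0))
    stop("`target_spacing` must be positive (mm)", call. = FALSE)
  dims <- dim(vol$data)
  sp <- vol$spacing
  n_out <- pmax(1L, as.integer(round(dims * sp / ts)))
  # input index (0-based, fractional) of each output voxel centre
  idx <- lapply(1:3, function(a) (seq_len(n_out[a]) - 1) * ts[a] / sp[a])
  if (method == "nearest") {
    take <- lapply(1:3, function(a) pmin(dims[a], pmax(1L, as.integer(round(idx[[a]])) + 1L)))
    out <- vol$data[take[[1]], take[[2]], take[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(a) pmin(dims[a] - 1L, pmax(0L, as.integer(floor(idx[[a]])))))
    fr <- lapply(1:3, function(a) {
      f <- idx[[a]] - lo[[a]]
      pmin(1, pmax(0, f))
    })
    if (any(dims == 1L)) {
      for (a in 1:3) if (dims[a] == 1L) { lo[[a]][] <- 0L; fr[[a]][] <- 0 }
    }
    hi <- lapply(1:3, function(a) pmin(dims[a] - 1L, lo[[a]] + 1L))
    g <- function(ia, ib, ic) vol$data[cbind(
      rep(ia + 1L, times = length(ib) * length(ic)),
      rep(rep(ib + 1L, each = length(ia)), times = length(ic)),
      rep(ic + 1L, each = length(ia) * length(ib)))]
    w <- function(fa, fb, fc) {
      array(outer(outer(fa, fb), fc), c(length(fa), length(fb), length(fc)))
    }
    acc <- array(0, n_out)
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      ia <- if (cx == 0) lo[[1]] else hi[[1]]
      ib <- if (cy == 0) lo[[2]] else hi[[2]]
      ic <- if (cz == 0) lo[[3]] else hi[[3]]
      fa <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
      fb <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
      fc <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
      acc <- acc + array(g(ia, ib, ic), n_out) * w(fa, fb, fc)
    }
    out <- acc
  }
  if (inherits(vol, "binary_mask") && method == "nearest") {
    binary_mask(out, spacing = ts, origin = vol$origin)
  } else {
    ct_volume(out, spacing = ts, origin = vol$origin)
  }
}
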