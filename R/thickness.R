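#' Opposing-face candidates
#'
#' Faces j are pairing candidates for face i when their unit normals
#' oppose: dot(A, B) < 0 strictly, i.e. the angle between the normals
#' exceeds 90 degrees, placing the two faces on opposite sides of the
#' calcification shell.  An angle of exactly 90 degrees is excluded.
#'
#' @param normals matrix of unit face normals (one row per face).
#' @param i face index (1-based).
#' @return integer vector of candidate face indices.
#' @export
opposing_candidates <- function(normals, i) {
  d <- as.vector(normals %*% normals[i, ])
  out <- which(d < 0)
  out[out != i]
}

#' Per-face thickness by shortest opposing-centroid distance
#'
#' For each face, thickness T is the distance from its centroid to the
#' nearest centroid among opposing-normal candidate faces; faces without
#' any candidate (e.g. an open sheet with parallel normals) are `NA`.
#' The reference definition is the exhaustive O(F^2) scan over all face
#' pairs; `accelerate = TRUE` (default) uses a uniform spatial grid whose
#' ring-expansion stopping rule guarantees the identical result,
#' including tie-breaking by lowest face index.
#'
#' @param mesh a [triangle_mesh] (at least 2 faces).
#' @param accelerate use the spatially indexed exact search (default).
#' @return tibble with one row per face: `face_id`, `thickness_mm`,
#'   `pair_id` (index of the chosen opposing face), `missing`.
#' @export
face_thickness <- function(mesh, accelerate = TRUE) {
  if (nrow(mesh$faces) < 2L)
    stop("mesh has fewer than 2 faces", call. = FALSE)
  cen <- face_centroids(mesh)
  nrm <- face_normals(mesh)
  res <- if (accelerate) .thickness_grid(cen, nrm) else .thickness_brute(cen, nrm)
  tibble::tibble(
    face_id = seq_len(nrow(cen)),
    thickness_mm = res$thickness,
    pair_id = res$pair,
    missing = is.na(res$thickness)
  )
}

#' Radial direction weights against the artery surface
#'
#' Down-weights thickness measurements that are not taken across the
#' artery's cross-sectional plane.  For each calcification face, the `k`
#' nearest artery-surface faces (by centroid distance; ties broken by
#' lowest face index) are found, the mean angle between the face normal
#' and the artery-face normals is computed (angles in \[0, 180\]
#' degrees), and the weight is `|cos(mean angle)|`: 1 when the face
#' normal is aligned (or anti-aligned) with the local artery-wall normal,
#' i.e. a radial measurement, and 0 when perpendicular to it.
#'
#' @param calc_mesh calcification [triangle_mesh].
#' @param artery_mesh artery-surface [triangle_mesh] (at least `k` faces).
#' @param k number of nearest artery faces to average over (default 5).
#' @param accelerate use the spatially indexed exact k-NN (default).
#' @return numeric vector of weights in \[0, 1\], one per calcification face.
#' @export
direction_weights <- function(calc_mesh, artery_mesh, k = 5, accelerate = TRUE) {
  if (nrow(artery_mesh$faces) < k)
    stop("artery mesh has fewer than k = ", k,
         " faces; use a smaller k", call. = FALSE)
  qc <- face_centroids(calc_mesh)
  qn <- face_normals(calc_mesh)
  tc <- face_centroids(artery_mesh)
  tn <- face_normals(artery_mesh)
  nn <- if (accelerate) .knn_grid(qc, tc, as.integer(k))
        else .knn_brute(qc, tc, as.integer(k))
  ang <- matrix(0, nrow(qc), k)
  for (j in seq_len(k)) {
    cosang <- rowSums(tn[nn[, j], , drop = FALSE] * qn)
    ang[, j] <- acos(pmin(1, pmax(-1, cosang)))
  }
  abs(cos(rowMeans(ang)))
}

#' Weighted quantile of thickness values
#'
#' Computes the weighted q-quantile of per-face thickness, with the
#' direction weights acting as frequency weights: zero-weight faces are
#' excluded, and the quantile position of the k-th order statistic is
#' `(C_{k-1}) / (W - w_k)` (cumulative weight before k over total weight
#' excluding k), linearly interpolated.  Under uniform weights this
#' reduces exactly to the ordinary linear-interpolation percentile
#' (`quantile(type = 7)`).
#'
#' @param x numeric values (NAs excluded together with their weights).
#' @param w non-negative weights, same length as `x`.
#' @param q quantile fraction in \[0, 1\] (default 0.97).
#' @return the weighted quantile.
#' @examples
#' weighted_quantile(1:100, rep(1, 100), 0.97)  # == quantile(1:100, .97)
#' @export
weighted_quantile <- function(x, w, q = 0.97) {
  if (length(x) != length(w)) stop("`x` and `w` lengths differ", call. = FALSE)
  keep <- !is.na(x) & !is.na(w) & w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L)
    stop("no values with positive weight", call. = FALSE)
  if (any(w < 0)) stop("negative weights", call. = FALSE)
  o <- order(x)
  x <- x[o]; w <- w[o]
  if (length(x) == 1L) return(x)
  W <- sum(w)
  s <- (cumsum(w) - w) / (W - w)
  stats::approx(s, x, xout = q, ties = list("ordered", min), rule = 2)$y
}

#' Representative thickness at the 97th percentile
#'
#' The participant-level thickness summary: the direction-weighted 97th
#' percentile of per-face T over the surface model.  The high percentile
#' captures extreme thickness while staying robust to local surface
#' irregularities.
#'
#' @param thickness tibble from [face_thickness()] (or a numeric vector).
#' @param weights weights from [direction_weights()] (or uniform).
#' @param q quantile fraction, default 0.97.
#' @return representative thickness in mm.
#' @export
representative_thickness <- function(thickness, weights = NULL, q = 0.97) {
  x <- if (is.data.frame(thickness)) thickness$thickness_mm else thickness
  if (is.null(weights)) weights <- rep(1, length(x))
  weighted_quantile(x, weights, q)
}

#' End-to-end morphometry of one artery
#'
#' Runs the full pipeline on a CT volume and its artery mask: HU-window
#' segmentation, connected-component separation, per-component surface
#' modelling, surface area S (summed over components), calcification
#' volume, per-face thickness with radial direction weighting against the
#' artery surface model, and the weighted 97th-percentile representative
#' thickness pooled across components.  Participants with no voxel in the
#' calcium window get S = 0, volume = 0, representative T = 0 and the
#' `no_calcification` flag, so cohort tables have no missing morphometry.
#'
#' @inheritParams threshold_calcification
#' @param id,side identifiers carried into the summary row.
#' @param q representative-thickness quantile (default 0.97).
#' @param knn number of nearest artery faces for weighting (default 5).
#' @param connectivity deposit adjacency, 26 (default) or 6.
#' @param sigma surface anti-aliasing width in voxels, see [build_surface()].
#' @param min_component_voxels drop deposits smaller than this many voxels
#'   (default 0: keep everything).
#' @param weighting apply radial direction weighting (default TRUE).
#' @return an object of class `morphometry_result`: a list with `summary`
#'   (one-row tibble: `id`, `side`, `S_mm2`, `T_rep_mm`, `volume_mm3`,
#'   `n_components`, `no_calcification`) and `faces` (per-face tibble with
#'   `component_id`, `thickness_mm`, `weight`, `missing`).
#' @export
morphometry <- function(vol, artery_mask, lo = 130, hi = 500,
                        id = "participant", side = "pooled",
                        q = 0.97, knn = 5, connectivity = 26,
                        sigma = 0.8, min_component_voxels = 0,
                        weighting = TRUE) {
  calc <- threshold_calcification(vol, artery_mask, lo, hi)
  if (sum(calc$data) == 0L) {
    return(empty_morphometry(id, side))
  }
  cc <- connected_components(calc, connectivity)
  keep <- cc$sizes$component_id[cc$sizes$voxels >= min_component_voxels]
  if (length(keep) == 0L) return(empty_morphometry(id, side))

  artery_mesh <- build_surface(artery_mask, sigma = sigma)
  faces <- purrr::map_dfr(keep, function(cid) {
    mesh <- build_surface(component_mask(calc, cc$labels, cid), sigma = sigma)
    ft <- if (nrow(mesh$faces) >= 2L) face_thickness(mesh)
          else tibble::tibble(face_id = seq_len(nrow(mesh$faces)),
                              thickness_mm = NA_real_, pair_id = NA_integer_,
                              missing = TRUE)
    w <- if (weighting) direction_weights(mesh, artery_mesh, k = knn)
         else rep(1, nrow(mesh$faces))
    tibble::tibble(component_id = cid, face_id = ft$face_id,
                   area_mm2 = face_areas(mesh),
                   thickness_mm = ft$thickness_mm, weight = w,
                   missing = ft$missing)
  })
  usable <- !faces$missing & faces$weight > 0
  t_rep <- if (any(usable))
    weighted_quantile(faces$thickness_mm, faces$weight, q) else NA_real_
  res <- list(
    summary = tibble::tibble(
      id = id, side = side,
      S_mm2 = sum(faces$area_mm2),
      T_rep_mm = t_rep,
      volume_mm3 = mask_volume_mm3(calc),
      n_components = length(keep),
      no_calcification = FALSE
    ),
    faces = faces
  )
  class(res) <- "morphometry_result"
  res
}

empty_morphometry <- function(id, side) {
  res <- list(
    summary = tibble::tibble(
      id = id, side = side, S_mm2 = 0, T_rep_mm = 0, volume_mm3 = 0,
      n_components = 0L, no_calcification = TRUE
    ),
    faces = tibble::tibble(
      component_id = integer(), face_id = integer(), area_mm2 = numeric(),
      thickness_mm = numeric(), weight = numeric(), missing = logical()
    )
  )
  class(res) <- "morphometry_result"
  res
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result>\n")
  print(x$summary)
  invisible(x)
}

#' Bilateral morphometry with pooled representative thickness
#'
#' Processes the left and right artery masks separately and also pools
#' per-face thickness values across sides and components before taking
#' the representative quantile, giving the single order-independent
#' per-participant value.
#'
#' @inheritParams morphometry
#' @param left_mask,right_mask per-side artery [binary_mask]s.
#' @return tibble with one row per side plus a `"pooled"` row.
#' @export
morphometry_bilateral <- function(vol, left_mask, right_mask,
                                  lo = 130, hi = 500, id = "participant",
                                  q = 0.97, knn = 5, connectivity = 26,
                                  sigma = 0.8, weighting = TRUE) {
  l <- morphometry(vol, left_mask, lo, hi, id = id, side = "left", q = q,
                   knn = knn, connectivity = connectivity, sigma = sigma,
                   weighting = weighting)
  r <- morphometry(vol, right_mask, lo, hi, id = id, side = "right", q = q,
                   knn = knn, connectivity = connectivity, sigma = sigma,
                   weighting = weighting)
  faces <- dplyr::bind_rows(l$faces, r$faces)
  usable <- !faces$missing & faces$weight > 0
  pooled_T <- if (any(usable))
    weighted_quantile(faces$thickness_mm, faces$weight, q) else 0
  pooled <- tibble::tibble(
    id = id, side = "pooled",
    S_mm2 = l$summary$S_mm2 + r$summary$S_mm2,
    T_rep_mm = pooled_T,
    volume_mm3 = l$summary$volume_mm3 + r$summary$volume_mm3,
    n_components = l$summary$n_components + r$summary$n_components,
    no_calcification = l$summary$no_calcification && r$summary$no_calcification
  )
  dplyr::bind_rows(l$summary, r$summary, pooled)
}
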