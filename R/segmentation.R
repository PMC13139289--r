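#' Segment arterial calcification by HU windowing
#'
#' Voxels inside the artery mask whose attenuation lies in the calcium
#' window `[lo, hi]` HU are labelled calcified.  The default window of
#' 130-500 HU follows the Agatston convention for the lower bound (>= 130
#' HU is calcium) while the upper bound excludes adjacent bone, which is
#' much denser than vascular calcification.  Both bounds are inclusive;
#' pass `hi_inclusive = FALSE` for a strict upper bound.
#'
#' @param vol a [ct_volume] in HU.
#' @param artery_mask a [binary_mask] with the same geometry as `vol`.
#' @param lo,hi calcium window bounds in HU (default 130 and 500).
#' @param hi_inclusive include voxels exactly at `hi`? Default `TRUE`.
#' @return a [binary_mask] of calcified voxels (a subset of `artery_mask`).
#' @examples
#' vol <- ct_volume(array(c(40, 300, 600, 40), c(4, 1, 1)))
#' art <- binary_mask(array(c(1, 1, 1, 0), c(4, 1, 1)))
#' threshold_calcification(vol, art)$data
#' @export
threshold_calcification <- function(vol, artery_mask, lo = 130, hi = 500,
                                    hi_inclusive = TRUE) {
  stopifnot(is_ct_volume(vol), inherits(artery_mask, "binary_mask"))
  check_same_geometry(vol, artery_mask)
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("invalid HU window: need lo < hi", call. = FALSE)
  inwin <- if (hi_inclusive) vol$data >= lo & vol$data <= hi
           else vol$data >= lo & vol$data < hi
  binary_mask((inwin & artery_mask$data == 1L) * 1L,
              spacing = vol$spacing, origin = vol$origin)
}

#' Physical volume of a binary mask
#'
#' @param mask a [binary_mask].
#' @return volume in mm^3: foreground voxel count times voxel volume.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * voxel_volume(mask)
}

#' Connected components of a binary mask
#'
#' Labels maximal connected foreground regions under 26-adjacency (voxels
#' sharing a face, edge, or corner) or 6-adjacency (faces only).  No
#' minimum-size filtering is applied.
#'
#' @param mask a [binary_mask].
#' @param connectivity 26 (default) or 6.
#' @return a list with `labels` (integer array, 0 = background, components
#'   numbered from 1) and `sizes`, a tibble with one row per component:
#'   `component_id`, `voxels`, `volume_mm3`.
#' @export
connected_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(6, 26))
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  lab <- .label_components3d(mask$data, dim(mask$data), as.integer(connectivity))
  n <- max(lab)
  counts <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  list(
    labels = lab,
    sizes = tibble::tibble(
      component_id = seq_len(n),
      voxels = counts,
      volume_mm3 = counts * voxel_volume(mask)
    )
  )
}

#' Extract a single labelled component as a mask
#'
#' @param mask the original [binary_mask].
#' @param labels label array from [connected_components()].
#' @param id component id to extract.
#' @return a [binary_mask] containing only that component.
#' @export
component_mask <- function(mask, labels, id) {
  binary_mask((labels == id) * 1L, spacing = mask$spacing, origin = mask$origin)
}

#' Per-component segmentation report
#'
#' Runs the HU-window segmentation and tabulates each connected deposit.
#'
#' @inheritParams threshold_calcification
#' @param connectivity adjacency for deposit separation, 26 or 6.
#' @param side optional label (e.g. `"left"`, `"right"`) carried through.
#' @return tibble with columns `side`, `component_id`, `voxels`,
#'   `volume_mm3`.
#' @export
segment_report <- function(vol, artery_mask, lo = 130, hi = 500,
                           connectivity = 26, side = NA_character_) {
  calc <- threshold_calcification(vol, artery_mask, lo, hi)
  cc <- connected_components(calc, connectivity)
  dplyr::mutate(cc$sizes, side = side, .before = 1)
}
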