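#' Euclidean distance map
#'
#' Exact Euclidean distance from every foreground pixel to the nearest
#' background pixel center (Felzenszwalb-Huttenlocher two-pass transform);
#' 0 on background.  This is the prototype topographic surface for the
#' seeded watershed.
#'
#' @param mask binary matrix.
#' @return numeric matrix of distances (pixels).
#' @export
distance_map <- function(mask) {
  cpp_distance_map(as_binary(mask))
}

#' Elementary geodesic dilation
#'
#' One grayscale geodesic dilation step: dilation of the marker by the
#' elementary 4-connected cross, followed by a pointwise minimum with the
#' bounding mask image.
#'
#' @param marker numeric matrix, pointwise `<= mask_img`.
#' @param mask_img numeric bounding image.
#' @return numeric matrix, still pointwise `<= mask_img`.
#' @export
geodesic_dilate <- function(marker, mask_img) {
  check_marker(marker, mask_img)
  cpp_geodesic_dilate(marker, mask_img)
}

#' Morphological reconstruction by dilation
#'
#' Limit of iterated elementary geodesic dilations (stability reached when
#' one pass changes nothing), computed with the exact hybrid
#' raster/queue algorithm.  Used to imprint seed maxima on the distance
#' topography.
#'
#' @inheritParams geodesic_dilate
#' @return the reconstruction of `marker` under `mask_img`.
#' @export
reconstruct <- function(marker, mask_img) {
  check_marker(marker, mask_img)
  cpp_reconstruct(marker, mask_img)
}

check_marker <- function(marker, mask_img) {
  if (!is.matrix(marker) || !is.matrix(mask_img) ||
      !all(dim(marker) == dim(mask_img)))
    stop("marker and mask image must be matrices of equal shape")
  if (any(marker > mask_img + 1e-12))
    stop("marker must be <= mask image everywhere")
  invisible(TRUE)
}

#' Impose seeds on a topographic map
#'
#' Combines binary seeds with the distance topography by morphological
#' reconstruction: the marker keeps the topographic height at seed pixels
#' and is 0 elsewhere, and its reconstruction under the map suppresses
#' every regional maximum that contains no seed (they are flattened down
#' to their connecting saddle).  Seed heights themselves are preserved.
#'
#' @param tm topographic map (e.g. [distance_map()] output).
#' @param seeds binary seed mask; every seed pixel must lie strictly
#'   inside the foreground of `tm` (height > 0).
#' @return refined topographic map.
#' @export
impose_seeds <- function(tm, seeds) {
  seeds <- as_binary(seeds)
  if (!any(seeds == 1L)) stop("seed mask is empty")
  bad <- which(seeds == 1L & tm <= 0)
  if (length(bad)) {
    lab <- cpp_label_components(seeds, 8L)
    stop("seed component(s) ", paste(sort(unique(lab[bad])), collapse = ", "),
         " lie outside the mask of the topographic map")
  }
  marker <- tm * (seeds == 1L)
  cpp_reconstruct(marker, tm)
}

#' Seeded watershed flooding
#'
#' Floods basins from the seed components over the negated topographic
#' map (so basins sit at its maxima), restricted to the mask,
#' 4-connected, with a priority queue and first-in-first-out tie
#' breaking on equal priority.  Watershed-line pixels are assigned to the
#' first-arriving basin, so the basins partition the mask.
#'
#' @param tm topographic map (typically [impose_seeds()] output).
#' @param seeds binary seed mask; each connected component becomes one
#'   basin.
#' @param mask binary mask to segment.
#' @return integer label matrix; basin labels follow the raster-scan order
#'   of the seed components.  Mask pixels unreachable from any seed keep
#'   label 0.
#' @export
flood <- function(tm, seeds, mask) {
  mask <- as_binary(mask)
  seeds <- as_binary(seeds)
  if (!any(seeds == 1L)) stop("seed mask is empty")
  slab <- cpp_label_components(seeds, 8L)
  cpp_watershed(-tm, slab, mask)
}

#' Regional maxima of a topographic map
#'
#' Connected plateaus (8-connected) with no strictly higher neighbor,
#' restricted to the mask.  Used for the unseeded (classical) watershed
#' baseline, where each regional maximum becomes a seed.
#'
#' @param tm numeric matrix.
#' @param mask binary matrix restricting the domain.
#' @return integer label matrix of maxima with attribute `n`.
#' @export
regional_maxima <- function(tm, mask) {
  cpp_regional_maxima(tm, as_binary(mask))
}

#' Unseeded (classical) watershed of a binary mask
#'
#' Floods the negated Euclidean distance map from its own regional
#' maxima.  On jagged masks this over-segments, which is exactly the
#' failure mode the seeded variant avoids.
#'
#' @param mask binary matrix.
#' @return integer label matrix of basins.
#' @export
watershed_unseeded <- function(mask) {
  mask <- as_binary(mask)
  tm <- cpp_distance_map(mask)
  mx <- cpp_regional_maxima(tm, mask)
  cpp_watershed(-tm, mx, mask)
}
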