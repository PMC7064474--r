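#' Structuring elements for conditional erosion
#'
#' `se_coarse()` is the 7x7 octagonal element (23 pixels) used while
#' objects are large; `se_fine()` is the 3x3 cross (5 pixels) that is less
#' likely to make a nucleus disappear.  `se_cross()` is the elementary
#' 4-connected cross used for geodesic dilation.
#'
#' @return binary integer matrix with the origin at the center.
#' @export
se_coarse <- function() {
  matrix(c(0, 0, 0, 1, 0, 0, 0,
           0, 0, 1, 1, 1, 0, 0,
           0, 1, 1, 1, 1, 1, 0,
           0, 1, 1, 1, 1, 1, 0,
           0, 1, 1, 1, 1, 1, 0,
           0, 0, 1, 1, 1, 0, 0,
           0, 0, 0, 1, 0, 0, 0), 7, 7, byrow = TRUE)
}

#' @rdname se_coarse
#' @export
se_fine <- function() {
  matrix(c(0, 1, 0,
           1, 1, 1,
           0, 1, 0), 3, 3, byrow = TRUE)
}

#' @rdname se_coarse
#' @export
se_cross <- se_fine

#' Binary erosion
#'
#' Classical binary erosion: a pixel is kept iff the structuring element
#' translated there fits entirely inside the mask.  Outside-of-image
#' counts as background, so objects shrink inward at image borders.
#'
#' @param mask binary matrix.
#' @param se binary structuring element with odd side lengths, origin at
#'   the center.
#' @return eroded binary matrix.
#' @export
erode <- function(mask, se = se_fine()) {
  se <- as_binary(se)
  if (se[(nrow(se) + 1) / 2, (ncol(se) + 1) / 2] != 1)
    stop("structuring element origin must be set")
  cpp_binary_erode(as_binary(mask), se)
}

#' Binary dilation
#'
#' @inheritParams erode
#' @return dilated binary matrix.
#' @export
dilate <- function(mask, se = se_fine()) {
  cpp_binary_dilate(as_binary(mask), as_binary(se))
}

#' Erosion policy for seed detection
#'
#' Area thresholds controlling the two-phase conditional erosion: the
#' coarse element is applied while a component's area is at least `t1`
#' (default 350 px), then the fine element while it is at least `t2`
#' (default 50 px).
#'
#' @param t1 coarse-to-fine switch area, pixels.
#' @param t2 stopping area, pixels.
#' @return object of class `erosion_policy`.
#' @export
erosion_policy <- function(t1 = 350, t2 = 50) {
  if (!(t1 > t2 && t2 > 0)) stop("need t1 > t2 > 0")
  structure(list(t1 = t1, t2 = t2), class = "erosion_policy")
}

#' Conditional erosion: one seed per nucleus in a clump
#'
#' Two-phase conditional erosion of a clump mask.  Per connected
#' component: while its area is at least `t1`, erode with the coarse
#' element; then while its area is at least `t2`, erode with the fine
#' element.  Components are re-identified (8-connectivity) after every
#' erosion pass, so a component that splits is afterwards handled piece by
#' piece.  A component that would vanish under the next erosion is kept at
#' its last non-empty state, so every non-empty input component yields at
#' least one seed.
#'
#' @param clump binary mask of the clump (may contain several components).
#' @param policy an [erosion_policy()].
#' @param mc,mf coarse and fine structuring elements.
#' @return binary seed mask, a subset of `clump`; its connected components
#'   are the nucleus seeds.
#' @export
conditional_erode <- function(clump, policy = erosion_policy(),
                              mc = se_coarse(), mf = se_fine()) {
  clump <- as_binary(clump)
  if (!any(clump == 1L)) return(clump)
  out <- matrix(0L, nrow(clump), ncol(clump))

  process <- function(comp) {
    repeat {
      area <- sum(comp)
      if (area < policy$t2) {
        out[comp == 1L] <<- 1L
        return(invisible())
      }
      se <- if (area >= policy$t1) mc else mf
      nxt <- erode(comp, se)
      if (!any(nxt == 1L)) {           # vanish protection
        out[comp == 1L] <<- 1L
        return(invisible())
      }
      lab <- cpp_label_components(nxt, 8L)
      n <- attr(lab, "n")
      if (n == 1L) {
        comp <- nxt
      } else {
        for (k in seq_len(n))
          process(matrix(as.integer(lab == k), nrow(lab), ncol(lab)))
        return(invisible())
      }
    }
  }

  lab0 <- cpp_label_components(clump, 8L)
  for (k in seq_len(attr(lab0, "n")))
    process(matrix(as.integer(lab0 == k), nrow(lab0), ncol(lab0)))
  out
}
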