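#' Semantic class codes and class order
#'
#' Semantic maps are integer matrices with the palette
#' 0 = indeterminate, 1 = background, 2 = cytoplasm, 3 = nucleus,
#' 4 = nucleus_border.  Indeterminate is only allowed in reference maps,
#' never in predictions.  The classifier's class order (also the argmax
#' tie-break order) is nucleus, nucleus_border, cytoplasm, background.
#'
#' @return named integer vector mapping class names to semantic codes, in
#'   classifier class order.
#' @export
semantic_classes <- function() {
  c(nucleus = 3L, nucleus_border = 4L, cytoplasm = 2L, background = 1L)
}

#' Extract labeled patches around every annotated pixel
#'
#' For each pixel of the reference semantic map whose label is not
#' indeterminate, one `size` x `size` patch of the stain image centered at
#' that pixel is extracted (reflection padding at image borders).  The
#' patch label is the class of the central pixel.
#'
#' @param stain H x W stain concentration matrix (typically hematoxylin).
#' @param reference H x W semantic map aligned with `stain` (see
#'   [semantic_classes()]).
#' @param size odd patch side length; default 43.
#' @param positions optional n x 2 matrix of (row, col) centers; default
#'   all annotated pixels.
#' @return list of class `patch_set`: `x` (N x size^2 matrix, patch values
#'   in column-major patch order), `y` (integer class index 1..4 in
#'   classifier order), `pos` (N x 2 centers), `size`.
#' @export
extract_patches <- function(stain, reference, size = 43, positions = NULL) {
  if (size %% 2 == 0) stop("patch size must be odd")
  if (!all(dim(stain) == dim(reference)))
    stop("stain and reference must have the same shape")
  if (is.null(positions)) {
    idx <- which(reference != 0L)
    positions <- cbind((idx - 1L) %% nrow(stain) + 1L,
                       (idx - 1L) %/% nrow(stain) + 1L)
  } else {
    positions <- as.matrix(positions)
    keep <- reference[cbind(positions[, 1], positions[, 2])] != 0L
    positions <- positions[keep, , drop = FALSE]
  }
  storage.mode(positions) <- "integer"
  x <- cpp_extract_patches(stain, positions, as.integer(size))
  codes <- reference[cbind(positions[, 1], positions[, 2])]
  y <- match(codes, semantic_classes())
  structure(list(x = x, y = y, pos = positions, size = as.integer(size)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d patches of %dx%d\n", length(x$y), x$size,
              x$size))
  print(table(names(semantic_classes())[x$y]))
  invisible(x)
}

# Randomized similarity transform of one square patch: scale, rotation,
# flips; inverse mapping with bilinear interpolation and reflection at
# the patch boundary, so the output keeps the input shape.
transform_patch <- function(p, scale = 1, angle = 0, flip_v = FALSE,
                            flip_h = FALSE) {
  n <- nrow(p)
  ctr <- (n + 1) / 2
  u <- rep(seq_len(n) - ctr, times = n)     # row offsets
  v <- rep(seq_len(n) - ctr, each = n)      # col offsets
  if (flip_v) u <- -u
  if (flip_h) v <- -v
  ca <- cos(-angle); sa <- sin(-angle)
  sy <- (ca * u - sa * v) / scale + ctr
  sx <- (sa * u + ca * v) / scale + ctr
  refl <- function(i) {
    per <- 2 * (n - 1)
    i <- (i - 1) %% per
    i <- ifelse(i < 0, i + per, i)
    ifelse(i <= n - 1, i + 1, per - i + 1)
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  g <- function(yy, xx) p[cbind(refl(yy), refl(xx))]
  out <- (1 - fy) * (1 - fx) * g(y0, x0) +
         fy * (1 - fx) * g(y0 + 1, x0) +
         (1 - fy) * fx * g(y0, x0 + 1) +
         fy * fx * g(y0 + 1, x0 + 1)
  matrix(out, n, n)
}

#' Augment a patch set
#'
#' Rebalances the under-represented nucleus-border class: every border
#' patch is multiplied `factor` times by randomized scaling (factor drawn
#' from `scale`), rotation by a random angle and random vertical and/or
#' horizontal flips.  Patches of the other classes are randomly
#' transformed in place (each original replaced by its transform), so
#' their class counts do not change.  Class labels are never altered.
#'
#' @param patches a `patch_set` from [extract_patches()].
#' @param factor multiplication factor for the border class (default 4).
#' @param scale scaling-factor range, default `c(0.8, 1.2)`.
#' @param transform_in_place if `FALSE`, patches of the non-border classes
#'   are left untouched (with `factor = 1` the call is then the identity).
#' @param seed RNG seed; fixed seed gives identical output.
#' @return augmented `patch_set`.
#' @export
augment <- function(patches, factor = 4, scale = c(0.8, 1.2),
                    transform_in_place = TRUE, seed = 1) {
  stopifnot(inherits(patches, "patch_set"), factor >= 1)
  if (factor == 1 && !transform_in_place) return(patches)
  border_cls <- match("nucleus_border", names(semantic_classes()))
  n <- length(patches$y)
  size <- patches$size
  with_seed(seed, {
    rnd_transform <- function(row) {
      p <- matrix(row, size, size)
      p <- transform_patch(p,
                           scale = runif(1, scale[1], scale[2]),
                           angle = runif(1, 0, 2 * pi),
                           flip_v = runif(1) < 0.5,
                           flip_h = runif(1) < 0.5)
      as.vector(p)
    }
    is_border <- patches$y == border_cls
    if (factor > 1 && !any(is_border)) {
      warning("no nucleus_border patches to augment; returning input")
      return(patches)
    }
    # in-place randomized transform of non-border patches
    x <- patches$x
    if (transform_in_place)
      for (i in which(!is_border)) x[i, ] <- rnd_transform(patches$x[i, ])
    extra_x <- NULL; extra_y <- integer(); extra_pos <- NULL
    if (factor > 1 && any(is_border)) {
      bi <- which(is_border)
      reps <- as.integer(factor) - 1L
      extra_x <- matrix(0, length(bi) * reps, size * size)
      k <- 0L
      for (r in seq_len(reps))
        for (i in bi) {
          k <- k + 1L
          extra_x[k, ] <- rnd_transform(patches$x[i, ])
        }
      extra_y <- rep(patches$y[rep(bi, reps)])
      extra_pos <- patches$pos[rep(bi, reps), , drop = FALSE]
    }
    structure(list(x = rbind(x, extra_x),
                   y = c(patches$y, extra_y),
                   pos = rbind(patches$pos, extra_pos),
                   size = size),
              class = "patch_set")
  })
}

#' Nuclei mask from a semantic map
#'
#' Marks 1 exactly where the semantic label is `nucleus`.  Border pixels
#' are excluded by default: the one-pixel border ring predicted between
#' touching nuclei is what lets the semantic mask separate them.
#'
#' @param map semantic map (see [semantic_classes()]).
#' @param include_border if `TRUE`, nucleus_border pixels are included.
#' @return binary nuclei mask.
#' @export
mask_from_semantic <- function(map, include_border = FALSE) {
  keep <- if (include_border) c(3L, 4L) else 3L
  matrix(as.integer(map %in% keep), nrow(map), ncol(map))
}

#' Global Otsu nuclei mask
#'
#' Otsu's threshold on a 256-bin histogram of the stain image; foreground
#' is everything above the threshold.  A constant image yields an empty
#' mask with a warning.
#'
#' @param stain stain concentration matrix (finite values).
#' @return binary mask with attribute `threshold`.
#' @export
mask_otsu <- function(stain) {
  if (!all(is.finite(stain))) stop("stain image must be finite")
  lo <- min(stain); hi <- max(stain)
  if (hi - lo < 1e-12) {
    warning("constant image: Otsu mask is empty")
    out <- matrix(0L, nrow(stain), ncol(stain))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  nb <- 256L
  br <- seq(lo, hi, length.out = nb + 1L)
  h <- tabulate(pmin(findInterval(stain, br, rightmost.closed = TRUE), nb),
                nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-(nb + 1)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  thr <- br[k + 1L]
  out <- matrix(as.integer(stain > thr), nrow(stain), ncol(stain))
  attr(out, "threshold") <- thr
  out
}

#' Adaptive-threshold nuclei mask
#'
#' Per-pixel threshold equal to the local mean over a square window minus
#' `offset`; foreground is everything above its local threshold.  A
#' negative `offset` raises the threshold above the local mean and
#' suppresses background speckle.
#'
#' @param stain stain concentration matrix.
#' @param window odd window side length, pixels.
#' @param offset value subtracted from the local mean to form the
#'   threshold (concentration units).
#' @return binary mask.
#' @export
mask_adaptive <- function(stain, window = 75, offset = -0.05) {
  if (!all(is.finite(stain))) stop("stain image must be finite")
  if (window %% 2 == 0) stop("window must be odd")
  thr <- cpp_box_mean(stain, as.integer((window - 1) / 2)) - offset
  matrix(as.integer(stain > thr), nrow(stain), ncol(stain))
}
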