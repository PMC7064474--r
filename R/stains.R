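#' H&E stain color matrix
#'
#' Returns the supervised stain color matrix used for color deconvolution.
#' Columns are unit-norm RGB absorption vectors for hematoxylin, eosin and
#' a residual channel (the normalized cross product of the first two, so
#' the matrix is always invertible).  Default values are the classic
#' ImageJ/Ruifrok H&E vectors.
#'
#' @param h,e numeric length-3 RGB absorption vectors (need not be
#'   normalized).
#' @return 3x3 matrix with unit-norm columns named
#'   `c("hematoxylin", "eosin", "residual")`.
#' @examples
#' W <- stain_matrix_he()
#' colSums(W^2)   # all 1
#' @export
stain_matrix_he <- function(h = c(0.650, 0.704, 0.286),
                            e = c(0.072, 0.990, 0.105)) {
  stopifnot(length(h) == 3, length(e) == 3)
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r <- abs(r)  # absorption vectors are non-negative
  r <- r / sqrt(sum(r^2))
  W <- cbind(h, e, r)
  dimnames(W) <- list(c("R", "G", "B"), c("hematoxylin", "eosin", "residual"))
  W
}

#' Read a stain matrix from CSV
#'
#' The CSV must contain a 3-row numeric table, one column per stain; column
#' headers become stain names.  Columns are normalized to unit Euclidean
#' norm.
#'
#' @param path file path.
#' @return 3xk numeric matrix with unit-norm columns.
#' @examples
#' read_stain_matrix(system.file("extdata", "stain_he.csv",
#'                               package = "nucseg"))
#' @export
read_stain_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  W <- as.matrix(tab)
  if (nrow(W) != 3) stop("stain matrix CSV must have exactly 3 rows (R,G,B)")
  storage.mode(W) <- "double"
  if (any(W < 0)) stop("stain vector entries must be non-negative")
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  rownames(W) <- c("R", "G", "B")
  W
}

#' RGB image to optical density
#'
#' Converts an 8-bit RGB image to per-channel optical density via the
#' Beer-Lambert law with the base-10 convention,
#' `OD = -log10(max(I, 1) / i0)`.  Zero intensities are clamped to 1 before
#' the logarithm so the result is finite everywhere.
#'
#' @param img H x W x 3 array of intensities in `[0, 255]` (numeric or
#'   integer).
#' @param i0 incident light intensity; must be positive.  Default 255
#'   (8-bit white).
#' @return H x W x 3 numeric array of optical densities.
#' @examples
#' px <- array(c(255, 25.5, 0), c(1, 1, 3))
#' rgb_to_optical_density(px)[1, 1, ]   # 0, 1, log10(255)
#' @export
rgb_to_optical_density <- function(img, i0 = 255) {
  if (!is.numeric(i0) || length(i0) != 1 || is.na(i0) || i0 <= 0)
    stop("i0 must be a positive scalar")
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("img must be an H x W x 3 array")
  od <- -log10(pmax(img, 1) / i0)
  array(od, dim(img))
}

#' Color deconvolution
#'
#' Inverts the stain mixing model `OD = W %*% H` per pixel with the
#' (pseudo-)inverse of the stain matrix, recovering one concentration
#' image per stain.
#'
#' @param od H x W x 3 optical density array (see
#'   [rgb_to_optical_density()]).
#' @param w stain matrix with 2 or 3 linearly independent unit-norm
#'   columns; default [stain_matrix_he()].
#' @return named list of H x W concentration matrices, one per column of
#'   `w` (for the default matrix: `hematoxylin`, `eosin`, `residual`).
#' @export
deconvolve <- function(od, w = stain_matrix_he()) {
  if (length(dim(od)) != 3 || dim(od)[3] != 3)
    stop("od must be an H x W x 3 array")
  w <- as.matrix(w)
  if (nrow(w) != 3 || !ncol(w) %in% c(2, 3))
    stop("stain matrix must be 3 x 2 or 3 x 3")
  qrw <- qr(w)
  if (qrw$rank < ncol(w)) {
    bad <- colnames(w)[setdiff(seq_len(ncol(w)), qrw$pivot[seq_len(qrw$rank)])]
    if (is.null(bad) || !length(bad)) bad <- "(unnamed)"
    stop("stain matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  h <- dim(od)[1]; wd <- dim(od)[2]
  odm <- matrix(od, ncol = 3)          # n x 3
  pinv <- solve(crossprod(w), t(w))    # k x 3
  conc <- odm %*% t(pinv)              # n x k
  nm <- colnames(w)
  if (is.null(nm)) nm <- paste0("stain", seq_len(ncol(w)))
  out <- lapply(seq_len(ncol(w)), function(k) matrix(conc[, k], h, wd))
  names(out) <- nm
  out
}

#' Convenience: hematoxylin concentration from an RGB image
#'
#' @inheritParams rgb_to_optical_density
#' @inheritParams deconvolve
#' @return H x W hematoxylin concentration matrix.
#' @export
hematoxylin_image <- function(img, w = stain_matrix_he(), i0 = 255) {
  deconvolve(rgb_to_optical_density(img, i0), w)[[1]]
}

#' Per-position patch statistics
#'
#' Computes the per-position mean and standard deviation over a sample of
#' equally sized stain patches, for feature-wise standardization: every
#' pixel position inside the patch frame is one feature.  The population
#' (divide by N) standard deviation is used and floored at `floor`.
#'
#' @param patches N x (size^2) matrix of patches (rows are patches in
#'   column-major patch order, as returned by patch extraction) or a
#'   size x size x N array.
#' @param floor lower bound applied to the standard deviation.
#' @return object of class `position_stats`: list with `mean` and `sd`
#'   (size x size matrices), `size` and `n`.
#' @export
fit_position_stats <- function(patches, floor = 1e-6) {
  if (is.array(patches) && length(dim(patches)) == 3) {
    d <- dim(patches)
    if (d[1] != d[2]) stop("patches must be square")
    patches <- t(matrix(patches, d[1] * d[2], d[3]))
  }
  if (!is.matrix(patches)) stop("patches must be a matrix or 3-d array")
  n <- nrow(patches)
  if (n < 2) stop("need at least 2 patches")
  size <- sqrt(ncol(patches))
  if (size != round(size)) stop("patch length is not a perfect square")
  size <- as.integer(size)
  mu <- colMeans(patches)
  sdv <- sqrt(pmax(colMeans(patches^2) - mu^2, 0))
  sdv <- pmax(sdv, floor)
  structure(list(mean = matrix(mu, size, size),
                 sd = matrix(sdv, size, size),
                 size = size, n = n),
            class = "position_stats")
}

#' @export
print.position_stats <- function(x, ...) {
  cat(sprintf("position_stats: %dx%d patch frame, fitted on %d patches\n",
              x$size, x$size, x$n))
  invisible(x)
}

#' Standardize a patch (or patch set) with fitted position statistics
#'
#' @param patch size x size matrix, or N x size^2 matrix of patches.
#' @param stats a [fit_position_stats()] result of matching size.
#' @return object of the same shape as `patch`, standardized elementwise
#'   as `(value - mean) / sd` per position.
#' @export
standardize <- function(patch, stats) {
  if (!inherits(stats, "position_stats")) stop("stats must be position_stats")
  if (is.matrix(patch) && nrow(patch) == stats$size &&
      ncol(patch) == stats$size) {
    return((patch - stats$mean) / stats$sd)
  }
  if (is.matrix(patch) && ncol(patch) == stats$size^2) {
    mu <- as.vector(stats$mean); sdv <- as.vector(stats$sd)
    return(sweep(sweep(patch, 2, mu, "-"), 2, sdv, "/"))
  }
  stop("patch shape does not match stats (", stats$size, "x", stats$size, ")")
}
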