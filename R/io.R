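#' Read a plain (ASCII) PNM image
#'
#' Supports P2 (grayscale) and P3 (RGB) plain PNM.  These text formats are
#' the package's on-disk image representation; 16-bit label masks use P2
#' with maxval 65535.
#'
#' @param path file path.
#' @return for P2, an H x W numeric matrix; for P3, an H x W x 3 array.
#'   The maxval is attached as attribute `maxval`.
#' @export
read_pnm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  magic <- tok[1]
  if (!magic %in% c("P2", "P3")) stop("only plain P2/P3 PNM is supported")
  nums <- as.numeric(tok[-1])
  w <- nums[1]; h <- nums[2]; maxval <- nums[3]
  px <- nums[-(1:3)]
  if (magic == "P2") {
    if (length(px) != w * h) stop("corrupt PGM: wrong pixel count")
    out <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
  } else {
    if (length(px) != 3 * w * h) stop("corrupt PPM: wrong pixel count")
    m <- matrix(px, ncol = 3, byrow = TRUE)
    out <- array(0, c(h, w, 3))
    for (ch in 1:3) out[, , ch] <- matrix(m[, ch], h, w, byrow = TRUE)
  }
  attr(out, "maxval") <- maxval
  out
}

#' Write a plain (ASCII) PNM image
#'
#' Matrices are written as P2 grayscale, H x W x 3 arrays as P3 RGB.
#' Values are rounded and clamped to `[0, maxval]`.
#'
#' @param img matrix or H x W x 3 array.
#' @param path output file path.
#' @param maxval maximum pixel value written to the header (255 for 8-bit
#'   images, 65535 for label masks).
#' @return `path`, invisibly.
#' @export
write_pnm <- function(img, path, maxval = 255) {
  clamp <- function(v) pmin(pmax(round(v), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  if (is.matrix(img)) {
    writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)),
               con)
    apply(img, 1, function(row)
      writeLines(paste(clamp(row), collapse = " "), con))
  } else if (length(dim(img)) == 3 && dim(img)[3] == 3) {
    writeLines(c("P3", paste(dim(img)[2], dim(img)[1]),
                 as.character(maxval)), con)
    for (y in seq_len(dim(img)[1])) {
      row <- rbind(clamp(img[y, , 1]), clamp(img[y, , 2]), clamp(img[y, , 3]))
      writeLines(paste(as.vector(row), collapse = " "), con)
    }
  } else stop("img must be a matrix or an H x W x 3 array")
  invisible(path)
}
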