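# Independent oracles: deliberately naive implementations (brute force,
# fixpoint iteration, exhaustive enumeration) kept free of the package's
# C++ paths.

# exact EDT by scanning every background pixel
oracle_edt <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, H, W)
  bg <- which(mask == 0)
  fg <- which(mask != 0)
  if (!length(bg)) return(matrix(sqrt(H^2 + W^2), H, W) * (mask != 0))
  by <- (bg - 1) %% H + 1; bx <- (bg - 1) %/% H + 1
  for (i in fg) {
    y <- (i - 1) %% H + 1; x <- (i - 1) %/% H + 1
    out[i] <- sqrt(min((by - y)^2 + (bx - x)^2))
  }
  out
}

# one elementary 4-connected geodesic dilation via shifted copies
oracle_geodesic_step <- function(marker, mask) {
  H <- nrow(marker); W <- ncol(marker)
  m <- marker
  if (H > 1) {
    m <- pmax(m, rbind(marker[-1, , drop = FALSE], -Inf))
    m <- pmax(m, rbind(-Inf, marker[-H, , drop = FALSE]))
  }
  if (W > 1) {
    m <- pmax(m, cbind(marker[, -1, drop = FALSE], -Inf))
    m <- pmax(m, cbind(-Inf, marker[, -W, drop = FALSE]))
  }
  pmin(m, mask)
}

# reconstruction by dilation as the literal fixpoint of elementary steps
oracle_reconstruct <- function(marker, mask) {
  cur <- marker
  repeat {
    nxt <- oracle_geodesic_step(cur, mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# Hausdorff distance by the full double loop
oracle_hausdorff <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

# connected component count by repeated flood fill
oracle_component_count <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  nb <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  count <- 0
  for (start in which(mask != 0)) {
    sy <- (start - 1) %% H + 1; sx <- (start - 1) %/% H + 1
    if (seen[sy, sx]) next
    count <- count + 1
    stack <- list(c(sy, sx)); seen[sy, sx] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (j in seq_len(nrow(nb))) {
        y <- p[1] + nb[j, 1]; x <- p[2] + nb[j, 2]
        if (y >= 1 && y <= H && x >= 1 && x <= W &&
            mask[y, x] != 0 && !seen[y, x]) {
          seen[y, x] <- TRUE
          stack[[length(stack) + 1]] <- c(y, x)
        }
      }
    }
  }
  count
}

# brute-force binary erosion straight from the definition
oracle_erode <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask)
  cy <- (nrow(se) + 1) / 2; cx <- (ncol(se) + 1) / 2
  off <- which(se == 1, arr.ind = TRUE)
  out <- matrix(0L, H, W)
  for (x in 1:W) for (y in 1:H) {
    keep <- TRUE
    for (j in seq_len(nrow(off))) {
      yy <- y + off[j, 1] - cy; xx <- x + off[j, 2] - cx
      if (yy < 1 || yy > H || xx < 1 || xx > W || mask[yy, xx] == 0) {
        keep <- FALSE; break
      }
    }
    out[y, x] <- as.integer(keep)
  }
  out
}

# contour-walk perimeter: Moore boundary tracing with the
# Vossepoel-Smeulders corrected step lengths (0.948 axial, 1.340
# diagonal); independent of the 2x2-configuration Crofton estimator.
oracle_contour_perimeter <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask != 0)
  if (length(fg) == 1) return(4 * 0.948)
  # raster-first pixel: smallest row, then column
  ys <- (fg - 1) %% H + 1; xs <- (fg - 1) %/% H + 1
  o <- order(ys, xs)
  sy <- ys[o[1]]; sx <- xs[o[1]]
  # Moore neighborhood clockwise starting from west
  dirs <- cbind(c(0, -1, -1, -1, 0, 1, 1, 1), c(-1, -1, 0, 1, 1, 1, 0, -1))
  inside <- function(y, x) y >= 1 && y <= H && x >= 1 && x <= W &&
    mask[y, x] != 0
  cy <- sy; cx <- sx; backtrack <- 0  # 0-based index of dir to previous px
  n_ax <- 0; n_di <- 0
  repeat {
    found <- FALSE
    for (s in 1:8) {
      k0 <- (backtrack + s) %% 8
      k <- k0 + 1
      y <- cy + dirs[k, 1]; x <- cx + dirs[k, 2]
      if (inside(y, x)) {
        if (dirs[k, 1] != 0 && dirs[k, 2] != 0) n_di <- n_di + 1
        else n_ax <- n_ax + 1
        backtrack <- (k0 + 4) %% 8  # direction back to the pixel we left
        cy <- y; cx <- x
        found <- TRUE
        break
      }
    }
    if (!found) return(4 * 0.948)  # isolated pixel
    if ((cy == sy && cx == sx && n_ax + n_di > 2) ||
        n_ax + n_di > 500000) break
  }
  0.948 * n_ax + 1.340 * n_di
}

# exhaustive maximum matching under a distance threshold: maximize match
# count, break ties by minimal total distance; returns the best count
oracle_best_match_count <- function(D, threshold) {
  nr <- nrow(D); np <- ncol(D)
  best <- list(count = 0, total = Inf)
  recurse <- function(i, used_p, count, total) {
    if (count + (nr - i + 1) < best$count) return()
    if (i > nr) {
      if (count > best$count ||
          (count == best$count && total < best$total))
        best <<- list(count = count, total = total)
      return()
    }
    recurse(i + 1, used_p, count, total)  # leave reference i unmatched
    for (j in seq_len(np)) {
      if (!used_p[j] && D[i, j] <= threshold) {
        used_p[j] <- TRUE
        recurse(i + 1, used_p, count + 1, total + D[i, j])
        used_p[j] <- FALSE
      }
    }
  }
  recurse(1, logical(np), 0, 0)
  best$count
}

# tiny helpers used across tests
disc_mask <- function(h, w, cy, cx, r) ellipse_mask(h, w, cy, cx, r, r)

rand_mask <- function(h, w, p = 0.5) {
  m <- matrix(as.integer(stats::runif(h * w) < p), h, w)
  m
}
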