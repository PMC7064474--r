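#' Rasterize a filled ellipse
#'
#' @param h,w canvas size.
#' @param cy,cx center (pixels, may be fractional).
#' @param a,b semi-axes (pixels).
#' @param angle rotation (radians).
#' @return binary matrix.
#' @export
ellipse_mask <- function(h, w, cy, cx, a, b, angle = 0) {
  y <- matrix(seq_len(h), h, w) - cy
  x <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  ca <- cos(angle); sa <- sin(angle)
  u <- ca * y + sa * x
  v <- -sa * y + ca * x
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), h, w)
}

#' Roughen the boundary of a binary mask
#'
#' Randomly deletes foreground boundary pixels and adds background pixels
#' adjacent to the object, emulating the jagged contours of intensity
#' thresholded masks.  Used to study watershed over-segmentation.
#'
#' @param mask binary matrix.
#' @param p toggle probability per boundary pixel.
#' @param seed RNG seed.
#' @return binary matrix.
#' @export
jitter_boundary <- function(mask, p = 0.35, seed = 1) {
  mask <- as_binary(mask)
  with_seed(seed, {
    er <- cpp_binary_erode(mask, se_fine())
    inner <- mask == 1L & er == 0L            # foreground boundary
    di <- cpp_binary_dilate(mask, se_fine())
    outer <- mask == 0L & di == 1L            # adjacent background
    out <- mask
    out[inner & matrix(runif(length(mask)) < p, nrow(mask))] <- 0L
    out[outer & matrix(runif(length(mask)) < p, nrow(mask))] <- 1L
    out
  })
}

# separable Gaussian blur with edge replication; sigma in pixels
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  clampi <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, H, W)
  for (d in -r:r) out <- out + k[d + r + 1] * m[clampi(seq_len(H) + d, H), ]
  m2 <- out
  out <- matrix(0, H, W)
  for (d in -r:r) out <- out + k[d + r + 1] * m2[, clampi(seq_len(W) + d, W)]
  out
}

#' Scene specification for the synthetic generator
#'
#' Describes a synthetic cytological scene: hematoxylin-dominant
#' elliptical nuclei (each surrounded by an eosin-dominant cytoplasm
#' halo) on a clean background.  Nuclei are ellipses with minor semi-axis
#' drawn from `axis_b` and aspect ratio from `aspect`; the defaults give
#' areas of roughly 4700-7300 px and roundness 0.92-0.98, i.e. the upper
#' part of the reference morphometric distribution (area 309-7801,
#' roundness 0.31-0.99).  This matters: with nuclei of this size a merged
#' pair exceeds the area gate and is detected as a clump, exactly the
#' regime the clump separator addresses, while every single nucleus still
#' passes the gate.  Rendering follows the base-10 Beer-Lambert model
#' `I = i0 * 10^(-W H)` with a 1 px optical blur of the concentration
#' maps and additive Gaussian sensor noise (sd 2 on the 8-bit scale).
#'
#' @param width,height canvas size in pixels.
#' @param n_nuclei number of nuclei.
#' @param overlap_fraction fraction of nuclei placed as overlap partners
#'   of a previously isolated nucleus, in `[0, 1)` (0.3 means 30 percent
#'   of the nuclei form two-nucleus clumps with a host, so 60 percent of
#'   all nuclei end up inside a clump).
#' @param axis_b minor semi-axis range (pixels).
#' @param aspect major/minor aspect-ratio range; keep the lower end above
#'   about 1.3 so that digital roundness stays below the 0.99 gate.
#' @param concentrations named list of `c(hematoxylin, eosin)`
#'   concentrations for `nucleus`, `cytoplasm`, `background`.
#' @param rim_factor multiplicative hematoxylin boost on the one-pixel
#'   visible contour of each nucleus, emulating peripheral chromatin
#'   condensation (the darker nuclear rim seen in H&E).  This is what
#'   gives the nucleus-border class a distinct intensity signature, in
#'   particular along the faint boundary between two overlapping nuclei.
#' @param noise_sd Gaussian noise sd on the 8-bit intensity scale.
#' @param blur_sigma optical blur of the concentration maps (pixels).
#' @param i0 incident intensity (8-bit white).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width = 1024, height = 1024, n_nuclei = 30,
                       overlap_fraction = 0.3,
                       axis_b = c(34, 38), aspect = c(1.3, 1.6),
                       concentrations = list(nucleus = c(1.0, 0.2),
                                             cytoplasm = c(0.15, 0.7),
                                             background = c(0.02, 0.02)),
                       rim_factor = 1.6, noise_sd = 2, blur_sigma = 1,
                       i0 = 255, seed = 1) {
  stopifnot(width >= 64, height >= 64, n_nuclei >= 0,
            overlap_fraction >= 0, overlap_fraction < 1,
            all(axis_b > 0), all(aspect >= 1), rim_factor >= 1,
            noise_sd >= 0, i0 > 0)
  structure(as.list(environment()), class = "scene_spec")
}

#' Generate a synthetic cytological scene with exact ground truth
#'
#' Non-overlapping nuclei are placed first by rejection sampling; then
#' `overlap_fraction * n_nuclei` additional nuclei are each attached to a
#' previously isolated host at a center distance of 1.3-1.5 times the
#' mean equivalent radius, so the pair merges into one clump whose seeds
#' remain recoverable by conditional erosion.  Overlaps in the label mask
#' are resolved by z-order (the later nucleus wins) while the truth list
#' keeps every full silhouette, so evaluation can use either convention.
#'
#' @param spec a [scene_spec()].
#' @return object of class `synthetic_scene`: `rgb` (H x W x 3 8-bit
#'   array), `labels` (z-order label mask), `mask` (binary union nuclei
#'   mask, the oracle mask input of the pipeline), `semantic` (reference
#'   semantic map with 1 px visible-contour border ring), `silhouettes`
#'   (list of full per-nucleus coordinate sets), `ellipses` (data.frame of
#'   true parameters), `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height; W <- spec$width
  n <- spec$n_nuclei
  with_seed(spec$seed, {
    if (n == 0) {
      return(structure(list(
        rgb = render_concentrations(matrix(spec$concentrations$background[1],
                                           H, W),
                                    matrix(spec$concentrations$background[2],
                                           H, W), spec),
        labels = matrix(0L, H, W), mask = matrix(0L, H, W),
        semantic = matrix(1L, H, W), silhouettes = list(),
        ellipses = data.frame(), spec = spec), class = "synthetic_scene"))
    }
    n_over <- round(n * spec$overlap_fraction)
    n_iso <- n - n_over
    margin <- max(spec$axis_b) * max(spec$aspect) + 4
    par <- data.frame(cy = double(), cx = double(), a = double(),
                      b = double(), angle = double(), host = integer())
    req <- function(k) sqrt(par$a[k] * par$b[k])
    tries <- 0
    while (nrow(par) < n_iso) {
      tries <- tries + 1
      if (tries > 5000 * n)
        stop("could not place ", n, " nuclei; reduce the count")
      b <- runif(1, spec$axis_b[1], spec$axis_b[2])
      a <- b * runif(1, spec$aspect[1], spec$aspect[2])
      cy <- runif(1, margin, H - margin); cx <- runif(1, margin, W - margin)
      ok <- TRUE
      if (nrow(par) > 0) {
        d <- sqrt((par$cy - cy)^2 + (par$cx - cx)^2)
        # keep full silhouettes (and their 1 px borders) disjoint
        ok <- all(d > par$a + a + 3)
      }
      if (ok) par[nrow(par) + 1, ] <- list(cy, cx, a, b, 0, NA_integer_)
    }
    free_hosts <- seq_len(n_iso)
    k <- 0
    while (k < n_over) {
      tries <- tries + 1
      if (tries > 5000 * n)
        stop("could not place ", n, " nuclei; reduce the count")
      if (!length(free_hosts)) stop("not enough hosts for overlap target")
      hst <- if (length(free_hosts) == 1) free_hosts else sample(free_hosts, 1)
      b <- runif(1, spec$axis_b[1], spec$axis_b[2])
      a <- b * runif(1, spec$aspect[1], spec$aspect[2])
      r_new <- sqrt(a * b)
      d <- runif(1, 1.3, 1.5) * mean(c(req(hst), r_new))
      th <- runif(1, 0, 2 * pi)
      cy <- par$cy[hst] + d * sin(th); cx <- par$cx[hst] + d * cos(th)
      if (cy < margin || cy > H - margin || cx < margin || cx > W - margin)
        next
      others <- setdiff(seq_len(nrow(par)), hst)
      if (length(others)) {
        dd <- sqrt((par$cy[others] - cy)^2 + (par$cx[others] - cx)^2)
        if (any(dd <= par$a[others] + a + 3)) next
      }
      par[nrow(par) + 1, ] <- list(cy, cx, a, b, runif(1, 0, pi), hst)
      free_hosts <- setdiff(free_hosts, hst)
      k <- k + 1
    }
    par$angle[seq_len(n_iso)] <- runif(n_iso, 0, pi)

    labels <- matrix(0L, H, W)
    sil <- vector("list", nrow(par))
    for (i in seq_len(nrow(par))) {
      m <- ellipse_mask(H, W, par$cy[i], par$cx[i], par$a[i], par$b[i],
                        par$angle[i])
      sil[[i]] <- as_coords(m)
      labels[m == 1L] <- i
    }
    mask <- matrix(as.integer(labels > 0L), H, W)

    # visible-contour border ring: pixels whose 8-neighborhood contains a
    # different label (including background), thickened by one inward
    # dilation (annotation strokes are wider than one pixel; a one-pixel
    # predicted ring would not survive single-pixel classifier errors)
    border <- visible_borders(labels)
    border <- matrix(as.integer(border == 1L |
                                  (dilate(border) == 1L & labels > 0L)),
                     H, W)
    semantic <- matrix(1L, H, W)
    cyto <- matrix(0L, H, W)
    for (i in seq_len(nrow(par))) {
      cm <- ellipse_mask(H, W, par$cy[i], par$cx[i], 1.6 * par$a[i],
                         1.6 * par$b[i], par$angle[i])
      cyto[cm == 1L] <- 1L
    }
    semantic[cyto == 1L] <- 2L
    semantic[mask == 1L] <- 3L
    semantic[border == 1L] <- 4L

    # concentration maps with mild per-nucleus brightness jitter
    cc <- spec$concentrations
    hmap <- matrix(cc$background[1], H, W)
    emap <- matrix(cc$background[2], H, W)
    hmap[cyto == 1L] <- cc$cytoplasm[1]
    emap[cyto == 1L] <- cc$cytoplasm[2]
    jit <- runif(nrow(par), 0.9, 1.1)
    for (i in seq_len(nrow(par))) {
      px <- sil[[i]]
      vis <- labels[px] == i
      hmap[px[vis, , drop = FALSE]] <- cc$nucleus[1] * jit[i]
      emap[px[vis, , drop = FALSE]] <- cc$nucleus[2]
    }
    # peripheral chromatin rim along each visible nucleus contour
    hmap[border == 1L] <- hmap[border == 1L] * spec$rim_factor
    rgb <- render_concentrations(gaussian_blur(hmap, spec$blur_sigma),
                                 gaussian_blur(emap, spec$blur_sigma), spec)
    structure(list(rgb = rgb, labels = labels, mask = mask,
                   semantic = semantic, silhouettes = sil,
                   ellipses = par, spec = spec),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %dx%d, %d nuclei (%d clumped)\n",
              nrow(x$labels), ncol(x$labels), length(x$silhouettes),
              sum(!is.na(x$ellipses$host)) * 2L))
  invisible(x)
}

# border ring: label pixels with a differently labeled 8-neighbor
visible_borders <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  pad <- matrix(-1L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- labels
  border <- matrix(FALSE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[2:(H + 1) + dy, 2:(W + 1) + dx]
    border <- border | (labels > 0L & nb != labels & nb != -1L)
  }
  matrix(as.integer(border), H, W)
}

#' Render concentration maps to an 8-bit RGB image
#'
#' Forward Beer-Lambert model in the base-10 convention,
#' `I = i0 * 10^(-W H)` with the default H&E stain matrix, additive
#' Gaussian noise, clamping to `[0, 255]` and rounding to integers.
#' Inverse of [rgb_to_optical_density()] + [deconvolve()] up to noise and
#' quantization.
#'
#' @param hmap,emap hematoxylin and eosin concentration matrices.
#' @param spec a [scene_spec()] (used for `i0` and `noise_sd`).
#' @return H x W x 3 integer-valued array.
#' @export
render_concentrations <- function(hmap, emap, spec = scene_spec()) {
  W3 <- stain_matrix_he()
  H <- nrow(hmap); Wd <- ncol(hmap)
  conc <- rbind(as.vector(hmap), as.vector(emap), 0)
  od <- W3 %*% conc                      # 3 x n
  I <- spec$i0 * 10^(-od)
  if (spec$noise_sd > 0)
    I <- I + rnorm(length(I), 0, spec$noise_sd)
  I <- round(pmin(pmax(I, 0), 255))
  out <- array(0, c(H, Wd, 3))
  for (ch in 1:3) out[, , ch] <- matrix(I[ch, ], H, Wd)
  out
}

#' Generate one clump of k overlapping discs
#'
#' Builds a chain of k discs with radii drawn from `radius` and
#' consecutive center distances of `dist_factor` times the mean radius of
#' the pair, returning one connected blob together with the true count.
#' This is the parameter-recovery fixture for conditional erosion.
#'
#' The default geometry keeps overlaps moderate: radius ratios within a
#' chain stay below 4:3 and center distances sit at 1.55-1.75 mean radii
#' (comfortably above the 1.2 lower bound, comfortably below the tangent
#' distance of 2).  Deeper overlaps - a nucleus mostly engulfed by a
#' larger one - leave a neck wider than the smaller disc's erosion
#' lifetime, so no erosion schedule can split them before the
#' vanish-protection stops; such clumps are exactly the ones the
#' pipeline later rejects as unseparable.
#'
#' @param k number of discs (>= 2).
#' @param radius radius range, pixels.
#' @param dist_factor range of center distance as a multiple of the pair's
#'   mean radius.
#' @param ratio_max maximum radius ratio between chain neighbors.
#' @param seed RNG seed.
#' @param boundary_jitter optional boundary roughening probability
#'   (see [jitter_boundary()]); 0 disables.
#' @return list with `mask` (binary blob on a tight canvas), `k`,
#'   `centers`, `radii`.
#' @export
generate_clump <- function(k, radius = c(12, 30),
                           dist_factor = c(1.55, 1.75), ratio_max = 4 / 3,
                           seed = 1, boundary_jitter = 0) {
  stopifnot(k >= 2, dist_factor[1] <= dist_factor[2])
  with_seed(seed, {
    for (attempt in 1:50) {
      r <- double(k)
      r[1] <- runif(1, radius[1], radius[2])
      for (i in seq_len(k - 1) + 1)
        r[i] <- min(max(r[i - 1] * runif(1, 1 / ratio_max, ratio_max),
                        radius[1]), radius[2])
      cy <- double(k); cx <- double(k)
      pad <- max(radius) * (k + 1) + 8
      cy[1] <- pad; cx[1] <- pad
      th <- runif(1, 0, 2 * pi)
      ok <- TRUE
      for (i in 2:k) {
        lo <- dist_factor[1] * mean(r[c(i - 1, i)])
        hi <- min(dist_factor[2] * mean(r[c(i - 1, i)]),
                  r[i - 1] + r[i] - 3)
        if (lo >= hi) { ok <- FALSE; break }
        d <- runif(1, lo, hi)
        th <- th + runif(1, -pi / 4, pi / 4)
        cy[i] <- cy[i - 1] + d * sin(th)
        cx[i] <- cx[i - 1] + d * cos(th)
      }
      if (!ok) next
      ylim <- range(cy); xlim <- range(cx)
      off <- max(r) + 4
      Hc <- ceiling(ylim[2] - ylim[1] + 2 * off)
      Wc <- ceiling(xlim[2] - xlim[1] + 2 * off)
      cy <- cy - ylim[1] + off; cx <- cx - xlim[1] + off
      m <- matrix(0L, Hc, Wc)
      for (i in 1:k)
        m <- pmax(m, ellipse_mask(Hc, Wc, cy[i], cx[i], r[i], r[i]))
      storage.mode(m) <- "integer"
      if (boundary_jitter > 0)
        m <- jitter_boundary(m, boundary_jitter,
                             seed = sample.int(1e6, 1))
      lab <- cpp_label_components(m, 8L)
      if (attr(lab, "n") == 1L)
        return(list(mask = m, k = k, centers = cbind(cy, cx), radii = r))
    }
    stop("could not build a connected clump with these parameters")
  })
}

#' Build a balanced labeled patch corpus from synthetic scenes
#'
#' Scenes are split into a training and a validation group (no scene
#' contributes to both, mirroring a patient-level split).  From each
#' scene's hematoxylin concentration image (obtained through the full
#' optical-density + deconvolution path), up to `n_per_class` patch
#' centers per class are sampled from the reference semantic map.
#' Position statistics are fitted on the training patches and applied to
#' both splits.
#'
#' @param scenes list of [generate_scene()] scenes.
#' @param size odd patch side.
#' @param n_per_class patches sampled per class per scene.
#' @param augment_factor if greater than 1, the training split is passed
#'   through [augment()] with this border-class multiplication factor
#'   (randomized scale/rotate/flip), mirroring the reference
#'   border-augmentation step; the validation split is never augmented.
#' @param val_scenes indices of scenes reserved for validation; default
#'   the second half.
#' @param seed RNG seed for sampling.
#' @return list with `train` and `val` (each `x`, `y`), `stats`
#'   (position statistics fitted on the training split), `counts`
#'   (class x split table).
#' @export
generate_patch_corpus <- function(scenes, size = 43, n_per_class = 250,
                                  augment_factor = 1, val_scenes = NULL,
                                  seed = 1) {
  stopifnot(length(scenes) >= 2)
  if (is.null(val_scenes))
    val_scenes <- seq_len(length(scenes)) > length(scenes) / 2
  else
    val_scenes <- seq_along(scenes) %in% val_scenes
  cls_codes <- semantic_classes()
  with_seed(seed, {
    harvest <- function(scene) {
      hema <- hematoxylin_image(scene$rgb)
      pos <- NULL
      for (code in cls_codes) {
        idx <- which(scene$semantic == code)
        if (!length(idx))
          stop("class with code ", code, " missing from a scene")
        take <- sample(idx, min(n_per_class, length(idx)))
        pos <- rbind(pos, cbind((take - 1L) %% nrow(hema) + 1L,
                                (take - 1L) %/% nrow(hema) + 1L))
      }
      extract_patches(hema, scene$semantic, size = size, positions = pos)
    }
    bind_sets <- function(sets) {
      list(x = do.call(rbind, lapply(sets, `[[`, "x")),
           y = do.call(c, lapply(sets, `[[`, "y")))
    }
    train <- bind_sets(lapply(scenes[!val_scenes], harvest))
    val <- bind_sets(lapply(scenes[val_scenes], harvest))
    if (length(unique(train$y)) < 4 || length(unique(val$y)) < 4)
      stop("a class is missing from the corpus")
    if (augment_factor > 1) {
      ps <- structure(list(x = train$x, y = train$y,
                           pos = matrix(0L, length(train$y), 2),
                           size = as.integer(size)),
                      class = "patch_set")
      ps <- augment(ps, factor = augment_factor,
                    seed = sample.int(1e6, 1))
      train <- list(x = ps$x, y = ps$y)
    }
    stats <- fit_position_stats(
      train$x[sample(nrow(train$x), min(10000, nrow(train$x))), ,
              drop = FALSE])
    train$x <- standardize(train$x, stats)
    val$x <- standardize(val$x, stats)
    counts <- rbind(train = tabulate(train$y, 4), val = tabulate(val$y, 4))
    colnames(counts) <- names(cls_codes)
    list(train = train, val = val, stats = stats, counts = counts)
  })
}
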