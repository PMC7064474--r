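#' Object sets for evaluation
#'
#' An object set is a list of per-object pixel sets on a shared canvas.
#' It can be built from an integer label matrix (predictions) or from a
#' list of binary masks (reference annotations, which may overlap each
#' other).
#'
#' @param x integer label matrix, or a list of binary matrices of common
#'   shape, or a list of n x 2 (row, col) coordinate matrices (requires
#'   `dim`).
#' @param dim canvas dimensions `c(H, W)`; taken from `x` when possible.
#' @param source tag, `"reference"` or `"predicted"`.
#' @return object of class `object_set`: list with `coords` (list of n x 2
#'   integer matrices), `dim`, `source`.
#' @export
object_set <- function(x, dim = NULL, source = "reference") {
  if (is.matrix(x)) {
    dim <- base::dim(x)
    n <- max(x, 0)
    coords <- vector("list", n)
    idx <- which(x > 0)
    lab <- x[idx]
    ys <- (idx - 1L) %% dim[1] + 1L
    xs <- (idx - 1L) %/% dim[1] + 1L
    sp <- split(seq_along(idx), factor(lab, levels = seq_len(n)))
    for (k in seq_len(n)) coords[[k]] <- cbind(ys[sp[[k]]], xs[sp[[k]]])
  } else if (is.list(x)) {
    coords <- lapply(x, function(m) {
      if (is.matrix(m) && ncol(m) == 2 && !all(m %in% c(0, 1))) {
        storage.mode(m) <- "integer"
        return(m)
      }
      if (is.null(dim)) dim <<- base::dim(m)
      i <- which(m != 0)
      cbind((i - 1L) %% nrow(m) + 1L, (i - 1L) %/% nrow(m) + 1L)
    })
  } else stop("x must be a label matrix or a list of masks")
  if (any(vapply(coords, nrow, 0L) == 0L)) stop("objects must be non-empty")
  if (is.null(dim)) stop("canvas dim required for coordinate input")
  structure(list(coords = coords, dim = dim, source = source),
            class = "object_set")
}

#' @export
print.object_set <- function(x, ...) {
  cat(sprintf("object_set (%s): %d objects on a %dx%d canvas\n", x$source,
              length(x$coords), x$dim[1], x$dim[2]))
  invisible(x)
}

as_coords <- function(m) {
  if (is.matrix(m) && ncol(m) == 2 && nrow(m) > 0 && !all(m %in% c(0, 1)))
    return(m)
  i <- which(m != 0)
  if (!length(i)) stop("empty object")
  cbind((i - 1L) %% nrow(m) + 1L, (i - 1L) %/% nrow(m) + 1L)
}

#' Hausdorff distance between two pixel sets
#'
#' `max(sup_a inf_b d, sup_b inf_a d)` over the full object pixel
#' coordinates (not contours only), Euclidean metric.
#'
#' @param a,b non-empty binary matrices or n x 2 coordinate matrices.
#' @return distance in pixels.
#' @examples
#' hausdorff(rbind(c(0, 0)), rbind(c(3, 4)))  # 5
#' @export
hausdorff <- function(a, b) {
  ca <- as_coords(a); cb <- as_coords(b)
  if (!nrow(ca) || !nrow(cb)) stop("empty object")
  cpp_hausdorff(matrix(as.double(ca), ncol = 2),
                matrix(as.double(cb), ncol = 2))
}

#' Jaccard distance between two pixel sets
#'
#' `1 - |intersection| / |union|` of the two pixel sets.
#'
#' @inheritParams hausdorff
#' @return value in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  ca <- as_coords(a); cb <- as_coords(b)
  if (!nrow(ca) || !nrow(cb)) stop("empty object")
  H <- max(ca[, 1], cb[, 1]) + 1L
  ia <- ca[, 1] + H * ca[, 2]
  ib <- cb[, 1] + H * cb[, 2]
  inter <- sum(ia %in% ib)
  1 - inter / (length(ia) + length(ib) - inter)
}

object_bbox <- function(coords)
  c(min(coords[, 1]), max(coords[, 1]), min(coords[, 2]), max(coords[, 2]))

bbox_gap <- function(b1, b2) {
  dy <- max(0, max(b1[1], b2[1]) - min(b1[2], b2[2]))
  dx <- max(0, max(b1[3], b2[3]) - min(b1[4], b2[4]))
  sqrt(dy^2 + dx^2)
}

#' Match predicted objects to reference objects
#'
#' Builds the reference x predicted distance matrix under the chosen
#' metric (candidate pairs are pruned by bounding boxes, which is exact
#' under the thresholds: boxes further apart than the Hausdorff threshold
#' cannot match, and disjoint boxes have Jaccard distance 1), then
#' matches greedily, globally smallest distance first, each object used
#' at most once, pairs above the threshold never matched.  Unmatched
#' reference objects are false negatives, unmatched predictions false
#' positives.  Rates: `tp_rate = TP / |reference|`,
#' `fp_rate = FP / |predicted|` (0 when there are no predictions).
#'
#' @param reference,predicted [object_set()]s (label matrices and lists of
#'   masks are converted automatically).
#' @param metric `"hausdorff"` or `"jaccard"`.
#' @param threshold maximum distance for a match; defaults 30 (Hausdorff)
#'   and 0.5 (Jaccard).
#' @return object of class `match_report`: counts `tp`, `fp`, `fn`, rates,
#'   and `pairs` (data.frame ref, pred, distance).
#' @export
match_objects <- function(reference, predicted,
                          metric = c("jaccard", "hausdorff"),
                          threshold = NULL) {
  metric <- match.arg(metric)
  if (is.null(threshold)) threshold <- if (metric == "hausdorff") 30 else 0.5
  if (threshold <= 0) stop("threshold must be positive")
  if (!inherits(reference, "object_set"))
    reference <- object_set(reference, source = "reference")
  if (!inherits(predicted, "object_set"))
    predicted <- object_set(predicted, source = "predicted")
  nr <- length(reference$coords); np <- length(predicted$coords)
  if (nr == 0) stop("empty reference set: rates undefined")

  rb <- lapply(reference$coords, object_bbox)
  pb <- lapply(predicted$coords, object_bbox)
  cand_r <- integer(); cand_p <- integer(); cand_d <- double()
  for (i in seq_len(nr)) {
    for (j in seq_len(np)) {
      gap <- bbox_gap(rb[[i]], pb[[j]])
      if (metric == "hausdorff") {
        if (gap > threshold) next
        d <- hausdorff(reference$coords[[i]], predicted$coords[[j]])
      } else {
        if (gap > 0) next  # disjoint boxes: JD = 1 > any threshold < 1
        d <- jaccard_distance(reference$coords[[i]], predicted$coords[[j]])
      }
      if (d <= threshold) {
        cand_r <- c(cand_r, i); cand_p <- c(cand_p, j); cand_d <- c(cand_d, d)
      }
    }
  }
  ord <- order(cand_d, cand_r, cand_p)
  used_r <- logical(nr); used_p <- logical(np)
  mr <- integer(); mp <- integer(); md <- double()
  for (k in ord) {
    i <- cand_r[k]; j <- cand_p[k]
    if (used_r[i] || used_p[j]) next
    used_r[i] <- TRUE; used_p[j] <- TRUE
    mr <- c(mr, i); mp <- c(mp, j); md <- c(md, cand_d[k])
  }
  tp <- length(mr)
  structure(list(metric = metric, threshold = threshold,
                 pairs = data.frame(ref = mr, pred = mp, distance = md),
                 tp = tp, fp = np - tp, fn = nr - tp,
                 n_ref = nr, n_pred = np,
                 tp_rate = tp / nr,
                 fp_rate = if (np > 0) (np - tp) / np else 0),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "match_report (%s <= %g): TP %d, FP %d, FN %d; tp_rate %.3f, fp_rate %.3f\n",
    x$metric, x$threshold, x$tp, x$fp, x$fn, x$tp_rate, x$fp_rate))
  invisible(x)
}

#' Summary statistics over match reports
#'
#' Per group, mean / standard deviation / max / min of the TP and FP
#' rates, mirroring the per-case result tables.
#'
#' @param reports list of [match_objects()] reports.
#' @param groups optional character vector of group labels (e.g. benign /
#'   malignant), recycled to the number of reports; default one group.
#' @return data.frame with one row per group and metric.
#' @export
summarize_match_reports <- function(reports, groups = NULL) {
  if (!length(reports)) stop("need at least one report")
  if (is.null(groups)) groups <- "all"
  groups <- rep_len(groups, length(reports))
  tp <- vapply(reports, `[[`, 0, "tp_rate")
  fp <- vapply(reports, `[[`, 0, "fp_rate")
  metric <- vapply(reports, `[[`, "", "metric")
  out <- do.call(rbind, lapply(split(seq_along(reports),
                                     list(groups, metric), drop = TRUE),
    function(i) {
      sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
      data.frame(group = groups[i[1]], metric = metric[i[1]],
                 n = length(i),
                 tp_mean = mean(tp[i]), tp_sd = sd0(tp[i]),
                 tp_max = max(tp[i]), tp_min = min(tp[i]),
                 fp_mean = mean(fp[i]), fp_sd = sd0(fp[i]),
                 fp_max = max(fp[i]), fp_min = min(fp[i]))
    }))
  rownames(out) <- NULL
  out
}
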