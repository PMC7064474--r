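#' Pipeline configuration
#'
#' One place for every threshold of the segmentation pipeline: the
#' morphometric gate, the conditional-erosion policy, component
#' connectivity, the adaptive-threshold baseline settings, and the
#' evaluation thresholds.
#'
#' @param rule a [gating_rule()].
#' @param policy an [erosion_policy()].
#' @param connectivity component connectivity (default 8).
#' @param adaptive_window,adaptive_offset settings of [mask_adaptive()].
#' @param hd_max,jd_max evaluation matching thresholds.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(rule = gating_rule(), policy = erosion_policy(),
                            connectivity = 8, adaptive_window = 75,
                            adaptive_offset = -0.05, hd_max = 30,
                            jd_max = 0.5) {
  structure(list(rule = rule, policy = policy,
                 connectivity = as.integer(connectivity),
                 adaptive_window = adaptive_window,
                 adaptive_offset = adaptive_offset,
                 hd_max = hd_max, jd_max = jd_max),
            class = "pipeline_config")
}

#' Full nuclei segmentation pipeline
#'
#' Runs the whole chain on one image: nuclei mask (from the chosen
#' source), connected components, morphometric gating, and seeded
#' watershed separation of every clump (conditional-erosion seeds,
#' Euclidean distance topography with imposed seed maxima, priority
#' flood).  Fragments produced by the watershed are gated again: those
#' passing as single nuclei are accepted, sub-minimum fragments are
#' dropped as debris, and clumps whose fragments still fail the gate are
#' rejected.  Accepted objects are relabeled 1..N.
#'
#' @param stain hematoxylin concentration matrix (required for the
#'   `cnn`, `otsu` and `adaptive` mask sources).
#' @param mask_method one of `"provided"` (use `mask` as is), `"cnn"`
#'   (semantic segmentation with `model`), `"otsu"`, `"adaptive"`.
#' @param mask binary nuclei mask when `mask_method = "provided"`.
#' @param model a trained [train_classifier()] model (required iff
#'   `mask_method = "cnn"`).
#' @param config a [pipeline_config()].
#' @return object of class `segmentation_result`: `labels` (final label
#'   mask), `objects` (morphometrics + `provenance`, `"direct"` or
#'   `"watershed"`), `rejected` (label ids of clumps that failed
#'   separation, in the initial component labeling), `initial_labels`,
#'   `mask_method`.
#' @export
run_pipeline <- function(stain = NULL,
                         mask_method = c("provided", "cnn", "otsu",
                                         "adaptive"),
                         mask = NULL, model = NULL,
                         config = pipeline_config()) {
  mask_method <- match.arg(mask_method)
  mask <- switch(
    mask_method,
    provided = {
      if (is.null(mask)) stop("stage mask: mask_method 'provided' needs a mask")
      as_binary(mask)
    },
    cnn = {
      if (is.null(model)) stop("stage mask: mask_method 'cnn' needs a model")
      if (is.null(stain)) stop("stage mask: 'cnn' needs a stain image")
      mask_from_semantic(predict_semantic_map(model, stain)$map)
    },
    otsu = {
      if (is.null(stain)) stop("stage mask: 'otsu' needs a stain image")
      mask_otsu(stain)
    },
    adaptive = {
      if (is.null(stain)) stop("stage mask: 'adaptive' needs a stain image")
      mask_adaptive(stain, config$adaptive_window, config$adaptive_offset)
    })

  H <- nrow(mask); W <- ncol(mask)
  out_labels <- matrix(0L, H, W)
  labels <- label_components(mask, config$connectivity)
  rec <- measure(labels)
  if (nrow(rec) == 0) {
    return(structure(list(labels = out_labels,
                          objects = cbind(rec, provenance = character()),
                          rejected = integer(), initial_labels = labels,
                          mask_method = mask_method, config = config),
                     class = "segmentation_result"))
  }
  cls <- classify_objects(rec, config$rule)
  nxt <- 0L
  provenance <- character()
  rejected <- integer()

  accept <- function(obj_mask, y0, x0, prov) {
    nxt <<- nxt + 1L
    px <- which(obj_mask == 1L)
    ys <- (px - 1L) %% nrow(obj_mask) + y0
    xs <- (px - 1L) %/% nrow(obj_mask) + x0
    out_labels[cbind(ys, xs)] <<- nxt
    provenance <<- c(provenance, prov)
  }

  for (i in seq_len(nrow(rec))) {
    if (cls[i] == "debris") next
    y0 <- rec$ymin[i] - 1L; x0 <- rec$xmin[i] - 1L
    sub <- labels[rec$ymin[i]:rec$ymax[i], rec$xmin[i]:rec$xmax[i],
                  drop = FALSE]
    obj <- matrix(as.integer(sub == i), nrow(sub), ncol(sub))
    if (cls[i] == "single") {
      accept(obj, y0, x0, "direct")
      next
    }
    # clump: pad 1 px of background so erosion and EDT see a margin
    padded <- matrix(0L, nrow(obj) + 2L, ncol(obj) + 2L)
    padded[2:(nrow(obj) + 1L), 2:(ncol(obj) + 1L)] <- obj
    res <- tryCatch({
      seeds <- conditional_erode(padded, config$policy)
      tm <- distance_map(padded)
      tm2 <- impose_seeds(tm, seeds)
      flood(tm2, seeds, padded)
    }, error = function(e)
      stop("stage separation (clump ", i, "): ", conditionMessage(e)))
    frec <- measure(res)
    fcls <- classify_objects(frec, config$rule)
    if (any(fcls == "clump")) rejected <- c(rejected, i)
    for (j in seq_len(nrow(frec))) {
      if (fcls[j] != "single") next
      fm <- matrix(as.integer(res == j), nrow(res), ncol(res))
      accept(fm, y0 - 1L, x0 - 1L, "watershed")
    }
  }

  objects <- measure(out_labels)
  objects$provenance <- provenance
  structure(list(labels = out_labels, objects = objects,
                 rejected = rejected, initial_labels = labels,
                 mask_method = mask_method, config = config),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "segmentation_result (%s mask): %d nuclei (%d direct, %d watershed), %d clump(s) rejected\n",
    x$mask_method, nrow(x$objects),
    sum(x$objects$provenance == "direct"),
    sum(x$objects$provenance == "watershed"), length(x$rejected)))
  invisible(x)
}
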