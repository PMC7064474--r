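#' Patch classifier configuration
#'
#' Architecture and training hyper-parameters of the 4-class patch
#' classifier: four convolutional layers (ReLU) separated by two 2x2
#' max-pooling layers, then dense layers of `dense` and 4 units.  Defaults
#' follow the reference training setup (SGD, learning rate 1e-4, weight
#' decay 1e-6, mini-batch 256, 20 epochs, Xavier initialization, dropout
#' on the hidden dense layer); kernel sizes and filter counts are not
#' printed in the reference description, so the declared defaults are 3x3
#' kernels with 32, 32, 64, 64 filters.  Tests and examples use far
#' smaller settings: at desk scale a tiny network with a larger learning
#' rate reaches the same separations in minutes.
#'
#' @param patch_size odd patch side, default 43.
#' @param kernel odd convolution kernel side.
#' @param filters integer vector of 4 filter counts.
#' @param dense hidden dense layer width.
#' @param dropout dropout rate on the hidden dense layer, in `[0, 1)`.
#' @param learning_rate,weight_decay,batch_size,epochs SGD settings.
#' @param lr_decay multiplicative learning-rate decay applied per epoch
#'   after the first; 1 (the default) keeps the rate constant as in the
#'   reference setup.  Short desk-scale runs at higher rates converge more
#'   steadily with decay around 0.5.
#' @param seed RNG seed covering initialization, shuffling and dropout.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(patch_size = 43, kernel = 3,
                              filters = c(32L, 32L, 64L, 64L),
                              dense = 512, dropout = 0.5,
                              learning_rate = 1e-4, weight_decay = 1e-6,
                              batch_size = 256, epochs = 20, lr_decay = 1,
                              seed = 1) {
  stopifnot(patch_size %% 2 == 1, kernel %% 2 == 1, length(filters) == 4,
            dropout >= 0, dropout < 1, learning_rate > 0, batch_size >= 1,
            epochs >= 0, lr_decay > 0, lr_decay <= 1)
  structure(list(patch_size = as.integer(patch_size),
                 kernel = as.integer(kernel),
                 filters = as.integer(filters),
                 dense = as.integer(dense),
                 dropout = dropout,
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_decay = lr_decay,
                 seed = as.integer(seed),
                 n_classes = 4L),
            class = "classifier_config")
}

#' Train the patch classifier
#'
#' Stochastic gradient descent with weight decay on softmax
#' cross-entropy; Xavier-initialized weights; dropout on the hidden dense
#' layer.  All randomness is driven by `cfg$seed`, so a fixed seed
#' reproduces the run bitwise.  With `epochs = 0` the untrained
#' (Xavier-initialized) model is returned.
#'
#' @param train,val `patch_set`-like lists with `x` (N x size^2 matrix of
#'   standardized patches) and `y` (class index 1..4 in classifier
#'   order).  Both must be non-empty and all four classes must appear in
#'   `train`.
#' @param cfg a [classifier_config()].
#' @param stats optional [fit_position_stats()] object stored with the
#'   model and applied when predicting whole images.
#' @return object of class `nucseg_model`: weights, config, stats, and a
#'   `history` list with `initial_loss`, per-epoch `train_loss` and
#'   `val_accuracy`.
#' @export
train_classifier <- function(train, val, cfg = classifier_config(),
                             stats = NULL) {
  stopifnot(inherits(cfg, "classifier_config"))
  if (!length(train$y) || !length(val$y)) stop("train and val must be non-empty")
  present <- sort(unique(train$y))
  missing_cls <- setdiff(seq_len(cfg$n_classes), present)
  if (length(missing_cls))
    stop("class(es) absent from training set: ",
         paste(names(semantic_classes())[missing_cls], collapse = ", "))
  if (ncol(train$x) != cfg$patch_size^2)
    stop("patch size does not match config")
  w0 <- cpp_cnn_init(cfg$patch_size, cfg$kernel, cfg$filters, cfg$dense,
                     cfg$n_classes, cfg$seed)
  fit <- cpp_cnn_train(train$x, as.integer(train$y) - 1L,
                       val$x, as.integer(val$y) - 1L,
                       w0, cfg$patch_size, cfg$kernel, cfg$filters,
                       cfg$dense, cfg$n_classes, cfg$epochs,
                       cfg$learning_rate, cfg$lr_decay, cfg$weight_decay,
                       cfg$batch_size, cfg$dropout, cfg$seed + 1L)
  structure(list(weights = fit$weights, cfg = cfg, stats = stats,
                 history = list(initial_loss = fit$initial_loss,
                                train_loss = fit$train_loss,
                                val_accuracy = fit$val_accuracy),
                 format_version = "nucseg-model-1"),
            class = "nucseg_model")
}

#' @export
print.nucseg_model <- function(x, ...) {
  va <- x$history$val_accuracy
  cat(sprintf(
    "nucseg_model (%s): patch %d, filters %s, dense %d; %d epoch(s)%s\n",
    x$format_version, x$cfg$patch_size,
    paste(x$cfg$filters, collapse = "-"), x$cfg$dense, x$cfg$epochs,
    if (length(va)) sprintf(", final val accuracy %.3f", va[length(va)])
    else ""))
  invisible(x)
}

#' Class probabilities for a set of patches
#'
#' @param model a trained [train_classifier()] model.
#' @param x N x size^2 matrix of standardized patches.
#' @return N x 4 matrix of class probabilities (columns in classifier
#'   class order; rows sum to 1).
#' @export
predict_patches <- function(model, x) {
  stopifnot(inherits(model, "nucseg_model"))
  if (ncol(x) != model$cfg$patch_size^2)
    stop("patch size does not match the model")
  p <- cpp_cnn_forward(x, model$weights, model$cfg$patch_size,
                       model$cfg$kernel, model$cfg$filters,
                       model$cfg$dense, model$cfg$n_classes)
  colnames(p) <- names(semantic_classes())
  p
}

#' Per-pixel semantic segmentation of a stain image
#'
#' Slides the patch classifier over every pixel (stride 1, reflection
#' padding, per-position standardization using the model's stored
#' statistics) and labels each pixel by the class with the highest
#' probability; exact ties break by the fixed class order (nucleus <
#' nucleus_border < cytoplasm < background).
#'
#' @param model a trained [train_classifier()] model carrying position
#'   statistics (`stats`); without them, patches are used unstandardized.
#' @param stain H x W stain concentration matrix.
#' @return list with `map` (H x W semantic code matrix, see
#'   [semantic_classes()]) and `prob` (H x W x 4 probability array).
#' @export
predict_semantic_map <- function(model, stain) {
  stopifnot(inherits(model, "nucseg_model"), is.matrix(stain))
  size <- model$cfg$patch_size
  if (min(dim(stain)) < 1) stop("empty image")
  if (is.null(model$stats)) {
    mu <- matrix(0, size, size); sdv <- matrix(1, size, size)
  } else {
    if (model$stats$size != size) stop("stats size does not match the model")
    mu <- model$stats$mean; sdv <- model$stats$sd
  }
  P <- cpp_cnn_predict_image(stain, mu, sdv, model$weights, size,
                             model$cfg$kernel, model$cfg$filters,
                             model$cfg$dense, model$cfg$n_classes)
  cls <- max.col(P, ties.method = "first")
  map <- matrix(semantic_classes()[cls], nrow(stain), ncol(stain))
  prob <- array(P, c(nrow(stain), ncol(stain), model$cfg$n_classes))
  list(map = map, prob = prob)
}

#' Serialize / restore a trained model
#'
#' Models are stored as versioned JSON (`nucseg-model-1`): configuration,
#' flattened weight arrays with their dimensions, optional position
#' statistics and training history.
#'
#' @param model a `nucseg_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `nucseg_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nucseg_model"))
  ser <- list(
    format_version = model$format_version,
    cfg = unclass(model$cfg),
    weights = lapply(model$weights, function(w)
      list(dim = if (is.matrix(w)) dim(w) else length(w),
           data = as.vector(w))),
    stats = if (!is.null(model$stats))
      list(mean = as.vector(model$stats$mean),
           sd = as.vector(model$stats$sd),
           size = model$stats$size, n = model$stats$n),
    history = model$history)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$format_version, "nucseg-model-1"))
    stop("unsupported model format: ", ser$format_version)
  cfg <- do.call(classifier_config, ser$cfg[setdiff(names(ser$cfg),
                                                    "n_classes")])
  weights <- lapply(ser$weights, function(w) {
    if (length(w$dim) == 2) matrix(w$data, w$dim[1], w$dim[2]) else w$data
  })
  stats <- NULL
  if (!is.null(ser$stats)) {
    sz <- ser$stats$size
    stats <- structure(list(mean = matrix(ser$stats$mean, sz, sz),
                            sd = matrix(ser$stats$sd, sz, sz),
                            size = sz, n = ser$stats$n),
                       class = "position_stats")
  }
  structure(list(weights = weights, cfg = cfg, stats = stats,
                 history = ser$history, format_version = ser$format_version),
            class = "nucseg_model")
}
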