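#' Mean squared error between predicted maps and binary labels
#'
#' The training loss: the mean over all batch items and pixels of the
#' squared difference between the network output and the \{0, 1\} label
#' raster.
#'
#' @param pred numeric matrix/array, or list of matrices (a batch).
#' @param label matching matrix/array or list, values in \{0, 1\}.
#' @return a non-negative scalar; 0 iff \code{pred == label} everywhere.
#' @export
mse_loss <- function(pred, label) {
  if (is.list(pred) != is.list(label))
    stop("pred and label must both be lists or both be rasters")
  if (!is.list(pred)) {
    pred <- list(pred)
    label <- list(label)
  }
  if (length(pred) != length(label)) stop("batch sizes differ")
  n <- 0
  ss <- 0
  for (k in seq_along(pred)) {
    p <- pred[[k]]
    l <- label[[k]]
    if (!identical(dim(p), dim(l)) || length(p) != length(l))
      stop("shape mismatch between pred and label in batch item ", k)
    ss <- ss + sum((as.numeric(p) - as.numeric(l))^2)
    n <- n + length(p)
  }
  ss / n
}

#' Training configuration
#'
#' Defaults follow the published training recipe: Adam, 60 epochs of 250
#' steps with batch size 2. Optimizer moments use the canonical Adam
#' defaults. Batches are sampled uniformly with replacement each step, so
#' \code{epochs * steps_per_epoch * batch_size} need not equal the dataset
#' size.
#'
#' @param epochs number of epochs.
#' @param steps_per_epoch gradient steps per epoch.
#' @param batch_size tiles per gradient step.
#' @param lr Adam step size.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabiliser.
#' @param seed RNG seed controlling batch sampling.
#' @param tau threshold used to binarise validation predictions when
#'   computing per-epoch segmentation metrics.
#' @param val_monitor maximum number of validation tiles scored per epoch
#'   (the full validation set is always scored after the final epoch).
#' @return a list of class \code{"glandnet_control"}.
#' @export
train_config <- function(epochs = 60L, steps_per_epoch = 250L,
                         batch_size = 2L, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, epsilon = 1e-8, seed = 1L,
                         tau = 0.5, val_monitor = 16L) {
  cfg <- list(epochs = as.integer(epochs),
              steps_per_epoch = as.integer(steps_per_epoch),
              batch_size = as.integer(batch_size), lr = lr, beta1 = beta1,
              beta2 = beta2, epsilon = epsilon, seed = as.integer(seed),
              tau = tau, val_monitor = as.integer(val_monitor))
  if (any(unlist(cfg[c("epochs", "steps_per_epoch", "batch_size")]) < 1L))
    stop("epochs, steps_per_epoch and batch_size must be positive")
  class(cfg) <- "glandnet_control"
  cfg
}

# validation pass: loss, pixel accuracy and confusion-matrix metrics
.validate <- function(object, x, y, tau) {
  tp <- fp <- fn <- tn <- 0
  ss <- 0
  n <- 0
  for (k in seq_along(x)) {
    map <- net_forward_cpp(object$params, object$running, x[[k]])
    lab <- y[[k]]
    ss <- ss + sum((map - lab)^2)
    n <- n + length(map)
    pm <- map > tau
    lm <- lab > 0.5
    tp <- tp + sum(pm & lm)
    fp <- fp + sum(pm & !lm)
    fn <- fn + sum(!pm & lm)
    tn <- tn + sum(!pm & !lm)
  }
  met <- segmentation_metrics(confusion_counts(tp, fp, fn, tn))
  list(loss = ss / n,
       accuracy = (tp + tn) / n,
       miou = met$miou, precision = met$precision, recall = met$recall,
       f1 = met$f1)
}

#' Fit the interpolation-pooling segmentation network
#'
#' Trains the network by stochastic gradient descent with the Adam update
#' rule on the mean-squared-error loss against \{0, 1\} masks. Each step
#' samples \code{batch_size} tiles uniformly with replacement from the
#' training set. After every epoch the model is scored on (a subset of)
#' the validation set: loss, pixel accuracy, mIoU, precision, recall and
#' F1 are recorded in the history, and the parameters with the best
#' validation loss seen so far are retained as the fitted model. Training
#' is deterministic for a fixed \code{seed}. If the loss becomes
#' non-finite the run aborts and returns the last finite checkpoint with a
#' warning.
#'
#' @param x list of H x W x C training tiles (arrays, values in \[0, 1\]).
#' @param y list of matching H x W binary label matrices.
#' @param val_x,val_y validation tiles and labels (same format).
#' @param spec a [network_spec()]; ignored when \code{object} is given.
#' @param control a [train_config()].
#' @param object optionally an existing \code{"glandnet"} model to continue
#'   training from (e.g. from [build_network()]).
#' @param verbose print one line per epoch.
#' @return a fitted \code{"glandnet"} model with a \code{history} data
#'   frame (one row per epoch).
#' @examples
#' \donttest{
#' set.seed(1)
#' dat <- generate_tile_set(8, density_level = 1, size = 24, seed = 1)
#' val <- generate_tile_set(4, density_level = 1, size = 24, seed = 2)
#' fit <- glandnet_fit(dat$x, dat$y, val$x, val$y,
#'                     spec = network_spec(input_size = 24, base_channels = 4),
#'                     control = train_config(epochs = 1, steps_per_epoch = 5,
#'                                            seed = 1))
#' fit$history
#' }
#' @export
glandnet_fit <- function(x, y, val_x, val_y, spec = network_spec(),
                         control = train_config(), object = NULL,
                         verbose = FALSE) {
  if (length(x) == 0 || length(val_x) == 0)
    stop("training and validation sets must be non-empty")
  if (length(x) != length(y) || length(val_x) != length(val_y))
    stop("tiles and labels differ in length")
  stopifnot(inherits(control, "glandnet_control"))
  if (is.null(object)) object <- build_network(spec, seed = control$seed)
  stopifnot(inherits(object, "glandnet"))

  trainer <- net_trainer_create(object$params, object$running)
  nmon <- min(control$val_monitor, length(val_x))
  hist <- vector("list", control$epochs)
  best <- list(loss = Inf, params = object$params, running = object$running)
  set.seed(control$seed)
  aborted <- FALSE
  for (epoch in seq_len(control$epochs)) {
    losses <- numeric(control$steps_per_epoch)
    for (step in seq_len(control$steps_per_epoch)) {
      idx <- sample.int(length(x), control$batch_size, replace = TRUE)
      loss <- net_trainer_step(trainer, x[idx], y[idx], control$lr,
                               control$beta1, control$beta2,
                               control$epsilon)
      if (!is.finite(loss)) {
        warning("non-finite loss at epoch ", epoch, ", step ", step,
                "; returning last finite checkpoint")
        aborted <- TRUE
        break
      }
      losses[step] <- loss
    }
    st <- net_trainer_state(trainer)
    object$params <- st$params
    object$running <- st$running
    if (aborted) break
    val <- .validate(object, val_x[seq_len(nmon)], val_y[seq_len(nmon)],
                     control$tau)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = mean(losses),
                                val_loss = val$loss,
                                val_accuracy = val$accuracy,
                                val_miou = val$miou,
                                val_precision = val$precision,
                                val_recall = val$recall,
                                val_f1 = val$f1)
    if (is.finite(val$loss) && val$loss < best$loss)
      best <- list(loss = val$loss, params = object$params,
                   running = object$running)
    if (verbose)
      message(sprintf(
        "epoch %d: train loss %.5f, val loss %.5f, val F1 %.4f",
        epoch, mean(losses), val$loss, val$f1))
  }
  object$params <- best$params
  object$running <- best$running
  object$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  object$control <- control
  object$fitted <- TRUE
  object
}
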