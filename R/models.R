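# The volumetric regressors and their training loop.
#
# Three deep families share one train/predict contract: conv5fc3 (five
# conv/batch-norm/ReLU/max-pool blocks, then three fully connected layers),
# resnet3d (five residual blocks separated by max pooling, then
# FC-ReLU-dropout-FC) and secnn (the same with a squeeze-and-excite gate in
# each residual block). One model is trained per criterion and hemisphere
# frame; composite scores are never a direct regression target -- they are
# the sum of the per-criterion predictions, which keeps the score
# interpretable. Training minimizes mean squared error on the raw
# (un-rounded) criterion values with Adam; the weights from the epoch with
# the lowest validation loss are retained.

#' Training hyper-parameters
#'
#' Defaults are the reference regime for this task: MSE loss, Adam with
#' learning rate 1e-4 and weight decay 1e-4, batch size 16, at most 50
#' epochs with zero early-stopping tolerance (training runs all epochs and
#' best-validation-epoch selection picks the model).
#'
#' @param learning_rate,weight_decay,batch_size,max_epochs Positive scalars.
#' @param early_stop_tolerance Minimum validation-loss improvement counted
#'   as progress; 0 disables early stopping.
#' @param patience Epochs without improvement tolerated before stopping
#'   (only active when `early_stop_tolerance > 0`).
#' @param seed RNG seed covering initialization, shuffling and dropout.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                         batch_size = 16L, max_epochs = 50L,
                         early_stop_tolerance = 0, patience = 10L, seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
                 early_stop_tolerance = early_stop_tolerance,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

check_input_dims <- function(input_dims) {
  if (length(input_dims) != 3L || any(!is.finite(input_dims)) || any(input_dims < 1)) {
    stop_input("input extents must be 3 positive integers")
  }
  as.integer(input_dims)
}

#' Build a conv5-FC3 network
#'
#' Five blocks of conv(3x3x3) - batch-norm - ReLU - max-pool(2, floor
#' semantics, axes of extent 1 stop shrinking), then three fully connected
#' layers ending in a single scalar output.
#'
#' @param input_dims Spatial extents `c(nx, ny, nz)` of the input crop.
#' @param channels Five convolutional channel widths.
#' @param fc_widths Widths of the first two fully connected layers.
#' @param seed Initialization seed.
#' @return An `ihi_network`.
#' @export
build_conv5fc3 <- function(input_dims, channels = c(8L, 16L, 32L, 64L, 128L),
                           fc_widths = c(1024L, 64L), seed = 1L) {
  input_dims <- check_input_dims(input_dims)
  if (length(channels) != 5L) stop_input("conv5fc3 has exactly 5 convolutional blocks")
  if (length(fc_widths) != 2L) stop_input("conv5fc3 has exactly 3 fully connected layers")
  with_seed(seed, {
    layers <- list()
    dims <- c(input_dims, 1L)
    block_dims <- list()
    for (i in 1:5) {
      cv <- layer_conv(dims, channels[i])
      bn <- layer_bn(cv$dims_out)
      rl <- layer_relu(cv$dims_out)
      pl <- layer_pool(cv$dims_out)
      layers <- c(layers, list(cv, bn, rl, pl))
      dims <- pl$dims_out
      block_dims[[i]] <- dims[1:3]
    }
    n_flat <- prod(dims)
    layers <- c(layers, list(layer_fc(n_flat, fc_widths[1]), layer_relu(NULL),
                             layer_fc(fc_widths[1], fc_widths[2]), layer_relu(NULL),
                             layer_fc(fc_widths[2], 1L)))
    structure(list(layers = layers, input_dims = input_dims, family = "conv5fc3",
                   block_dims = block_dims,
                   spec = list(channels = channels, fc_widths = fc_widths, seed = seed)),
              class = "ihi_network")
  })
}

build_residual_family <- function(input_dims, channels, fc_width, dropout,
                                  se, reduction, seed, family) {
  input_dims <- check_input_dims(input_dims)
  if (length(channels) != 5L) stop_input(family, " has exactly 5 residual blocks")
  with_seed(seed, {
    layers <- list()
    dims <- c(input_dims, 1L)
    block_dims <- list()
    for (i in 1:5) {
      rb <- layer_res(dims, channels[i], se = se, reduction = reduction)
      pl <- layer_pool(rb$dims_out)
      layers <- c(layers, list(rb, pl))
      dims <- pl$dims_out
      block_dims[[i]] <- dims[1:3]
    }
    n_flat <- prod(dims)
    layers <- c(layers, list(layer_fc(n_flat, fc_width), layer_relu(NULL),
                             layer_dropout(dropout), layer_fc(fc_width, 1L)))
    structure(list(layers = layers, input_dims = input_dims, family = family,
                   block_dims = block_dims,
                   spec = list(channels = channels, fc_width = fc_width,
                               dropout = dropout, se = se, reduction = reduction,
                               seed = seed)),
              class = "ihi_network")
  })
}

#' Build a 3D ResNet
#'
#' Five residual blocks (conv-bn-relu-conv-bn plus identity shortcut, 1x1x1
#' projection when channels change) separated by max pooling, then a head of
#' fully connected - ReLU - dropout(0.5) - fully connected to one scalar.
#'
#' @inheritParams build_conv5fc3
#' @param fc_width Width of the head's hidden layer.
#' @param dropout Head dropout probability.
#' @return An `ihi_network`.
#' @export
build_resnet3d <- function(input_dims, channels = c(8L, 16L, 32L, 64L, 128L),
                           fc_width = 128L, dropout = 0.5, seed = 1L) {
  build_residual_family(input_dims, channels, fc_width, dropout,
                        se = FALSE, reduction = 4L, seed = seed, family = "resnet3d")
}

#' Build a squeeze-and-excite CNN
#'
#' [build_resnet3d()] with a squeeze-and-excite gate in every residual
#' block: per-channel global average pool, FC(reduction), ReLU, FC, sigmoid
#' gate, channel-wise rescale.
#'
#' @inheritParams build_resnet3d
#' @param reduction Squeeze-excite reduction ratio (must not exceed the
#'   smallest channel width).
#' @return An `ihi_network`.
#' @export
build_secnn <- function(input_dims, channels = c(8L, 16L, 32L, 64L, 128L),
                        fc_width = 128L, dropout = 0.5, reduction = 4L, seed = 1L) {
  build_residual_family(input_dims, channels, fc_width, dropout,
                        se = TRUE, reduction = reduction, seed = seed, family = "secnn")
}

#' Build a network by family name
#'
#' @param family `"conv5fc3"`, `"resnet3d"` or `"secnn"`.
#' @param input_dims Crop extents.
#' @param ... Family-specific arguments.
#' @return An `ihi_network`.
#' @export
build_network <- function(family = c("conv5fc3", "resnet3d", "secnn"),
                          input_dims, ...) {
  family <- match.arg(family)
  switch(family,
         conv5fc3 = build_conv5fc3(input_dims, ...),
         resnet3d = build_resnet3d(input_dims, ...),
         secnn = build_secnn(input_dims, ...))
}

#' @export
print.ihi_network <- function(x, ...) {
  n_par <- sum(vapply(nn_get_params(x), length, integer(1)))
  cat(sprintf("%s network, input %s, %d parameters, post-pool extents %s\n",
              x$family, paste(x$input_dims, collapse = "x"), n_par,
              paste(x$block_dims[[5]], collapse = "x")))
  invisible(x)
}

as_feature_matrix <- function(x, input_dims = NULL) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "gm_crop")) x <- list(x)
  crops_to_matrix(x)
}

eval_in_chunks <- function(net, X, chunk = 64L) {
  n <- ncol(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx] <- as.vector(nn_forward(net, X[, idx, drop = FALSE], training = FALSE))
  }
  out
}

#' Train a criterion regressor
#'
#' Mini-batch Adam on the mean-squared-error between network output and the
#' raw (un-rounded) criterion labels. Per-epoch train and validation losses
#' are logged and the parameters from the epoch with minimal validation
#' loss are returned. Fully reproducible given `cfg$seed`.
#'
#' @param net An `ihi_network` (left untouched; training clones it).
#' @param x_train,x_val Feature matrices (voxels x n, from
#'   [crops_to_matrix()]) or lists of `gm_crop`s.
#' @param y_train,y_val Numeric label vectors.
#' @param cfg A [train_config()].
#' @param criterion,hemisphere,strategy Metadata stored in the result.
#' @return An `ihi_regressor`: the fitted network plus `best_epoch`,
#'   `best_val_loss` and the per-epoch `log`.
#' @export
train_regressor <- function(net, x_train, y_train, x_val, y_val,
                            cfg = train_config(), criterion = NA_character_,
                            hemisphere = NA_character_, strategy = NA_character_) {
  X <- as_feature_matrix(x_train)
  Xv <- as_feature_matrix(x_val)
  if (!ncol(X) || !ncol(Xv)) stop_input("training and validation sets must be non-empty")
  if (length(y_train) != ncol(X) || length(y_val) != ncol(Xv)) {
    stop_input("label vectors must match the number of crops")
  }
  net <- clone_network(net)
  refs <- nn_param_refs(net)
  n <- ncol(X)
  bs <- min(cfg$batch_size, n)
  log <- data.frame(epoch = integer(), train_loss = numeric(), val_loss = numeric())
  best <- list(loss = Inf, epoch = NA_integer_, params = NULL, bn = NULL)
  with_seed(cfg$seed, {
    t_step <- 0L
    stall <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1L, n)]
        xb <- X[, idx, drop = FALSE]
        yb <- y_train[idx]
        pred <- nn_forward(net, xb, training = TRUE)
        err <- as.vector(pred) - yb
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop_input("training diverged: non-finite loss at epoch ", epoch,
                     " (learning rate ", cfg$learning_rate, ")")
        }
        tot <- tot + loss * length(idx)
        nn_backward(net, matrix(2 * err / length(err), nrow = 1L))
        t_step <- t_step + 1L
        adam_step(refs, cfg$learning_rate, cfg$weight_decay, t_step)
      }
      val_loss <- mean((eval_in_chunks(net, Xv) - y_val)^2)
      log[nrow(log) + 1L, ] <- list(epoch, tot / n, val_loss)
      if (val_loss < best$loss - cfg$early_stop_tolerance) stall <- 0L else stall <- stall + 1L
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, epoch = epoch,
                     params = nn_get_params(net), bn = nn_get_bn_stats(net))
      }
      if (cfg$early_stop_tolerance > 0 && stall >= cfg$patience) break
    }
  })
  nn_set_params(net, best$params)
  nn_set_bn_stats(net, best$bn)
  structure(list(net = net, family = net$family, criterion = criterion,
                 hemisphere = hemisphere, strategy = strategy,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 log = log, config = cfg, input_dims = net$input_dims),
            class = "ihi_regressor")
}

#' @export
print.ihi_regressor <- function(x, ...) {
  cat(sprintf("%s regressor (criterion %s, hemisphere %s, strategy %s): best epoch %d, val MSE %.4f\n",
              x$family, x$criterion, x$hemisphere, x$strategy, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict raw criterion scores
#'
#' Deterministic eval-mode forward pass (batch-norm uses running statistics,
#' dropout is disabled). Outputs are continuous; round them with
#' [round_prediction()] before computing kappas or composites.
#'
#' @param trained An `ihi_regressor` or `ihi_ridge`.
#' @param crops Feature matrix, `gm_crop` or list of `gm_crop`s matching the
#'   training extents.
#' @return Numeric vector of raw predictions.
#' @export
predict_criterion <- function(trained, crops) {
  X <- as_feature_matrix(crops)
  if (inherits(trained, "ihi_ridge")) {
    if (nrow(X) != length(trained$coef)) stop_input("crop extents do not match training")
    return(as.vector(crossprod(X, trained$coef)) + trained$intercept)
  }
  if (nrow(X) != prod(trained$input_dims)) stop_input("crop extents do not match training")
  eval_in_chunks(trained$net, X)
}

#' Group saliency map
#'
#' Gradient magnitude of the model output with respect to the input voxels
#' (eval mode), averaged across the supplied crops, thresholded to retain
#' exactly `n_retain` voxels (ties broken by voxel order). For the linear
#' ridge model the gradient is its coefficient vector, so the saliency is
#' the |coefficient| map.
#'
#' @param trained An `ihi_regressor` or `ihi_ridge`.
#' @param crops Crops to average the saliency over (>= 1).
#' @param n_retain Number of voxels to keep (default 1000).
#' @return 3D array of retained gradient magnitudes (zero elsewhere) with
#'   attributes `retained_mask` (logical array) and `n_retained`.
#' @export
saliency_group_map <- function(trained, crops, n_retain = 1000L) {
  if (inherits(trained, "ihi_ridge")) {
    dims <- trained$input_dims
    vals <- abs(trained$coef)
  } else {
    X <- as_feature_matrix(crops)
    if (!ncol(X)) stop_input("need at least one crop")
    dims <- trained$input_dims
    acc <- numeric(nrow(X))
    chunk <- 32L
    for (start in seq(1L, ncol(X), by = chunk)) {
      idx <- start:min(start + chunk - 1L, ncol(X))
      xb <- X[, idx, drop = FALSE]
      nn_forward(trained$net, xb, training = FALSE)
      dX <- nn_backward(trained$net, matrix(1, nrow = 1L, ncol = length(idx)))
      acc <- acc + rowSums(abs(dX))
    }
    vals <- acc / ncol(X)
  }
  n_retain <- min(n_retain, length(vals))
  keep <- order(vals, decreasing = TRUE)[seq_len(n_retain)]
  mask <- logical(length(vals))
  mask[keep] <- TRUE
  out <- numeric(length(vals))
  out[mask] <- vals[mask]
  structure(array(out, dims),
            retained_mask = array(mask, dims), n_retained = n_retain)
}
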