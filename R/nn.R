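# Minimal reverse-mode framework for the 3D volumetric regressors.
#
# Layers are mutable environments holding parameters, gradients, Adam state
# and the forward caches needed for backpropagation. A batch is a dense
# matrix with one column per sample; within a column the x voxel index
# varies fastest, then y, then z, then channel. Convolution and pooling run
# through the compiled im2col/GEMM kernels; batch-norm, fully connected,
# ReLU, dropout and squeeze-excite layers are vectorized R.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (n in names(fields)) assign(n, fields[[n]], envir = e)
  class(e) <- "nn_layer"
  e
}

he_weights <- function(fan_in, n_out) {
  matrix(stats::rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out)
}

layer_conv <- function(dims_in, c_out, k = 3L) {
  c_in <- dims_in[4]
  new_layer("conv",
            W = he_weights(c_in * k^3, c_out), b = rep(0, c_out),
            k = as.integer(k), dims_in = dims_in,
            dims_out = c(dims_in[1:3], c_out))
}

layer_bn <- function(dims_in) {
  C <- dims_in[4]
  new_layer("bn", gamma = rep(1, C), beta = rep(0, C),
            running_mean = rep(0, C), running_var = rep(1, C),
            momentum = 0.1, eps = 1e-5,
            V = prod(dims_in[1:3]), C = C, dims_in = dims_in, dims_out = dims_in)
}

layer_relu <- function(dims_in) new_layer("relu", dims_in = dims_in, dims_out = dims_in)

layer_pool <- function(dims_in) {
  sp <- dims_in[1:3]
  out <- ifelse(sp >= 2, sp %/% 2, 1L)
  new_layer("pool", dims_in = dims_in, dims_out = c(out, dims_in[4]))
}

layer_fc <- function(n_in, n_out) {
  new_layer("fc", W = t(he_weights(n_in, n_out)), b = rep(0, n_out),
            n_in = n_in, n_out = n_out)
}

layer_dropout <- function(p) new_layer("dropout", p = p)

layer_se <- function(dims_in, reduction) {
  C <- dims_in[4]
  if (reduction > C) {
    stop_input("squeeze-excite reduction ratio ", reduction,
               " exceeds the channel count ", C)
  }
  Cr <- max(1L, C %/% reduction)
  new_layer("se",
            W1 = t(he_weights(C, Cr)), b1 = rep(0, Cr),
            W2 = t(he_weights(Cr, C)), b2 = rep(0, C),
            C = C, V = prod(dims_in[1:3]), dims_in = dims_in, dims_out = dims_in)
}

# Residual block: conv-bn-relu-conv-bn (+ optional squeeze-excite), added to
# an identity shortcut (1x1x1 conv + bn projection when channels change),
# followed by ReLU.
layer_res <- function(dims_in, c_out, se = FALSE, reduction = 4L) {
  dims_mid <- c(dims_in[1:3], c_out)
  sub <- list(conv1 = layer_conv(dims_in, c_out),
              bn1 = layer_bn(dims_mid),
              relu1 = layer_relu(dims_mid),
              conv2 = layer_conv(dims_mid, c_out),
              bn2 = layer_bn(dims_mid))
  if (se) sub$se <- layer_se(dims_mid, reduction)
  if (dims_in[4] != c_out) {
    sub$proj <- layer_conv(dims_in, c_out, k = 1L)
    sub$proj_bn <- layer_bn(dims_mid)
  }
  new_layer("res", sub = sub, dims_in = dims_in, dims_out = dims_mid)
}

# ---- forward ---------------------------------------------------------------

# Channel index of each column after reshaping (V*C) x B into V x (C*B).
channel_ids <- function(C, B) rep(seq_len(C), times = B)

layer_forward <- function(l, X, training) {
  switch(l$type,
    conv = {
      l$X <- X
      d <- l$dims_in
      conv3d_fwd(X, l$W, l$b, d[1], d[2], d[3], d[4], l$k)
    },
    bn = {
      B <- ncol(X)
      m <- matrix(X, nrow = l$V)
      ch <- channel_ids(l$C, B)
      l$last_training <- training
      if (training) {
        N <- l$V * B
        mu <- as.vector(rowsum(colSums(m), ch)) / N
        ex2 <- as.vector(rowsum(colSums(m * m), ch)) / N
        v <- pmax(ex2 - mu^2, 0)
        l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
        l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
      } else {
        mu <- l$running_mean
        v <- l$running_var
      }
      inv_std <- 1 / sqrt(v + l$eps)
      xhat <- (m - rep(mu[ch], each = l$V)) * rep(inv_std[ch], each = l$V)
      l$xhat <- xhat
      l$inv_std <- inv_std
      matrix(xhat * rep(l$gamma[ch], each = l$V) + rep(l$beta[ch], each = l$V),
             nrow = l$V * l$C)
    },
    relu = {
      l$mask <- X > 0
      X * l$mask
    },
    pool = {
      d <- l$dims_in
      r <- maxpool3d_fwd(X, d[1], d[2], d[3], d[4])
      l$argmax <- r$argmax
      l$in_rows <- nrow(X)
      r$Y
    },
    fc = {
      l$X <- X
      l$W %*% X + l$b
    },
    dropout = {
      if (training && l$p > 0) {
        l$mask <- matrix(stats::runif(length(X)) >= l$p, nrow(X), ncol(X)) / (1 - l$p)
        X * l$mask
      } else {
        l$mask <- NULL
        X
      }
    },
    se = {
      B <- ncol(X)
      ch <- channel_ids(l$C, B)
      z <- matrix(as.vector(colSums(matrix(X, nrow = l$V))), l$C, B)
      z <- z / l$V
      h_pre <- l$W1 %*% z + l$b1
      h <- pmax(h_pre, 0)
      g <- stats::plogis(l$W2 %*% h + l$b2)
      l$X <- X; l$z <- z; l$h <- h; l$g <- g
      X * g[rep(seq_len(l$C), each = l$V), , drop = FALSE]
    },
    res = {
      s <- l$sub
      h <- layer_forward(s$conv1, X, training)
      h <- layer_forward(s$bn1, h, training)
      h <- layer_forward(s$relu1, h, training)
      h <- layer_forward(s$conv2, h, training)
      h <- layer_forward(s$bn2, h, training)
      if (!is.null(s$se)) h <- layer_forward(s$se, h, training)
      short <- if (!is.null(s$proj)) {
        layer_forward(s$proj_bn, layer_forward(s$proj, X, training), training)
      } else X
      pre <- h + short
      l$mask <- pre > 0
      pre * l$mask
    },
    stop("unknown layer type ", l$type)
  )
}

# ---- backward --------------------------------------------------------------

layer_backward <- function(l, dY) {
  switch(l$type,
    conv = {
      d <- l$dims_in
      g <- conv3d_bwd(l$X, l$W, dY, d[1], d[2], d[3], d[4], l$k)
      l$gW <- g$dW
      l$gb <- as.vector(g$db)
      g$dX
    },
    bn = {
      B <- ncol(dY)
      ch <- channel_ids(l$C, B)
      dm <- matrix(dY, nrow = l$V)
      l$gbeta <- as.vector(rowsum(colSums(dm), ch))
      l$ggamma <- as.vector(rowsum(colSums(dm * l$xhat), ch))
      scale <- l$gamma * l$inv_std
      if (isTRUE(l$last_training)) {
        N <- l$V * B
        dx <- rep(scale[ch], each = l$V) *
          (dm - rep(l$gbeta[ch], each = l$V) / N -
             l$xhat * rep(l$ggamma[ch], each = l$V) / N)
      } else {
        dx <- dm * rep(scale[ch], each = l$V)
      }
      matrix(dx, nrow = l$V * l$C)
    },
    relu = dY * l$mask,
    pool = maxpool3d_bwd(dY, l$argmax, l$in_rows),
    fc = {
      l$gW <- dY %*% t(l$X)
      l$gb <- rowSums(dY)
      t(l$W) %*% dY
    },
    dropout = if (is.null(l$mask)) dY else dY * l$mask,
    se = {
      gexp <- l$g[rep(seq_len(l$C), each = l$V), , drop = FALSE]
      dX1 <- dY * gexp
      dg <- matrix(as.vector(colSums(matrix(dY * l$X, nrow = l$V))), l$C, ncol(dY))
      ds <- dg * l$g * (1 - l$g)
      l$gW2 <- ds %*% t(l$h)
      l$gb2 <- rowSums(ds)
      dh <- (t(l$W2) %*% ds) * (l$h > 0)
      l$gW1 <- dh %*% t(l$z)
      l$gb1 <- rowSums(dh)
      dz <- t(l$W1) %*% dh
      dX1 + dz[rep(seq_len(l$C), each = l$V), , drop = FALSE] / l$V
    },
    res = {
      s <- l$sub
      dpre <- dY * l$mask
      dh <- dpre
      if (!is.null(s$se)) dh <- layer_backward(s$se, dh)
      dh <- layer_backward(s$bn2, dh)
      dh <- layer_backward(s$conv2, dh)
      dh <- layer_backward(s$relu1, dh)
      dh <- layer_backward(s$bn1, dh)
      dX <- layer_backward(s$conv1, dh)
      dX + if (!is.null(s$proj)) {
        layer_backward(s$proj, layer_backward(s$proj_bn, dpre))
      } else dpre
    },
    stop("unknown layer type ", l$type)
  )
}

nn_forward <- function(net, X, training = FALSE) {
  for (l in net$layers) X <- layer_forward(l, X, training)
  X
}

nn_backward <- function(net, dY) {
  for (l in rev(net$layers)) dY <- layer_backward(l, dY)
  dY
}

# ---- parameters & optimizer -------------------------------------------------

PARAM_NAMES <- list(conv = c("W", "b"), bn = c("gamma", "beta"),
                    fc = c("W", "b"), se = c("W1", "b1", "W2", "b2"))

walk_layers <- function(layers, fn) {
  for (l in layers) {
    fn(l)
    if (l$type == "res") walk_layers(l$sub, fn)
  }
  invisible(NULL)
}

nn_param_refs <- function(net) {
  refs <- list()
  walk_layers(net$layers, function(l) {
    for (nm in PARAM_NAMES[[l$type]] %||% character()) {
      refs[[length(refs) + 1]] <<- list(layer = l, name = nm)
    }
  })
  refs
}

# One Adam step with L2 weight decay folded into the gradient, matching the
# conventional (non-decoupled) Adam weight_decay.
adam_step <- function(refs, lr, weight_decay, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (r in refs) {
    l <- r$layer; nm <- r$name
    g <- l[[paste0("g", nm)]] + weight_decay * l[[nm]]
    mkey <- paste0("adam_m_", nm); vkey <- paste0("adam_v_", nm)
    m <- (l[[mkey]] %||% 0) * beta1 + (1 - beta1) * g
    v <- (l[[vkey]] %||% 0) * beta2 + (1 - beta2) * g^2
    l[[mkey]] <- m
    l[[vkey]] <- v
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    l[[nm]] <- l[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

nn_get_params <- function(net) {
  lapply(nn_param_refs(net), function(r) r$layer[[r$name]])
}

nn_set_params <- function(net, values) {
  refs <- nn_param_refs(net)
  stopifnot(length(refs) == length(values))
  for (i in seq_along(refs)) refs[[i]]$layer[[refs[[i]]$name]] <- values[[i]]
  invisible(net)
}

# Running batch-norm statistics, captured alongside parameters when
# snapshotting the best-validation-epoch model.
nn_get_bn_stats <- function(net) {
  out <- list()
  walk_layers(net$layers, function(l) {
    if (l$type == "bn") {
      out[[length(out) + 1]] <<- list(mean = l$running_mean, var = l$running_var)
    }
  })
  out
}

nn_set_bn_stats <- function(net, stats) {
  i <- 0L
  walk_layers(net$layers, function(l) {
    if (l$type == "bn") {
      i <<- i + 1L
      l$running_mean <- stats[[i]]$mean
      l$running_var <- stats[[i]]$var
    }
  })
  invisible(net)
}

clone_layer <- function(l) {
  e <- new.env(parent = emptyenv())
  for (nm in ls(l, all.names = TRUE)) {
    v <- get(nm, envir = l)
    assign(nm, if (nm == "sub") lapply(v, clone_layer) else v, envir = e)
  }
  class(e) <- "nn_layer"
  e
}

clone_network <- function(net) {
  net$layers <- lapply(net$layers, clone_layer)
  net
}
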