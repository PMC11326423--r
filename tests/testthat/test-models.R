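test_that("conv5fc3 pooling shrinks extents by floor-halving, stopping at 1", {
  net <- build_conv5fc3(c(72L, 53L, 33L), channels = c(2L, 2L, 2L, 2L, 2L),
                        fc_widths = c(8L, 4L))
  dims <- do.call(rbind, net$block_dims)
  expect_equal(dims[, 1], c(36, 18, 9, 4, 2))
  expect_equal(dims[, 2], c(26, 13, 6, 3, 1))
  expect_equal(dims[, 3], c(16, 8, 4, 2, 1))
  expect_error(build_conv5fc3(c(0, 8, 8)), "positive")
  expect_error(build_conv5fc3(tiny_grid, channels = c(2, 2, 2)), "5 convolutional")
})

test_that("forward passes honour the batch contract deterministically", {
  for (family in c("conv5fc3", "resnet3d", "secnn")) {
    args <- switch(family,
                   conv5fc3 = tiny_net_args,
                   resnet3d = list(channels = tiny_net_args$channels, fc_width = 8L),
                   secnn = list(channels = tiny_net_args$channels, fc_width = 8L,
                                reduction = 2L))
    net1 <- do.call(build_network, c(list(family = family, input_dims = tiny_grid),
                                     args, list(seed = 21)))
    net2 <- do.call(build_network, c(list(family = family, input_dims = tiny_grid),
                                     args, list(seed = 21)))
    expect_identical(ihiscore:::nn_get_params(net1), ihiscore:::nn_get_params(net2))
    set.seed(1)
    X <- matrix(stats::rnorm(prod(tiny_grid) * 5), ncol = 5)
    out1 <- ihiscore:::nn_forward(net1, X, training = FALSE)
    out2 <- ihiscore:::nn_forward(net1, X, training = FALSE)
    expect_length(as.vector(out1), 5)
    expect_identical(out1, out2) # eval mode: dropout off, running stats
    expect_true(all(is.finite(out1)))
  }
})

test_that("a residual block with a zeroed convolution path is the gated identity", {
  dims <- c(6L, 5L, 4L, 3L)
  set.seed(4)
  rb <- ihiscore:::layer_res(dims, 3L) # same channels: identity shortcut
  rb$sub$conv2$W[] <- 0
  rb$sub$conv2$b[] <- 0
  rb$sub$bn2$beta[] <- 0
  X <- matrix(stats::rnorm(prod(dims) * 2), ncol = 2)
  out <- ihiscore:::layer_forward(rb, X, training = TRUE)
  expect_equal(out, pmax(X, 0), tolerance = 1e-12) # relu(0 + shortcut)
})

test_that("squeeze-excite gates stay in (0,1), pass constants, and cap reduction", {
  dims <- c(4L, 4L, 3L, 4L)
  se <- ihiscore:::layer_se(dims, reduction = 2L)
  V <- prod(dims[1:3])
  X <- matrix(stats::rnorm(V * 4 * 3), ncol = 3)
  X[seq_len(V), ] <- 0.7 # constant first channel
  out <- ihiscore:::layer_forward(se, X, training = TRUE)
  expect_true(all(se$g > 0 & se$g < 1))
  expect_equal(se$z[1, ], rep(0.7, 3)) # squeeze of a constant channel
  # forcing the gate open recovers the input
  se$W2[] <- 0
  se$b2[] <- 30 # sigmoid(30) ~ 1
  out_open <- ihiscore:::layer_forward(se, X, training = TRUE)
  expect_equal(out_open, X, tolerance = 1e-8)
  expect_error(ihiscore:::layer_se(dims, reduction = 8L), "reduction")
  expect_error(build_secnn(tiny_grid, channels = c(2L, 2L, 3L, 3L, 4L),
                           reduction = 16L), "reduction")
})

test_that("training learns, logs, selects the best epoch and reproduces", {
  set.seed(6)
  n <- 40
  crops <- lapply(seq_len(n), function(i) {
    render_crop(phantom_latents(t2 = (i - 1) / (n - 1)), grid_shape = tiny_grid)
  })
  y <- 2 * (seq_len(n) - 1) / (n - 1)
  net <- do.call(build_conv5fc3, c(list(input_dims = tiny_grid), tiny_net_args))
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 6, seed = 2)
  fit <- train_regressor(net, crops[1:30], y[1:30], crops[31:40], y[31:40], cfg)
  expect_lt(fit$log$train_loss[6], fit$log$train_loss[1])
  expect_equal(fit$best_epoch, which.min(fit$log$val_loss))
  expect_equal(fit$best_val_loss, min(fit$log$val_loss))
  fit2 <- train_regressor(net, crops[1:30], y[1:30], crops[31:40], y[31:40], cfg)
  expect_identical(fit$best_val_loss, fit2$best_val_loss)
  expect_identical(predict_criterion(fit, crops[35:38]),
                   predict_criterion(fit2, crops[35:38]))
  # the snapshot reproduces the recorded validation loss
  expect_equal(mean((predict_criterion(fit, crops[31:40]) - y[31:40])^2),
               fit$best_val_loss, tolerance = 1e-10)
  expect_error(train_regressor(net, crops[1:30], rep(1e200, 30),
                               crops[31:40], y[31:40], cfg), "diverged")
  expect_error(train_regressor(net, list(), numeric(0), crops[1:2], y[1:2], cfg),
               "non-empty")
})

test_that("prediction is shape-checked and elementwise consistent", {
  co <- small_cohort()
  crops <- co$crops$left[1:6]
  y <- co$ratings_observed$c1[1:6]
  net <- do.call(build_conv5fc3, c(list(input_dims = tiny_grid), tiny_net_args))
  fit <- train_regressor(net, crops[1:4], y[1:4], crops[5:6], y[5:6],
                         train_config(max_epochs = 2, seed = 1))
  p <- predict_criterion(fit, crops)
  expect_length(p, 6)
  expect_true(all(is.finite(p)))
  expect_identical(predict_criterion(fit, crops[c(2, 2)])[1],
                   predict_criterion(fit, crops[c(2, 2)])[2])
  # mirrored input is a different but valid input (no equivariance claim)
  pm <- predict_criterion(fit, list(mirror_hemisphere(crops[[1]])))
  expect_true(is.finite(pm))
  wrong <- list(gm_crop(array(0.5, c(4, 4, 4))))
  expect_error(predict_criterion(fit, wrong), "extents")
})

test_that("ridge nested CV recovers a noiseless linear signal honestly", {
  set.seed(10)
  n <- 120; p <- 25
  X <- matrix(stats::rnorm(n * p), n, p)
  y <- 3 * X[, 17] + 1
  fit <- ridge_nested_cv(X, y, seed = 4)
  expect_lt(max(abs(fit$outer_predictions$pred - fit$outer_predictions$y)), 1e-3)
  expect_true(fit$lambda %in% fit$lambda_grid)
  expect_true(all(fit$outer_predictions$lambda %in% fit$lambda_grid))
  expect_setequal(fit$outer_predictions$index, seq_len(n))
  expect_error(ridge_nested_cv(X, rep(2, n)), "constant")
})

test_that("ridge with permuted labels carries no held-out signal", {
  set.seed(11)
  n <- 200; p <- 60
  X <- matrix(stats::rnorm(n * p), n, p)
  y <- sample(2 * X[, 5] + stats::rnorm(n, 0, 0.1)) # permuted: signal destroyed
  fit <- ridge_nested_cv(X, y, seed = 12)
  expect_lt(abs(icc(fit$outer_predictions$y, fit$outer_predictions$pred)), 0.2)
})

test_that("closed-form ridge matches the reference coordinate-descent fit", {
  set.seed(13)
  n <- 50; p <- 12
  X <- matrix(stats::rnorm(n * p), n, p)
  y <- X %*% stats::rnorm(p) + stats::rnorm(n, 0, 0.3)
  lam <- 5
  fit <- ihiscore:::ridge_dual_fit(X, y, lam)
  coef_mine <- as.vector(crossprod(fit$Xc, fit$alphas[[1]]))
  # glmnet standardizes y internally, so its penalty is scaled by sd_n(y)
  sd_n <- sqrt(mean((y - mean(y))^2))
  ref <- glmnet::glmnet(X, y, alpha = 0, lambda = lam / n * sd_n,
                        standardize = FALSE, intercept = TRUE, thresh = 1e-14)
  expect_equal(coef_mine, as.vector(ref$beta), tolerance = 1e-6)
  # and the primal normal equations agree with the dual route exactly
  Xc <- scale(X, scale = FALSE)
  primal <- solve(crossprod(Xc) + lam * diag(p), crossprod(Xc, y - mean(y)))
  expect_equal(coef_mine, as.vector(primal), tolerance = 1e-10)
})

test_that("saliency retains the requested voxels and is the |coef| map for ridge", {
  co <- small_cohort()
  crops <- co$crops$left
  y <- co$ratings_observed$c2[co$ratings_observed$hemisphere == "left"]
  rid <- ridge_nested_cv(crops_to_matrix(crops), y, seed = 3)
  sal <- saliency_group_map(rid, crops, n_retain = 50)
  mask <- attr(sal, "retained_mask")
  expect_equal(sum(mask), 50)
  expect_equal(sal[mask], abs(rid$coef)[mask], tolerance = 1e-12)
  expect_equal(sort(abs(rid$coef), decreasing = TRUE)[1:50],
               sort(sal[mask], decreasing = TRUE))
  # requesting more voxels than exist keeps them all
  sal_all <- saliency_group_map(rid, crops, n_retain = 1e6)
  expect_equal(sum(attr(sal_all, "retained_mask")), prod(tiny_grid))

  net <- do.call(build_conv5fc3, c(list(input_dims = tiny_grid), tiny_net_args))
  fit <- train_regressor(net, crops[1:20], y[1:20], crops[21:30], y[21:30],
                         train_config(max_epochs = 2, seed = 1))
  sal_cnn <- saliency_group_map(fit, crops[1:10], n_retain = 40)
  expect_equal(sum(attr(sal_cnn, "retained_mask")), 40)
  expect_true(all(sal_cnn[attr(sal_cnn, "retained_mask")] > 0))
  expect_equal(dim(sal_cnn), tiny_grid)
})
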