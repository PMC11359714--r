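zeroed_net <- function(input_dim, n_targets, hidden = c(3, 4)) {
  net <- new_bilstm_network(input_dim, n_targets, hidden = hidden, seed = 1)
  for (nm in c("layer1_fwd", "layer1_bwd", "layer2_fwd", "layer2_bwd"))
    for (f in c("W_f", "W_i", "W_o", "W_c", "b_f", "b_i", "b_o", "b_c"))
      net[[nm]][[f]][] <- 0
  net$readout_W[] <- 0
  net$readout_b[] <- 0
  net
}

test_that("cell step validates dimensions and keeps hidden state bounded", {
  set.seed(41)
  p <- random_cell(4, 3)
  expect_error(lstm_cell_step(p, list(h = numeric(4), C = numeric(4)),
                              numeric(2)))
  st <- list(h = numeric(4), C = numeric(4))
  for (i in 1:50) {
    st <- lstm_cell_step(p, st, rnorm(3, sd = 3))
    expect_true(all(abs(st$h) < 1))
    expect_true(all(is.finite(st$C)))
  }
})

test_that("bidirectional layer handles single steps, palindromes and zeros", {
  set.seed(42)
  p <- random_cell(3, 2)
  x1 <- matrix(rnorm(2), 1)
  out1 <- bilstm_layer(p, p, x1)
  expect_equal(dim(out1), c(1, 6))
  expect_equal(out1[, 1:3], out1[, 4:6])   # both directions see one input
  # palindromic sequence with shared parameters: block-swapped time reversal
  half <- matrix(rnorm(3 * 2), 3)
  pal <- rbind(half, half[3:1, ])
  outp <- bilstm_layer(p, p, pal)
  swapped <- cbind(outp[, 4:6], outp[, 1:3])
  expect_equal(outp, swapped[nrow(pal):1, ], tolerance = 1e-12)
  z <- zeroed_net(2, 1)
  expect_true(all(bilstm_layer(z$layer1_fwd, z$layer1_bwd,
                               matrix(rnorm(10), 5)) == 0))
  expect_error(bilstm_layer(p, p, matrix(numeric(0), 0, 2)), "empty")
})

test_that("window maker counts, slices and drops masked windows correctly", {
  m <- load_builtin_montage()
  sp <- builtin_split(18, m)
  rec <- new_recording(matrix(seq_len(60 * 1500), 60), 250, m$names)
  w <- make_windows(rec, sp, seq_len = 150)
  expect_equal(dim(w$X), c(18, 10, 150))
  expect_equal(dim(w$Y), c(42, 10, 150))
  # stride-1 slicing oracle on a short stretch
  rec10 <- new_recording(matrix(seq_len(60 * 10), 60), 250, m$names)
  w2 <- make_windows(rec10, sp, seq_len = 5, stride = 1)
  expect_equal(dim(w2$X)[2], 6)
  for (b in 1:6)
    expect_equal(w2$X[, b, ], rec10$data[sp$observed, b:(b + 4)],
                 ignore_attr = TRUE)
  # windows touching artifact samples are dropped
  mask <- matrix(FALSE, 60, 1500); mask[3, 400] <- TRUE
  w3 <- make_windows(rec, sp, seq_len = 150, mask = mask)
  expect_equal(dim(w3$X)[2], 9)
  expect_false(any(w3$starts <= 400 & w3$starts + 149 >= 400))
  expect_error(make_windows(rec10, sp, seq_len = 11), "exceeds")
})

test_that("zero-weight forward broadcasts the de-standardized readout bias", {
  net <- zeroed_net(2, 3)
  net$readout_b <- c(0.5, -1, 0)
  net$norm_stats <- list(obs_mean = c(0, 0), obs_sd = c(1, 1),
                         tgt_mean = c(10, 20, 30), tgt_sd = c(2, 2, 2))
  out <- bilstm_forward(net, matrix(rnorm(10), 5, 2))
  expect_equal(dim(out), c(5, 3))
  expect_equal(out, matrix(rep(c(11, 18, 30), each = 5), 5),
               tolerance = 1e-12)
})

test_that("compiled backpropagation matches finite differences", {
  set.seed(43)
  net <- new_bilstm_network(2, 3, hidden = c(3, 4), seed = 7)
  p <- eegdense:::net_params(net)
  X <- array(rnorm(2 * 2 * 5), c(2, 2, 5))
  Y <- array(rnorm(3 * 2 * 5), c(3, 2, 5))
  gr <- eegdense:::cpp_bilstm_loss_grad(p, X, Y)
  flat <- eegdense:::flatten_params(p)
  g <- eegdense:::flatten_params(gr$grads)
  eps <- 1e-6
  idx <- sort(sample(length(flat), 30))
  num <- vapply(idx, function(i) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    (eegdense:::cpp_bilstm_loss(eegdense:::unflatten_params(up, p), X, Y) -
     eegdense:::cpp_bilstm_loss(eegdense:::unflatten_params(dn, p), X, Y)) /
      (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - g[idx])), 1e-7)
})

tiny_fixture <- function(noise_sd, seed = 51, duration = 14) {
  m <- load_builtin_montage()
  sp <- channel_split(m, m$names[builtin_split(9)$observed],
                      c("FCz", "C1", "CP1"))
  fx <- make_linear_mixture_case(m, sp, mix_seed = seed, noise_sd = noise_sd,
                                 duration_s = duration)
  n <- ncol(fx$recording$data)
  cut <- round(n * 5 / 7)
  list(montage = m, split = sp, fx = fx,
       train = new_recording(fx$recording$data[, 1:cut], 250, m$names),
       val = new_recording(fx$recording$data[, (cut + 1):n], 250, m$names))
}

test_that("zero-epoch training returns a shape-correct initialized network", {
  fz <- tiny_fixture(0.1)
  cfg <- train_config(batch_size = 80, seq_len = 120, max_epochs = 0,
                      hidden = c(6, 8), seed = 3)
  net <- bilstm_train(fz$train, fz$val, fz$split, fz$montage, cfg)
  expect_s3_class(net, "bilstm_network")
  expect_equal(net$hidden, c(6L, 8L))
  expect_equal(ncol(net$layer2_fwd$W_f), 8 + 2 * 6)  # stacked input = 2 x h1
  expect_equal(dim(net$readout_W), c(3, 2 * 8))
  out <- bilstm_forward(net, matrix(rnorm(120 * 9), 120, 9))
  expect_equal(dim(out), c(120, 3))
})

test_that("training is deterministic and reduces the loss by orders of magnitude", {
  fz <- tiny_fixture(0)
  cfg <- train_config(batch_size = 80, seq_len = 120, stride = 15,
                      max_epochs = 60, patience = 60, hidden = c(16, 16),
                      learning_rate = 2e-2, seed = 4)
  net1 <- bilstm_train(fz$train, fz$val, fz$split, fz$montage, cfg)
  net2 <- bilstm_train(fz$train, fz$val, fz$split, fz$montage, cfg)
  expect_identical(attr(net1, "best_val"), attr(net2, "best_val"))
  expect_identical(net1$readout_W, net2$readout_W)
  h <- attr(net1, "history")
  init_val <- h$val[h$epoch == 0]
  expect_gt(init_val / attr(net1, "best_val"), 100)
})

test_that("checkpoints round-trip through the JSON archive", {
  fz <- tiny_fixture(0.1)
  cfg <- train_config(batch_size = 80, seq_len = 120, max_epochs = 1,
                      hidden = c(5, 6), seed = 9, stride = 240)
  net <- bilstm_train(fz$train, fz$val, fz$split, fz$montage, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_bilstm(net, path)
  net2 <- load_bilstm(path)
  win <- matrix(rnorm(120 * 9), 120, 9)
  expect_equal(bilstm_forward(net2, win), bilstm_forward(net, win),
               tolerance = 1e-12)
  expect_identical(net2$target_labels, net$target_labels)
  other <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "something-else"}', other)
  expect_error(load_bilstm(other), "unrecognized")
})

test_that("prediction intervals are honest for a trained network", {
  fz <- tiny_fixture(0.2, duration = 16)
  cfg <- train_config(batch_size = 80, seq_len = 120, stride = 60,
                      max_epochs = 10, patience = 10, hidden = c(16, 16),
                      learning_rate = 1e-2, seed = 6)
  net <- bilstm_train(fz$train, fz$val, fz$split, fz$montage, cfg)
  # fresh data from the same mixture for calibration and test
  res <- predict_with_ci(net, fz$val, fz$split, calib_rec = fz$train,
                         level = 0.95)
  expect_true(all(res$ci_half_width_per_channel > 0))
  expect_true(all(res$rmse_per_channel >= 0))
  expect_true(all(res$ci_coverage_per_channel >= 0.8))
  res50 <- predict_with_ci(net, fz$val, fz$split, calib_rec = fz$train,
                           level = 0.5)
  expect_true(all(res50$ci_half_width_per_channel <
                  res$ci_half_width_per_channel))
  expect_error(predict_with_ci(net, fz$val, fz$split, calib_rec = NULL),
               "calibration")
})
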