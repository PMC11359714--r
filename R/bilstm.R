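# The interpolation network: a two-layer stacked bidirectional LSTM over
# windows of the observed channels, with a per-timestep linear readout that
# predicts all target channels jointly. Channels are z-scored with training
# statistics; the readout is de-standardized back to microvolts.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' LSTM gate parameter block
#'
#' Holds the four gate weight matrices (forget, input, output, candidate),
#' each `hidden x (hidden + input)`, operating on the concatenation
#' `[h_{t-1}, x_t]`, plus their bias vectors.
#'
#' @param W_f,W_i,W_o,W_c gate weight matrices.
#' @param b_f,b_i,b_o,b_c bias vectors of length `hidden`.
#' @return an `lstm_cell_params` object.
#' @export
lstm_cell_params <- function(W_f, W_i, W_o, W_c, b_f, b_i, b_o, b_c) {
  dims <- dim(W_f)
  for (W in list(W_i, W_o, W_c))
    if (!identical(dim(W), dims)) stop("gate weight blocks must share shape")
  h <- dims[1]
  for (b in list(b_f, b_i, b_o, b_c))
    if (length(b) != h) stop("bias length must equal hidden size")
  structure(list(W_f = W_f, W_i = W_i, W_o = W_o, W_c = W_c,
                 b_f = b_f, b_i = b_i, b_o = b_o, b_c = b_c,
                 hidden = h, input = dims[2] - h),
            class = "lstm_cell_params")
}

#' One LSTM cell update
#'
#' Applies the gated state update: sigmoid forget/input/output gates and a
#' tanh candidate, all computed from `[h_{t-1}, x_t]`; then
#' `C_t = f * C_{t-1} + i * Ctilde` and `h_t = o * tanh(C_t)`
#' (elementwise products).
#'
#' @param params an [lstm_cell_params()].
#' @param prev list with `h` and `C`, the previous hidden and cell state.
#' @param x_t input vector of length `params$input`.
#' @return list with updated `h` and `C`.
#' @export
lstm_cell_step <- function(params, prev, x_t) {
  stopifnot(inherits(params, "lstm_cell_params"),
            length(x_t) == params$input,
            length(prev$h) == params$hidden,
            length(prev$C) == params$hidden)
  z <- c(prev$h, x_t)
  f <- sigmoid(drop(params$W_f %*% z) + params$b_f)
  i <- sigmoid(drop(params$W_i %*% z) + params$b_i)
  o <- sigmoid(drop(params$W_o %*% z) + params$b_o)
  ctilde <- tanh(drop(params$W_c %*% z) + params$b_c)
  C <- f * prev$C + i * ctilde
  list(h = o * tanh(C), C = C)
}

zero_state <- function(hidden) list(h = numeric(hidden), C = numeric(hidden))

#' Bidirectional LSTM layer over one sequence
#'
#' Runs one forward pass (t = 1..T) and one backward pass (t = T..1), both
#' from zero initial state, and concatenates the two hidden sequences per
#' timestep.
#'
#' @param params_fwd,params_bwd [lstm_cell_params()] for each direction.
#' @param sequence numeric matrix, T x input_dim.
#' @return numeric matrix, T x (2 * hidden): columns `[h_fwd, h_bwd]`.
#' @export
bilstm_layer <- function(params_fwd, params_bwd, sequence) {
  sequence <- as.matrix(sequence)
  T_ <- nrow(sequence)
  if (T_ < 1) stop("empty sequence")
  run <- function(params, idx) {
    st <- zero_state(params$hidden)
    out <- matrix(NA_real_, T_, params$hidden)
    for (t in idx) {
      st <- lstm_cell_step(params, st, sequence[t, ])
      out[t, ] <- st$h
    }
    out
  }
  cbind(run(params_fwd, seq_len(T_)), run(params_bwd, rev(seq_len(T_))))
}

# --- parameter plumbing ------------------------------------------------

# concatenated form used by the compiled kernels: G = [W_f; W_i; W_o; W_c]
cell_to_dir <- function(cell)
  list(G = rbind(cell$W_f, cell$W_i, cell$W_o, cell$W_c),
       b = c(cell$b_f, cell$b_i, cell$b_o, cell$b_c))

dir_to_cell <- function(dir) {
  h <- nrow(dir$G) / 4
  rows <- function(k) dir$G[((k - 1) * h + 1):(k * h), , drop = FALSE]
  seg <- function(k) dir$b[((k - 1) * h + 1):(k * h)]
  lstm_cell_params(rows(1), rows(2), rows(3), rows(4),
                   seg(1), seg(2), seg(3), seg(4))
}

net_params <- function(net)
  list(l1f = cell_to_dir(net$layer1_fwd), l1b = cell_to_dir(net$layer1_bwd),
       l2f = cell_to_dir(net$layer2_fwd), l2b = cell_to_dir(net$layer2_bwd),
       Wr = net$readout_W, br = net$readout_b)

set_net_params <- function(net, p) {
  net$layer1_fwd <- dir_to_cell(p$l1f); net$layer1_bwd <- dir_to_cell(p$l1b)
  net$layer2_fwd <- dir_to_cell(p$l2f); net$layer2_bwd <- dir_to_cell(p$l2b)
  net$readout_W <- p$Wr; net$readout_b <- as.numeric(p$br)
  net
}

init_cell <- function(hidden, input) {
  r <- 1 / sqrt(hidden + input)
  W <- function() matrix(runif(hidden * (hidden + input), -r, r), hidden)
  # forget-gate bias starts at 1 so early training does not erase memory
  lstm_cell_params(W(), W(), W(), W(),
                   rep(1, hidden), numeric(hidden), numeric(hidden),
                   numeric(hidden))
}

#' Initialize a stacked bidirectional LSTM interpolation network
#'
#' @param input_dim number of observed channels.
#' @param n_targets number of target channels.
#' @param hidden length-2 integer, hidden units of the two stacked layers
#'   (defaults 120 and 128).
#' @param seed integer seed for the weight initialization.
#' @return a `bilstm_network` with untrained weights and empty
#'   normalization statistics.
#' @export
new_bilstm_network <- function(input_dim, n_targets, hidden = c(120, 128),
                               seed = 1) {
  stopifnot(length(hidden) == 2, input_dim >= 1, n_targets >= 1)
  with_seed(seed, {
    h1 <- hidden[1]; h2 <- hidden[2]
    r <- 1 / sqrt(2 * h2)
    structure(list(
      layer1_fwd = init_cell(h1, input_dim),
      layer1_bwd = init_cell(h1, input_dim),
      layer2_fwd = init_cell(h2, 2 * h1),
      layer2_bwd = init_cell(h2, 2 * h1),
      readout_W = matrix(runif(n_targets * 2 * h2, -r, r), n_targets),
      readout_b = numeric(n_targets),
      input_dim = as.integer(input_dim),
      n_targets = as.integer(n_targets),
      hidden = as.integer(hidden),
      norm_stats = NULL, observed_labels = NULL, target_labels = NULL,
      seed = as.integer(seed)), class = "bilstm_network")
  })
}

#' @export
print.bilstm_network <- function(x, ...) {
  cat(sprintf(
    "<bilstm_network> %d observed -> %d targets, hidden %d+%d (bidirectional x2)%s\n",
    x$input_dim, x$n_targets, x$hidden[1], x$hidden[2],
    if (is.null(x$norm_stats)) " [untrained]" else ""))
  invisible(x)
}

#' Training configuration for the interpolation network
#'
#' Batch size and sequence length default to 100 windows and 150 samples
#' (0.6 s at 250 Hz); values outside 80-120 / 120-180 require
#' `allow_outside_ranges = TRUE`, since those are the ranges the network
#' was designed around.
#'
#' @param batch_size windows per gradient step.
#' @param seq_len window length in samples.
#' @param learning_rate initial Adam step size.
#' @param lr_decay multiplicative per-epoch learning-rate decay in (0, 1].
#' @param max_epochs maximum passes over the training windows.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed governing initialization and batch shuffling.
#' @param hidden length-2 hidden sizes of the stacked layers.
#' @param grad_clip global gradient-norm ceiling.
#' @param stride window stride (default `seq_len`, non-overlapping).
#' @param readout_refit after gradient training, refit the linear readout
#'   in closed form (ridge least squares on the training-window features);
#'   kept only if it improves the validation loss.
#' @param allow_outside_ranges permit batch/sequence values outside the
#'   designed ranges.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 100, seq_len = 150,
                         learning_rate = 1e-2, lr_decay = 0.95,
                         max_epochs = 200,
                         patience = 10, seed = 1, hidden = c(120, 128),
                         grad_clip = 1, stride = NULL,
                         readout_refit = TRUE,
                         allow_outside_ranges = FALSE) {
  if (!allow_outside_ranges) {
    if (batch_size < 80 || batch_size > 120)
      stop("batch_size outside 80-120; set allow_outside_ranges = TRUE to override")
    if (seq_len < 120 || seq_len > 180)
      stop("seq_len outside 120-180; set allow_outside_ranges = TRUE to override")
  }
  if (is.null(stride)) stride <- seq_len
  structure(list(batch_size = as.integer(batch_size),
                 seq_len = as.integer(seq_len),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 hidden = as.integer(hidden), grad_clip = grad_clip,
                 stride = as.integer(stride),
                 readout_refit = isTRUE(readout_refit)),
            class = "train_config")
}

#' Cut a recording into training windows
#'
#' Slices the observed channels (inputs) and target channels (outputs) into
#' windows of `seq_len` samples. Windows containing any artifact-masked
#' sample are dropped.
#'
#' @param rec an `eeg_recording`.
#' @param split a `channel_split` (indices into the montage order, which
#'   must match the recording's channel order).
#' @param seq_len window length in samples.
#' @param stride step between window starts (default `seq_len`).
#' @param mask optional logical channels x samples artifact mask.
#' @return list with arrays `X` (`|observed| x n_windows x seq_len`), `Y`
#'   (`|targets| x n_windows x seq_len`) and integer `starts`.
#' @export
make_windows <- function(rec, split, seq_len, stride = seq_len, mask = NULL) {
  n <- ncol(rec$data)
  if (seq_len > n) stop("seq_len exceeds recording length")
  starts <- seq(1, n - seq_len + 1, by = stride)
  if (!is.null(mask)) {
    bad <- apply(mask, 2, any)
    keep <- vapply(starts, function(s) !any(bad[s:(s + seq_len - 1)]),
                   logical(1))
    starts <- starts[keep]
  }
  nb <- length(starts)
  X <- array(NA_real_, c(length(split$observed), nb, seq_len))
  Y <- array(NA_real_, c(length(split$targets), nb, seq_len))
  for (b in seq_len(nb)) {
    sl <- starts[b]:(starts[b] + seq_len - 1)
    X[, b, ] <- rec$data[split$observed, sl]
    Y[, b, ] <- rec$data[split$targets, sl]
  }
  list(X = X, Y = Y, starts = starts)
}

channel_norm_stats <- function(rec, rows = seq_len(nrow(rec$data))) {
  mu <- rowMeans(rec$data[rows, , drop = FALSE])
  sdv <- apply(rec$data[rows, , drop = FALSE], 1, sd)
  if (any(sdv < 1e-12))
    stop("zero-variance channel(s): ",
         paste(rec$channel_labels[rows][sdv < 1e-12], collapse = ", "),
         " (standardization undefined)")
  list(mean = mu, sd = sdv, rows = rows)
}

standardize_rows <- function(mat, mu, sdv) (mat - mu) / sdv

#' Forward pass of the network on one window
#'
#' Standardizes the window with the network's stored training statistics,
#' runs both stacked bidirectional layers and the linear readout, and
#' de-standardizes the output back to microvolts.
#'
#' @param net a trained `bilstm_network`.
#' @param window numeric matrix, seq_len x input_dim, microvolts.
#' @return numeric matrix, seq_len x n_targets, microvolts.
#' @export
bilstm_forward <- function(net, window) {
  window <- as.matrix(window)
  if (ncol(window) != net$input_dim)
    stop("window has ", ncol(window), " channels; network expects ",
         net$input_dim)
  ns <- net$norm_stats
  if (is.null(ns)) stop("network has no normalization statistics (untrained)")
  xs <- t(standardize_rows(t(window), ns$obs_mean, ns$obs_sd))
  Xc <- array(t(xs), c(net$input_dim, 1, nrow(window)))
  Yc <- cpp_bilstm_forward(net_params(net), Xc)
  ys <- t(Yc[, 1, , drop = TRUE])
  if (net$n_targets == 1) ys <- matrix(Yc[1, 1, ], ncol = 1)
  t(t(ys) * ns$tgt_sd + ns$tgt_mean)
}

flatten_params <- function(p) unlist(p, use.names = FALSE)
unflatten_params <- function(flat, skeleton) {
  out <- skeleton
  pos <- 0L
  for (i in seq_along(out)) {
    if (is.list(out[[i]])) {
      for (j in seq_along(out[[i]])) {
        n <- length(out[[i]][[j]])
        out[[i]][[j]][] <- flat[(pos + 1):(pos + n)]
        pos <- pos + n
      }
    } else {
      n <- length(out[[i]])
      out[[i]][] <- flat[(pos + 1):(pos + n)]
      pos <- pos + n
    }
  }
  stopifnot(pos == length(flat))
  out
}

#' Train the interpolation network
#'
#' Minimizes the mean squared error between the network output and the true
#' target channels on standardized windows, using Adam with global
#' gradient-norm clipping and early stopping on the validation windows.
#' Standardization statistics come from the training recording only.
#' Deterministic given `cfg$seed`.
#'
#' @param train_rec,val_rec `eeg_recording`s holding all montage channels;
#'   validation data must be disjoint from training data.
#' @param split a `channel_split`.
#' @param montage the montage the split refers to.
#' @param cfg a [train_config()].
#' @param train_mask,val_mask optional artifact masks; masked windows are
#'   excluded.
#' @param verbose print per-epoch losses.
#' @return a trained `bilstm_network`; attribute `history` holds per-epoch
#'   train/validation losses (standardized MSE).
#' @export
bilstm_train <- function(train_rec, val_rec, split, montage, cfg,
                         train_mask = NULL, val_mask = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  used <- sort(union(split$observed, split$targets))
  ns_all <- channel_norm_stats(train_rec, used)
  at <- function(idx) match(idx, used)
  ns <- list(obs_mean = ns_all$mean[at(split$observed)],
             obs_sd = ns_all$sd[at(split$observed)],
             tgt_mean = ns_all$mean[at(split$targets)],
             tgt_sd = ns_all$sd[at(split$targets)])
  std_rec <- function(rec) {
    d <- rec$data
    d[used, ] <- standardize_rows(d[used, , drop = FALSE], ns_all$mean,
                                  ns_all$sd)
    new_recording(d, rec$fs, rec$channel_labels)
  }
  wtr <- make_windows(std_rec(train_rec), split, cfg$seq_len, cfg$stride,
                      train_mask)
  wva <- make_windows(std_rec(val_rec), split, cfg$seq_len, cfg$stride,
                      val_mask)
  if (dim(wtr$X)[2] == 0) stop("no usable training windows")

  net <- new_bilstm_network(length(split$observed), length(split$targets),
                            hidden = cfg$hidden, seed = cfg$seed)
  net$norm_stats <- ns
  net$observed_labels <- montage$names[split$observed]
  net$target_labels <- montage$names[split$targets]

  params <- net_params(net)
  flat <- flatten_params(params)
  m <- numeric(length(flat)); v <- numeric(length(flat))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  nb <- dim(wtr$X)[2]
  history <- data.frame(epoch = integer(), train = numeric(),
                        val = numeric())
  best_val <- Inf; best_flat <- flat; wait <- 0L

  val_loss <- function(fl) {
    p <- unflatten_params(fl, params)
    cpp_bilstm_loss(p, wva$X, wva$Y)
  }

  with_seed(cfg$seed, {
    if (cfg$max_epochs > 0) {
      best_val <- val_loss(flat); best_flat <- flat
      history <- rbind(history,
                       data.frame(epoch = 0L, train = NA_real_,
                                  val = best_val))
      for (ep in seq_len(cfg$max_epochs)) {
        lr_ep <- cfg$learning_rate * cfg$lr_decay^(ep - 1)
        ord <- sample.int(nb)
        batch_starts <- seq(1, nb, by = cfg$batch_size)
        tr_loss <- 0
        for (bs in batch_starts) {
          idx <- ord[bs:min(bs + cfg$batch_size - 1, nb)]
          p <- unflatten_params(flat, params)
          gr <- cpp_bilstm_loss_grad(p, wtr$X[, idx, , drop = FALSE],
                                     wtr$Y[, idx, , drop = FALSE])
          g <- flatten_params(gr$grads)
          gn <- sqrt(sum(g^2))
          if (gn > cfg$grad_clip) g <- g * cfg$grad_clip / gn
          step <- step + 1L
          m <- b1 * m + (1 - b1) * g
          v <- b2 * v + (1 - b2) * g^2
          mhat <- m / (1 - b1^step); vhat <- v / (1 - b2^step)
          flat <- flat - lr_ep * mhat / (sqrt(vhat) + eps)
          tr_loss <- tr_loss + gr$loss * length(idx)
        }
        vl <- val_loss(flat)
        history <- rbind(history,
                         data.frame(epoch = ep, train = tr_loss / nb,
                                    val = vl))
        if (verbose)
          message(sprintf("epoch %3d  train %.5g  val %.5g", ep,
                          tr_loss / nb, vl))
        if (vl < best_val - 1e-12) {
          best_val <- vl; best_flat <- flat; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      }
    }
  })
  best <- unflatten_params(best_flat, params)
  if (cfg$readout_refit && cfg$max_epochs > 0) {
    refit <- refit_readout(best, wtr)
    vl <- cpp_bilstm_loss(refit, wva$X, wva$Y)
    if (vl < best_val) { best <- refit; best_val <- vl }
  }
  net <- set_net_params(net, best)
  attr(net, "history") <- history
  attr(net, "best_val") <- best_val
  net
}

# exact ridge least-squares solution for the readout given the recurrent
# features on the training windows
refit_readout <- function(params, windows, ridge = 1e-8) {
  Z <- cpp_bilstm_features(params, windows$X)   # 2*H2 x B x T
  d <- dim(Z)
  Zm <- matrix(aperm(Z, c(1, 2, 3)), d[1], d[2] * d[3])
  Ym <- matrix(aperm(windows$Y, c(1, 2, 3)), dim(windows$Y)[1], d[2] * d[3])
  Za <- rbind(Zm, 1)
  A <- Za %*% t(Za)
  A <- A + ridge * mean(diag(A)) * diag(nrow(A))
  Wb <- t(solve(A, Za %*% t(Ym)))
  params$Wr <- Wb[, seq_len(d[1]), drop = FALSE]
  params$br <- Wb[, d[1] + 1]
  params
}

#' Predict all target channels over a full recording
#'
#' Covers the recording with consecutive `seq_len` windows (a final window
#' is right-aligned to the last sample, overwriting its overlap) and runs
#' the network on each.
#'
#' @param net a trained `bilstm_network`.
#' @param rec an `eeg_recording` containing at least the observed channels
#'   in montage order positions.
#' @param split the `channel_split` the network was trained with.
#' @param seq_len window length (defaults to 150).
#' @param chunk windows evaluated per compiled call.
#' @return matrix targets x samples, microvolts.
#' @export
bilstm_predict_series <- function(net, rec, split, seq_len = 150,
                                  chunk = 64) {
  ns <- net$norm_stats
  n <- ncol(rec$data)
  seq_len <- min(seq_len, n)
  starts <- unique(c(seq(1, n - seq_len + 1, by = seq_len), n - seq_len + 1))
  obs <- standardize_rows(rec$data[split$observed, , drop = FALSE],
                          ns$obs_mean, ns$obs_sd)
  pred <- matrix(NA_real_, length(split$targets), n)
  p <- net_params(net)
  for (cs in split(starts, ceiling(seq_along(starts) / chunk))) {
    X <- array(NA_real_, c(length(split$observed), length(cs), seq_len))
    for (b in seq_along(cs)) X[, b, ] <- obs[, cs[b]:(cs[b] + seq_len - 1)]
    Yc <- cpp_bilstm_forward(p, X)
    for (b in seq_along(cs))
      pred[, cs[b]:(cs[b] + seq_len - 1)] <- Yc[, b, ]
  }
  pred <- pred * ns$tgt_sd + ns$tgt_mean
  rownames(pred) <- net$target_labels
  pred
}

#' Predict target channels with calibrated confidence intervals
#'
#' Runs the network on the test recording and attaches per-channel
#' Gaussian-calibrated confidence intervals: the half-width is
#' `z_(1+level)/2 * sd(residuals)` where the residual standard deviation is
#' estimated on a held-out calibration recording (never on training data).
#' When the test recording contains the true target channels, per-channel
#' RMSE and empirical CI coverage are reported.
#'
#' @param net a trained `bilstm_network`.
#' @param test_rec recording to predict on.
#' @param split the trained `channel_split`.
#' @param calib_rec calibration recording with true target channels,
#'   disjoint from training data.
#' @param level confidence level (default 0.95).
#' @param seq_len prediction window length.
#' @return a `prediction_result`: list with `predicted` (targets x
#'   samples), `rmse_per_channel`, `ci_half_width_per_channel`,
#'   `ci_coverage_per_channel` and `level`.
#' @export
predict_with_ci <- function(net, test_rec, split, calib_rec, level = 0.95,
                            seq_len = 150) {
  if (missing(calib_rec) || is.null(calib_rec))
    stop("calibration recording is required for confidence intervals")
  calib_pred <- bilstm_predict_series(net, calib_rec, split, seq_len)
  calib_res <- calib_pred - calib_rec$data[split$targets, , drop = FALSE]
  half <- gaussian_ci_half_width(calib_res, level)
  pred <- bilstm_predict_series(net, test_rec, split, seq_len)
  rmse_ch <- cover <- rep(NA_real_, length(split$targets))
  truth_known <- nrow(test_rec$data) >= max(split$targets)
  if (truth_known) {
    truth <- test_rec$data[split$targets, , drop = FALSE]
    err <- pred - truth
    rmse_ch <- sqrt(rowMeans(err^2))
    cover <- rowMeans(abs(err) <= half)
  }
  names(rmse_ch) <- names(cover) <- names(half) <- net$target_labels
  structure(list(predicted = pred, rmse_per_channel = rmse_ch,
                 ci_half_width_per_channel = half,
                 ci_coverage_per_channel = cover, level = level),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "<prediction_result> %d channels x %d samples; mean RMSE %.4g uV, mean CI half-width %.4g uV, mean coverage %.3f\n",
    nrow(x$predicted), ncol(x$predicted), mean(x$rmse_per_channel),
    mean(x$ci_half_width_per_channel), mean(x$ci_coverage_per_channel)))
  invisible(x)
}

#' Save / load a network checkpoint
#'
#' Single-file JSON archive holding every parameter block, the
#' normalization statistics, channel labels and seed, under a versioned
#' format id.
#'
#' @param net a `bilstm_network`.
#' @param path file path.
#' @return `load_bilstm` returns the restored `bilstm_network`.
#' @export
save_bilstm <- function(net, path) {
  ser_cell <- function(cell)
    list(W_f = cell$W_f, W_i = cell$W_i, W_o = cell$W_o, W_c = cell$W_c,
         b_f = cell$b_f, b_i = cell$b_i, b_o = cell$b_o, b_c = cell$b_c)
  obj <- list(format = "eegdense-bilstm-1",
              input_dim = net$input_dim, n_targets = net$n_targets,
              hidden = net$hidden, seed = net$seed,
              observed_labels = net$observed_labels,
              target_labels = net$target_labels,
              norm_stats = net$norm_stats,
              layer1_fwd = ser_cell(net$layer1_fwd),
              layer1_bwd = ser_cell(net$layer1_bwd),
              layer2_fwd = ser_cell(net$layer2_fwd),
              layer2_bwd = ser_cell(net$layer2_bwd),
              readout_W = net$readout_W, readout_b = net$readout_b)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_bilstm
#' @export
load_bilstm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "eegdense-bilstm-1"))
    stop("unrecognized checkpoint format: ", obj$format)
  de_cell <- function(cl)
    lstm_cell_params(as.matrix(cl$W_f), as.matrix(cl$W_i),
                     as.matrix(cl$W_o), as.matrix(cl$W_c),
                     cl$b_f, cl$b_i, cl$b_o, cl$b_c)
  structure(list(
    layer1_fwd = de_cell(obj$layer1_fwd), layer1_bwd = de_cell(obj$layer1_bwd),
    layer2_fwd = de_cell(obj$layer2_fwd), layer2_bwd = de_cell(obj$layer2_bwd),
    readout_W = as.matrix(obj$readout_W), readout_b = obj$readout_b,
    input_dim = obj$input_dim, n_targets = obj$n_targets,
    hidden = obj$hidden, norm_stats = lapply(obj$norm_stats, as.numeric),
    observed_labels = obj$observed_labels,
    target_labels = obj$target_labels, seed = obj$seed),
    class = "bilstm_network")
}


#' Gaussian-calibrated confidence-interval half-width
#'
#' Half-width of a symmetric prediction interval under a Gaussian residual
#' model: `z_(1+level)/2` times the per-channel residual standard
#' deviation. This is the calibration used by [predict_with_ci()].
#'
#' @param residuals numeric vector or channels x samples matrix of
#'   calibration residuals (microvolts).
#' @param level confidence level.
#' @return per-channel half-width (scalar for a vector input).
#' @export
gaussian_ci_half_width <- function(residuals, level = 0.95) {
  if (is.null(dim(residuals))) residuals <- matrix(residuals, nrow = 1)
  drop(qnorm((1 + level) / 2) * apply(residuals, 1, sd))
}
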