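# Reconstruction metrics and the downstream quality check: common spatial
# patterns (CSP) feature extraction and one-versus-rest (OVR) four-class
# motor-imagery classification, run identically on low-density, predicted
# high-density and true high-density signals.

#' Root-mean-square error
#'
#' @param pred,truth numeric vectors or matrices of equal length,
#'   microvolts.
#' @return scalar RMSE in microvolts.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) == 0) stop("empty input")
  sqrt(mean((as.numeric(pred) - as.numeric(truth))^2))
}

epoch_array <- function(x) {
  if (inherits(x, "eeg_epochs")) x$data else x
}

trial_cov <- function(X) {
  C <- X %*% t(X)
  C / sum(diag(C))
}

avg_cov <- function(arr, reg) {
  ch <- dim(arr)[2]
  S <- matrix(0, ch, ch)
  for (i in seq_len(dim(arr)[1])) S <- S + trial_cov(arr[i, , ])
  S <- S / dim(arr)[1]
  S + reg * sum(diag(S)) / ch * diag(ch)
}

#' Fit common spatial pattern filters for two conditions
#'
#' Computes the average trace-normalized covariance of each condition,
#' regularizes, and solves the generalized eigenproblem
#' `S_A w = lambda (S_A + S_B) w`. Returns the `m` filters with the largest
#' and the `m` with the smallest generalized eigenvalues, ordered by
#' descending eigenvalue, as rows of a `2m x channels` matrix.
#'
#' @param epochs_A,epochs_B `eeg_epochs` or trials x channels x samples
#'   arrays for the two conditions (>= 2 trials each).
#' @param m number of filter pairs.
#' @param reg covariance shrinkage factor (times `trace/channels`),
#'   stabilizing the eigensolve for many channels and few trials.
#' @return a `csp_filters` object: list with `filters` (2m x channels) and
#'   `eigenvalues` (length 2m, descending, in [0, 1]).
#' @export
csp_fit <- function(epochs_A, epochs_B, m = 3, reg = 1e-6) {
  A <- epoch_array(epochs_A); B <- epoch_array(epochs_B)
  stopifnot(dim(A)[1] >= 2, dim(B)[1] >= 2, dim(A)[2] == dim(B)[2])
  ch <- dim(A)[2]
  if (2 * m > ch) stop("2m exceeds the channel count")
  SA <- avg_cov(A, reg); SB <- avg_cov(B, reg)
  SC <- SA + SB
  ec <- eigen(SC, symmetric = TRUE)
  keep <- ec$values > max(ec$values) * 1e-10
  P <- diag(1 / sqrt(ec$values[keep]), sum(keep)) %*% t(ec$vectors[, keep])
  es <- eigen(P %*% SA %*% t(P), symmetric = TRUE)  # eigenvalues descending
  W <- t(es$vectors) %*% P
  sel <- c(seq_len(m), (nrow(W) - m + 1):nrow(W))
  structure(list(filters = W[sel, , drop = FALSE],
                 eigenvalues = es$values[sel], m = m),
            class = "csp_filters")
}

#' Log-variance CSP features of one epoch
#'
#' Projects the epoch through the filters and returns the log of each
#' projection's variance share: `f_j = log(var_j / sum_k var_k)`, so that
#' `sum(exp(f)) = 1` and features are invariant to global amplitude
#' scaling.
#'
#' @param filters a `csp_filters` (or bare filter matrix).
#' @param epoch numeric channels x samples matrix.
#' @return numeric feature vector of length `2m`.
#' @export
csp_features <- function(filters, epoch) {
  W <- if (inherits(filters, "csp_filters")) filters$filters else filters
  stopifnot(ncol(W) == nrow(epoch))
  v <- apply(W %*% epoch, 1, var)
  if (any(v <= 0)) stop("zero-variance projection")
  log(v / sum(v))
}

ridge_lda <- function(F_, y, ridge = 1e-6) {
  # binary regularized linear discriminant; y logical (TRUE = positive)
  mu1 <- colMeans(F_[y, , drop = FALSE])
  mu0 <- colMeans(F_[!y, , drop = FALSE])
  n1 <- sum(y); n0 <- sum(!y)
  X1 <- sweep(F_[y, , drop = FALSE], 2, mu1)
  X0 <- sweep(F_[!y, , drop = FALSE], 2, mu0)
  Sp <- (t(X1) %*% X1 + t(X0) %*% X0) / (n1 + n0 - 2)
  Sp <- Sp + ridge * mean(diag(Sp)) * diag(ncol(F_))
  w <- solve(Sp, mu1 - mu0)
  b <- -0.5 * sum(w * (mu1 + mu0)) + log(n1 / n0)
  list(w = w, b = b)
}

#' Train the one-versus-rest CSP classifier
#'
#' For each of the four motor-imagery classes, fits CSP filters for that
#' class against the pooled rest and a regularized linear discriminant on
#' the log-variance features. Prediction takes the argmax of the four
#' binary discriminant scores, breaking ties toward the lowest class
#' index.
#'
#' @param epochs an `eeg_epochs` containing all four classes.
#' @param m CSP filter pairs per class model.
#' @param reg covariance shrinkage passed to [csp_fit()]. The default is
#'   deliberately larger than the bare numerical floor: when some channels
#'   are reconstructions of others the class covariances are close to rank
#'   deficient, and unshrunk CSP amplifies near-null directions.
#' @return an `ovr_model`.
#' @export
ovr_train <- function(epochs, m = 3, reg = 0.05) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  classes <- mi_classes()
  if (!all(classes %in% epochs$labels))
    stop("all four classes must be present in the training set")
  models <- lapply(classes, function(cl) {
    is_cl <- epochs$labels == cl
    filt <- csp_fit(epochs$data[is_cl, , , drop = FALSE],
                    epochs$data[!is_cl, , , drop = FALSE], m = m, reg = reg)
    F_ <- t(vapply(seq_len(n_trials(epochs)),
                   function(i) csp_features(filt, epochs$data[i, , ]),
                   numeric(2 * m)))
    scorer <- ridge_lda(F_, is_cl)
    list(filters = filt, scorer = scorer)
  })
  names(models) <- classes
  structure(list(models = models, m = m), class = "ovr_model")
}

ovr_scores <- function(model, epochs) {
  arr <- epoch_array(epochs)
  vapply(model$models, function(md) {
    vapply(seq_len(dim(arr)[1]), function(i) {
      f <- csp_features(md$filters, arr[i, , ])
      sum(md$scorer$w * f) + md$scorer$b
    }, numeric(1))
  }, numeric(dim(arr)[1]))
}

#' Classify epochs with a trained OVR model
#'
#' @param model an `ovr_model` from [ovr_train()].
#' @param epochs an `eeg_epochs` to classify.
#' @return list with `labels` (predicted factor), `confusion` (4x4 counts,
#'   rows = true), `per_class_accuracy`, `total_accuracy` (the latter three
#'   `NA`-free only when `epochs` carries true labels).
#' @export
ovr_predict <- function(model, epochs) {
  sc <- ovr_scores(model, epochs)
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1)
  pred_idx <- max.col(sc, ties.method = "first")
  pred <- factor(mi_classes()[pred_idx], levels = mi_classes())
  cm <- table(true = factor(epochs$labels, levels = mi_classes()),
              predicted = pred)
  per_class <- diag(cm) / rowSums(cm)
  list(labels = pred, confusion = unclass(cm),
       per_class_accuracy = per_class,
       total_accuracy = sum(diag(cm)) / sum(cm))
}

crop_feature_window <- function(epochs, window_s) {
  lo <- epochs$cue_sample + round(window_s[1] * epochs$fs)
  hi <- epochs$cue_sample + round(window_s[2] * epochs$fs) - 1
  lo <- max(1, lo); hi <- min(dim(epochs$data)[3], hi)
  new_epochs(epochs$data[, , lo:hi, drop = FALSE], epochs$labels,
             epochs$fs, cue_sample = 1, epochs$round_id,
             epochs$channel_labels)
}

#' Compare classification accuracy across signal densities
#'
#' Runs the identical pipeline -- band-pass, feature-window crop, CSP + OVR
#' over the five round-folds -- on each supplied epoch set (typically the
#' low-density channels, the network-predicted high-density channels, and
#' the true high-density channels) and tabulates per-class and total
#' accuracy.
#'
#' @param epoch_sets named list of `eeg_epochs`, identical trials/labels/
#'   rounds across entries.
#' @param band classification band in Hz (default mu + beta, 8-30).
#' @param m CSP filter pairs.
#' @param window_s feature window relative to the cue, seconds.
#' @param folds which round-folds to run (default all five).
#' @param reg covariance shrinkage (see [ovr_train()]).
#' @return data.frame, one row per input, columns per class plus `total`;
#'   attribute `confusion` holds the pooled 4x4 matrices.
#' @export
compare_densities <- function(epoch_sets, band = c(8, 30), m = 3,
                              window_s = c(0.5, 3.5), folds = 1:5,
                              reg = 0.05) {
  stopifnot(is.list(epoch_sets), length(names(epoch_sets)) ==
              length(epoch_sets))
  ref <- epoch_sets[[1]]
  for (e in epoch_sets)
    if (!identical(as.character(e$labels), as.character(ref$labels)) ||
        !identical(e$round_id, ref$round_id))
      stop("epoch sets must share labels and round ids (fold alignment)")
  confusions <- list()
  rows <- lapply(names(epoch_sets), function(nm) {
    ep <- bandpass_epochs(epoch_sets[[nm]], band[1], band[2])
    ep <- crop_feature_window(ep, window_s)
    cm <- matrix(0, 4, 4, dimnames = list(mi_classes(), mi_classes()))
    for (k in folds) {
      sp <- split_rounds(ep, k)
      mdl <- ovr_train(sp$train, m = m, reg = reg)
      res <- ovr_predict(mdl, sp$test)
      cm <- cm + res$confusion
    }
    confusions[[nm]] <<- cm
    acc <- diag(cm) / rowSums(cm)
    c(acc, total = sum(diag(cm)) / sum(cm))
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- names(epoch_sets)
  attr(out, "confusion") <- confusions
  out
}

#' Interpolate per-electrode values onto a scalp grid
#'
#' Inverse-distance-squared interpolation of one value per electrode onto a
#' regular planar grid masked to the head disk, with equally spaced contour
#' levels spanning the value range -- the numeric content of a topographic
#' map (rendering is left to the caller).
#'
#' @param values numeric vector, one value per montage electrode.
#' @param montage an `eeg_montage` (>= 3 electrodes).
#' @param grid_n grid resolution per axis.
#' @param n_contours number of contour levels.
#' @return a `topo_grid`: list with `x`, `y` (axes), `grid` (grid_n x
#'   grid_n, `NA` outside the head disk) and `levels`.
#' @export
topogrid <- function(values, montage, grid_n = 64, n_contours = 6) {
  stopifnot(length(values) == length(montage$names),
            length(values) >= 3)
  R <- max(sqrt(rowSums(montage$pos2d^2))) * 1.02
  ax <- seq(-R, R, length.out = grid_n)
  g <- matrix(NA_real_, grid_n, grid_n)
  px <- montage$pos2d[, 1]; py <- montage$pos2d[, 2]
  for (i in seq_len(grid_n)) {
    for (j in seq_len(grid_n)) {
      if (ax[i]^2 + ax[j]^2 > R^2) next
      d <- sqrt((px - ax[i])^2 + (py - ax[j])^2)
      g[i, j] <- idw_predict(values, d, power = 2)
    }
  }
  lv <- if (diff(range(values)) == 0) rep(values[1], n_contours)
        else seq(min(values), max(values), length.out = n_contours)
  structure(list(x = ax, y = ax, grid = g, levels = lv),
            class = "topo_grid")
}
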