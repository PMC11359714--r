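test_that("rmse matches its closed forms and a two-pass loop", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  set.seed(61)
  a <- rnorm(1000); b <- rnorm(1000)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_lt(abs(rmse(a, b) - sqrt(acc / 1000)), 1e-12)
  expect_error(rmse(1:3, 1:4), "length")
})

random_spd <- function(ch) {
  A <- matrix(rnorm(ch * ch), ch)
  crossprod(A) + diag(ch) * 0.1
}

trials_from_cov <- function(S, n, T_, seed) {
  R <- chol(S)
  with_seed(seed, {
    arr <- array(NA_real_, c(n, nrow(S), T_))
    for (i in seq_len(n)) arr[i, , ] <- t(R) %*% matrix(rnorm(nrow(S) * T_),
                                                        nrow(S))
    arr
  })
}

test_that("CSP solves the two-condition generalized eigenproblem", {
  # identical conditions: every generalized eigenvalue is 1/2
  arr <- trials_from_cov(random_spd(5), 20, 80, seed = 62)
  f_same <- csp_fit(arr, arr, m = 2, reg = 0)
  expect_equal(f_same$eigenvalues, rep(0.5, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
  # diagonal case: variance confined to opposite channels
  A2 <- trials_from_cov(diag(c(4, 0.01)), 30, 100, seed = 63)
  B2 <- trials_from_cov(diag(c(0.01, 4)), 30, 100, seed = 64)
  f2 <- csp_fit(A2, B2, m = 1)
  top <- f2$filters[1, ] / sqrt(sum(f2$filters[1, ]^2))
  bot <- f2$filters[2, ] / sqrt(sum(f2$filters[2, ]^2))
  expect_gt(abs(top[1]), 0.99)
  expect_gt(abs(bot[2]), 0.99)
  # random 3-channel pair against the dense generalized-eigen oracle
  SA <- random_spd(3); SB <- random_spd(3)
  A3 <- trials_from_cov(SA, 2, 50, 65); B3 <- trials_from_cov(SB, 2, 50, 65)
  # feed covariances directly through single "trials" built to have them:
  # use the oracle on the same averaged covariances the fit uses
  f3 <- csp_fit(A3, B3, m = 1, reg = 0)
  SAn <- eegdense:::avg_cov(A3, 0); SBn <- eegdense:::avg_cov(B3, 0)
  orc <- dense_csp_oracle(SAn, SBn)
  expect_equal(f3$eigenvalues, orc$values[c(1, 3)], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_gt(cosine_abs(f3$filters[1, ], orc$vectors[, 1]), 1 - 1e-8)
  expect_gt(cosine_abs(f3$filters[2, ], orc$vectors[, 3]), 1 - 1e-8)
})

test_that("CSP filters ignore global channel rescaling", {
  A <- trials_from_cov(random_spd(4), 15, 60, 66)
  B <- trials_from_cov(random_spd(4), 15, 60, 67)
  f1 <- csp_fit(A, B, m = 2)
  f2 <- csp_fit(A * 5, B * 5, m = 2)
  for (j in 1:4)
    expect_gt(cosine_abs(f1$filters[j, ], f2$filters[j, ]), 1 - 1e-8)
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-8)
})

test_that("log-variance features are normalized, scale-free and match a loop", {
  set.seed(68)
  W <- matrix(rnorm(12), 4, 3)
  X <- matrix(rnorm(3 * 200), 3)
  f <- csp_features(W, X)
  expect_lt(abs(sum(exp(f)) - 1), 1e-10)
  expect_equal(csp_features(W, 2 * X), f, tolerance = 1e-10)
  v <- numeric(4)
  for (j in 1:4) v[j] <- var(as.numeric(W[j, , drop = FALSE] %*% X))
  expect_equal(f, log(v / sum(v)), tolerance = 1e-12)
})

test_that("OVR classification is near-perfect on strongly separable data and ties go low", {
  m <- load_builtin_montage()
  cfg <- synth_config(seed = 69, noise_sd = 1, erd_depth = 0.9)
  ep <- generate_mi_epochs(m, cfg, n_trials_per_class = 8)
  ep <- bandpass_epochs(ep, 8, 30)
  mdl <- ovr_train(ep, m = 3)
  res <- ovr_predict(mdl, ep)
  expect_gte(res$total_accuracy, 0.95)
  expect_equal(rowSums(res$confusion),
               unname(table(ep$labels)), ignore_attr = TRUE)
  expect_true(all(res$per_class_accuracy >= 0 & res$per_class_accuracy <= 1))
  # equal scores for every class: the tie rule picks the first class
  flat_mdl <- mdl
  for (cl in names(flat_mdl$models)) {
    flat_mdl$models[[cl]]$scorer$w[] <- 0
    flat_mdl$models[[cl]]$scorer$b <- 0
  }
  res_tie <- ovr_predict(flat_mdl, ep)
  expect_true(all(res_tie$labels == mi_classes()[1]))
})

test_that("identical inputs give identical density-comparison accuracies", {
  m <- load_builtin_montage()
  ep <- generate_mi_epochs(m, synth_config(seed = 70), 5)
  ep18 <- eegdense:::select_channels(ep, builtin_split(18, m)$observed)
  tab <- compare_densities(list(a = ep18, b = ep18), folds = 1:2)
  expect_equal(unlist(tab["a", ]), unlist(tab["b", ]))
  expect_true(all(tab >= 0 & tab <= 1))
  bad <- eegdense:::subset_epochs(ep, c(2:dim(ep$data)[1], 1))
  expect_error(compare_densities(list(a = ep, b = bad)), "labels")
})

test_that("topographic grids stay inside the electrode value range", {
  m <- load_builtin_montage()
  g0 <- topogrid(rep(3, 60), m, grid_n = 21)
  expect_true(all(abs(g0$grid[!is.na(g0$grid)] - 3) < 1e-12))
  expect_equal(diff(range(g0$levels)), 0)
  set.seed(71)
  v <- rnorm(60)
  g <- topogrid(v, m, grid_n = 41, n_contours = 7)
  vals <- g$grid[!is.na(g$grid)]
  expect_gte(min(vals), min(v) - 1e-12)
  expect_lte(max(vals), max(v) + 1e-12)
  expect_length(g$levels, 7)
  expect_equal(g$levels[1], min(v)); expect_equal(g$levels[7], max(v))
  # a grid node exactly on Cz passes that electrode's value through
  gi <- topogrid(v, m, grid_n = 41)
  centre <- gi$grid[21, 21]
  expect_equal(centre, v[31], tolerance = 1e-12)
  expect_true(any(is.na(g$grid)))   # corners lie outside the head disk
})
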