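test_that("design matrix has the mandated structure", {
  tl <- build_block_timeline()
  n <- 2L * n_volumes(tl)
  X <- build_design_matrix(tl, n, tl$tr_pair / 2)
  expect_identical(dim(X), c(738L, 4L))
  expect_true(all(X[, "dc"] == 1))
  expect_equal(mean(X[, "ramp"]), 0)
  expect_true(all(X[, c("rf0", "rf4")] %in% c(0, 1)))
  expect_true(all(X[, "rf0"] + X[, "rf4"] <= 1))  # non-overlapping
  # 14 blocks x 24 upsampled samples of stimulus-on rows
  expect_equal(sum(X[, "rf0"] + X[, "rf4"]), 336)
  expect_equal(sum(X[, "rf0"]), sum(X[, "rf4"]))
  expect_error(build_design_matrix(tl, 100, tl$tr_pair / 2), "inconsistent")
})

test_that("noiseless OLS recovers coefficients to machine precision", {
  tl <- build_block_timeline(n_initial_rest = 4, n_blocks = 2)
  n <- n_volumes(tl)
  X <- build_design_matrix(tl, n, tl$tr_pair)
  beta_true <- c(100, 0, 2, 1)
  y <- matrix(drop(X %*% beta_true), 1)
  fit <- fit_glm(y, X)
  expect_equal(drop(fit$beta), beta_true, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(fit$df, n - 4L)
  # exchanging the condition regressors negates the difference contrast
  withr::with_seed(5, {
    ysym <- matrix(drop(X %*% c(50, 0, 3, 3)) + stats::rnorm(n), 1)
  })
  X_swap <- X[, c(1, 2, 4, 3)]
  colnames(X_swap) <- colnames(X)
  expect_equal(glm_tmap(fit_glm(ysym, X_swap), c(0, 0, 1, -1)),
               -glm_tmap(fit_glm(ysym, X), c(0, 0, 1, -1)),
               tolerance = 1e-12)
  expect_error(fit_glm(y, cbind(X, X[, 3])), "rank deficient")
})

test_that("GLM t maps match an independent least-squares oracle", {
  tl <- build_block_timeline(n_initial_rest = 4, n_blocks = 2)
  n <- n_volumes(tl)  # 52 timepoints
  X <- build_design_matrix(tl, n, tl$tr_pair)
  withr::with_seed(21, {
    y <- matrix(drop(X %*% c(100, 1, 2, 1)), 8, n, byrow = TRUE) +
      stats::rnorm(8 * n)
  })
  fit <- fit_glm(y, X)
  t_rf0 <- glm_tmap(fit, c(0, 0, 1, 0))
  t_diff <- glm_tmap(fit, c(0, 0, 1, -1))
  for (v in 1:8) {
    lmf <- stats::lm(y[v, ] ~ X - 1)
    expect_equal(t_rf0[v], summary(lmf)$coefficients["Xrf0", "t value"],
                 tolerance = 1e-8)
    cvec <- c(0, 0, 1, -1)
    t_ref <- drop(cvec %*% coef(lmf)) /
      sqrt(drop(t(cvec) %*% stats::vcov(lmf) %*% cvec))
    expect_equal(t_diff[v], t_ref, tolerance = 1e-8)
  }
})

test_that("block-peak amplitudes isolate the stimulus response", {
  z <- tiny_zero_noise()
  # drift-free variant: same-condition responses are then identical
  sim0 <- simulate_acquisition(z$geo, z$dom, z$vas, z$tl, noise_sigma = 0,
                               drift = 0)
  pp0 <- preprocess_run(sim0)
  bt <- block_peak_responses(pp0$bold, z$tl)
  gm <- z$geo$labels == TISSUE["GM"]
  p <- z$dom$p
  amp <- bt$amplitude
  i_gm_pos <- which(as.vector(gm & p > 0))
  i_gm_neg <- which(as.vector(gm & p < 0))
  rf0 <- bt$condition == "RF0"
  # noiseless response: identical amplitude on same-condition blocks
  spread <- apply(amp[i_gm_pos, rf0, drop = FALSE], 1,
                  function(a) diff(range(a)))
  expect_lt(max(spread), 1e-6 * max(amp))
  # curvature-preferring voxels respond more to RF0 than RF4, and vice versa
  expect_true(all(rowMeans(amp[i_gm_pos, rf0]) >
                    rowMeans(amp[i_gm_pos, !rf0])))
  expect_true(all(rowMeans(amp[i_gm_neg, rf0]) <
                    rowMeans(amp[i_gm_neg, !rf0])))
  expect_error(block_peak_responses(pp0$bold, z$tl,
                                    peak_window = c(5, 40)),
               "within the stimulus block")
  expect_error(block_peak_responses(pp0$bold, z$tl, baseline_dur = 60),
               "overlaps")
})

test_that("rest-only series yields zero block amplitudes", {
  tl <- tiny_timeline()
  n2 <- 2L * n_volumes(tl)
  cs <- contrast_series(array(100, c(2, 2, 1, n2)), "bold",
                        tl$tr_pair / 2,
                        c("separate", "replace_nonsteady", "upsample"))
  bt <- block_peak_responses(cs, tl)
  expect_true(all(bt$amplitude == 0))
})

test_that("preference t is antisymmetric and matches Welch's t oracle", {
  withr::with_seed(31, {
    amp <- matrix(stats::rnorm(60, mean = rep(c(1, 0.2), each = 30)),
                  nrow = 5)  # 5 voxels x 12 blocks
  })
  cond <- rep(c("RF0", "RF4"), each = 6)
  bt <- structure(list(amplitude = amp, condition = cond,
                       grid_dim = c(5L, 1L, 1L), tag = "bold"),
                  class = "block_table")
  pm <- preference_map(bt)
  for (v in 1:5) {
    ref <- stats::t.test(amp[v, cond == "RF0"], amp[v, cond == "RF4"])
    expect_equal(as.vector(pm$t)[v], unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(as.vector(pm$df)[v], unname(ref$parameter),
                 tolerance = 1e-10)
  }
  # swapping condition labels negates the statistic
  bt_sw <- bt
  bt_sw$condition <- rev(cond)
  expect_equal(as.vector(preference_map(bt_sw)$t), -as.vector(pm$t))
  # identical amplitude sets give t = 0
  bt_eq <- bt
  bt_eq$amplitude <- cbind(amp[, 1:6], amp[, 1:6])
  expect_true(all(preference_map(bt_eq)$t == 0))
  # Welch vs pooled: magnitudes differ, signs never
  pooled <- preference_map(bt, method = "pooled")
  expect_identical(sign(as.vector(pooled$t)), sign(as.vector(pm$t)))
  # degenerate: too few blocks
  bt_short <- bt
  bt_short$amplitude <- amp[, c(1, 7), drop = FALSE]
  bt_short$condition <- c("RF0", "RF4")
  expect_error(preference_map(bt_short), "two blocks")
})

test_that("VASO and BOLD preference maps agree in sign without noise", {
  z <- tiny_zero_noise()
  pv <- preference_map(block_peak_responses(z$pp$vaso, z$tl))
  pb <- preference_map(block_peak_responses(z$pp$bold, z$tl))
  gm <- z$geo$labels == TISSUE["GM"] & abs(z$dom$p) > 0
  expect_identical(sign(pv$t[gm]), sign(pb$t[gm]))
  expect_identical(sign(pv$t[gm]), sign(z$dom$p[gm]))
})

test_that("the corrected VASO branch is sign-inverted for activation maps", {
  z <- tiny_zero_noise()
  n2 <- dim(z$pp$vaso$data)[4]
  X <- build_design_matrix(z$tl, n2, z$tl$tr_pair / 2)
  tm_v <- activation_tmaps(z$pp$vaso, X)
  tm_b <- activation_tmaps(z$pp$bold, X)
  gm <- z$geo$labels == TISSUE["GM"]
  # activation positive on both branches under the convention
  expect_true(all(tm_v$t_stim[gm] > 0))
  expect_true(all(tm_b$t_stim[gm] > 0))
  # without the inversion the CBV response is a signal decrease
  raw <- activation_tmaps(z$pp$vaso, X, invert = FALSE)
  expect_true(all(raw$t_stim[gm] < 0))
})
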