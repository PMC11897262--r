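#' Build the unconvolved GLM design matrix
#'
#' Columns: DC offset, zero-mean linear ramp, and one unconvolved boxcar per
#' stimulus condition (RF0, RF4), sampled at the series' effective sampling
#' interval. No haemodynamic convolution is applied — CBV and BOLD do not
#' share a response profile, so the boxcar reflects the stimulus timing
#' only. Separate condition boxcars keep both stimulus-vs-baseline and
#' difference contrasts expressible.
#'
#' @param timeline A [build_block_timeline()] object.
#' @param n_timepoints Number of samples in the (possibly upsampled) series.
#' @param dt Effective sampling interval, s.
#' @return Numeric matrix `n_timepoints` x 4 with columns
#'   `dc, ramp, rf0, rf4` and attributes `dt` and `times`.
#' @export
build_design_matrix <- function(timeline, n_timepoints, dt) {
  stopifnot(inherits(timeline, "block_timeline"), n_timepoints >= 2, dt > 0)
  run_dur <- n_volumes(timeline) * timeline$tr_pair
  if (abs(n_timepoints * dt - run_dur) > timeline$tr_pair + 1e-6)
    stop("n_timepoints * dt inconsistent with the timeline duration")
  times <- (seq_len(n_timepoints) - 1) * dt
  eps <- 1e-6
  box <- function(cond) {
    bl <- timeline$blocks[timeline$blocks$condition == cond, , drop = FALSE]
    on <- rep(FALSE, n_timepoints)
    for (i in seq_len(nrow(bl)))
      on <- on | (times >= bl$onset_s[i] - eps &
                    times < bl$offset_s[i] - eps)
    as.numeric(on)
  }
  rf0 <- box("RF0")
  rf4 <- box("RF4")
  if (any(rf0 + rf4 > 1)) stop("condition boxcars overlap")
  ramp <- seq(-0.5, 0.5, length.out = n_timepoints)
  X <- cbind(dc = 1, ramp = ramp - mean(ramp), rf0 = rf0, rf4 = rf4)
  attr(X, "dt") <- dt
  attr(X, "times") <- times
  X
}

#' Fit the voxelwise GLM by ordinary least squares
#'
#' @param y A [contrast_series()] or a voxels-by-time numeric matrix.
#' @param X Design matrix from [build_design_matrix()] (must have full
#'   column rank).
#' @return An object of class `glm_result`: per-voxel coefficients `beta`
#'   (voxels x columns), residual variance `sigma2`, degrees of freedom
#'   `df`, and `(X'X)^-1`.
#' @export
fit_glm <- function(y, X) {
  grid_dim <- NULL
  if (inherits(y, "contrast_series")) {
    grid_dim <- dim(y$data)[1:3]
    y <- .series_matrix(y)
  }
  stopifnot(is.matrix(y), nrow(X) == ncol(y))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop("non-positive residual degrees of freedom")
  xtx_inv <- solve(crossprod(X))
  beta <- y %*% X %*% xtx_inv          # voxels x p
  resid <- y - tcrossprod(beta, X)
  sigma2 <- rowSums(resid^2) / df
  structure(list(beta = beta, sigma2 = sigma2, df = df, xtx_inv = xtx_inv,
                 columns = colnames(X), grid_dim = grid_dim),
            class = "glm_result")
}

#' Contrast t statistics from a fitted GLM
#'
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` per voxel. Zero-variance
#' voxels give `sign(c'beta) * Inf` (0 where the numerator is 0).
#'
#' @param fit A [fit_glm()] result.
#' @param contrast Numeric contrast vector over the design columns.
#' @return Vector (or 3D array, when the fit came from a series) of t
#'   values.
#' @export
glm_tmap <- function(fit, contrast) {
  stopifnot(inherits(fit, "glm_result"),
            length(contrast) == ncol(fit$beta))
  num <- drop(fit$beta %*% contrast)
  qf <- drop(crossprod(contrast, fit$xtx_inv %*% contrast))
  se <- sqrt(fit$sigma2 * qf)
  t <- ifelse(se > 0, num / se, sign(num) * Inf)
  t[se == 0 & num == 0] <- 0
  if (!is.null(fit$grid_dim)) t <- array(t, fit$grid_dim)
  t
}

#' Stimulus-versus-baseline and per-condition t maps
#'
#' Fits the GLM and returns t maps for RF0 vs baseline, RF4 vs baseline,
#' and both stimuli vs baseline. On the `vaso_corrected` branch activation
#' is a signal *decrease* (blood nulling), so t values are sign-inverted to
#' the convention positive = activation.
#'
#' @param cs A [contrast_series()].
#' @param X Design matrix matching the series length.
#' @param invert Override the automatic VASO sign inversion.
#' @return List of 3D arrays `t_rf0`, `t_rf4`, `t_stim` and the `glm_result`
#'   as `fit`.
#' @export
activation_tmaps <- function(cs, X, invert = NULL) {
  stopifnot(inherits(cs, "contrast_series"))
  if (is.null(invert)) invert <- cs$tag == "vaso_corrected"
  fit <- fit_glm(cs, X)
  sgn <- if (invert) -1 else 1
  list(t_rf0 = sgn * glm_tmap(fit, c(0, 0, 1, 0)),
       t_rf4 = sgn * glm_tmap(fit, c(0, 0, 0, 1)),
       t_stim = sgn * glm_tmap(fit, c(0, 0, 0.5, 0.5)),
       fit = fit)
}

#' Per-voxel, per-block peak response amplitudes
#'
#' For each stimulus block the amplitude is the mean signal within the peak
#' window (after the ~6 s haemodynamic rise, by default 5.22-31.32 s from
#' block onset) minus the mean over the baseline window (the final
#' `baseline_dur` seconds of the preceding rest period). `vaso_corrected`
#' series are sign-inverted first so that positive amplitude = activation.
#'
#' @param cs A [contrast_series()].
#' @param timeline The run's [build_block_timeline()].
#' @param peak_window Length-2 window relative to block onset, s; must lie
#'   within the block.
#' @param baseline_dur Baseline window length, s; must fit in the preceding
#'   rest period.
#' @return Object of class `block_table`: `amplitude` (voxels x blocks
#'   matrix), `condition` per block, the source grid dimensions and tag.
#' @export
block_peak_responses <- function(cs, timeline, peak_window = c(5.22, 31.32),
                                 baseline_dur = 10.44) {
  stopifnot(inherits(cs, "contrast_series"),
            inherits(timeline, "block_timeline"))
  if (peak_window[1] < 0 || peak_window[2] > timeline$block_dur + 1e-6 ||
      peak_window[1] >= peak_window[2])
    stop("peak_window must lie within the stimulus block")
  rest_before <- min(timeline$n_initial_rest * timeline$tr_pair,
                     timeline$block_dur)
  if (baseline_dur <= 0 || baseline_dur > rest_before + 1e-6)
    stop("baseline window overlaps the preceding stimulus block")
  n <- .n_time(cs)
  times <- (seq_len(n) - 1) * cs$dt
  eps <- 1e-6
  m <- .series_matrix(cs)
  if (cs$tag == "vaso_corrected") m <- -m
  blocks <- timeline$blocks
  amp <- matrix(NA_real_, nrow(m), nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    o <- blocks$onset_s[b]
    pk <- times >= o + peak_window[1] - eps & times < o + peak_window[2] - eps
    bs <- times >= o - baseline_dur - eps & times < o - eps
    if (!any(pk) || !any(bs)) stop("analysis windows contain no samples")
    amp[, b] <- rowMeans(m[, pk, drop = FALSE]) -
      rowMeans(m[, bs, drop = FALSE])
  }
  structure(list(amplitude = amp, condition = blocks$condition,
                 grid_dim = dim(cs$data)[1:3], tag = cs$tag),
            class = "block_table")
}

#' Curvature-preference map from block-peak amplitudes
#'
#' Per voxel, a two-sample t statistic comparing RF0-block against
#' RF4-block peak amplitudes; positive t indicates preference for curvature
#' (RF0). Welch's t (unequal variances, Welch-Satterthwaite df) by default;
#' `"pooled"` gives the equal-variance statistic. When both condition
#' variances are zero the statistic is `sign(difference) * Inf` (0 for a
#' zero difference). The map is deliberately un-thresholded.
#'
#' @param block_table A [block_peak_responses()] result with at least two
#'   blocks per condition.
#' @param method `"welch"` or `"pooled"`.
#' @return Object of class `preference_map`: 3D array `t`, the method, the
#'   source contrast tag, and per-voxel degrees of freedom `df`.
#' @export
preference_map <- function(block_table, method = c("welch", "pooled")) {
  stopifnot(inherits(block_table, "block_table"))
  method <- match.arg(method)
  a <- block_table$amplitude
  i0 <- block_table$condition == "RF0"
  i4 <- block_table$condition == "RF4"
  n0 <- sum(i0); n4 <- sum(i4)
  if (n0 < 2 || n4 < 2) stop("need at least two blocks per condition")
  x0 <- a[, i0, drop = FALSE]
  x4 <- a[, i4, drop = FALSE]
  m0 <- rowMeans(x0); m4 <- rowMeans(x4)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  v4 <- rowSums((x4 - m4)^2) / (n4 - 1)
  diff <- m0 - m4
  if (method == "welch") {
    se2 <- v0 / n0 + v4 / n4
    df <- se2^2 / (v0^2 / (n0^2 * (n0 - 1)) + v4^2 / (n4^2 * (n4 - 1)))
  } else {
    sp2 <- ((n0 - 1) * v0 + (n4 - 1) * v4) / (n0 + n4 - 2)
    se2 <- sp2 * (1 / n0 + 1 / n4)
    df <- rep(n0 + n4 - 2, length(diff))
  }
  t <- ifelse(se2 > 0, diff / sqrt(se2), sign(diff) * Inf)
  t[se2 == 0 & diff == 0] <- 0
  structure(list(t = array(t, block_table$grid_dim), method = method,
                 contrast_tag = block_table$tag,
                 df = array(df, block_table$grid_dim)),
            class = "preference_map")
}

#' @export
print.preference_map <- function(x, ...) {
  cat(sprintf("preference_map [%s, %s t]: %s grid, %d voxels with t > 0\n",
              x$contrast_tag, x$method,
              paste(dim(x$t), collapse = "x"), sum(x$t > 0, na.rm = TRUE)))
  invisible(x)
}
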