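#' Construct a contrast series
#'
#' A `contrast_series` wraps a 4D array with a contrast tag, the effective
#' sampling interval, and an append-only log of applied preprocessing steps.
#' The log enforces the preprocessing order: separate -> replace_nonsteady ->
#' temporal_upsample -> align_nulled -> boco_correct -> average_runs.
#'
#' @param data 4D numeric array (`x, y, z, t`).
#' @param tag One of `"nulled"`, `"not_nulled"`, `"vaso_corrected"`,
#'   `"bold"`.
#' @param dt Effective sampling interval, s.
#' @param log Character vector of applied steps.
#' @return An object of class `contrast_series`.
#' @export
contrast_series <- function(data, tag, dt, log = character()) {
  stopifnot(is.array(data), length(dim(data)) == 4L, dt > 0)
  tag <- match.arg(tag, c("nulled", "not_nulled", "vaso_corrected", "bold"))
  structure(list(data = data, tag = tag, dt = dt, log = log),
            class = "contrast_series")
}

#' @export
print.contrast_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("contrast_series [%s]: %dx%dx%d x %d volumes, dt %.4g s\n",
              x$tag, d[1], d[2], d[3], d[4]),
      sprintf("  steps: %s\n",
              if (length(x$log)) paste(x$log, collapse = " -> ") else "none"))
  invisible(x)
}

.n_time <- function(cs) dim(cs$data)[4]

.series_matrix <- function(cs) {
  d <- dim(cs$data)
  matrix(cs$data, prod(d[1:3]), d[4])
}

.matrix_series <- function(cs, m, dt = cs$dt) {
  d <- dim(cs$data)
  cs$data <- array(m, c(d[1:3], ncol(m)))
  cs$dt <- dt
  cs
}

.check_steps <- function(cs, require = character(), forbid = character(),
                         op = "step") {
  miss <- setdiff(require, cs$log)
  if (length(miss))
    stop(sprintf("%s requires prior step(s): %s", op,
                 paste(miss, collapse = ", ")))
  dup <- intersect(forbid, cs$log)
  if (length(dup))
    stop(sprintf("%s already applied: %s", op, paste(dup, collapse = ", ")))
  invisible(TRUE)
}

#' Separate an interleaved acquisition into its two contrasts
#'
#' @param series An [simulate_acquisition()] `interleaved_series` (or a list
#'   with `nulled`/`not_nulled` 4D arrays and `tr_pair`).
#' @return List with elements `nulled` and `not_nulled`, each a
#'   [contrast_series()] sampled at the pair TR.
#' @export
separate_contrasts <- function(series) {
  if (is.null(series$nulled) || is.null(series$not_nulled))
    stop("input must carry nulled and not_nulled arrays")
  if (!identical(dim(series$nulled), dim(series$not_nulled)))
    stop("nulled and not_nulled grids mismatch")
  if (length(dim(series$nulled)) != 4L || dim(series$nulled)[4] < 1)
    stop("empty series")
  list(
    nulled = contrast_series(series$nulled, "nulled", series$tr_pair,
                             log = "separate"),
    not_nulled = contrast_series(series$not_nulled, "not_nulled",
                                 series$tr_pair, log = "separate")
  )
}

#' Replace non-steady-state volumes
#'
#' The first `n_replace` volumes (acquired before the longitudinal
#' magnetisation reaches steady state; no dummy scans are played out by the
#' sequence) are replaced by a copy of the `(n_replace + 1)`-th volume.
#'
#' @param cs A [contrast_series()].
#' @param n_replace Number of leading volumes to replace (default 4).
#' @return The modified series with `"replace_nonsteady"` logged.
#' @export
replace_nonsteady <- function(cs, n_replace = 4L) {
  stopifnot(inherits(cs, "contrast_series"), n_replace >= 0)
  .check_steps(cs, require = "separate", forbid = "replace_nonsteady",
               op = "replace_nonsteady")
  n <- .n_time(cs)
  if (n <= n_replace) stop("series too short for non-steady-state replacement")
  if (n_replace > 0) {
    for (k in seq_len(n_replace))
      cs$data[, , , k] <- cs$data[, , , n_replace + 1L]
  }
  cs$log <- c(cs$log, "replace_nonsteady")
  cs
}

#' Temporally upsample a contrast series
#'
#' Interpolates the series onto a grid `factor` times finer (restoring the
#' effective sampling rate of the interleaved acquisition for `factor = 2`).
#' `"linear"` interpolation inserts exact midpoints and is the default — it
#' matches the piecewise-linear contamination model under which dynamic
#' division is an exact inverse; `"cubic"` uses a natural cubic spline
#' (both preserve constants and linear ramps exactly). Beyond the final
#' sample the last value is carried forward.
#'
#' @param cs A [contrast_series()].
#' @param factor Integer upsampling factor (>= 1).
#' @param method `"linear"` or `"cubic"`.
#' @return Series of length `factor * n` with `dt` divided by `factor`.
#' @export
temporal_upsample <- function(cs, factor = 2L, method = c("linear", "cubic")) {
  stopifnot(inherits(cs, "contrast_series"))
  method <- match.arg(method)
  if (length(factor) != 1L || factor < 1 || abs(factor - round(factor)) > 0)
    stop("factor must be an integer >= 1")
  .check_steps(cs, require = "replace_nonsteady", forbid = "upsample",
               op = "temporal_upsample")
  factor <- as.integer(factor)
  m <- .series_matrix(cs)
  n <- ncol(m)
  if (factor > 1L) {
    pos <- (seq_len(n * factor) - 1) / factor + 1  # in original index units
    if (method == "linear") {
      lo <- pmin(floor(pos), n)
      hi <- pmin(lo + 1L, n)
      w <- pos - lo
      out <- sweep(m[, lo, drop = FALSE], 2, 1 - w, `*`) +
        sweep(m[, hi, drop = FALSE], 2, w, `*`)
    } else {
      out <- t(apply(m, 1, function(y)
        stats::spline(seq_len(n), y, xout = pmin(pos, n), method = "fmm")$y))
    }
    m <- out
  }
  cs <- .matrix_series(cs, m, dt = cs$dt / factor)
  cs$log <- c(cs$log, "upsample")
  cs
}

#' Align the nulled series to the not-nulled timing
#'
#' After upsampling, the first nulled timepoint is duplicated (and the final
#' one dropped) so that sample k of the nulled series is simultaneous with
#' sample k of the not-nulled series: the nulled volume of a pair is read
#' out half a pair-TR after the not-nulled grid origin. Not idempotent; the
#' step log rejects re-application.
#'
#' @param cs A nulled [contrast_series()] that has been upsampled.
#' @return Series of unchanged length with `"align"` logged.
#' @export
align_nulled <- function(cs) {
  stopifnot(inherits(cs, "contrast_series"))
  .check_steps(cs, require = "upsample", forbid = "align", op = "align_nulled")
  n <- .n_time(cs)
  cs$data <- cs$data[, , , c(1L, seq_len(n - 1L)), drop = FALSE]
  cs$log <- c(cs$log, "align")
  cs
}

#' BOLD correction of the nulled series by dynamic division
#'
#' Computes the voxelwise ratio nulled / not-nulled, removing the
#' multiplicative BOLD contamination from the VASO signal. Denominator
#' samples below `guard_eps` times the voxel's temporal mean inherit the
#' voxel's previous ratio (1 for the first volume); the output is clipped to
#' `clip_range`. Voxels whose denominator is identically zero are flagged in
#' the `qc_allzero` attribute.
#'
#' @param nulled Aligned, upsampled nulled [contrast_series()].
#' @param not_nulled Upsampled not-nulled [contrast_series()].
#' @param guard_eps Division guard as a fraction of the voxel temporal mean.
#' @param clip_range Length-2 output clip range (default `c(0, 2)`).
#' @return A `vaso_corrected` [contrast_series()].
#' @export
boco_correct <- function(nulled, not_nulled, guard_eps = 0.05,
                         clip_range = c(0, 2)) {
  stopifnot(inherits(nulled, "contrast_series"),
            inherits(not_nulled, "contrast_series"))
  if (nulled$tag != "nulled" || not_nulled$tag != "not_nulled")
    stop("boco_correct expects a nulled and a not_nulled series")
  .check_steps(nulled, require = c("upsample", "align"), op = "boco_correct")
  .check_steps(not_nulled, require = "upsample", op = "boco_correct")
  if (!identical(dim(nulled$data), dim(not_nulled$data)))
    stop("aligned series must share grid and length")
  num <- .series_matrix(nulled)
  den <- .series_matrix(not_nulled)
  vmean <- rowMeans(den)
  allzero <- vmean == 0
  bad <- sweep(den, 1, pmax(guard_eps * abs(vmean), .Machine$double.xmin),
               `<`)
  ratio <- num / den
  prev <- rep(1, nrow(ratio))
  for (k in seq_len(ncol(ratio))) {
    b <- bad[, k]
    if (any(b)) ratio[b, k] <- prev[b]
    prev <- ratio[, k]
  }
  ratio <- pmin(pmax(ratio, clip_range[1]), clip_range[2])
  out <- .matrix_series(nulled, ratio)
  out$tag <- "vaso_corrected"
  out$log <- c(nulled$log, "boco")
  attr(out, "qc_allzero") <- array(allzero, dim(nulled$data)[1:3])
  out
}

#' Average runs voxelwise
#'
#' @param series_list List of [contrast_series()] with identical grids,
#'   lengths, tags and step logs.
#' @return The voxelwise arithmetic mean series with `"average"` logged.
#' @export
average_runs <- function(series_list) {
  stopifnot(is.list(series_list), length(series_list) >= 1)
  tags <- vapply(series_list, `[[`, "", "tag")
  if (length(unique(tags)) != 1L) stop("cannot average mixed contrast tags")
  dims <- lapply(series_list, function(s) dim(s$data))
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("runs must share grid and length")
  out <- series_list[[1]]
  if (length(series_list) > 1L) {
    acc <- series_list[[1]]$data
    for (s in series_list[-1]) acc <- acc + s$data
    out$data <- acc / length(series_list)
  }
  out$log <- c(out$log, "average")
  out
}

#' Temporal signal-to-noise ratio map
#'
#' Voxelwise temporal mean divided by temporal standard deviation.
#' Zero-variance voxels are set to `Inf` and flagged in the `zero_variance`
#' attribute.
#'
#' @param cs A [contrast_series()] with at least two volumes.
#' @return 3D tSNR array with attribute `zero_variance`.
#' @export
tsnr_map <- function(cs) {
  stopifnot(inherits(cs, "contrast_series"))
  n <- .n_time(cs)
  if (n < 2) stop("tSNR requires at least two volumes")
  m <- .series_matrix(cs)
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (n - 1))
  zero <- sdv == 0
  out <- mu / sdv
  out[zero] <- Inf
  out <- array(out, dim(cs$data)[1:3])
  attr(out, "zero_variance") <- array(zero, dim(cs$data)[1:3])
  out
}

#' Run the full preprocessing chain on one interleaved run
#'
#' Convenience wrapper applying the curvature-mapping preprocessing order:
#' separate contrasts, replace non-steady-state volumes, temporally upsample
#' both series by `factor`, align the nulled series, and divide (BOCO).
#' Motion correction is assumed to have been applied externally.
#'
#' @param series An `interleaved_series`.
#' @param n_replace Non-steady-state volumes to replace.
#' @param factor Temporal upsampling factor.
#' @param method Interpolation method for upsampling.
#' @param guard_eps,clip_range Passed to [boco_correct()].
#' @return List with `vaso` (corrected series) and `bold` (upsampled
#'   not-nulled series, tagged `bold`).
#' @export
preprocess_run <- function(series, n_replace = 4L, factor = 2L,
                           method = "linear", guard_eps = 0.05,
                           clip_range = c(0, 2)) {
  sep <- separate_contrasts(series)
  nul <- temporal_upsample(replace_nonsteady(sep$nulled, n_replace),
                           factor, method)
  nn <- temporal_upsample(replace_nonsteady(sep$not_nulled, n_replace),
                          factor, method)
  vaso <- boco_correct(align_nulled(nul), nn, guard_eps, clip_range)
  bold <- nn
  bold$tag <- "bold"
  list(vaso = vaso, bold = bold)
}
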