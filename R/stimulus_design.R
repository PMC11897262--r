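#' Radial-frequency pattern specification
#'
#' A radial-frequency (RF) pattern is a closed contour obtained by sinusoidal
#' modulation of a circle's radius, r(theta) = r0 * (1 + A * sin(omega * theta
#' + phase)). `omega = 0` (or `A = 0`) gives a circle (pure curvature, "RF0");
#' `omega = 4` gives a rounded square ("RF4") whose sides are straight
#' contours.
#'
#' @param omega Radial frequency in cycles per revolution (non-negative
#'   integer).
#' @param amplitude Modulation amplitude A (dimensionless, `0 <= A < 1`;
#'   `A >= 1` would self-intersect).
#' @param phase Phase in radians; rotates the pattern.
#' @param r0 Base radius in degrees of visual angle (> 0).
#' @param max_extent Maximum radial extent of the rendered pattern in degrees
#'   (default 9).
#' @return An object of class `rf_pattern_spec`.
#' @export
rf_pattern_spec <- function(omega = 0, amplitude = 0, phase = 0, r0 = 9,
                            max_extent = 9) {
  stopifnot(length(omega) == 1L, length(amplitude) == 1L, length(phase) == 1L,
            length(r0) == 1L, length(max_extent) == 1L)
  if (!is.finite(omega) || omega < 0 || abs(omega - round(omega)) > 1e-9)
    stop("omega must be a non-negative integer")
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be non-negative")
  if (amplitude >= 1)
    stop("amplitude >= 1 yields a self-intersecting contour")
  if (r0 <= 0) stop("r0 must be positive")
  if (max_extent <= 0) stop("max_extent must be positive")
  structure(
    list(omega = as.integer(round(omega)), amplitude = amplitude,
         phase = phase, r0 = r0, max_extent = max_extent),
    class = "rf_pattern_spec"
  )
}

#' Radius of a radial-frequency contour
#'
#' @param theta Angle(s) around the contour, radians.
#' @param spec An [rf_pattern_spec()].
#' @return Radius in degrees of visual angle, same length as `theta`.
#'   2*pi/omega-periodic in theta for integer omega > 0.
#' @export
rf_radius <- function(theta, spec) {
  stopifnot(inherits(spec, "rf_pattern_spec"))
  spec$r0 * (1 + spec$amplitude * sin(spec$omega * theta + spec$phase))
}

#' Render a concentric radial-frequency stimulus image
#'
#' Pixels are assigned alternating contrast (+1/-1) between successive scaled
#' copies of the RF contour out to `max_extent`; the outermost contour is
#' scaled so that its maximum radius equals `max_extent`. Background beyond
#' the pattern is 0 (mean gray). `polarity = -1` returns the contrast-reversed
#' image (pixelwise negation inside the pattern), used to alternate contrast
#' during presentation and minimise adaptation.
#'
#' @param spec An [rf_pattern_spec()].
#' @param image_size Image width/height in pixels (square canvas).
#' @param deg_per_pixel Degrees of visual angle per pixel. Default scales the
#'   canvas to cover exactly +/- `max_extent`.
#' @param polarity `+1` or `-1` contrast polarity.
#' @param n_bands Number of concentric contrast bands inside the contour.
#' @return `image_size` x `image_size` matrix with values in `{-1, 0, 1}`.
#' @export
render_rf_stimulus <- function(spec, image_size = 256, deg_per_pixel = NULL,
                               polarity = 1, n_bands = 8) {
  stopifnot(inherits(spec, "rf_pattern_spec"))
  if (length(image_size) != 1L || !is.finite(image_size) || image_size < 1)
    stop("image_size must be a positive integer")
  image_size <- as.integer(image_size)
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  if (is.null(deg_per_pixel)) deg_per_pixel <- 2 * spec$max_extent / image_size

  centre <- (image_size + 1) / 2
  coord <- (seq_len(image_size) - centre) * deg_per_pixel
  x <- matrix(coord, image_size, image_size)
  y <- t(x)
  rho <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  # shape function normalised so max_theta s(theta) = 1
  s <- (1 + spec$amplitude * sin(spec$omega * theta + spec$phase)) /
    (1 + spec$amplitude)
  q <- rho / (spec$max_extent * s)
  band <- floor(q * n_bands)
  img <- ifelse(q < 1, polarity * (1 - 2 * (band %% 2)), 0)
  img[!is.finite(img)] <- 0
  img
}

#' Block-design timeline for the curvature-mapping runs
#'
#' One "volume" here is an interleaved nulled/not-nulled volume *pair*
#' acquired in `tr_pair` seconds. A run is `n_initial_rest` rest pairs
#' followed by `n_blocks` repetitions of (stimulus block, rest block), with
#' the stimulus condition alternating through `condition_order`.
#'
#' @param tr_pair Volume-pair repetition time, seconds.
#' @param n_initial_rest Initial rest volume pairs (33 pairs = 86.13 s at the
#'   default TR).
#' @param block_dur Stimulus/rest block duration, seconds; must be an integer
#'   multiple of `tr_pair`.
#' @param n_blocks Number of stimulus blocks per run.
#' @param condition_order Conditions cycled across stimulus blocks.
#' @param reversal_interval Contrast-reversal period within a stimulus block,
#'   seconds.
#' @param trailing_rest Trailing rest volume pairs after the final block.
#' @return An object of class `block_timeline`: a list with `volumes`
#'   (per-pair `volume_index`, `time_s`, `condition`), `blocks` (per-block
#'   condition and onset/offset), and the design parameters.
#' @export
build_block_timeline <- function(tr_pair = 2.610, n_initial_rest = 33,
                                 block_dur = 31.32, n_blocks = 14,
                                 condition_order = c("RF0", "RF4"),
                                 reversal_interval = 0.522,
                                 trailing_rest = 0) {
  stopifnot(tr_pair > 0, block_dur > 0, n_blocks >= 1, n_initial_rest >= 0)
  vols_per_block <- block_dur / tr_pair
  if (abs(vols_per_block - round(vols_per_block)) > 1e-6)
    stop("block_dur must be an integer multiple of tr_pair")
  vols_per_block <- as.integer(round(vols_per_block))
  conditions <- rep_len(condition_order, n_blocks)

  labels <- rep("rest", n_initial_rest)
  onsets <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    onsets[b] <- length(labels) * tr_pair
    labels <- c(labels, rep(conditions[b], vols_per_block),
                rep("rest", vols_per_block))
  }
  labels <- c(labels, rep("rest", trailing_rest))
  n_vol <- length(labels)

  volumes <- data.frame(
    volume_index = seq_len(n_vol),
    time_s = (seq_len(n_vol) - 1) * tr_pair,
    condition = labels,
    stringsAsFactors = FALSE
  )
  blocks <- data.frame(
    block = seq_len(n_blocks),
    condition = conditions,
    onset_s = onsets,
    offset_s = onsets + block_dur,
    stringsAsFactors = FALSE
  )
  structure(
    list(volumes = volumes, blocks = blocks, tr_pair = tr_pair,
         n_initial_rest = n_initial_rest, block_dur = block_dur,
         n_blocks = n_blocks, reversal_interval = reversal_interval,
         trailing_rest = trailing_rest),
    class = "block_timeline"
  )
}

#' @export
print.block_timeline <- function(x, ...) {
  cat(sprintf(
    "block_timeline: %d volume pairs (TR %.3f s), %d blocks of %.2f s, %s\n",
    nrow(x$volumes), x$tr_pair, x$n_blocks, x$block_dur,
    paste(unique(x$blocks$condition), collapse = "/")
  ))
  invisible(x)
}

#' Number of volume pairs in a timeline
#' @param timeline A [build_block_timeline()] object.
#' @return Integer count of volume pairs.
#' @export
n_volumes <- function(timeline) {
  stopifnot(inherits(timeline, "block_timeline"))
  nrow(timeline$volumes)
}

#' Total trial count across an experiment
#'
#' @param n_participants,n_runs,n_blocks Positive integers.
#' @return `n_participants * n_runs * n_blocks`.
#' @export
count_trials <- function(n_participants, n_runs, n_blocks) {
  stopifnot(n_participants >= 1, n_runs >= 1, n_blocks >= 1)
  as.integer(n_participants) * as.integer(n_runs) * as.integer(n_blocks)
}

#' Write a timeline as a three-column TSV
#' @param timeline A [build_block_timeline()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeline_tsv <- function(timeline, path) {
  stopifnot(inherits(timeline, "block_timeline"))
  utils::write.table(timeline$volumes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a rendered stimulus to a grayscale PNG
#' @param img Matrix in `[-1, 1]` from [render_rf_stimulus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(img, path) {
  png::writePNG((img + 1) / 2, path)
  invisible(path)
}
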