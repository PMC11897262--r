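#' Parametric cortical patch geometry
#'
#' Builds a voxelised cortical sheet with WM/GM/CSF tissue labels, equidistant
#' cortical depth `d` in `[0, 1]` (0 = WM boundary, 1 = CSF boundary),
#' analytic flat coordinates `(u, v)` in mm, and local mid-surface curvature
#' `kappa` (1/mm) for every gray-matter column. `flat_slab` is a plane
#' (`kappa = 0` everywhere); `folded_sheet` folds the mid-surface
#' sinusoidally along x, with depth taken along the level sets of
#' `z - A*sin(2*pi*x/lambda)` and `u` the arc length of the mid-surface, so
#' flat coordinates and depths remain closed-form.
#'
#' @param nx,ny,nz Grid dimensions (voxels).
#' @param voxel_mm Isotropic voxel size, mm (default 1.2, the nominal
#'   acquisition resolution).
#' @param thickness_mm Cortical (GM) thickness, mm; must be at least two
#'   voxels for depth sampling to be non-degenerate.
#' @param wm_mm Thickness of the WM compartment below the GM sheet, mm.
#' @param kind `"flat_slab"` or `"folded_sheet"`.
#' @param fold_amplitude_mm,fold_period_mm Fold amplitude and period along x
#'   (folded sheet only).
#' @return An object of class `patch_geometry`: arrays `labels` (1 = WM,
#'   2 = GM, 3 = CSF), `depth` (NA outside GM), `u`, `v`, `kappa`, logical
#'   `csf_adjacent` (first CSF voxel above each column, where draining-vein
#'   signal persists), plus grid metadata.
#' @export
make_patch_geometry <- function(nx = 48, ny = 16, nz = 10, voxel_mm = 1.2,
                                thickness_mm = 3.6, wm_mm = 3.6,
                                kind = c("flat_slab", "folded_sheet"),
                                fold_amplitude_mm = 1.2,
                                fold_period_mm = 19.2) {
  kind <- match.arg(kind)
  stopifnot(nx >= 1, ny >= 1, nz >= 2, voxel_mm > 0, wm_mm >= 0)
  if (thickness_mm < 2 * voxel_mm)
    stop("thickness_mm below two voxels: depth sampling degenerate")

  xc <- (seq_len(nx) - 0.5) * voxel_mm
  yc <- (seq_len(ny) - 0.5) * voxel_mm
  zc <- (seq_len(nz) - 0.5) * voxel_mm
  amp <- if (kind == "flat_slab") 0 else fold_amplitude_mm
  k_fold <- 2 * pi / fold_period_mm

  # signed distance above the WM/GM boundary surface, per (x, z)
  offset_x <- amp * sin(k_fold * xc)              # shift of the sheet at x
  tmat <- outer(-offset_x, zc, function(o, z) z + o) - wm_mm  # nx x nz

  labels_xz <- matrix(2L, nx, nz)
  labels_xz[tmat < 0] <- 1L
  labels_xz[tmat >= thickness_mm] <- 3L
  depth_xz <- tmat / thickness_mm
  depth_xz[labels_xz != 2L] <- NA_real_
  csf_adj_xz <- tmat >= thickness_mm & tmat < thickness_mm + voxel_mm

  # mid-surface curvature, positive where GM is convex toward CSF
  if (amp == 0) {
    kappa_x <- rep(0, nx)
    u_x <- xc
  } else {
    zp <- amp * k_fold * cos(k_fold * xc)
    zpp <- -amp * k_fold^2 * sin(k_fold * xc)
    kappa_x <- -zpp / (1 + zp^2)^1.5
    # arc length of the mid-surface (deterministic fine-grid quadrature)
    xf <- seq(0, max(xc), by = voxel_mm / 50)
    integrand <- sqrt(1 + (amp * k_fold * cos(k_fold * xf))^2)
    cumlen <- c(0, cumsum((integrand[-1] + integrand[-length(xf)]) / 2 *
                            diff(xf)))
    u_x <- stats::approx(xf, cumlen, xout = xc)$y
  }

  expand_xz <- function(m) aperm(array(m, c(nx, nz, ny)), c(1, 3, 2))
  labels <- expand_xz(labels_xz)
  depth <- expand_xz(depth_xz)
  csf_adjacent <- expand_xz(csf_adj_xz) > 0
  kappa <- array(rep(kappa_x, ny * nz), c(nx, ny, nz))
  kappa[labels != 2L] <- NA_real_
  u <- array(rep(u_x, ny * nz), c(nx, ny, nz))
  v <- array(rep(rep(yc, each = nx), nz), c(nx, ny, nz))

  structure(
    list(dim = c(nx, ny, nz), voxel_mm = voxel_mm,
         thickness_mm = thickness_mm, wm_mm = wm_mm, kind = kind,
         fold_amplitude_mm = amp, fold_period_mm = fold_period_mm,
         labels = labels, depth = depth, u = u, v = v, kappa = kappa,
         csf_adjacent = csf_adjacent),
    class = "patch_geometry"
  )
}

#' Tissue label codes
#' @format Named integer vector mapping `WM`, `GM`, `CSF` to label codes.
#' @export
TISSUE <- c(WM = 1L, GM = 2L, CSF = 3L)

#' Ground-truth columnar curvature-preference domains
#'
#' Assigns each cortical column a preference `p in [-1, 1]` (+1 = prefers
#' curved contours/RF0, -1 = prefers straight contours/RF4), constant across
#' depth (columnar by construction). `stripes` gives a binary square-wave
#' pattern `sign(sin(2*pi*u/lambda))`, `stripes_graded` the graded sinusoid,
#' and `blobs` the sign of band-pass-filtered Gaussian noise at scale
#' `lambda`.
#'
#' @param geometry A [make_patch_geometry()] object.
#' @param pattern `"stripes"`, `"stripes_graded"` or `"blobs"`.
#' @param lambda_mm Characteristic domain period, mm. Must exceed the voxel
#'   size; a warning is raised below two voxels (under-sampled).
#' @param seed RNG seed (blobs only).
#' @return An object of class `domain_map` with 3D array `p` (defined on
#'   every voxel of a column so that vein-drained CSF voxels inherit the
#'   column preference), the pattern kind, `lambda_mm` and `seed`.
#' @export
make_domain_map <- function(geometry,
                            pattern = c("stripes", "stripes_graded", "blobs"),
                            lambda_mm = 1.6, seed = 1L) {
  stopifnot(inherits(geometry, "patch_geometry"))
  pattern <- match.arg(pattern)
  if (lambda_mm <= geometry$voxel_mm)
    stop("lambda_mm must exceed the voxel size")
  if (lambda_mm < 2 * geometry$voxel_mm)
    warning("lambda_mm below two voxels: domain pattern is under-sampled")

  d <- geometry$dim
  if (pattern %in% c("stripes", "stripes_graded")) {
    g <- sin(2 * pi * geometry$u / lambda_mm)
    p <- if (pattern == "stripes") sign(g) else g
  } else {
    nx <- d[1]; ny <- d[2]
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    noise <- matrix(stats::rnorm(nx * ny), nx, ny)
    narrow <- .gauss_smooth2d(noise, lambda_mm / 4 / geometry$voxel_mm)
    wide <- .gauss_smooth2d(noise, lambda_mm / geometry$voxel_mm)
    bp <- narrow - wide
    p2 <- sign(bp - mean(bp))
    p <- array(rep(p2, d[3]), d)
  }
  structure(
    list(p = p, pattern = pattern, lambda_mm = lambda_mm,
         seed = as.integer(seed)),
    class = "domain_map"
  )
}

# separable Gaussian smoothing with reflecting boundaries
.gauss_smooth2d <- function(m, sigma_vox) {
  if (sigma_vox <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_vox))
  kern <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  kern <- kern / sum(kern)
  smooth_lines <- function(mat) {  # smooth along rows of mat
    n <- nrow(mat)
    idx <- seq_len(n)
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(kern)) {
      shift <- j - half - 1L
      src <- pmin(pmax(idx + shift, 1L), n)
      out <- out + kern[j] * mat[src, , drop = FALSE]
    }
    out
  }
  t(smooth_lines(t(smooth_lines(m))))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Vascular responsiveness and venous weighting maps
#'
#' Microvascular responsiveness `m` drives the CBV (VASO) response and is
#' nonzero only in gray matter. The venous weight `w_vein` scales the BOLD
#' response; it increases linearly from `w_min` at the WM boundary to 1 at
#' the CSF surface, and persists (amplified) into the first CSF voxel above
#' each column, emulating surface draining veins.
#'
#' @param geometry A [make_patch_geometry()] object.
#' @param w_min Venous weight at the WM boundary.
#' @param csf_weight Venous weight assigned to CSF-adjacent voxels.
#' @param micro Microvascular responsiveness within GM.
#' @return An object of class `vascular_map` with arrays `m` and `w_vein`.
#' @export
make_vascular_map <- function(geometry, w_min = 0.3, csf_weight = 1.2,
                              micro = 1) {
  stopifnot(inherits(geometry, "patch_geometry"),
            w_min >= 0, w_min <= 1, csf_weight >= 0, micro >= 0)
  gm <- geometry$labels == TISSUE["GM"]
  m <- array(0, geometry$dim)
  m[gm] <- micro
  w <- array(0, geometry$dim)
  w[gm] <- w_min + (1 - w_min) * geometry$depth[gm]
  w[geometry$csf_adjacent] <- csf_weight
  structure(list(m = m, w_vein = w, w_min = w_min, csf_weight = csf_weight),
            class = "vascular_map")
}

#' Haemodynamic block-response parameters
#'
#' @param onset_delay Response onset delay after stimulus onset, s.
#' @param time_to_peak Time from stimulus onset to response peak, s
#'   (default 6).
#' @param plateau Plateau level relative to the peak (`0..1`).
#' @param plateau_tau Time constant of the peak-to-plateau decay, s.
#' @param fall_time Return-to-baseline duration after stimulus offset, s
#'   (BOLD).
#' @param cbv_fall_lag Extra return-to-baseline duration for the CBV
#'   response, s (delayed vascular compliance).
#' @return An object of class `hemo_params`.
#' @export
hemo_params <- function(onset_delay = 0.5, time_to_peak = 6, plateau = 0.8,
                        plateau_tau = 3, fall_time = 6, cbv_fall_lag = 4) {
  stopifnot(onset_delay >= 0, time_to_peak > onset_delay,
            plateau >= 0, plateau <= 1, plateau_tau > 0,
            fall_time > 0, cbv_fall_lag >= 0)
  structure(list(onset_delay = onset_delay, time_to_peak = time_to_peak,
                 plateau = plateau, plateau_tau = plateau_tau,
                 fall_time = fall_time, cbv_fall_lag = cbv_fall_lag),
            class = "hemo_params")
}

#' Model haemodynamic block response
#'
#' Piecewise-smooth response to a sustained stimulus block: zero before
#' `onset + onset_delay`, raised-cosine rise peaking (normalised to 1)
#' exactly at `onset + time_to_peak`, exponential settling onto the plateau
#' until stimulus offset, then a raised-cosine return to baseline. The CBV
#' variant returns to baseline more slowly (`fall_time + cbv_fall_lag`),
#' modelling delayed vascular compliance; both variants peak at the same
#' time.
#'
#' @param t Time grid, s (increasing).
#' @param onset Stimulus onset, s.
#' @param duration Stimulus duration, s (> 0).
#' @param params A [hemo_params()] object.
#' @param contrast `"CBV"` or `"BOLD"`.
#' @return Response fraction in `[0, 1]` at each `t`.
#' @export
hemodynamic_response <- function(t, onset, duration, params = hemo_params(),
                                 contrast = c("CBV", "BOLD")) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(params, "hemo_params"))
  if (duration <= 0) stop("duration must be positive")
  if (is.unsorted(t)) stop("t must be increasing")
  s <- t - onset
  delay <- params$onset_delay
  ttp <- params$time_to_peak
  fall <- params$fall_time + if (contrast == "CBV") params$cbv_fall_lag else 0

  r <- numeric(length(t))
  rise <- s >= delay & s <= ttp
  r[rise] <- 0.5 * (1 - cos(pi * (s[rise] - delay) / (ttp - delay)))
  sustain <- s > ttp & s <= duration
  r[sustain] <- params$plateau +
    (1 - params$plateau) * exp(-(s[sustain] - ttp) / params$plateau_tau)
  level_off <- params$plateau +
    (1 - params$plateau) * exp(-(duration - ttp) / params$plateau_tau)
  off <- s > duration & s < duration + fall
  r[off] <- level_off * 0.5 * (1 + cos(pi * (s[off] - duration) / fall))
  r
}

#' Thermal-noise calibration against a tSNR target
#'
#' For a single constant-mean series of level `S0`, `sigma = S0 / target`
#' yields temporal SNR `target`. For the BOLD-corrected VASO branch
#' (`series = "boco"`) the dynamic division of two independently noisy
#' series doubles the noise variance of the ratio, so the calibrated sigma
#' is `S0 / (target * sqrt(2))`.
#'
#' @param S0 Baseline signal level (arbitrary units).
#' @param target Target temporal SNR (> 0).
#' @param series `"raw"` for a single series, `"boco"` for the
#'   division-corrected VASO branch.
#' @return Gaussian noise standard deviation.
#' @export
calibrate_noise <- function(S0, target, series = c("raw", "boco")) {
  series <- match.arg(series)
  stopifnot(S0 > 0, target > 0)
  sigma <- S0 / target
  if (series == "boco") sigma <- sigma / sqrt(2)
  sigma
}

#' Simulate an interleaved nulled/not-nulled acquisition
#'
#' For voxel x at volume-pair i, the condition drive is the haemodynamic
#' response scaled by the column's preference match: RF0 blocks drive
#' `(1 + p)/2`, RF4 blocks `(1 - p)/2`. The not-nulled (BOLD) signal is
#' `S0 * (1 + dbold * w_vein * D_BOLD)` sampled at the pair time; the nulled
#' signal carries the CBV response `1 - dcbv * m * D_CBV` (a signal
#' *decrease* on activation — blood nulling) multiplied by BOLD
#' contamination. The nulled volume is acquired mid-way between consecutive
#' not-nulled readouts, so its BOLD contamination factor is the mean of the
#' two bracketing not-nulled factors: under this piecewise-linear
#' contamination model the dynamic-division correction in the preprocessing
#' chain removes BOLD contamination exactly (see the methods vignette).
#' Optional shared multiplicative linear drift exercises the GLM ramp
#' regressor; independent Gaussian thermal noise of sd `noise_sigma` is
#' added to both series.
#'
#' @param geometry A [make_patch_geometry()] object.
#' @param domains A [make_domain_map()] object.
#' @param vasc A [make_vascular_map()] object.
#' @param timeline A [build_block_timeline()] object.
#' @param hemo A [hemo_params()] object.
#' @param noise_sigma Thermal noise sd (same units as `s0`).
#' @param amplitudes Named vector `c(cbv = , bold = )`: maximal relative
#'   signal changes, each in `[0, 0.5]`.
#' @param s0 Named baseline signal levels `c(wm = , gm = , csf = )`.
#' @param drift Relative amplitude of a shared linear drift across the run.
#' @param seed RNG seed; output is bit-reproducible given the seed.
#' @param run_id Run identifier carried in the output.
#' @return An object of class `interleaved_series`: 4D arrays `nulled` and
#'   `not_nulled` (`x, y, z, t`), acquisition metadata (`tr_pair`, TI1/TI2),
#'   and `ground_truth` containing the noiseless CBV component
#'   `1 - dcbv * m * D_CBV` at the nulled acquisition times.
#' @export
simulate_acquisition <- function(geometry, domains, vasc, timeline,
                                 hemo = hemo_params(), noise_sigma = 0,
                                 amplitudes = c(cbv = 0.02, bold = 0.04),
                                 s0 = c(wm = 70, gm = 100, csf = 50),
                                 drift = 0.001, seed = 1L, run_id = 1L) {
  stopifnot(inherits(geometry, "patch_geometry"),
            inherits(domains, "domain_map"),
            inherits(vasc, "vascular_map"),
            inherits(timeline, "block_timeline"),
            inherits(hemo, "hemo_params"))
  if (any(amplitudes < 0) || any(amplitudes > 0.5))
    stop("amplitudes must lie in [0, 0.5]")
  amp_cbv <- unname(amplitudes["cbv"])
  amp_bold <- unname(amplitudes["bold"])

  d <- geometry$dim
  nvox <- prod(d)
  n <- n_volumes(timeline)
  tr <- timeline$tr_pair
  tau <- (seq_len(n) - 1) * tr          # not-nulled acquisition times
  sig <- tau + tr / 2                   # nulled acquisition times (mid-pair)

  drive <- function(times, cond, contrast) {
    bl <- timeline$blocks[timeline$blocks$condition == cond, , drop = FALSE]
    out <- numeric(length(times))
    for (i in seq_len(nrow(bl)))
      out <- out + hemodynamic_response(times, bl$onset_s[i],
                                        timeline$block_dur, hemo, contrast)
    out
  }
  p <- as.vector(domains$p)
  cm0 <- (1 + p) / 2
  cm4 <- (1 - p) / 2
  wv <- as.vector(vasc$w_vein)
  mv <- as.vector(vasc$m)

  # BOLD factor at not-nulled times (voxels x time), separable in voxel/time
  bold <- 1 + amp_bold * (tcrossprod(wv * cm0, drive(tau, "RF0", "BOLD")) +
                          tcrossprod(wv * cm4, drive(tau, "RF4", "BOLD")))
  if (drift != 0) {
    g <- 1 + drift * (tau / max(tau) - 0.5)
    bold <- sweep(bold, 2, g, `*`)
  }
  cbv <- 1 - amp_cbv * (tcrossprod(mv * cm0, drive(sig, "RF0", "CBV")) +
                        tcrossprod(mv * cm4, drive(sig, "RF4", "CBV")))

  s0_vox <- s0[c("wm", "gm", "csf")][as.vector(geometry$labels)]
  not_nulled <- s0_vox * bold
  # BOLD contamination at the mid-pair nulled readout: linear interpolant
  # of the bracketing not-nulled samples (carried forward past the end)
  nn_mid <- (not_nulled + not_nulled[, c(seq_len(n)[-1], n),
                                     drop = FALSE]) / 2
  nulled <- cbv * nn_mid
  stopifnot(all(nulled > 0), all(not_nulled > 0))

  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    nulled <- nulled + stats::rnorm(length(nulled), sd = noise_sigma)
    not_nulled <- not_nulled + stats::rnorm(length(not_nulled),
                                            sd = noise_sigma)
  }

  structure(
    list(nulled = array(nulled, c(d, n)),
         not_nulled = array(not_nulled, c(d, n)),
         tr_pair = tr, ti1_ms = 1145, ti2_ms = 2115,
         run_id = as.integer(run_id), seed = as.integer(seed),
         noise_sigma = noise_sigma, amplitudes = amplitudes, drift = drift,
         ground_truth = list(cbv_component = array(cbv, c(d, n)),
                             p = domains$p)),
    class = "interleaved_series"
  )
}

#' @export
print.interleaved_series <- function(x, ...) {
  d <- dim(x$nulled)
  cat(sprintf(
    "interleaved_series: %dx%dx%d grid, %d volume pairs, TR %.3f s, seed %d\n",
    d[1], d[2], d[3], d[4], x$tr_pair, x$seed))
  invisible(x)
}
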