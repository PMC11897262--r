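test_that("flat-slab geometry has well-formed columns and zero curvature", {
  geo <- make_patch_geometry()  # default 48x16x10, 1.2 mm, T = 3.6 mm
  gm <- geo$labels == TISSUE["GM"]
  expect_true(all(geo$kappa[gm] == 0))
  expect_true(all(geo$depth[gm] >= 0 & geo$depth[gm] <= 1))
  # every column carries at least two depth samples (here three)
  per_column <- apply(gm, c(1, 2), sum)
  expect_true(all(per_column >= 2))
  expect_identical(sort(unique(round(geo$depth[gm], 6))),
                   round(c(1, 3, 5) / 6, 6))
  # flat coordinates are unique per column
  cols <- unique(cbind(as.vector(geo$u[gm]), as.vector(geo$v[gm])))
  expect_identical(nrow(cols), sum(per_column > 0))
  # CSF-adjacent shell sits directly above the GM sheet
  expect_identical(sum(geo$csf_adjacent), sum(per_column > 0))

  expect_error(make_patch_geometry(thickness_mm = 2), "degenerate")
})

test_that("folded sheet reduces to the flat slab at zero fold amplitude", {
  flat <- make_patch_geometry(nx = 12, ny = 4, nz = 8)
  fold0 <- make_patch_geometry(nx = 12, ny = 4, nz = 8,
                               kind = "folded_sheet",
                               fold_amplitude_mm = 0)
  expect_identical(fold0$labels, flat$labels)
  expect_equal(fold0$depth, flat$depth)
  expect_equal(fold0$kappa, flat$kappa)

  folded <- make_patch_geometry(nx = 32, ny = 4, nz = 10,
                                kind = "folded_sheet",
                                fold_amplitude_mm = 1.2,
                                fold_period_mm = 19.2)
  gm <- folded$labels == TISSUE["GM"]
  expect_true(any(folded$kappa[gm] > 0) && any(folded$kappa[gm] < 0))
  # arc-length flat coordinate is strictly increasing along x
  ux <- folded$u[, 1, 1]
  expect_true(all(diff(ux) > 0))
})

test_that("domain maps are columnar with balanced stripes", {
  geo <- make_patch_geometry()
  dom <- make_domain_map(geo, "stripes", lambda_mm = 4.8)
  # columnar: identical preference at all depths of a column
  expect_true(all(apply(dom$p, c(1, 2), function(z) length(unique(z))) == 1))
  # sign flips every half period (2.4 mm = 2 voxels along u)
  nx <- geo$dim[1]
  expect_true(all(dom$p[1:(nx - 2), , 1] == -dom$p[3:nx, , 1]))
  # near-zero mean over whole-period extents
  expect_lt(abs(mean(dom$p)), 0.05)

  graded <- make_domain_map(geo, "stripes_graded", lambda_mm = 9.6)
  expect_equal(graded$p[, 1, 1], sin(2 * pi * geo$u[, 1, 1] / 9.6))

  expect_error(make_domain_map(geo, "stripes", lambda_mm = 1.0), "exceed")
  expect_warning(make_domain_map(geo, "stripes", lambda_mm = 1.6),
                 "under-sampled")
})

test_that("blob domains are deterministic in the seed", {
  geo <- make_patch_geometry(nx = 24, ny = 24, nz = 8)
  b1 <- make_domain_map(geo, "blobs", lambda_mm = 4.8, seed = 42)
  b2 <- make_domain_map(geo, "blobs", lambda_mm = 4.8, seed = 42)
  b3 <- make_domain_map(geo, "blobs", lambda_mm = 4.8, seed = 43)
  expect_identical(b1$p, b2$p)
  expect_false(identical(b1$p, b3$p))
  expect_true(all(b1$p %in% c(-1, 1)))
})

test_that("haemodynamic model peaks at 6 s and CBV returns later", {
  t <- seq(0, 80, by = 0.1)
  onset <- 10; dur <- 31.32
  for (contrast in c("CBV", "BOLD")) {
    r <- hemodynamic_response(t, onset, dur, contrast = contrast)
    expect_true(all(r[t < onset] == 0))
    expect_true(all(r >= 0 & r <= 1))
    expect_equal(t[which.max(r)] - onset, 6)
    expect_equal(max(r), 1)
    # plateau below the peak until offset
    sustain <- t > onset + 12 & t <= onset + dur
    expect_true(all(r[sustain] < 1 & r[sustain] >= 0.8))
  }
  rc <- hemodynamic_response(t, onset, dur, contrast = "CBV")
  rb <- hemodynamic_response(t, onset, dur, contrast = "BOLD")
  t5 <- function(r) t[t > onset + dur & r < 0.05][1]
  expect_gt(t5(rc), t5(rb))  # delayed compliance
  expect_error(hemodynamic_response(t, onset, 0), "positive")
})

test_that("noise calibration hits its tSNR target", {
  expect_equal(calibrate_noise(100, 25), 4)
  expect_equal(calibrate_noise(100, 40), 2.5)
  expect_equal(calibrate_noise(100, 25, "boco"), 4 / sqrt(2))
  # Monte-Carlo: measured tSNR of a calibrated rest-only series
  withr::with_seed(7, {
    x <- 100 + stats::rnorm(600, sd = calibrate_noise(100, 25))
    expect_equal(mean(x) / stats::sd(x), 25, tolerance = 0.05)
  })
})

test_that("simulator is quiescent without vascular response", {
  tl <- tiny_timeline()
  geo <- tiny_geometry()
  dom <- make_domain_map(geo, "stripes", lambda_mm = 4.8)
  vas <- make_vascular_map(geo, w_min = 0, csf_weight = 0, micro = 0)
  vas$w_vein[] <- 0
  sim <- simulate_acquisition(geo, dom, vas, tl, noise_sigma = 0, drift = 0)
  s0 <- c(70, 100, 50)[as.vector(geo$labels)]
  expect_equal(as.vector(sim$nulled), rep(s0, dim(sim$nulled)[4]))
  expect_equal(as.vector(sim$not_nulled), rep(s0, dim(sim$nulled)[4]))
})

test_that("nulled/not-nulled ratio equals the CBV component when BOLD is flat", {
  tl <- tiny_timeline()
  geo <- tiny_geometry()
  dom <- make_domain_map(geo, "stripes", lambda_mm = 4.8)
  vas <- make_vascular_map(geo)
  vas$w_vein[] <- 0  # no BOLD response: contamination factor constant
  sim <- simulate_acquisition(geo, dom, vas, tl, noise_sigma = 0, drift = 0)
  expect_equal(sim$nulled / sim$not_nulled, sim$ground_truth$cbv_component,
               tolerance = 1e-14)
  # CBV response is a signal decrease, confined to GM
  gm4 <- array(geo$labels == TISSUE["GM"], dim(sim$nulled))
  expect_true(all(sim$ground_truth$cbv_component <= 1))
  expect_true(all(sim$ground_truth$cbv_component[!gm4] == 1))
})

test_that("simulation is bit-reproducible from its seed", {
  tl <- tiny_timeline()
  geo <- tiny_geometry()
  dom <- make_domain_map(geo, "stripes", lambda_mm = 4.8)
  vas <- make_vascular_map(geo)
  s1 <- simulate_acquisition(geo, dom, vas, tl, noise_sigma = 2.5, seed = 9)
  s2 <- simulate_acquisition(geo, dom, vas, tl, noise_sigma = 2.5, seed = 9)
  s3 <- simulate_acquisition(geo, dom, vas, tl, noise_sigma = 2.5, seed = 10)
  expect_identical(s1$nulled, s2$nulled)
  expect_identical(s1$not_nulled, s2$not_nulled)
  expect_false(identical(s1$nulled, s3$nulled))
  expect_error(
    simulate_acquisition(geo, dom, vas, tl, amplitudes = c(cbv = 0.6,
                                                           bold = 0.04)),
    "amplitudes")
})

test_that("venous weighting rises toward the surface and into CSF", {
  geo <- make_patch_geometry()
  vas <- make_vascular_map(geo)
  gm <- geo$labels == TISSUE["GM"]
  expect_true(all(vas$m[!gm] == 0))
  deep <- gm & geo$depth <= 0.2
  shallow <- gm & geo$depth >= 0.8
  expect_gt(mean(vas$w_vein[shallow]), mean(vas$w_vein[deep]))
  expect_true(all(vas$w_vein[geo$csf_adjacent] > 0))
})

test_that("noiseless activation: BOLD reaches CSF-adjacent voxels, VASO stays in GM", {
  z <- tiny_zero_noise()
  bt_b <- block_peak_responses(z$pp$bold, z$tl)
  bt_v <- block_peak_responses(z$pp$vaso, z$tl)
  amp_b <- array(rowMeans(bt_b$amplitude), z$geo$dim)
  amp_v <- array(rowMeans(bt_v$amplitude), z$geo$dim)
  gm <- z$geo$labels == TISSUE["GM"]
  # BOLD block response present above the GM surface (draining veins)...
  expect_gt(min(amp_b[z$geo$csf_adjacent]), 0.5 * min(amp_b[gm]))
  # ...while the corrected VASO response there is negligible next to the
  # weakest GM response (residual interpolation ripple only)
  expect_lt(max(abs(amp_v[z$geo$csf_adjacent])), 0.05 * min(amp_v[gm]))
  expect_gt(min(amp_v[gm]), 0)
})
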