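# helper: build a 1-voxel contrast series with a given step log
series1 <- function(values, tag = "nulled", dt = 2.610,
                    log = c("separate", "replace_nonsteady", "upsample")) {
  contrast_series(array(values, c(1, 1, 1, length(values))), tag, dt, log)
}

test_that("contrast separation preserves counts and tags", {
  z <- tiny_zero_noise()
  sep <- separate_contrasts(z$sim)
  n <- n_volumes(z$tl)
  expect_identical(dim(sep$nulled$data)[4], n)
  expect_identical(dim(sep$not_nulled$data)[4], n)
  expect_identical(sep$nulled$tag, "nulled")
  expect_identical(sep$not_nulled$tag, "not_nulled")
  expect_identical(sep$nulled$log, "separate")

  bad <- z$sim
  bad$nulled <- bad$nulled[, , , 1:10, drop = FALSE]
  expect_error(separate_contrasts(bad), "mismatch")
  empty <- list(nulled = array(0, c(2, 2, 2, 0)),
                not_nulled = array(0, c(2, 2, 2, 0)), tr_pair = 2.61)
  expect_error(separate_contrasts(empty), "empty")
})

test_that("a full-length default run separates into 369-volume series", {
  tl <- build_block_timeline()
  expect_identical(n_volumes(tl), 369L)
  sim <- list(nulled = array(1, c(2, 2, 1, 369)),
              not_nulled = array(1, c(2, 2, 1, 369)), tr_pair = 2.610)
  sep <- separate_contrasts(sim)
  expect_identical(dim(sep$nulled$data)[4], 369L)
})

test_that("non-steady-state volumes are replaced by the first steady volume", {
  cs <- series1(c(10, 20, 30, 40, 50, 60), log = "separate")
  out <- replace_nonsteady(cs, 4)
  expect_equal(as.vector(out$data), c(50, 50, 50, 50, 50, 60))
  expect_equal(stats::var(as.vector(out$data)[1:4]), 0)

  same <- replace_nonsteady(series1(1:6, log = "separate"), 0)
  expect_equal(as.vector(same$data), 1:6)
  expect_error(replace_nonsteady(series1(1:4, log = "separate"), 4),
               "too short")
  expect_error(replace_nonsteady(out, 4), "already applied")
})

test_that("temporal upsampling doubles length and recovers linear midpoints", {
  ramp <- series1(seq(2, 20, by = 2))
  ramp$log <- c("separate", "replace_nonsteady")
  for (method in c("linear", "cubic")) {
    up <- temporal_upsample(ramp, 2, method = method)
    expect_identical(dim(up$data)[4], 20L)
    expect_equal(up$dt, ramp$dt / 2)
    # interior samples interleave originals with exact midpoints
    expect_equal(as.vector(up$data)[1:18], as.numeric(2:19))
  }
  const <- series1(rep(7, 10))
  const$log <- c("separate", "replace_nonsteady")
  expect_true(all(temporal_upsample(const, 2)$data == 7))
  expect_error(temporal_upsample(const, 0), "integer")
  expect_error(temporal_upsample(series1(1:5, log = "separate"), 2),
               "requires prior")
})

test_that("nulled alignment duplicates the first timepoint and drops the last", {
  cs <- series1(c(1, 2, 3))
  out <- align_nulled(cs)
  expect_equal(as.vector(out$data), c(1, 1, 2))
  expect_identical(dim(out$data)[4], 3L)
  expect_error(align_nulled(out), "already applied")
  expect_error(align_nulled(series1(1:3, log = "separate")), "requires prior")
})

test_that("dynamic division cancels multiplicative BOLD contamination", {
  b <- 100 + 10 * sin(seq(0, 6, length.out = 24))
  nulled <- series1(0.95 * b,
                    log = c("separate", "replace_nonsteady", "upsample",
                            "align"))
  not_nulled <- series1(b, tag = "not_nulled")
  out <- boco_correct(nulled, not_nulled)
  expect_identical(out$tag, "vaso_corrected")
  expect_equal(as.vector(out$data), rep(0.95, 24), tolerance = 1e-12)

  ident <- boco_correct(series1(b, log = nulled$log),
                        series1(b, tag = "not_nulled"))
  expect_equal(as.vector(ident$data), rep(1, 24), tolerance = 1e-12)

  # order enforcement: division before upsampling/alignment is rejected
  expect_error(boco_correct(series1(b, log = "separate"), not_nulled),
               "requires prior")
  expect_error(boco_correct(not_nulled, not_nulled), "expects")
})

test_that("division guard holds the previous ratio and flags dead voxels", {
  b <- rep(100, 6)
  b[4] <- 1e-9  # transient signal dropout
  nulled <- series1(0.9 * rep(100, 6),
                    log = c("separate", "replace_nonsteady", "upsample",
                            "align"))
  not_nulled <- series1(b, tag = "not_nulled")
  out <- boco_correct(nulled, not_nulled)
  expect_equal(as.vector(out$data)[4], as.vector(out$data)[3])

  dead <- series1(rep(0, 6), tag = "not_nulled")
  out2 <- boco_correct(nulled, dead)
  expect_true(all(attr(out2, "qc_allzero")))
  expect_true(all(out2$data == 1))  # previous-ratio chain from 1
})

test_that("the preprocessing chain is an exact inverse of the simulator", {
  z <- tiny_zero_noise()
  n <- dim(z$sim$nulled)[4]
  corrected <- z$pp$vaso$data
  gt <- z$sim$ground_truth$cbv_component
  # fine-grid samples aligned to nulled acquisitions, steady-state pairs
  keep <- 5:n
  dev <- abs(corrected[, , , 2 * keep] - gt[, , , keep])
  expect_lte(max(dev), 2^-52)
  expect_identical(z$pp$vaso$log,
                   c("separate", "replace_nonsteady", "upsample", "align",
                     "boco"))
})

test_that("run averaging reduces noise like 1/sqrt(n)", {
  log_full <- c("separate", "replace_nonsteady", "upsample", "align", "boco")
  withr::with_seed(11, {
    runs <- lapply(1:2, function(i)
      contrast_series(array(stats::rnorm(4000), c(5, 4, 2, 100)),
                      "vaso_corrected", 1.305, log_full))
    avg <- average_runs(runs)
    expect_equal(stats::sd(avg$data), 1 / sqrt(2), tolerance = 0.1)
  })
  one <- average_runs(list(runs_id <- contrast_series(
    array(1:8, c(2, 2, 2, 1)), "bold", 1, "separate")))
  expect_equal(one$data, array(1:8, c(2, 2, 2, 1)))
  ident <- average_runs(list(one, one))
  expect_equal(ident$data, one$data)
  expect_error(average_runs(list(
    contrast_series(array(1, c(1, 1, 1, 2)), "bold", 1),
    contrast_series(array(1, c(1, 1, 1, 2)), "nulled", 1))), "mixed")
})

test_that("tSNR is temporal mean over sd with flagged dead voxels", {
  withr::with_seed(3, {
    x <- 100 + stats::rnorm(400, sd = 4)
    cs <- series1(x, tag = "bold", log = "separate")
    expect_equal(as.vector(tsnr_map(cs)), mean(x) / stats::sd(x))
  })
  const <- series1(rep(5, 10), tag = "bold", log = "separate")
  out <- tsnr_map(const)
  expect_identical(as.vector(out), Inf)
  expect_true(all(attr(out, "zero_variance")))
  expect_error(tsnr_map(series1(1, tag = "bold", log = "separate")),
               "at least two")
})

test_that("BOLD branch tSNR exceeds the VASO branch under default calibration", {
  m <- default_manifest()
  expect_gt(m$tsnr_gm_median["bold"], m$tsnr_gm_median["vaso"])
})
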