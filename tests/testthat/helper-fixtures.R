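# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# short timeline/geometry for fast unit tests
tiny_timeline <- function() build_block_timeline(n_initial_rest = 8,
                                                 n_blocks = 4)

tiny_geometry <- function() make_patch_geometry(nx = 8, ny = 4, nz = 8,
                                                wm_mm = 2.4)

# zero-noise simulated run + preprocessing chain on a small grid
tiny_zero_noise <- function() {
  cached_fixture("tiny_zero_noise", {
    tl <- tiny_timeline()
    geo <- tiny_geometry()
    dom <- make_domain_map(geo, "stripes", lambda_mm = 4.8)
    vas <- make_vascular_map(geo)
    sim <- simulate_acquisition(geo, dom, vas, tl, noise_sigma = 0)
    pp <- preprocess_run(sim)
    list(tl = tl, geo = geo, dom = dom, vas = vas, sim = sim, pp = pp)
  })
}

# full default-configuration analysis (the study conditions), seed 1
default_manifest <- function() {
  cached_fixture("default_manifest",
                 suppressWarnings(run_pipeline(run_config(seed = 1))))
}

# default-scale stripe simulations at a given domain period
stripe_manifest <- function(lambda_mm) {
  cached_fixture(paste0("stripes_", lambda_mm), suppressWarnings(
    run_pipeline(run_config(seed = 1,
                            domain = list(lambda_mm = lambda_mm)))))
}

# zero-noise single run at the default (study-scale) geometry
default_zero_noise <- function() {
  cached_fixture("default_zero_noise", {
    cfg <- run_config(seed = 1, domain = list(lambda_mm = 4.8))
    tl <- do.call(build_block_timeline, cfg$timeline)
    geo <- do.call(make_patch_geometry, cfg$geometry)
    dom <- make_domain_map(geo, cfg$domain$pattern,
                           lambda_mm = cfg$domain$lambda_mm,
                           seed = cfg$seed)
    vas <- make_vascular_map(geo)
    sim <- simulate_acquisition(geo, dom, vas, tl,
                                hemo = do.call(hemo_params, cfg$hemo),
                                noise_sigma = 0,
                                amplitudes = cfg$amplitudes, s0 = cfg$s0,
                                drift = cfg$drift, seed = cfg$seed)
    pp <- preprocess_run(sim)
    list(cfg = cfg, tl = tl, geo = geo, dom = dom, sim = sim, pp = pp)
  })
}
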