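test_that("presets reproduce their defining equilibrium ratios", {
  m3c <- kinetic_preset("m3C-like")
  expect_equal(m3c$rates$k_fwd[1] / m3c$rates$k_rev[1], 2.3e5)
  ea <- kinetic_preset("epsilonA-like")
  expect_equal(ea$rates$k_fwd[1] / ea$rates$k_rev[1], 8.6e5)
  m1a <- kinetic_preset("m1A-like")
  expect_equal(m1a$scheme$n_reversible, 3)
  expect_true(m1a$scheme$include_catalysis && m1a$scheme$include_release)
})

test_that("zero-noise series equal the deterministic model output", {
  p <- kinetic_preset("m3C-like")
  g <- generate_sf_series(p$scheme, p$rates, p$obs, noise_sd = 0, seed = 4,
                          grid = small_grid())
  tr <- g$series$traces[[2]]
  traj <- integrate_scheme(p$scheme, p$rates, tr$e0, tr$s0, tr$time)
  expect_equal(tr$signal, observe(traj, p$obs, p$scheme))
})

test_that("series generation is seed-deterministic and uses the default design", {
  p <- kinetic_preset("m3C-like")
  g1 <- generate_sf_series(p$scheme, p$rates, p$obs, seed = 9,
                           grid = small_grid())
  g2 <- generate_sf_series(p$scheme, p$rates, p$obs, seed = 9,
                           grid = small_grid())
  expect_identical(g1$series$traces, g2$series$traces)
  g3 <- generate_sf_series(p$scheme, p$rates, p$obs, seed = 10,
                           grid = small_grid())
  expect_false(identical(g1$series$traces[[1]]$signal,
                         g3$series$traces[[1]]$signal))

  # default single-turnover design: fixed 1.5 uM, counterpart 0.5-5 uM
  expect_equal(g1$truth$fixed_uM, 1.5)
  expect_equal(g1$truth$counterpart_uM, c(0.5, 1, 2, 3, 5))
  expect_length(g1$series, 5)
  full <- make_time_grid()
  expect_equal(range(full$times), c(1e-3, 550))
})

test_that("generated noise matches the requested standard deviation", {
  p <- kinetic_preset("m3C-like")
  grid <- make_time_grid(list(c(1e-3, 550, 4000)))
  noise <- generate_sf_series(p$scheme, p$rates, p$obs, noise_sd = 0.05,
                              seed = 21, grid = grid,
                              counterpart_uM = c(1, 2, 3))
  clean <- generate_sf_series(p$scheme, p$rates, p$obs, noise_sd = 0,
                              seed = 21, grid = grid,
                              counterpart_uM = c(1, 2, 3))
  resid <- unlist(lapply(1:3, function(j) {
    noise$series$traces[[j]]$signal - clean$series$traces[[j]]$signal
  }))
  expect_gt(length(resid), 1e4)
  expect_equal(stats::sd(resid), 0.05, tolerance = 0.05)
})

test_that("truth records travel with every generator", {
  p <- kinetic_preset("epsilonA-like")
  g <- generate_sf_series(p$scheme, p$rates, p$obs, seed = 2,
                          grid = small_grid())
  expect_identical(g$truth$rates, p$rates)
  expect_identical(g$truth$seed, 2)

  iso <- isotherm_params(5e-6, 0, 1e6, 0.5e6, 1e-6)
  t1 <- generate_titration(iso, (1:8) * 1e-6, 0.01, seed = 3)
  expect_identical(t1$truth$params, iso)
})

test_that("replicate averaging reduces titration noise variance about 3-fold", {
  iso <- isotherm_params(5e-6, 0, 1e6, 0.5e6, 1e-6)
  p0 <- (1:10) * 1e-6
  single <- vapply(1:300, function(s) {
    generate_titration(iso, p0, noise_sd = 0.05, seed = s)$F_obs[1]
  }, numeric(1))
  avg <- vapply(1:300, function(s) {
    generate_titration(iso, p0, noise_sd = 0.05, seed = 1000 + s,
                       replicates = 3)$F_obs[1]
  }, numeric(1))
  ratio <- stats::var(single) / stats::var(avg)
  expect_gt(ratio, 2); expect_lt(ratio, 4.5)
})

test_that("product time course needs chemistry and stays a fraction", {
  p <- kinetic_preset("m3C-like")
  expect_error(
    generate_page_timecourse(p$scheme, p$rates, 2e-6, 2e-6),
    "catalysis")

  ea <- kinetic_preset("epsilonA-like")
  tc <- generate_page_timecourse(ea$scheme, ea$rates, 2e-6, 2e-6,
                                 times = seq(30, 7200, by = 120),
                                 noise_sd = 0.02, seed = 6)
  expect_true(all(tc$product_fraction >= 0 & tc$product_fraction <= 1))
  expect_true(all(tc$truth$fraction_noiseless <= 1 + 1e-9))
  # effectively no chemistry -> no product
  slow <- ea$rates; slow$k_r <- 1e-12
  tc0 <- generate_page_timecourse(ea$scheme, slow, 2e-6, 2e-6,
                                  times = c(60, 600, 7200),
                                  noise_sd = 0, seed = 1)
  expect_true(all(tc0$product_fraction < 1e-6))
})

test_that("gel-assay analysis recovers a slow demethylation rate consistently", {
  # truth built so that initial-slope analysis gives k_obs near 0.0037 1/s:
  # tight, fast binding equilibrium ahead of slow chemistry; enzyme excess
  # keeps the substrate saturated so conversion is single-exponential
  sch <- build_scheme(2, include_catalysis = TRUE, include_release = TRUE,
                      labeled_molecule = "dna")
  rates <- rate_parameters(k_fwd = c(2.3e7, 2), k_rev = c(1, 2),
                           k_r = 0.0074, K_d_product = 1e-6)
  e0 <- 6e-6; s0 <- 2e-6
  tc <- generate_page_timecourse(sch, rates, e0, s0,
                                 times = seq(5, 7200, by = 15),
                                 noise_sd = 0, seed = 1)
  V0 <- initial_velocity(tc$times, tc$product_fraction, s0)
  Ka <- association_constant_sf(rates, 2)
  kobs <- kobs_from_v0(V0, e0, s0, Ka)
  expect_equal(kobs, 0.0037, tolerance = 0.1)
  # half-conversion of the noiseless curve near ln2 / k_obs
  t_half <- tc$times[min(which(tc$truth$fraction_noiseless >= 0.5))]
  expect_equal(t_half, half_time(kobs), tolerance = 0.05)
})
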