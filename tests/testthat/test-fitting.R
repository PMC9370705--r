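m3c_series <- function(noise_sd = NULL, seed = 42, points = 40) {
  p <- kinetic_preset("m3C-like")
  generate_sf_series(p$scheme, p$rates, p$obs, noise_sd = noise_sd,
                     seed = seed, grid = small_grid(points))
}

test_that("trace_set validates its traces", {
  ok <- list(time = c(1, 2), signal = c(0.1, 0.2), e0 = 1e-6, s0 = 1e-6,
             fluorophore = "FRET")
  expect_s3_class(trace_set(list(ok)), "trace_set")
  bad_time <- ok; bad_time$time <- c(2, 1)
  expect_error(trace_set(list(bad_time)), "increasing")
  bad_sig <- ok; bad_sig$signal <- c(0.1, NaN)
  expect_error(trace_set(list(bad_sig)), "non-finite")
  bad_conc <- ok; bad_conc$e0 <- 0
  expect_error(trace_set(list(bad_conc)), "positive")
  other <- ok; other$fluorophore <- "aPu"
  expect_error(trace_set(list(ok, other)), "mix")
})

test_that("noise-free global fit recovers all Scheme-2 rate constants within 1%", {
  g <- m3c_series(noise_sd = 0, seed = 5)
  fit <- fit_traces(g$series, g$truth$scheme, quick_opts(seed = 2))
  truth <- rates_truth <- c(k1 = 2.3e6, k2 = 2, km1 = 10, km2 = 2)
  rel <- abs(fit$estimates[names(truth)] / truth - 1)
  expect_true(all(rel < 0.01))
  # observation model recovered too
  expect_equal(unname(fit$f_per_uM[c("S", "C1", "C2")]), c(1, 0.70, 0.85),
               tolerance = 1e-3)
  expect_equal(fit$F_b, rep(0.2, 5), tolerance = 1e-3)
})

test_that("starting at the truth on noise-free data is a fixed point", {
  g <- m3c_series(noise_sd = 0, seed = 6)
  truth <- c(k1 = 2.3e6, k2 = 2, km1 = 10, km2 = 2)
  fit <- fit_traces(g$series, g$truth$scheme,
                    fit_options(n_starts = 1, seed = 1), warm_start = truth)
  expect_lt(fit$sse, 1e-12)
  expect_equal(fit$estimates[names(truth)], truth, tolerance = 1e-4)
})

test_that("noisy fits recover rate constants within experiment-level error", {
  g <- m3c_series(seed = 31)   # 1% of dynamic range
  fit <- fit_traces(g$series, g$truth$scheme, quick_opts(seed = 3))
  truth <- c(k1 = 2.3e6, k2 = 2, km1 = 10, km2 = 2)
  rel <- abs(fit$estimates[names(truth)] / truth - 1)
  expect_true(all(rel < 0.25))
  expect_true(all(is.finite(fit$se)))
})

test_that("identical options and seed give identical fits", {
  g <- m3c_series(seed = 12)
  f1 <- fit_traces(g$series, g$truth$scheme, quick_opts(seed = 9))
  f2 <- fit_traces(g$series, g$truth$scheme, quick_opts(seed = 9))
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$sse, f2$sse)
  expect_identical(f1$starts, f2$starts)
})

test_that("fixing a rate constant away from its estimate degrades the fit", {
  g <- m3c_series(noise_sd = 0, seed = 7)
  free_fit <- fit_traces(g$series, g$truth$scheme, quick_opts(seed = 2))
  for (par in c("k1", "km2")) {
    fixed_fit <- fit_traces(g$series, g$truth$scheme, quick_opts(seed = 2),
                            fixed = stats::setNames(free_fit$estimates[par] * 2,
                                                    par))
    expect_gt(fixed_fit$sse, free_fit$sse * 100)
  }
})

test_that("SSE is non-increasing along the complication ladder", {
  g <- m3c_series(seed = 77)
  sel <- select_scheme(g$series, 3, quick_opts(seed = 11))
  sse <- sel$table$sse
  expect_true(all(diff(sse) <= sse[-length(sse)] * 1e-3))
})

test_that("scheme selection finds the generating two-step mechanism", {
  g <- m3c_series(seed = 55)
  sel <- select_scheme(g$series, 3, quick_opts(seed = 4))
  expect_equal(sel$scheme$n_reversible, 2)
  expect_equal(nrow(sel$table), 3)           # complication 2->3 was examined
  expect_false(sel$table$selected[3])
})

test_that("scheme selection does not over-complicate one-step binding data", {
  sch <- build_scheme(1, labeled_molecule = "dna")
  rates <- rate_parameters(2e6, 5)
  obs <- observation_model(sch, c(S = 1, C1 = 0.6), F_b = 0.1)
  g <- generate_sf_series(sch, rates, obs, seed = 3, grid = small_grid())
  sel <- select_scheme(g$series, 3, quick_opts(seed = 5))
  expect_equal(sel$scheme$n_reversible, 1)
})

test_that("noise-free five-step data select the five-step scheme exactly", {
  p <- kinetic_preset("m1A-like")
  g <- generate_sf_series(p$scheme, p$rates, p$obs, noise_sd = 0, seed = 8,
                          counterpart_uM = c(0.5, 2, 5),
                          grid = small_grid(60))
  sel <- select_scheme(g$series, 4, fit_options(n_starts = 8, seed = 7, n_polish = 8),
                       include_catalysis = TRUE, include_release = TRUE)
  expect_equal(sel$scheme$n_reversible, 3)
  expect_true(sel$scheme$include_catalysis)
  expect_true(sel$scheme$include_release)
})

test_that("fits expose per-start diagnostics and keep the best run", {
  g <- m3c_series(seed = 1, points = 20)
  fit <- fit_traces(g$series, g$truth$scheme, quick_opts(seed = 3))
  expect_s3_class(fit$starts, "data.frame")
  expect_equal(nrow(fit$starts), 3)
  expect_true(all(is.finite(fit$starts$sse)))
  # the polished optimum is at least as good as every multi-start run
  expect_lte(fit$sse, min(fit$starts$sse) * (1 + 1e-8))
  expect_true(is.logical(fit$starts$converged))
})
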