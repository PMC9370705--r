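test_that("time grids concatenate log-spaced split windows", {
  g <- make_time_grid(list(c(0.001, 0.1, 3)))
  expect_equal(g$times, c(0.001, 0.01, 0.1))

  gd <- make_time_grid()
  expect_equal(min(gd$times), 1e-3)
  expect_equal(max(gd$times), 550)
  expect_true(all(diff(gd$times) > 0))
  expect_equal(length(unique(gd$window)), 4)

  expect_error(make_time_grid(list()), "no windows")
  expect_error(make_time_grid(list(c(0.1, 1, 10), c(0.5, 2, 10))),
               "non-overlapping")
})

test_that("irreversible equimolar binding matches the second-order closed form", {
  sch <- build_scheme(1)
  r <- rate_parameters(1e6, 1e-12)   # reverse rate negligible
  e0 <- 1e-6
  tr <- integrate_scheme(sch, r, e0, e0, c(0.5, 1, 2))
  # [E](t) = e0 / (1 + k1*e0*t)
  expect_equal(tr[, "E"], e0 / (1 + 1e6 * e0 * c(0.5, 1, 2)),
               tolerance = 1e-6)
})

test_that("reversible binding relaxes to the quadratic-isotherm equilibrium", {
  sch <- build_scheme(1)
  r <- rate_parameters(1e6, 1)       # K_d = 1 uM
  tr <- integrate_scheme(sch, r, 1e-6, 1e-6, c(10, 100))
  expect_equal(unname(tr[2, "C1"]), 3.81966e-7, tolerance = 1e-5)
})

test_that("equilibrium of the 1-step scheme matches the isotherm for random draws", {
  set.seed(202)
  for (i in 1:20) {
    k1 <- 10^runif(1, 5, 7.5)
    km1 <- 10^runif(1, -0.5, 1.5)
    e0 <- runif(1, 0.3, 4) * 1e-6
    s0 <- runif(1, 0.3, 4) * 1e-6
    sch <- build_scheme(1)
    r <- rate_parameters(k1, km1)
    t_end <- 60 / km1
    tr <- integrate_scheme(sch, r, e0, s0, c(t_end / 2, t_end))
    eq <- complex_concentration(e0, s0, km1 / k1)
    expect_equal(unname(tr[2, "C1"]), eq, tolerance = 1e-6)
  }
})

test_that("trajectory accuracy is tolerance-limited, not grid-limited", {
  p <- kinetic_preset("epsilonA-like")
  g <- small_grid()
  base <- integrate_scheme(p$scheme, p$rates, 1.5e-6, 2e-6, g)
  tight <- integrate_scheme(p$scheme, p$rates, 1.5e-6, 2e-6, g,
                            atol = 5e-13, rtol = 5e-10)
  rel <- abs(base[, -1] - tight[, -1]) / max(abs(base[, -1]))
  expect_lt(max(rel), 1e-6)
})

test_that("compiled reduced system agrees with the full-state R definition", {
  p <- kinetic_preset("epsilonA-like")
  sch <- p$scheme
  rhs_full <- function(t, y, parms) {
    list(unname(mass_action_rhs(sch, p$rates,
                                stats::setNames(pmax(y, 0), sch$species))))
  }
  times <- c(0, 10^seq(-3, 2, length.out = 40))
  y0 <- stats::setNames(numeric(length(sch$species)), sch$species)
  y0["E"] <- 1.5e-6; y0["S"] <- 2e-6
  full <- deSolve::lsoda(y0, times, rhs_full, NULL,
                         atol = 1e-14, rtol = 1e-10)
  red <- integrate_scheme(sch, p$rates, 1.5e-6, 2e-6, times[-1])
  for (spc in sch$species) {
    expect_equal(red[, spc], unname(full[-1, spc]), tolerance = 1e-6)
  }
})

test_that("observation model validates coefficients and evaluates linearly", {
  sch <- build_scheme(2)
  expect_error(observation_model(sch, c(E = 1)), "without the fluorophore")
  expect_error(observation_model(sch, c(1, 2)), "named")

  # background only
  obs0 <- observation_model(sch, c(S = 0), F_b = 0.5)
  tr <- integrate_scheme(sch, kinetic_preset("m3C-like")$rates,
                         1e-6, 1.5e-6, c(0.01, 1, 10))
  expect_equal(observe(tr, obs0, sch), rep(0.5, 3))

  # single species linear arithmetic: 5e-7 M at 2 a.u./uM over background 0.1
  sch1 <- build_scheme(1)
  traj <- cbind(time_s = 1, E = 0, S = 5e-7, C1 = 0)
  obs1 <- observation_model(sch1, c(S = 2), F_b = 0.1)
  expect_equal(observe(traj, obs1, sch1), 1.1)

  # dot-product oracle with two species
  f <- c(S = 0.8, C1 = 1.7)
  obs2 <- observation_model(sch1, f, F_b = 0.3)
  traj2 <- cbind(time_s = c(1, 2), E = c(0, 0),
                 S = c(4e-7, 2e-7), C1 = c(1e-7, 3e-7))
  manual <- 0.3 + traj2[, c("S", "C1")] %*% (f * 1e6)
  expect_equal(observe(traj2, obs2, sch1), as.numeric(manual))
})

test_that("observe is linear in coefficients and in trajectories", {
  sch <- build_scheme(2)
  p <- kinetic_preset("m3C-like")
  tr <- integrate_scheme(sch, p$rates, 1e-6, 1.5e-6, c(0.01, 0.1, 1, 10))
  f1 <- c(S = 1, C1 = 0.7, C2 = 0.85)
  f2 <- c(S = 0.2, C1 = 1.1, C2 = 0.4)
  o1 <- observation_model(sch, f1)
  o2 <- observation_model(sch, f2)
  osum <- observation_model(sch, f1 + 2 * f2)
  expect_equal(observe(tr, osum, sch),
               observe(tr, o1, sch) + 2 * observe(tr, o2, sch))
})
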