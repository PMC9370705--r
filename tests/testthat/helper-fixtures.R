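# shared fixtures: small grids and quick fit options keep unit tests fast;
# acceptance checks use the full default design instead

small_grid <- function(points = 40) make_time_grid(sf_windows(points))

quick_opts <- function(seed = 1, n_starts = 3) {
  fit_options(n_starts = n_starts, seed = seed)
}

# conservation deviation of a trajectory matrix relative to the totals
conservation_error <- function(traj, scheme, e0, s0) {
  n <- scheme$n_reversible
  Csum <- rowSums(traj[, paste0("C", seq_len(n)), drop = FALSE])
  EP <- if (scheme$include_catalysis) traj[, "EP"] else 0
  P <- if (scheme$include_release) traj[, "P"] else 0
  enz <- traj[, "E"] + Csum + EP
  dna <- traj[, "S"] + Csum + EP + P
  max(abs(enz - e0) / e0, abs(dna - s0) / s0)
}

# independent sum-of-products evaluation of the composite association
# constant: K1 + K1*K2 + K1*K2*K3 + ...
ka_sum_of_products <- function(K) sum(cumprod(K))

# temporary directory removed when the calling test finishes
local_dir <- function(env = parent.frame()) {
  d <- tempfile("sfkin")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
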