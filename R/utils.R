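# internal numerics helpers

# forward-difference Jacobian of a vector-valued function
numeric_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - f0) / h
  }
  J
}

# Gauss-Newton covariance of least-squares estimates
ls_covariance <- function(fn, par, sse, n_obs, n_par_total) {
  J <- numeric_jacobian(fn, par)
  dof <- max(n_obs - n_par_total, 1L)
  sigma2 <- sse / dof
  tryCatch(sigma2 * solve(crossprod(J)),
           error = function(e) matrix(NA_real_, length(par), length(par)))
}

# evaluate fn with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
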