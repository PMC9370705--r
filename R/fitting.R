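#' A concentration series of fluorescence traces
#'
#' Bundles traces recorded under one mechanism with one fluorophore at
#' several enzyme/substrate concentration pairs, as acquired in a
#' single-turnover stopped-flow titration of the fixed fluorescent component
#' with its non-fluorescent counterpart.
#'
#' @param traces List of traces. Each trace is a list with `time` (s,
#'   strictly increasing), `signal` (a.u., same length), `e0` and `s0`
#'   (total molar concentrations), `fluorophore` (character), and
#'   optionally `window` (integer acquisition-window index per point, used
#'   for residual weighting).
#' @return Object of class `trace_set`.
#' @export
trace_set <- function(traces) {
  if (length(traces) == 0L) stop("empty trace list", call. = FALSE)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    if (is.null(tr$time) || is.null(tr$signal) ||
        length(tr$time) != length(tr$signal))
      stop("trace ", i, ": time/signal missing or of unequal length",
           call. = FALSE)
    if (any(diff(tr$time) <= 0))
      stop("trace ", i, ": time must be strictly increasing", call. = FALSE)
    if (any(!is.finite(tr$signal)))
      stop("trace ", i, ": non-finite signal values", call. = FALSE)
    if (is.null(tr$e0) || is.null(tr$s0) || tr$e0 <= 0 || tr$s0 <= 0)
      stop("trace ", i, ": e0 and s0 must be positive", call. = FALSE)
  }
  fl <- unique(vapply(traces, function(tr) tr$fluorophore %||% "unknown", ""))
  if (length(fl) > 1L)
    stop("traces mix fluorophores: ", paste(fl, collapse = ", "),
         call. = FALSE)
  structure(list(traces = traces, fluorophore = fl), class = "trace_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
length.trace_set <- function(x) length(x$traces)

#' @export
print.trace_set <- function(x, ...) {
  cat("Trace set:", length(x$traces), "traces, fluorophore:",
      x$fluorophore, "\n")
  for (tr in x$traces) {
    cat(sprintf("  e0 = %.3g uM, s0 = %.3g uM, %d points\n",
                tr$e0 * 1e6, tr$s0 * 1e6, length(tr$time)))
  }
  invisible(x)
}

#' Options controlling global trace fits
#'
#' @param n_starts Number of multi-start optimizer runs (>= 1). The first
#'   start uses a fixed heuristic (or a supplied warm start); the rest are
#'   drawn log-uniformly within the bounds.
#' @param seed Integer seed making the random starts (and polish jitters)
#'   reproducible.
#' @param bounds Named list of per-class box bounds `c(lower, upper)` in
#'   natural units: `k_bi` for the bimolecular association rate (1/M/s),
#'   `k_uni` for unimolecular isomerization rates (1/s), `k_r` for the
#'   chemistry rate (1/s), and `K_d` for the product-complex dissociation
#'   constant (M). Optimization works on the log scale, so the bounds also
#'   enforce positivity; the physically typed defaults (association below
#'   the diffusion limit, molar-range dissociation constants) prune the
#'   spurious boundary minima a single generic box admits.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param n_polish Iterated-local-search refinements after the multi-start
#'   phase: the incumbent optimum is jittered (log-normal, `jitter_sd`) and
#'   re-optimized, keeping improvements. Escapes the shallow local minima
#'   that multi-phase kinetic landscapes produce.
#' @param jitter_sd Standard deviation of the log-scale jitter.
#' @param weighting `"window"` weights each acquisition window equally
#'   (per-point weight inversely proportional to points in the window), so
#'   the dense millisecond window does not dominate; `"uniform"` weights
#'   all points equally.
#' @param release_rate Fixed EP dissociation rate (1/s) used when a scheme
#'   includes product release (only the ratio to the association rate, i.e.
#'   `K_d_product`, is fitted).
#' @return Object of class `fit_options`.
#' @export
fit_options <- function(n_starts = 5, seed = 1,
                        bounds = list(k_bi = c(1e4, 1e9),
                                      k_uni = c(1e-4, 1e4),
                                      k_r = c(1e-5, 1e2),
                                      K_d = c(1e-9, 1e-3)),
                        maxiter = 120,
                        n_polish = 5, jitter_sd = 0.6,
                        weighting = c("window", "uniform"),
                        release_rate = 100) {
  weighting <- match.arg(weighting)
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  need <- c("k_bi", "k_uni", "k_r", "K_d")
  if (!all(need %in% names(bounds)))
    stop("bounds must name ", paste(need, collapse = ", "), call. = FALSE)
  for (b in bounds) if (b[1] <= 0 || b[2] <= b[1])
    stop("each bound must satisfy 0 < lower < upper", call. = FALSE)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 bounds = bounds, maxiter = as.integer(maxiter),
                 n_polish = as.integer(n_polish), jitter_sd = jitter_sd,
                 weighting = weighting, release_rate = release_rate),
            class = "fit_options")
}

# per-parameter log-scale box bounds by parameter class
parameter_bounds <- function(scheme, options) {
  pn <- rate_parameter_names(scheme)
  b <- options$bounds
  cls <- function(p) {
    if (p == "k1") "k_bi"
    else if (p == "kr") "k_r"
    else if (p == "Kd") "K_d"
    else "k_uni"
  }
  lo <- vapply(pn, function(p) log(b[[cls(p)]][1]), numeric(1))
  hi <- vapply(pn, function(p) log(b[[cls(p)]][2]), numeric(1))
  list(lower = lo, upper = hi)
}

trace_weights <- function(tr, weighting) {
  n <- length(tr$time)
  if (weighting == "window" && !is.null(tr$window)) {
    cnt <- table(tr$window)
    w <- 1 / as.numeric(cnt[as.character(tr$window)])
    w * n / sum(w)                     # normalize to mean weight 1
  } else {
    rep.int(1, n)
  }
}

# random multi-start values in log space, one column per parameter
start_matrix <- function(scheme, options, warm = NULL) {
  pn <- rate_parameter_names(scheme)
  n <- scheme$n_reversible
  heur <- stats::setNames(numeric(length(pn)), pn)
  heur[paste0("k", seq_len(n))] <- c(1e6, rep(5, n - 1))
  heur[paste0("km", seq_len(n))] <- rep(2, n)
  if (scheme$include_catalysis) heur["kr"] <- 0.05
  if (scheme$include_release) heur["Kd"] <- 1e-6
  if (!is.null(warm)) heur[names(warm)[names(warm) %in% pn]] <-
      warm[names(warm) %in% pn]
  lo <- stats::setNames(numeric(length(pn)), pn)
  hi <- lo
  lo[paste0("k", seq_len(n))] <- c(1e5, rep(0.05, n - 1))
  hi[paste0("k", seq_len(n))] <- c(1e8, rep(50, n - 1))
  lo[paste0("km", seq_len(n))] <- 0.05; hi[paste0("km", seq_len(n))] <- 50
  if (scheme$include_catalysis) { lo["kr"] <- 1e-3; hi["kr"] <- 1 }
  if (scheme$include_release) { lo["Kd"] <- 1e-7; hi["Kd"] <- 1e-5 }
  starts <- matrix(NA_real_, options$n_starts, length(pn),
                   dimnames = list(NULL, pn))
  starts[1, ] <- log(heur)
  if (options$n_starts > 1L) {
    for (i in 2:options$n_starts) {
      starts[i, ] <- log(lo) + stats::runif(length(pn)) * (log(hi) - log(lo))
    }
  }
  starts
}

# Weighted residual vector for one candidate log-parameter vector.
# The observation coefficients enter linearly and are profiled out:
# given trajectories, per-trace backgrounds F_b and the shared coefficients
# of all labeled species except the free one (anchored at 1 a.u./uM) are
# solved by weighted linear least squares.
series_residuals <- function(theta, series, scheme, options, return_fit = FALSE) {
  rates <- named_to_rates(scheme, exp(theta), options$release_rate)
  lab <- labeled_species(scheme)
  anchor <- free_labeled_species(scheme)
  others <- setdiff(lab, anchor)
  anchor_f <- 1e6                      # 1 a.u./uM in a.u./M
  n_tr <- length(series$traces)

  rows <- integer(0); ys <- list(); Xs <- list(); ws <- list()
  for (j in seq_len(n_tr)) {
    tr <- series$traces[[j]]
    traj <- integrate_scheme(scheme, rates, tr$e0, tr$s0, tr$time)
    y <- tr$signal - anchor_f * traj[, anchor]
    X <- matrix(0, length(y), n_tr + length(others))
    X[, j] <- 1                                    # per-trace background F_b
    if (length(others) > 0L)
      X[, n_tr + seq_along(others)] <- traj[, others, drop = FALSE]
    ys[[j]] <- y; Xs[[j]] <- X
    ws[[j]] <- trace_weights(tr, options$weighting)
  }
  y <- unlist(ys); X <- do.call(rbind, Xs); w <- unlist(ws)
  lin <- stats::lm.wfit(X, y, w)
  res <- sqrt(w) * lin$residuals
  if (!return_fit) return(res)
  coefs <- lin$coefficients
  coefs[is.na(coefs)] <- 0
  f <- stats::setNames(numeric(length(lab)), lab)
  f[anchor] <- anchor_f
  if (length(others) > 0L) f[others] <- coefs[n_tr + seq_along(others)]
  list(residuals = res, F_b = coefs[seq_len(n_tr)], f_per_M = f,
       n_linear = sum(!is.na(lin$coefficients)))
}

#' Globally fit a concentration series of stopped-flow traces
#'
#' Estimates the rate constants of a sequential mechanism by nonlinear
#' least squares over all traces of a series simultaneously. Rate constants
#' are shared across traces and optimized on the log scale within box
#' bounds; the observation model enters linearly (specific-fluorescence
#' coefficients shared across traces, background per trace, free labeled
#' species anchored at 1 a.u./uM) and is profiled out at every candidate
#' parameter vector, so only the mechanism parameters are searched. The best
#' of `n_starts` Levenberg-Marquardt runs is returned.
#'
#' Parameter uncertainties are reported two ways: asymptotic standard errors
#' from the Gauss-Newton curvature at the optimum, and the dispersion
#' (standard deviation) of the estimates across converged multi-start runs.
#'
#' @param series A [trace_set()].
#' @param scheme The candidate [build_scheme()].
#' @param options A [fit_options()].
#' @param warm_start Optional named vector of rate parameters (natural
#'   units) used as the first start.
#' @param fixed Optional named vector of rate parameters (natural units) to
#'   hold fixed at the given values while the rest are optimized, e.g. for
#'   profile checks of parameter identifiability.
#' @return Object of class `sf_fit`: estimated `rates`
#'   ([rate_parameters()]), `f_per_uM`, `F_b`, `sse` (weighted), `n_obs`,
#'   `n_par` (mechanism + linear parameters), `aic`, per-parameter
#'   `se` and `multistart_sd` (natural units), the per-start summary table
#'   `starts`, and `convergence` info of the winning run.
#' @export
fit_traces <- function(series, scheme, options = fit_options(),
                       warm_start = NULL, fixed = NULL) {
  stopifnot(inherits(series, "trace_set"), inherits(scheme, "kinetic_scheme"))
  pn <- rate_parameter_names(scheme)
  box <- parameter_bounds(scheme, options)
  lo <- box$lower; hi <- box$upper
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), pn)
    if (length(bad) > 0L)
      stop("unknown parameter(s) in `fixed`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    lo[names(fixed)] <- hi[names(fixed)] <- log(fixed)
  }

  run_lm <- function(st, maxit) {
    tryCatch({
      fit <- minpack.lm::nls.lm(
        par = pmin(pmax(st, lo), hi), lower = lo, upper = hi,
        fn = series_residuals,
        series = series, scheme = scheme, options = options,
        control = minpack.lm::nls.lm.control(maxiter = maxit, epsfcn = 1e-6)
      )
      list(par = fit$par, sse = sum(fit$fvec^2), info = fit$info,
           message = fit$message, ok = fit$info %in% 1:4)
    }, error = function(e) list(par = st, sse = Inf, info = -1L,
                                message = conditionMessage(e), ok = FALSE))
  }

  fitted <- with_seed(options$seed, {
    starts <- start_matrix(scheme, options, warm_start)
    if (!is.null(fixed))
      starts[, names(fixed)] <- rep(log(fixed), each = nrow(starts))
    runs <- lapply(seq_len(options$n_starts),
                   function(i) run_lm(starts[i, ], options$maxiter))
    sses <- vapply(runs, `[[`, numeric(1), "sse")
    if (all(!is.finite(sses))) {
      stop("all ", options$n_starts, " optimizer starts failed; diagnostics: ",
           paste(vapply(runs, `[[`, "", "message"), collapse = " | "),
           call. = FALSE)
    }
    # iterated local search around the incumbent optimum
    incumbent <- runs[[which.min(sses)]]
    for (i in seq_len(options$n_polish)) {
      jit <- incumbent$par + stats::rnorm(length(pn), 0, options$jitter_sd)
      if (!is.null(fixed)) jit[names(fixed)] <- log(fixed)
      cand <- run_lm(jit, options$maxiter)
      if (cand$sse < incumbent$sse) incumbent <- cand
    }
    list(runs = runs, sses = sses, incumbent = incumbent)
  })
  runs <- fitted$runs; sses <- fitted$sses
  theta <- fitted$incumbent$par
  final <- series_residuals(theta, series, scheme, options, return_fit = TRUE)
  sse <- sum(final$residuals^2)
  n_obs <- length(final$residuals)
  n_par <- length(pn) + final$n_linear
  aic <- n_obs * log(sse / n_obs) + 2 * (n_par + 1)

  cov <- ls_covariance(function(th) series_residuals(th, series, scheme, options),
                       theta, sse, n_obs, n_par)
  se_log <- sqrt(pmax(diag(cov), 0))
  est <- exp(theta)
  # multi-start dispersion over runs within 0.1% of the best SSE
  near <- which(is.finite(sses) & sses <= sse * 1.001)
  ms_sd <- if (length(near) > 1L) {
    apply(exp(do.call(rbind, lapply(runs[near], `[[`, "par"))), 2, stats::sd)
  } else {
    stats::setNames(rep(NA_real_, length(pn)), pn)
  }

  structure(list(
    scheme = scheme,
    rates = named_to_rates(scheme, est, options$release_rate),
    estimates = stats::setNames(est, pn),
    se = stats::setNames(est * se_log, pn),      # delta method to natural scale
    multistart_sd = stats::setNames(as.numeric(ms_sd), pn),
    f_per_uM = final$f_per_M / 1e6,
    F_b = as.numeric(final$F_b),
    sse = sse, n_obs = n_obs, n_par = n_par, aic = aic,
    options = options,
    starts = data.frame(start = seq_len(options$n_starts), sse = sses,
                        converged = vapply(runs, `[[`, logical(1), "ok")),
    convergence = list(info = fitted$incumbent$info,
                       message = fitted$incumbent$message)
  ), class = "sf_fit")
}

#' @export
print.sf_fit <- function(x, ...) {
  cat("Global stopped-flow fit:", x$scheme$n_reversible, "reversible steps",
      if (x$scheme$include_catalysis) "+ catalysis",
      if (x$scheme$include_release) "+ release", "\n")
  cat(sprintf("  SSE %.6g over %d points, %d parameters, AIC %.1f\n",
              x$sse, x$n_obs, x$n_par, x$aic))
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    se = signif(x$se, 3),
                    multistart_sd = signif(x$multistart_sd, 3))
  print(tab)
  invisible(x)
}

# F-test between nested least-squares fits (small nested in big)
nested_f_test <- function(fit_small, fit_big) {
  df1 <- fit_big$n_par - fit_small$n_par
  df2 <- fit_big$n_obs - fit_big$n_par
  if (df1 <= 0 || df2 <= 0 || fit_big$sse <= 0) return(NA_real_)
  Fstat <- ((fit_small$sse - fit_big$sse) / df1) / (fit_big$sse / df2)
  if (Fstat <= 0) return(1)
  stats::pf(Fstat, df1, df2, lower.tail = FALSE)
}

#' Choose the minimal adequate scheme by sequential complication
#'
#' Fits a nested ladder of schemes of increasing complexity (1, 2, ...,
#' `max_reversible` reversible steps, with the catalysis/release steps of
#' `include_catalysis`/`include_release` applied to every rung) and stops at
#' the smallest scheme for which the next complication is not statistically
#' justified. A complication is accepted only if the nested F-test rejects
#' the simpler model at `alpha` and the AIC improves decisively (by more
#' than `delta_aic`; the default 10 is the conventional "essentially no
#' support" level, guarding against the over-selection that near-zero
#' significance thresholds produce on series with thousands of points).
#' Complication also stops once the simpler model already fits at numerical
#' precision (weighted root-mean-square residual below 1e-6 of the signal
#' root-mean-square), where further SSE ratios are meaningless.
#'
#' Each rung is warm-started from the previous rung's estimates.
#'
#' @param series A [trace_set()].
#' @param max_reversible Largest number of reversible steps to consider.
#' @param options A [fit_options()].
#' @param include_catalysis,include_release Step flags applied to every
#'   candidate scheme.
#' @param alpha F-test significance level for accepting a complication.
#' @param delta_aic Minimum AIC improvement for accepting a complication.
#' @return List with `scheme` (the chosen [build_scheme()]), `fit` (its
#'   [fit_traces()] result), `fits` (all candidates), and `table`
#'   (per-candidate SSE, AIC, and p-value against the previous rung).
#' @export
select_scheme <- function(series, max_reversible, options = fit_options(),
                          include_catalysis = FALSE, include_release = FALSE,
                          alpha = 0.05, delta_aic = 10) {
  if (max_reversible < 1) stop("max_reversible must be >= 1", call. = FALSE)
  signal_rms <- sqrt(mean(unlist(
    lapply(series$traces, function(tr) tr$signal^2))))
  floor_sse <- function(fit) fit$n_obs * (1e-6 * signal_rms)^2

  fits <- list(); pvals <- numeric(0)
  chosen <- NULL
  for (n in seq_len(max_reversible)) {
    sch <- build_scheme(n, include_catalysis, include_release,
                        series$traces[[1]]$labeled_molecule %||% "dna")
    # embed the previous rung's optimum: the added step starts effectively
    # switched off (tiny forward rate, fast reverse), so the bigger model's
    # first start reproduces the simpler fit and SSE cannot get worse
    warm <- if (n > 1L) {
      w <- fits[[n - 1L]]$estimates
      w[paste0("k", n)] <- options$bounds$k_uni[1] * 2
      w[paste0("km", n)] <- 1e3
      w
    }
    fit <- tryCatch(fit_traces(series, sch, options, warm_start = warm),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      if (n == 1L && length(fits) == 0L)
        stop("all candidate schemes failed: ", conditionMessage(fit),
             call. = FALSE)
      break
    }
    fits[[n]] <- fit
    if (n == 1L) {
      chosen <- 1L
      pvals[1] <- NA_real_
      next
    }
    p <- nested_f_test(fits[[n - 1L]], fit)
    pvals[n] <- p
    justified <- !is.na(p) && p < alpha &&
      (fits[[n - 1L]]$aic - fit$aic) > delta_aic &&
      fits[[n - 1L]]$sse > floor_sse(fits[[n - 1L]])
    if (justified) {
      chosen <- n
    } else {
      break
    }
  }
  tab <- data.frame(
    n_reversible = seq_along(fits),
    n_par = vapply(fits, `[[`, numeric(1), "n_par"),
    sse = vapply(fits, `[[`, numeric(1), "sse"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    p_vs_simpler = pvals[seq_along(fits)]
  )
  tab$selected <- tab$n_reversible == chosen
  list(scheme = fits[[chosen]]$scheme, fit = fits[[chosen]],
       fits = fits, table = tab)
}
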