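#' Equilibrium complex concentration (quadratic binding root)
#'
#' Single-site binding of a titrant (total `p0`) to a receptor (total `e0`)
#' with dissociation constant `K_d`, without the free-ligand approximation:
#' \deqn{[EP] = \frac{(e_0 + p_0 + K_d) - \sqrt{(e_0 + p_0 + K_d)^2 - 4 e_0 p_0}}{2}}
#' Valid at comparable receptor and ligand concentrations (tight binding),
#' where free-ligand isotherms are badly biased.
#'
#' @param e0 Total receptor concentration (M).
#' @param p0 Total titrant concentration(s) (M), `>= 0`.
#' @param K_d Dissociation constant (M).
#' @return Complex concentration(s) (M); always `<= min(e0, p0)`.
#' @export
complex_concentration <- function(e0, p0, K_d) {
  if (any(p0 < 0)) stop("p0 must be non-negative", call. = FALSE)
  if (e0 <= 0 || K_d <= 0) stop("e0 and K_d must be positive", call. = FALSE)
  b <- e0 + p0 + K_d
  disc <- b^2 - 4 * e0 * p0
  (b - sqrt(pmax(disc, 0))) / 2
}

#' Parameters of the fluorescence titration isotherm
#'
#' @param K_d Dissociation constant (M).
#' @param F_0 Background fluorescence (a.u.).
#' @param f_1 Partial fluorescence of the free protein (a.u. per M).
#' @param f_2 Partial fluorescence of the saturated complex (a.u. per M).
#' @param e_0 Total protein concentration (M).
#' @return Object of class `isotherm_params`.
#' @export
isotherm_params <- function(K_d, F_0, f_1, f_2, e_0) {
  if (K_d <= 0 || e_0 <= 0) stop("K_d and e_0 must be positive", call. = FALSE)
  structure(list(K_d = K_d, F_0 = F_0, f_1 = f_1, f_2 = f_2, e_0 = e_0),
            class = "isotherm_params")
}

#' Fluorescence titration isotherm
#'
#' Predicted fluorescence of a protein titrated with a ligand under the
#' single-site quadratic (tight-binding) isotherm. The canonical form is
#' \deqn{F = F_0 + f_1 (e_0 - [EP]) + f_2 [EP]}
#' with `[EP]` from [complex_concentration()]: at `p0 = 0` it reduces to the
#' free-protein fluorescence and at saturation to the complex fluorescence.
#' The `as_printed` variant evaluates a published typeset arrangement of the
#' same quadratic root,
#' \deqn{F = F_0 + f_2 e_0 + \frac{f_2 - f_1}{2}\left(\sqrt{(K_d + p_0 - e_0)^2
#'   + 4 K_d e_0} - K_d - p_0 + e_0\right),}
#' which does not reduce to the free-protein limit at `p0 = 0` and is kept
#' only for traceability against literature fits.
#'
#' @param params An [isotherm_params()] object.
#' @param p0 Total titrant concentration(s), M.
#' @param variant `"canonical"` (default) or `"as_printed"`.
#' @return Fluorescence (a.u.), same length as `p0`.
#' @export
binding_isotherm <- function(params, p0, variant = c("canonical", "as_printed")) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "isotherm_params"))
  if (any(p0 < 0)) stop("p0 must be non-negative", call. = FALSE)
  with(params, {
    if (variant == "canonical") {
      EP <- complex_concentration(e_0, p0, K_d)
      F_0 + f_1 * (e_0 - EP) + f_2 * EP
    } else {
      F_0 + f_2 * e_0 + (f_2 - f_1) / 2 *
        (sqrt((K_d + p0 - e_0)^2 + 4 * K_d * e_0) - K_d - p0 + e_0)
    }
  })
}

#' Fit a fluorescence titration with the quadratic isotherm
#'
#' Estimates `K_d` and the fluorescence scale parameters from a titration
#' series. `K_d` is optimized on the log scale (enforcing positivity); for
#' each candidate `K_d` the remaining parameters (`F_0 + f_1 e_0` intercept
#' structure) enter linearly and are profiled out by ordinary least squares,
#' after which a Levenberg-Marquardt polish provides standard errors from
#' the local curvature.
#'
#' Note `F_0` and `f_1` are jointly unidentifiable from a single series
#' (both act on the unbound signal); `F_0` is fixed at 0 by default so that
#' `f_1` absorbs the free-protein fluorescence, matching common practice.
#'
#' @param p0 Total titrant concentrations (M), strictly increasing, at least
#'   5 points spanning below and above `e_0`.
#' @param F_obs Fluorescence readings (a.u.).
#' @param e0 Total protein concentration (M).
#' @param K_d_bounds Search interval for `K_d` (M).
#' @return List with `params` ([isotherm_params()]), `se` (standard errors,
#'   `K_d` on the natural scale via the delta method), `sse`, `residuals`,
#'   and `fitted`.
#' @export
fit_titration <- function(p0, F_obs, e0,
                          K_d_bounds = c(1e-9, 1e-2)) {
  if (length(p0) != length(F_obs)) stop("length mismatch", call. = FALSE)
  if (length(p0) < 5L) stop("need at least 5 titration points", call. = FALSE)
  if (any(diff(p0) <= 0)) stop("p0 must be strictly increasing", call. = FALSE)
  if (stats::sd(F_obs) == 0)
    stop("degenerate titration: constant fluorescence signal", call. = FALSE)

  # profile out the linear parameters (a = f1*e0 + F0, b = f2 - f1)
  profile_sse <- function(logKd) {
    EP <- complex_concentration(e0, p0, exp(logKd))
    X <- cbind(1, EP)
    fit <- stats::lm.fit(X, F_obs)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(profile_sse, log(K_d_bounds), tol = 1e-10)
  logKd <- opt$minimum
  EP <- complex_concentration(e0, p0, exp(logKd))
  lin <- stats::lm.fit(cbind(1, EP), F_obs)
  a <- lin$coefficients[1]; b <- lin$coefficients[2]
  f_1 <- a / e0                      # F_0 fixed at 0
  f_2 <- f_1 + b

  start <- c(logKd = logKd, f_1 = f_1, f_2 = f_2)
  resid_fun <- function(par) {
    pp <- isotherm_params(exp(par[1]), 0, par[2], par[3], e0)
    F_obs - binding_isotherm(pp, p0)
  }
  nlm <- minpack.lm::nls.lm(start, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- nlm$par
  sse <- sum(nlm$fvec^2)
  cov <- ls_covariance(resid_fun, est, sse, length(p0), 3L)
  se_log <- sqrt(pmax(diag(cov), 0))
  params <- isotherm_params(unname(exp(est[1])), 0, unname(est[2]),
                            unname(est[3]), e0)
  fitted <- binding_isotherm(params, p0)
  list(
    params = params,
    se = c(K_d = unname(exp(est[1]) * se_log[1]),     # delta method
           f_1 = unname(se_log[2]), f_2 = unname(se_log[3])),
    sse = sse,
    residuals = F_obs - fitted,
    fitted = fitted
  )
}
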