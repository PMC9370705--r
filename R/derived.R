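#' Composite association constant over sequential reversible steps
#'
#' For a mechanism with up to three reversible steps, the overall affinity
#' of the enzyme for its substrate accumulates over the binding and
#' isomerization equilibria:
#' \deqn{K_a^{SF} = \frac{k_1}{k_{-1}}\left(1 + \frac{k_2}{k_{-2}}\left(1 +
#'   \frac{k_3}{k_{-3}}\right)\right)}
#' which is identically the sum of products
#' \eqn{K_1 + K_1 K_2 + K_1 K_2 K_3} with \eqn{K_i = k_i / k_{-i}},
#' truncated to the available steps. The superscript marks constants derived
#' from stopped-flow rate constants, as opposed to equilibrium titration.
#'
#' @param rates A [rate_parameters()] object (or a plain list with `k_fwd`,
#'   `k_rev`) providing at least `n_reversible` steps.
#' @param n_reversible How many reversible steps to include (1, 2 or 3).
#' @return Composite association constant (1/M).
#' @examples
#' r <- rate_parameters(k_fwd = c(8.6e5, 5.2), k_rev = c(1, 4.3))
#' association_constant_sf(r, 2)
#' @export
association_constant_sf <- function(rates, n_reversible) {
  if (!n_reversible %in% 1:3)
    stop("n_reversible must be 1, 2 or 3", call. = FALSE)
  if (length(rates$k_fwd) < n_reversible || length(rates$k_rev) < n_reversible)
    stop("rates provide only ", length(rates$k_fwd), " steps; ",
         n_reversible, " requested", call. = FALSE)
  K <- rates$k_fwd[seq_len(n_reversible)] / rates$k_rev[seq_len(n_reversible)]
  # nested evaluation K1*(1 + K2*(1 + K3)), truncated
  acc <- 1
  for (i in rev(seq_len(n_reversible))) {
    acc <- if (i == n_reversible) K[i] else K[i] * (1 + acc)
  }
  acc
}

#' Observed dealkylation rate constant from an initial velocity
#'
#' Under single-turnover conditions the observed rate constant of the
#' chemistry step is the initial velocity divided by the equilibrium
#' concentration of the pre-catalytic complex,
#' \deqn{k_{obs} = V_0 / [ES], \quad
#'   [ES] = \frac{b - \sqrt{b^2 - 4 e_0 s_0}}{2}, \quad
#'   b = e_0 + s_0 + 1/K_a.}
#' The `as_printed` variant evaluates a published typeset form with the
#' plus-root in the denominator, \eqn{2 V_0 / (b + \sqrt{b^2 - 4 e_0 s_0})},
#' which algebraically equals \eqn{V_0 [ES] / (e_0 s_0)} rather than
#' \eqn{V_0/[ES]}; it is retained for traceability only.
#'
#' @param V_0 Initial velocity (M/s), e.g. from the linear part of a gel
#'   assay product time course.
#' @param e_0,s_0 Total enzyme and substrate concentrations (M).
#' @param K_a Association constant of the pre-catalytic complex (1/M),
#'   typically [association_constant_sf()] of the fitted mechanism.
#' @param variant `"canonical"` (default) or `"as_printed"`.
#' @return Observed rate constant (1/s).
#' @export
kobs_from_v0 <- function(V_0, e_0, s_0, K_a,
                         variant = c("canonical", "as_printed")) {
  variant <- match.arg(variant)
  if (any(c(V_0, e_0, s_0, K_a) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  b <- e_0 + s_0 + 1 / K_a
  disc <- b^2 - 4 * e_0 * s_0
  root <- sqrt(pmax(disc, 0))
  if (variant == "canonical") {
    ES <- (b - root) / 2
    V_0 / ES
  } else {
    2 * V_0 / (b + root)
  }
}

#' Half-conversion time of a first-order process
#'
#' @param k_obs Observed rate constant (1/s), positive.
#' @return `ln(2) / k_obs`, in seconds.
#' @examples
#' half_time(0.0037)  # ~187 s
#' @export
half_time <- function(k_obs) {
  if (any(k_obs <= 0)) stop("k_obs must be positive", call. = FALSE)
  log(2) / k_obs
}

#' Initial velocity from a product-fraction time course
#'
#' Slope of the early, approximately linear part of a single-turnover
#' product accumulation curve, converted to molar units.
#'
#' @param times Sampling times (s).
#' @param product_fraction Fraction of substrate converted, in `[0, 1]`.
#' @param s_0 Total substrate concentration (M).
#' @param fraction_max Points with conversion at or below this value are
#'   taken as the linear part (default 0.15).
#' @return Initial velocity (M/s).
#' @export
initial_velocity <- function(times, product_fraction, s_0, fraction_max = 0.15) {
  keep <- which(product_fraction <= fraction_max)
  if (length(keep) < 2L)
    stop("fewer than 2 points in the linear region", call. = FALSE)
  # least-squares slope through the origin at t = 0, fraction = 0
  slope <- sum(times[keep] * product_fraction[keep]) / sum(times[keep]^2)
  slope * s_0
}
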