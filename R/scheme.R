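#' Build a sequential kinetic scheme
#'
#' Constructs a sequential binding/isomerization mechanism of the form
#' \deqn{E + S \rightleftharpoons C_1 \rightleftharpoons \dots
#'       \rightleftharpoons C_n [\rightarrow EP [\rightleftharpoons E + P]]}
#' The first reversible step is bimolecular association of enzyme and DNA;
#' every subsequent reversible step is a unimolecular isomerization of the
#' enzyme-substrate complex. An optional irreversible step converts the last
#' complex into the enzyme-product complex (the chemistry, e.g. oxidative
#' dealkylation), and an optional release equilibrium lets the product
#' dissociate.
#'
#' @param n_reversible Number of reversible steps (>= 1). One gives simple
#'   binding, two adds an isomerization, and so on.
#' @param include_catalysis Add the irreversible chemistry step
#'   \eqn{C_n \rightarrow EP}?
#' @param include_release Add the product-release equilibrium
#'   \eqn{EP \rightleftharpoons E + P}? Requires `include_catalysis`.
#' @param labeled_molecule Which reactant carries the fluorophore: `"dna"`
#'   (substrate strand labeled, e.g. 2-aminopurine, a FRET pair, or an
#'   intrinsically fluorescent lesion) or `"enzyme"` (tryptophan
#'   fluorescence).
#'
#' @return An object of class `kinetic_scheme` with the ordered species
#'   labels (`E`, `S`, `C1..Cn`, and `EP`/`P` when present).
#' @examples
#' build_scheme(3, include_catalysis = TRUE, include_release = TRUE)  # five steps
#' build_scheme(2)                                                    # binding + isomerization
#' @export
build_scheme <- function(n_reversible,
                         include_catalysis = FALSE,
                         include_release = FALSE,
                         labeled_molecule = c("dna", "enzyme")) {
  labeled_molecule <- match.arg(labeled_molecule)
  if (!is.numeric(n_reversible) || length(n_reversible) != 1L ||
      n_reversible < 1 || n_reversible != round(n_reversible)) {
    stop("`n_reversible` must be a single integer >= 1", call. = FALSE)
  }
  if (include_release && !include_catalysis) {
    stop("product release requires the catalysis step (`include_catalysis`)",
         call. = FALSE)
  }
  n <- as.integer(n_reversible)
  species <- c("E", "S", paste0("C", seq_len(n)))
  if (include_catalysis) species <- c(species, "EP")
  if (include_release) species <- c(species, "P")
  structure(
    list(
      n_reversible = n,
      include_catalysis = isTRUE(include_catalysis),
      include_release = isTRUE(include_release),
      species = species,
      labeled_molecule = labeled_molecule
    ),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  n <- x$n_reversible
  steps <- c("E + S <=> C1",
             if (n > 1) paste0("C", seq_len(n - 1), " <=> C", seq_len(n - 1) + 1))
  if (x$include_catalysis) steps <- c(steps, paste0("C", n, " -> EP"))
  if (x$include_release) steps <- c(steps, "EP <=> E + P")
  cat("Sequential kinetic scheme (", length(steps), " steps, labeled: ",
      x$labeled_molecule, ")\n", sep = "")
  cat(paste0("  ", steps, collapse = "\n"), "\n")
  invisible(x)
}

#' Species carrying the fluorophore
#'
#' All species that contain the labeled molecule and therefore may carry a
#' non-zero specific-fluorescence coefficient. For a DNA-borne label these
#' are the free substrate, every complex, and the product species; for
#' protein fluorescence the free enzyme and every complex.
#'
#' @param scheme A [build_scheme()] object.
#' @return Character vector of species labels.
#' @export
labeled_species <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  complexes <- c(paste0("C", seq_len(scheme$n_reversible)),
                 if (scheme$include_catalysis) "EP")
  if (scheme$labeled_molecule == "dna") {
    c("S", complexes, if (scheme$include_release) "P")
  } else {
    c("E", complexes)
  }
}

#' Free (unbound) labeled species of a scheme
#' @param scheme A [build_scheme()] object.
#' @return `"S"` or `"E"`.
#' @export
free_labeled_species <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (scheme$labeled_molecule == "dna") "S" else "E"
}

#' Rate parameters of a sequential scheme
#'
#' Bundles the forward and reverse rate constants per reversible step, the
#' irreversible chemistry rate, and the product-complex dissociation
#' constant. The first forward constant is bimolecular (1/M/s); all other
#' rate constants are 1/s. Only the ratio of the product-release rates is
#' kinetically identifiable, so release is parameterized by its equilibrium
#' dissociation constant `K_d_product` together with a fixed dissociation
#' rate `release_rate`; the association rate is `release_rate / K_d_product`.
#'
#' @param k_fwd Forward rate constants, one per reversible step. Step 1 in
#'   1/M/s, later steps in 1/s.
#' @param k_rev Reverse rate constants (1/s), same length as `k_fwd`.
#' @param k_r Irreversible chemistry rate (1/s), or `NULL` if the scheme has
#'   no catalysis step.
#' @param K_d_product Equilibrium dissociation constant of the
#'   enzyme-product complex (M), or `NULL` without a release step.
#' @param release_rate Fixed magnitude of the EP dissociation rate (1/s).
#'   Its value does not affect equilibria; it only sets how fast the release
#'   step relaxes.
#' @return An object of class `rate_parameters`.
#' @examples
#' rate_parameters(k_fwd = c(2.3e6, 2), k_rev = c(10, 2))
#' @export
rate_parameters <- function(k_fwd, k_rev, k_r = NULL, K_d_product = NULL,
                            release_rate = 100) {
  if (length(k_fwd) != length(k_rev) || length(k_fwd) < 1L) {
    stop("`k_fwd` and `k_rev` must have equal length >= 1", call. = FALSE)
  }
  vals <- c(k_fwd, k_rev, k_r, K_d_product, release_rate)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all rate parameters must be finite and strictly positive",
         call. = FALSE)
  }
  structure(
    list(k_fwd = as.numeric(k_fwd), k_rev = as.numeric(k_rev),
         k_r = if (!is.null(k_r)) as.numeric(k_r),
         K_d_product = if (!is.null(K_d_product)) as.numeric(K_d_product),
         release_rate = as.numeric(release_rate)),
    class = "rate_parameters"
  )
}

check_rates_match_scheme <- function(scheme, rates) {
  if (length(rates$k_fwd) != scheme$n_reversible) {
    stop("scheme has ", scheme$n_reversible, " reversible steps but rates ",
         "provide ", length(rates$k_fwd), call. = FALSE)
  }
  if (scheme$include_catalysis && is.null(rates$k_r)) {
    stop("scheme includes catalysis but `k_r` is missing", call. = FALSE)
  }
  if (scheme$include_release && is.null(rates$K_d_product)) {
    stop("scheme includes product release but `K_d_product` is missing",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Mass-action time derivative of a concentration state
#'
#' Evaluates d\[species\]/dt for every species of a sequential scheme under
#' mass-action kinetics. The returned derivatives satisfy both conservation
#' laws exactly: the enzyme total (E plus all complexes) and the DNA total
#' (S, complexes, product) have zero net flux.
#'
#' This is the full-state definition of the model; [integrate_scheme()] uses
#' an equivalent reduced system (complexes only) in compiled code for speed
#' and exact conservation along trajectories.
#'
#' @param scheme A [build_scheme()] object.
#' @param rates A [rate_parameters()] object matching the scheme.
#' @param state Named numeric vector of molar concentrations, in the
#'   scheme's species order.
#' @return Named numeric vector of derivatives (M/s).
#' @export
mass_action_rhs <- function(scheme, rates, state) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  check_rates_match_scheme(scheme, rates)
  if (length(state) != length(scheme$species)) {
    stop("state has ", length(state), " entries; scheme expects ",
         length(scheme$species), call. = FALSE)
  }
  if (any(state < 0)) stop("negative concentrations", call. = FALSE)
  names(state) <- scheme$species
  n <- scheme$n_reversible
  C <- state[paste0("C", seq_len(n))]
  E <- state[["E"]]; S <- state[["S"]]

  v <- numeric(n)
  v[1] <- rates$k_fwd[1] * E * S - rates$k_rev[1] * C[1]
  if (n > 1) {
    for (i in 2:n) v[i] <- rates$k_fwd[i] * C[i - 1] - rates$k_rev[i] * C[i]
  }
  vcat <- if (scheme$include_catalysis) rates$k_r * C[n] else 0
  vrel <- 0
  if (scheme$include_release) {
    k_off <- rates$release_rate
    k_on <- k_off / rates$K_d_product
    vrel <- k_off * state[["EP"]] - k_on * E * state[["P"]]
  }

  d <- stats::setNames(numeric(length(state)), scheme$species)
  d[["E"]] <- -v[1] + vrel
  d[["S"]] <- -v[1]
  for (i in seq_len(n)) {
    outflux <- if (i < n) v[i + 1] else vcat
    d[[paste0("C", i)]] <- v[i] - outflux
  }
  if (scheme$include_catalysis) d[["EP"]] <- vcat - vrel
  if (scheme$include_release) d[["P"]] <- vrel
  d
}

#' Number of free mechanism parameters of a scheme
#'
#' Counts 2 per reversible step, plus 1 for the chemistry rate and 1 for the
#' product-complex dissociation constant where those steps are present.
#'
#' @param scheme A [build_scheme()] object.
#' @return Integer.
#' @export
n_rate_parameters <- function(scheme) {
  2L * scheme$n_reversible + scheme$include_catalysis + scheme$include_release
}

rate_parameter_names <- function(scheme) {
  n <- scheme$n_reversible
  c(paste0("k", seq_len(n)), paste0("km", seq_len(n)),
    if (scheme$include_catalysis) "kr",
    if (scheme$include_release) "Kd")
}

rates_to_named <- function(scheme, rates) {
  stats::setNames(
    c(rates$k_fwd, rates$k_rev,
      if (scheme$include_catalysis) rates$k_r,
      if (scheme$include_release) rates$K_d_product),
    rate_parameter_names(scheme)
  )
}

named_to_rates <- function(scheme, x, release_rate = 100) {
  n <- scheme$n_reversible
  rate_parameters(
    k_fwd = unname(x[paste0("k", seq_len(n))]),
    k_rev = unname(x[paste0("km", seq_len(n))]),
    k_r = if (scheme$include_catalysis) unname(x[["kr"]]),
    K_d_product = if (scheme$include_release) unname(x[["Kd"]]),
    release_rate = release_rate
  )
}
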