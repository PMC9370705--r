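#' Default stopped-flow acquisition windows
#'
#' The split-mode recording periods of the instrument: 1-100 ms, 0.1-1 s,
#' 1-50 s, and 50-550 s. Recording starts at the ~1 ms dead time of the
#' mixing cell.
#'
#' @param points_per_window Samples per window (log-spaced).
#' @return A list of `(start_s, end_s, points)` triplets suitable for
#'   [make_time_grid()].
#' @export
sf_windows <- function(points_per_window = 200) {
  lapply(list(c(1e-3, 0.1), c(0.1, 1), c(1, 50), c(50, 550)),
         function(w) c(w, points_per_window))
}

#' Build a split-window time grid
#'
#' Concatenates per-window sample grids, log-spaced by default as stopped-flow
#' instruments record them. Duplicate boundary points between adjacent
#' windows are kept in their later window only.
#'
#' @param windows List of numeric triplets `(start_s, end_s, points)`,
#'   ordered and non-overlapping, with `start_s > 0`.
#' @param spacing `"log"` (default) or `"linear"`.
#' @return An object of class `time_grid`: list with `times` (s) and
#'   `window` (integer window index per time point).
#' @examples
#' make_time_grid(list(c(0.001, 0.1, 3)))  # 0.001, 0.01, 0.1
#' @export
make_time_grid <- function(windows = sf_windows(), spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (length(windows) == 0L) stop("no windows given", call. = FALSE)
  mat <- do.call(rbind, lapply(windows, function(w) {
    if (length(w) != 3L || w[1] <= 0 || w[2] <= w[1] || w[3] < 2)
      stop("each window must be (start_s, end_s, points) with ",
           "0 < start < end and points >= 2", call. = FALSE)
    w
  }))
  if (any(mat[-1, 1, drop = TRUE] < mat[-nrow(mat), 2, drop = TRUE] - 1e-12))
    stop("windows must be ordered and non-overlapping", call. = FALSE)
  times <- list(); window <- list()
  for (i in seq_len(nrow(mat))) {
    pts <- if (spacing == "log") {
      exp(seq(log(mat[i, 1]), log(mat[i, 2]), length.out = mat[i, 3]))
    } else {
      seq(mat[i, 1], mat[i, 2], length.out = mat[i, 3])
    }
    if (i > 1L && abs(pts[1] - mat[i - 1, 2]) < 1e-12) {
      # boundary shared with the previous window: keep it once, here
      prev <- length(times[[i - 1]])
      times[[i - 1]] <- times[[i - 1]][-prev]
      window[[i - 1]] <- window[[i - 1]][-prev]
    }
    times[[i]] <- pts
    window[[i]] <- rep.int(i, length(pts))
  }
  structure(list(times = unlist(times), window = unlist(window)),
            class = "time_grid")
}

seq_parms <- function(scheme, rates, e0, s0) {
  n <- scheme$n_reversible
  k_off <- if (scheme$include_release) rates$release_rate else 0
  k_on <- if (scheme$include_release) k_off / rates$K_d_product else 0
  p <- c(n, scheme$include_catalysis, scheme$include_release, e0, s0,
         rates$k_fwd, rates$k_rev,
         if (scheme$include_catalysis) rates$k_r else 0, k_on, k_off)
  c(p, numeric(64L - length(p)))
}

#' Integrate a kinetic scheme
#'
#' Solves the mass-action system for a single mixing experiment starting
#' from free enzyme and free substrate (`[E] = e0`, `[S] = s0`, all
#' complexes zero) and reports species concentrations on the requested time
#' grid. Integration runs from t = 0; the grid's first point is typically
#' the instrument dead time.
#'
#' Internally only the complex species are propagated (with `lsoda`, which
#' switches to a stiff method as needed); free enzyme and substrate are
#' reconstructed from the conservation totals, so mass balance holds to
#' rounding error at every reported time.
#'
#' @param scheme A [build_scheme()] object.
#' @param rates A [rate_parameters()] object matching the scheme.
#' @param e0,s0 Total enzyme and DNA concentrations (M).
#' @param grid A [make_time_grid()] object, or a numeric vector of times (s).
#' @param atol,rtol Integrator tolerances. The defaults (1e-12 M absolute,
#'   1e-9 relative) suit rate constants spanning many decades and keep
#'   accumulated error on long split-window grids well below 1e-6 relative.
#' @return Numeric matrix with one row per grid time and one named column
#'   per species, plus a `time` attribute-free first column `time_s`.
#' @examples
#' sch <- build_scheme(1)
#' rts <- rate_parameters(1e6, 1)
#' tr <- integrate_scheme(sch, rts, 1e-6, 1e-6, c(0.1, 1, 100))
#' tr[, "C1"]  # approaches the quadratic-isotherm equilibrium
#' @export
integrate_scheme <- function(scheme, rates, e0, s0, grid,
                             atol = 1e-12, rtol = 1e-9) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  check_rates_match_scheme(scheme, rates)
  if (e0 <= 0 || s0 <= 0) stop("e0 and s0 must be positive", call. = FALSE)
  times <- if (inherits(grid, "time_grid")) grid$times else as.numeric(grid)
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing",
                                  call. = FALSE)
  n <- scheme$n_reversible
  n_state <- n + scheme$include_catalysis + scheme$include_release
  out <- deSolve::lsoda(
    y = numeric(n_state),
    times = c(0, times),
    func = "seq_rhs", parms = seq_parms(scheme, rates, e0, s0),
    dllname = "sfkin", initfunc = "seq_init",
    atol = atol, rtol = rtol
  )
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed for scheme with ", n, " reversible steps ",
         "(e0 = ", e0, " M, s0 = ", s0, " M)", call. = FALSE)
  }
  cmpx <- out[-1, -1, drop = FALSE]          # drop t = 0 row and time column
  cmpx[cmpx < 0] <- 0                        # clip integrator undershoot
  Csum <- rowSums(cmpx[, seq_len(n), drop = FALSE])
  EP <- if (scheme$include_catalysis) cmpx[, n + 1L] else 0
  P <- if (scheme$include_release) cmpx[, n + 2L] else 0
  traj <- cbind(
    time_s = times,
    E = pmax(0, e0 - Csum - EP),
    S = pmax(0, s0 - Csum - EP - P),
    cmpx
  )
  colnames(traj) <- c("time_s", scheme$species)
  traj
}

#' Linear fluorescence observation model
#'
#' The recorded signal is modeled as a background plus a linear combination
#' of the concentrations of all species that carry the fluorophore:
#' \deqn{F(t) = F_b + \sum_i f_i [X_i](t)}
#' Species not containing the labeled molecule have no coefficient. The
#' free labeled species acts as the normalization anchor: with an arbitrary
#' instrument scale, only relative coefficients are meaningful, so its
#' coefficient defaults to 1 a.u. per uM and fits keep it fixed.
#'
#' @param scheme A [build_scheme()] object.
#' @param f Named vector of specific-fluorescence coefficients in a.u. per
#'   uM, names drawn from [labeled_species()]. Unlisted labeled species get
#'   coefficient 0; naming an unlabeled species is an error.
#' @param F_b Background fluorescence (a.u.).
#' @return Object of class `observation_model` with coefficients stored in
#'   a.u. per M internally.
#' @examples
#' sch <- build_scheme(2)
#' observation_model(sch, c(S = 1, C1 = 0.7, C2 = 0.85), F_b = 0.2)
#' @export
observation_model <- function(scheme, f, F_b = 0) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  lab <- labeled_species(scheme)
  if (is.null(names(f)) || any(!nzchar(names(f))))
    stop("`f` must be a fully named vector", call. = FALSE)
  bad <- setdiff(names(f), lab)
  if (length(bad) > 0L)
    stop("coefficient given for species without the fluorophore: ",
         paste(bad, collapse = ", "), call. = FALSE)
  full <- stats::setNames(numeric(length(lab)), lab)
  full[names(f)] <- f
  structure(
    list(F_b = as.numeric(F_b),
         f_per_uM = full,
         f_per_M = full * 1e6,
         labeled = lab),
    class = "observation_model"
  )
}

#' Map species trajectories to fluorescence
#'
#' Evaluates the linear observation model on integrated trajectories:
#' background plus the dot product of specific-fluorescence coefficients
#' with labeled-species concentrations at each time.
#'
#' @param trajectories Matrix from [integrate_scheme()].
#' @param obs An [observation_model()].
#' @param scheme The scheme the trajectories were integrated under.
#' @return Numeric vector of fluorescence values (a.u.), one per time point.
#' @export
observe <- function(trajectories, obs, scheme) {
  stopifnot(inherits(obs, "observation_model"),
            inherits(scheme, "kinetic_scheme"))
  lab <- labeled_species(scheme)
  if (!identical(sort(obs$labeled), sort(lab)))
    stop("observation model does not match the scheme's labeled species",
         call. = FALSE)
  conc <- trajectories[, lab, drop = FALSE]
  as.numeric(obs$F_b + conc %*% obs$f_per_M[lab])
}
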