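#' Uniform 1-D finite-volume grid on [0, 1]
#'
#' The computational domain is the dimensionless interval `[0, 1]`
#' (reference length 1 cm): `x = 0` is the tumor-core end and `x = 1` the
#' far field where glucose is injected. Cells are indexed left to right
#' with uniform spacing `dx = 1/n_cells`.
#'
#' @param n_cells Number of cells (default 100, i.e. `dx = 0.01`).
#' @return An object of class `grid1d` with `n_cells`, `dx`, cell
#'   `centers` and `faces`.
#' @examples
#' g <- grid1d()
#' g$dx
#' @export
grid1d <- function(n_cells = 100L) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 4L) abort("grid1d: need at least 4 cells")
  dx <- 1 / n_cells
  structure(list(n_cells = n_cells, dx = dx,
                 centers = (seq_len(n_cells) - 0.5) * dx,
                 faces = seq(0, 1, by = dx)),
            class = "grid1d")
}

#' @export
print.grid1d <- function(x, ...) {
  cat(sprintf("<grid1d> %d cells on [0, 1], dx = %g\n", x$n_cells, x$dx))
  invisible(x)
}

#' Pulsed (or constant) glucose injection schedule
#'
#' Glucose is supplied in the far-field band `omega_b = [1 - band_width, 1]`
#' at discrete times `t_i = i * tau` (`i = 1, 2, ...`), each pulse lasting
#' `duration` hours at rate `g_in`. A `constant` schedule delivers the
#' same dose continuously at rate `g_in * duration / tau` on the same
#' band; [run_constant_supply_twin()] builds it from a pulsed schedule.
#'
#' @param tau Injection period in hours.
#' @param g_in Dimensionless glucose supply rate during a pulse
#'   (published range 1-30).
#' @param duration Pulse duration in hours (default 0.01).
#' @param band_width Width of the far-field injection band (default 0.08).
#' @param mode `"pulsed"` or `"constant"`.
#' @return An object of class `injection_schedule`.
#' @examples
#' injection_schedule(tau = 10, g_in = 5)
#' @export
injection_schedule <- function(tau = 10, g_in = 5, duration = 0.01,
                               band_width = 0.08, mode = c("pulsed", "constant")) {
  mode <- match.arg(mode)
  if (tau <= 0 || g_in < 0 || duration <= 0) {
    abort("injection_schedule: tau and duration must be positive, g_in nonnegative")
  }
  if (duration >= tau) {
    abort("injection_schedule: `duration` must be smaller than the period `tau`")
  }
  if (band_width <= 0 || band_width >= 1) {
    abort("injection_schedule: `band_width` must lie in (0, 1)")
  }
  structure(list(tau = tau, g_in = g_in, duration = duration,
                 band_width = band_width, mode = mode),
            class = "injection_schedule")
}

#' @export
print.injection_schedule <- function(x, ...) {
  if (x$mode == "pulsed") {
    cat(sprintf("<injection_schedule> pulsed: g_in = %g for %g h every %g h on [%g, 1]\n",
                x$g_in, x$duration, x$tau, 1 - x$band_width))
  } else {
    cat(sprintf("<injection_schedule> constant: rate %g on [%g, 1]\n",
                x$g_in * x$duration / x$tau, 1 - x$band_width))
  }
  invisible(x)
}

# Spatial weight of the injection band per cell: overlap fraction of each
# cell with [1 - band_width, 1].
band_weight <- function(schedule, grid) {
  lo <- 1 - schedule$band_width
  left <- grid$faces[-length(grid$faces)]
  right <- grid$faces[-1]
  pmax(0, (pmin(right, 1) - pmax(left, lo))) / grid$dx
}

#' Instantaneous injection source indicator
#'
#' Returns the per-cell indicator of the glucose source at time `t`: 1 for
#' cells inside the injection band during a pulse window
#' `[i tau, i tau + duration]`, the overlap fraction for cells straddling
#' the band edge, and 0 otherwise. The glucose source term is
#' `g_in * indicator`.
#'
#' @param t Time (hours), nonnegative.
#' @param schedule An [injection_schedule()].
#' @param grid A [grid1d()].
#' @return Numeric vector of length `n_cells` with values in `[0, 1]`.
#' @examples
#' s <- injection_schedule(tau = 10)
#' max(injection_source(10.005, s, grid1d()))
#' @export
injection_source <- function(t, schedule, grid) {
  if (t < 0) abort("injection_source: `t` must be nonnegative")
  w <- band_weight(schedule, grid)
  if (schedule$mode == "constant") {
    return(w * schedule$duration / schedule$tau)
  }
  i <- floor(t / schedule$tau)
  on <- i >= 1 && (t - i * schedule$tau) <= schedule$duration
  if (on) w else w * 0
}

# Fraction of [t0, t1] covered by pulse windows (exact, used by the
# reaction step so that each pulse deposits its dose to round-off).
pulse_overlap_fraction <- function(t0, t1, schedule) {
  if (t1 <= t0) return(0)
  if (schedule$mode == "constant") return(schedule$duration / schedule$tau)
  i0 <- max(1, floor(t0 / schedule$tau))
  i1 <- floor(t1 / schedule$tau)
  if (i1 < i0) return(0)
  tot <- 0
  for (i in i0:i1) {
    a <- i * schedule$tau
    tot <- tot + max(0, min(t1, a + schedule$duration) - max(t0, a))
  }
  tot / (t1 - t0)
}

# Times within (t0, t1] at which the pulsed source switches on or off;
# used to split reaction substeps so the source is constant on each piece.
pulse_breakpoints <- function(t0, t1, schedule) {
  if (schedule$mode == "constant") return(numeric(0))
  i0 <- max(1, floor(t0 / schedule$tau))
  i1 <- ceiling(t1 / schedule$tau) + 1
  edges <- as.vector(vapply(i0:i1, function(i)
    c(i * schedule$tau, i * schedule$tau + schedule$duration), numeric(2)))
  sort(edges[edges > t0 + 1e-14 & edges < t1 - 1e-14])
}

#' Smoothed growth/invasion phase indicators
#'
#' The go-or-grow switch thresholds the local miR-451 level at `M_th`:
#' cells with `M > M_th` proliferate, cells with `M < M_th` migrate. The
#' sharp indicators are smoothed with a logistic sigmoid of width
#' `smoothing_width`; the two weights sum to 1 everywhere and both equal
#' 1/2 exactly at `M = M_th`.
#'
#' @param M miR-451 level(s).
#' @param M_th Switching threshold (default 2).
#' @param smoothing_width Sigmoid width in miR-451 units; must be > 0.
#' @return A list with fields `growth` and `invasion`, each in `[0, 1]`.
#' @examples
#' phase_indicators(c(1, 2, 3))
#' @export
phase_indicators <- function(M, M_th = 2, smoothing_width = 0.05) {
  if (smoothing_width <= 0) abort("phase_indicators: `smoothing_width` must be > 0")
  g <- plogis((M - M_th) / smoothing_width)
  list(growth = g, invasion = 1 - g)
}

#' Bundle of the six spatial fields
#'
#' @param n Tumor cell density (carrying capacity 1).
#' @param rho ECM density (carrying capacity 1).
#' @param P MMP concentration.
#' @param G Glucose concentration.
#' @param M miR-451 level per location.
#' @param A AMPK-complex level per location.
#' @return An object of class `field_set` (list of six equal-length
#'   numeric vectors).
#' @export
field_set <- function(n, rho, P, G, M, A) {
  f <- list(n = n, rho = rho, P = P, G = G, M = M, A = A)
  len <- unique(vapply(f, length, integer(1)))
  if (length(len) != 1L) abort("field_set: all fields must share one grid")
  for (nm in names(f)) {
    if (any(!is.finite(f[[nm]]))) abort(sprintf("field_set: non-finite `%s`", nm))
    if (any(f[[nm]] < 0)) abort(sprintf("field_set: negative `%s`", nm))
  }
  structure(f, class = "field_set")
}

#' @export
print.field_set <- function(x, ...) {
  cat(sprintf("<field_set> %d cells\n", length(x$n)))
  for (nm in names(x)) {
    cat(sprintf("  %-3s in [%.4g, %.4g]\n", nm, min(x[[nm]]), max(x[[nm]])))
  }
  invisible(x)
}

#' Canonical initial conditions
#'
#' The default scenario places the tumor as a height-1 plateau with a
#' smooth (tanh) front adjacent to `x = 0`; the ECM is intact (`rho = 1`)
#' outside the tumor support and partially degraded inside; MMP starts at
#' zero; glucose is low and uniform, so the cells begin in the migratory
#' regime; and the intracellular fields `(M, A)` start at the local steady
#' state of the switch for the initial glucose signal.
#'
#' @param scenario Scenario name; only `"default"` is defined.
#' @param grid A [grid1d()].
#' @param params A [pde_params()] object.
#' @return A [field_set()].
#' @examples
#' f <- initial_conditions("default", grid1d(), pde_params())
#' max(f$M) < 2
#' @export
initial_conditions <- function(scenario = "default", grid = grid1d(),
                               params = pde_params()) {
  if (!identical(scenario, "default")) {
    abort(sprintf("initial_conditions: unknown scenario '%s' (available: default)",
                  scenario))
  }
  x <- grid$centers
  n <- 0.5 * (1 - tanh((x - params$tumor_width) / params$front_width))
  rho <- 1 - (1 - params$rho_inside) * n
  P <- rep(0, grid$n_cells)
  G <- rep(params$G_init, grid$n_cells)
  sig <- params$G_init / params$G_signal_scale
  eq <- steady_states(sig, params$switch)
  stable <- eq[eq$stability == "stable", ]
  # start on the low-miR-451 (migratory) branch
  M0 <- stable$M[which.min(stable$M)]
  A0 <- stable$A[which.min(stable$M)]
  field_set(n = n, rho = rho, P = P, G = G,
            M = rep(M0, grid$n_cells), A = rep(A0, grid$n_cells))
}
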