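#' Right-hand side of the miR-451/AMPK switch
#'
#' Evaluates the time derivatives of the dimensionless mutual-antagonism
#' system
#' \deqn{dM/dt = G + k_1 k_2^2/(k_2^2 + \alpha A^2) - M,}
#' \deqn{dA/dt = \epsilon (S + k_3 k_4^2/(k_4^2 + \beta M^2) - A).}
#' Production terms are bounded, so `dM/dt < 0` whenever `M > G + k1` and
#' `dA/dt < 0` whenever `A > S + k3`. All arguments are vectorized over
#' `M`, `A` and `G`, which lets the spatial model evaluate the network in
#' every grid cell at once.
#'
#' @param M miR-451 level(s), nonnegative.
#' @param A AMPK-complex level(s), nonnegative.
#' @param G Glucose input level(s), nonnegative.
#' @param params A [switch_params()] object.
#' @return A list with components `dM` and `dA`.
#' @examples
#' switch_rhs(0, 0, 0, switch_params(S = 0))
#' @export
switch_rhs <- function(M, A, G, params = switch_params()) {
  if (!is_switch_params(params)) abort("switch_rhs: `params` must be switch_params")
  if (any(!is.finite(M)) || any(!is.finite(A)) || any(!is.finite(G))) {
    abort("switch_rhs: non-finite state or input")
  }
  if (any(M < 0) || any(A < 0)) abort("switch_rhs: state must be nonnegative")
  if (any(G < 0)) abort("switch_rhs: glucose input must be nonnegative")
  list(
    dM = G + params$k1 * params$k2^2 / (params$k2^2 + params$alpha * A^2) - M,
    dA = params$eps *
      (params$S + params$k3 * params$k4^2 / (params$k4^2 + params$beta * M^2) - A)
  )
}

# Unchecked elementwise kernel shared with the PDE reaction step.
switch_rhs_raw <- function(M, A, G, p) {
  list(
    dM = G + p$k1 * p$k2^2 / (p$k2^2 + p$alpha * A^2) - M,
    dA = p$eps * (p$S + p$k3 * p$k4^2 / (p$k4^2 + p$beta * M^2) - A)
  )
}

# A-nullcline: the quasi-steady A level for a given M.
a_nullcline <- function(M, p) {
  p$S + p$k3 * p$k4^2 / (p$k4^2 + p$beta * M^2)
}

# M-nullcline: the quasi-steady M level for a given A and glucose input.
m_nullcline <- function(A, G, p) {
  G + p$k1 * p$k2^2 / (p$k2^2 + p$alpha * A^2)
}

# Scalar steady-state residual in M after eliminating A via its nullcline.
steady_residual <- function(M, G, p) {
  m_nullcline(a_nullcline(M, p), G, p) - M
}

# Jacobian of the (M, A) system at a point (analytic).
switch_jacobian <- function(M, A, G, p) {
  dfdA <- -2 * p$alpha * A * p$k1 * p$k2^2 / (p$k2^2 + p$alpha * A^2)^2
  dgdM <- -p$eps * 2 * p$beta * M * p$k3 * p$k4^2 / (p$k4^2 + p$beta * M^2)^2
  matrix(c(-1, dgdM, dfdA, -p$eps), 2, 2)
}

#' Integrate the miR-451/AMPK switch in time
#'
#' Solves the two-variable switch with a stiff-aware integrator
#' ([deSolve::ode()], `lsoda`). The glucose input may be a constant or an
#' arbitrary nonnegative function of time, which is how hysteresis sweeps
#' and glucose-deprivation protocols are run.
#'
#' @param initial Named numeric vector `c(M = ..., A = ...)`, nonnegative.
#' @param glucose Either a single nonnegative number (constant input) or a
#'   function of time returning the glucose level.
#' @param params A [switch_params()] object.
#' @param t_span Length-2 numeric, integration window.
#' @param n_out Number of equally spaced output times.
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @return A tibble of class `switch_trajectory` with columns `time`,
#'   `M`, `A`, `G`, carrying the parameters as an attribute. If the
#'   integrator stops early the result is truncated and flagged with
#'   attribute `partial = TRUE` plus the time reached.
#' @examples
#' tr <- integrate_switch(c(M = 1, A = 1), glucose = 0.5, t_span = c(0, 50))
#' tail(tr, 1)
#' @export
integrate_switch <- function(initial, glucose, params = switch_params(),
                             t_span = c(0, 100), n_out = 400L,
                             rtol = 1e-8, atol = 1e-10) {
  if (!is_switch_params(params)) abort("integrate_switch: bad `params`")
  if (length(initial) != 2L || any(initial < 0)) {
    abort("integrate_switch: `initial` must be two nonnegative values (M, A)")
  }
  gfun <- if (is.function(glucose)) glucose else function(t) rep_len(glucose, length(t))
  times <- seq(t_span[1], t_span[2], length.out = n_out)
  gt <- gfun(times)
  if (any(!is.finite(gt)) || any(gt < 0)) {
    abort("integrate_switch: glucose waveform must be nonnegative on t_span")
  }
  rhs <- function(t, y, parms) {
    g <- gfun(t)
    d <- switch_rhs_raw(max(y[1], 0), max(y[2], 0), g, parms)
    list(c(d$dM, d$dA))
  }
  sol <- deSolve::ode(y = c(M = unname(initial[1]), A = unname(initial[2])),
                      times = times, func = rhs, parms = params,
                      method = "lsoda", rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  partial <- nrow(out) < length(times)
  tr <- tibble(time = out$time, M = out$M, A = out$A, G = gfun(out$time))
  attr(tr, "params") <- params
  attr(tr, "partial") <- partial
  if (partial) {
    attr(tr, "time_reached") <- max(out$time)
    warn(sprintf("integrate_switch: integrator stopped early at t = %g",
                 max(out$time)))
  }
  class(tr) <- c("switch_trajectory", class(tr))
  tr
}

#' Steady states of the switch at a fixed glucose level
#'
#' Finds all equilibria of the switch for glucose input `G`. `A` is
#' eliminated through its nullcline and the scalar residual in `M` is
#' scanned for sign changes on a dense grid over the production-bounded
#' box `[0, G + k1]`, followed by root polishing; duplicates closer than
#' `1e-8` are merged. Stability is classified from the eigenvalues of the
#' analytic 2x2 Jacobian.
#'
#' @param G Glucose input level, a nonnegative scalar.
#' @param params A [switch_params()] object.
#' @param dM Scan resolution as a fraction of the `M` box (default
#'   `1e-4`).
#' @return A tibble with columns `G`, `M`, `A`, `stability`
#'   (`"stable"`/`"unstable"`), ordered by increasing `M`.
#' @examples
#' steady_states(0.5)
#' @export
steady_states <- function(G, params = switch_params(), dM = 1e-4) {
  if (!is_switch_params(params)) abort("steady_states: bad `params`")
  if (!is.numeric(G) || length(G) != 1L || !is.finite(G) || G < 0) {
    abort("steady_states: `G` must be a nonnegative scalar")
  }
  M_hi <- G + params$k1
  grid <- seq(0, M_hi, by = dM * max(M_hi, 1))
  r <- steady_residual(grid, G, params)
  idx <- which(diff(sign(r)) != 0)
  roots <- vapply(idx, function(j) {
    uniroot(steady_residual, c(grid[j], grid[j + 1]), G = G, p = params,
            tol = 1e-12)$root
  }, numeric(1))
  # exact zeros on the grid (e.g. the origin with all production off)
  zero_hits <- grid[abs(r) < 1e-14]
  roots <- sort(c(roots, zero_hits))
  if (length(roots) > 1L) {
    roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  }
  # Newton polish to residual ~ 1e-10
  for (k in seq_along(roots)) {
    for (i in 1:8) {
      f0 <- steady_residual(roots[k], G, params)
      if (abs(f0) < 1e-12) break
      h <- 1e-7
      fp <- (steady_residual(roots[k] + h, G, params) - f0) / h
      if (!is.finite(fp) || abs(fp) < 1e-12) break
      roots[k] <- max(roots[k] - f0 / fp, 0)
    }
  }
  A <- a_nullcline(roots, params)
  stab <- vapply(seq_along(roots), function(k) {
    J <- switch_jacobian(roots[k], A[k], G, params)
    ev <- eigen(J, only.values = TRUE)$values
    if (max(Re(ev)) < 0) "stable" else "unstable"
  }, character(1))
  tibble(G = rep(G, length(roots)), M = roots, A = A, stability = stab)
}

#' Equilibrium continuation of the switch over a glucose range
#'
#' Assembles the S-shaped equilibrium curve `M*(G)` by computing all
#' steady states on a glucose grid and locating the saddle-node (fold)
#' points, where the equilibrium count changes, by bisection to
#' `|dG| <= 1e-4`. For the default parameters the curve is bistable
#' between the two folds: the upper and lower branches are stable and the
#' middle branch is unstable.
#'
#' @param params A [switch_params()] object.
#' @param G_range Length-2 nonnegative numeric, glucose interval.
#' @param G_resolution Spacing of the continuation grid.
#' @return An object of class `equilibrium_branch`: a list with `points`
#'   (tibble `G`, `M`, `A`, `stability`, `branch`), `fold_low`,
#'   `fold_high` (both `NA` when the curve is monotone), and `params`.
#' @examples
#' br <- continue_branch(G_resolution = 0.01)
#' glance(br)
#' @export
continue_branch <- function(params = switch_params(), G_range = c(0, 1),
                            G_resolution = 0.002) {
  if (!is_switch_params(params)) abort("continue_branch: bad `params`")
  if (any(G_range < 0) || diff(G_range) <= 0) {
    abort("continue_branch: `G_range` must be an increasing nonnegative interval")
  }
  if (G_resolution <= 0) abort("continue_branch: `G_resolution` must be > 0")
  Gs <- seq(G_range[1], G_range[2], by = G_resolution)
  pts <- purrr::map(Gs, steady_states, params = params)
  counts <- vapply(pts, nrow, integer(1))
  n_eq <- function(G) nrow(steady_states(G, params))
  bisect_fold <- function(lo, hi) {
    # invariant: count differs between lo and hi
    c_lo <- n_eq(lo)
    while (hi - lo > 1e-4) {
      mid <- (lo + hi) / 2
      if (n_eq(mid) == c_lo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  multi <- which(counts >= 3)
  if (length(multi) == 0L) {
    fold_low <- NA_real_
    fold_high <- NA_real_
  } else {
    i_lo <- min(multi); i_hi <- max(multi)
    fold_low <- if (i_lo > 1L) bisect_fold(Gs[i_lo - 1L], Gs[i_lo]) else Gs[1]
    fold_high <- if (i_hi < length(Gs)) bisect_fold(Gs[i_hi], Gs[i_hi + 1L]) else Gs[length(Gs)]
  }
  # branch labels by nearest-neighbor continuation in M: with <=3 roots the
  # ordered roots map onto lower/middle/upper; single roots attach to the
  # branch they continue (lower left of the window, upper right of it).
  label_one <- function(tb) {
    k <- nrow(tb)
    if (k == 3L) {
      tb$branch <- c("lower", "middle", "upper")
    } else if (k == 1L) {
      tb$branch <- if (!is.na(fold_low) && tb$G[1] >= fold_low) "upper" else "lower"
      if (is.na(fold_low)) tb$branch <- "lower"
    } else {
      # fold point itself (2 roots): outermost root keeps its branch
      tb$branch <- if (tb$G[1] > mean(G_range)) c("lower", "upper") else c("lower", "upper")
    }
    tb
  }
  points <- dplyr::bind_rows(purrr::map(pts, label_one))
  structure(list(points = points, fold_low = fold_low, fold_high = fold_high,
                 params = params, G_range = G_range,
                 G_resolution = G_resolution),
            class = "equilibrium_branch")
}

#' @export
print.equilibrium_branch <- function(x, ...) {
  cat("<equilibrium_branch>\n")
  if (is.na(x$fold_low)) {
    cat("  monotone branch, no folds\n")
  } else {
    cat(sprintf("  saddle-node folds: G = %.4f (lower), %.4f (upper)\n",
                x$fold_low, x$fold_high))
    cat(sprintf("  bistable window: %.4f < G < %.4f\n", x$fold_low, x$fold_high))
  }
  cat(sprintf("  %d equilibrium points on G in [%g, %g]\n",
              nrow(x$points), x$G_range[1], x$G_range[2]))
  invisible(x)
}

#' Predicted miR-451 reduction under glucose deprivation
#'
#' Emulates the glucose-deprivation experiment (cells cultured in normal
#' 4.5 g/l versus reduced 0.3 g/l glucose): the high-glucose state is the
#' upper-branch equilibrium at `G_high`; the low-glucose state is the
#' equilibrium reached from it when glucose is stepped down to `G_low`,
#' which is history-consistent -- the system stays on the upper branch
#' until `G_low` falls below the lower fold, and only then drops to the
#' low-miR-451 branch.
#'
#' @param params A [switch_params()] object.
#' @param G_high Dimensionless glucose of the normal-glucose condition;
#'   default 1.0, on the monostable upper region above the upper fold.
#' @param G_low Dimensionless glucose of the deprived condition; default
#'   preserves the experimental 0.3/4.5 g/l ratio.
#' @return A one-row tibble with `G_high`, `G_low`, `M_high`, `M_low`,
#'   `percent_reduction` = `100 (1 - M_low/M_high)`, and `distinct_state`
#'   (`FALSE`, with a warning, when `G_low` lies above the upper fold so
#'   no separate low state exists).
#' @examples
#' glucose_deprivation_response()
#' @export
glucose_deprivation_response <- function(params = switch_params(),
                                         G_high = 1.0,
                                         G_low = G_high * 0.3 / 4.5) {
  if (G_high < G_low || G_low < 0) {
    abort("glucose_deprivation_response: need G_high >= G_low >= 0")
  }
  br <- continue_branch(params,
                        G_range = c(0, max(G_high, 1) + 1e-6),
                        G_resolution = 0.002)
  eq_hi <- steady_states(G_high, params)
  M_high <- max(eq_hi$M[eq_hi$stability == "stable"])
  eq_lo <- steady_states(G_low, params)
  stable_lo <- eq_lo[eq_lo$stability == "stable", ]
  distinct <- TRUE
  if (!is.na(br$fold_high) && G_low >= br$fold_low) {
    # history-consistent: coming down from high glucose the system stays on
    # the upper branch through the bistable window
    M_low <- max(stable_lo$M)
    if (G_low > br$fold_high) {
      distinct <- FALSE
      warn("glucose_deprivation_response: G_low above the upper fold; no distinct low-glucose state")
    }
  } else {
    M_low <- min(stable_lo$M)
  }
  tibble(G_high = G_high, G_low = G_low, M_high = M_high, M_low = M_low,
         percent_reduction = 100 * (1 - M_low / M_high),
         distinct_state = distinct)
}
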