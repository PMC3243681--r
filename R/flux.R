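# Taxis velocity at interior faces: saturating chemotaxis up glucose
# gradients plus saturating haptotaxis up ECM gradients. Kept in one place
# because the saturation forms are the movement model's calibration point.
taxis_velocity <- function(G, rho, grid, params) {
  dx <- grid$dx
  dG <- diff(G) / dx
  drho <- diff(rho) / dx
  G_face <- (G[-1] + G[-length(G)]) / 2
  rho_face <- (rho[-1] + rho[-length(rho)]) / 2
  params$chi / (1 + params$chi_sat * G_face) * dG +
    params$h_hapto / (1 + params$hapto_sat * rho_face) * drho
}

#' Movement flux of the tumor field
#'
#' Computes the finite-volume face fluxes of the tumor cell density:
#' random motility `-D_n dn/dx` (central differences) plus advective
#' chemotaxis and haptotaxis, `n v` with the saturating taxis velocity
#' `v = chi/(1 + chi_sat G) dG/dx + h_hapto/(1 + hapto_sat rho) drho/dx`,
#' discretized with first-order upwinding. Both domain boundaries are
#' zero-flux, so pure transport conserves total mass to round-off.
#'
#' @param n Tumor density per cell (nonnegative).
#' @param G Glucose field on the same grid.
#' @param rho ECM field on the same grid.
#' @param grid A [grid1d()].
#' @param params A [pde_params()] object.
#' @return Numeric vector of `n_cells + 1` face fluxes (first and last 0).
#' @examples
#' g <- grid1d(20)
#' movement_flux(rep(1, 20), rep(0.5, 20), rep(1, 20), g, pde_params())
#' @export
movement_flux <- function(n, G, rho, grid, params = pde_params()) {
  if (any(n < 0) || any(G < 0) || any(rho < 0)) {
    abort("movement_flux: fields must be nonnegative")
  }
  nc <- grid$n_cells
  if (length(n) != nc || length(G) != nc || length(rho) != nc) {
    abort("movement_flux: fields must live on `grid`")
  }
  v <- taxis_velocity(G, rho, grid, params)
  n_up <- ifelse(v >= 0, n[-nc], n[-1])        # upwind donor cell
  diffusive <- -params$D_n * diff(n) / grid$dx # central
  c(0, diffusive + v * n_up, 0)
}

#' Local reaction terms of the six-field model
#'
#' Evaluates the non-transport right-hand sides in every cell:
#' * tumor: logistic growth `r_growth n (1 - n)` weighted by the smoothed
#'   growth indicator of the local miR-451 level;
#' * ECM: degradation by MMP `-d_rho P rho` plus logistic remodeling
#'   `r_rho rho (1 - rho)` toward carrying capacity 1;
#' * MMP: production `a_P n rho` by (invasion-weighted) cells in the
#'   presence of ECM, minus linear decay `d_P P`;
#' * glucose: consumption `-lambda_G n G` plus the injection source;
#' * miR-451/AMPK: the switch equations driven by the local glucose
#'   signal `G / G_signal_scale`.
#'
#' @param fields A [field_set()].
#' @param params A [pde_params()] object.
#' @param glucose_source Per-cell glucose supply rate (already
#'   `g_in * indicator`); default 0.
#' @return A list of per-cell derivatives `dn`, `drho`, `dP`, `dG`, `dM`,
#'   `dA`.
#' @examples
#' g <- grid1d(10)
#' f <- initial_conditions("default", g, pde_params())
#' str(reaction_terms(f, pde_params()))
#' @export
reaction_terms <- function(fields, params = pde_params(), glucose_source = 0) {
  w <- phase_indicators(fields$M, params$switch$M_th, params$smoothing_width)
  p_gate <- if (params$mmp_invasion_gated) w$invasion else 1
  sw <- switch_rhs_raw(fields$M, fields$A, fields$G / params$G_signal_scale,
                       params$switch)
  list(
    dn = w$growth * params$r_growth * fields$n * (1 - fields$n),
    drho = -params$d_rho * fields$P * fields$rho +
      params$r_rho * fields$rho * (1 - fields$rho),
    dP = params$a_P * p_gate * fields$n * fields$rho - params$d_P * fields$P,
    dG = -params$lambda_G * fields$n * fields$G + glucose_source,
    dM = sw$dM,
    dA = sw$dA
  )
}
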