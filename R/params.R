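#' Parameters of the miR-451/AMPK switch
#'
#' Constructs the dimensionless parameter set of the two-variable
#' mutual-antagonism network between miR-451 (`M`) and the CAB39/LKB1/AMPK
#' complex (`A`). Defaults are the values used throughout the glioma
#' growth-invasion model:
#'
#' \deqn{dM/dt = G + k_1 k_2^2 / (k_2^2 + \alpha A^2) - M}
#' \deqn{dA/dt = \epsilon \, (S + k_3 k_4^2 / (k_4^2 + \beta M^2) - A)}
#'
#' Glucose input `G` drives miR-451; each species has a bounded
#' autocatalytic production term inhibited by the other, plus linear decay.
#' Because miR-451 turns over much faster than the kinase complex, the
#' complex dynamics carry the small factor `eps`, making `A` the slow
#' variable.
#'
#' @param k1 miR-451 autocatalytic production rate (dimensionless).
#' @param k2 Half-max (inhibition) parameter of miR-451 production by the
#'   AMPK complex.
#' @param alpha Inhibition strength of miR-451 by the AMPK complex.
#' @param k3 AMPK-complex autocatalytic production rate.
#' @param k4 Half-max (inhibition) parameter of AMPK-complex production by
#'   miR-451.
#' @param beta Inhibition strength of the AMPK complex by miR-451.
#' @param S Constant signaling source of the AMPK complex.
#' @param eps Time-scale separation factor; ratio of AMPK-complex to
#'   miR-451 degradation rates. Must be positive.
#' @param M_th miR-451 threshold separating the migratory regime
#'   (`M < M_th`) from the proliferative regime (`M > M_th`).
#'
#' @return An object of class `switch_params` (a named list).
#' @examples
#' p <- switch_params()
#' p$alpha
#' @export
switch_params <- function(k1 = 4.0, k2 = 1.0, alpha = 1.6,
                          k3 = 4.0, k4 = 1.0, beta = 1.0,
                          S = 0.2, eps = 0.02, M_th = 2.0) {
  p <- list(k1 = k1, k2 = k2, alpha = alpha, k3 = k3, k4 = k4,
            beta = beta, S = S, eps = eps, M_th = M_th)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("switch_params: `%s` must be a finite numeric scalar", nm))
    }
    if (v < 0) {
      abort(sprintf("switch_params: `%s` must be nonnegative (got %g)", nm, v))
    }
  }
  if (p$eps <= 0) abort("switch_params: `eps` must be strictly positive")
  structure(p, class = "switch_params")
}

#' @export
print.switch_params <- function(x, ...) {
  cat("<switch_params>\n")
  cat(sprintf("  production: k1 = %g (half-max k2 = %g), k3 = %g (half-max k4 = %g)\n",
              x$k1, x$k2, x$k3, x$k4))
  cat(sprintf("  inhibition: alpha = %g (A -| M), beta = %g (M -| A)\n",
              x$alpha, x$beta))
  cat(sprintf("  source S = %g, eps = %g, M_th = %g\n", x$S, x$eps, x$M_th))
  invisible(x)
}

is_switch_params <- function(x) inherits(x, "switch_params")

#' Parameters of the spatial growth-invasion model
#'
#' Constructs the dimensionless parameter set for the one-dimensional
#' six-field model: tumor cell density `n`, extracellular matrix (ECM)
#' density `rho`, matrix metalloproteinase (MMP) concentration `P`,
#' glucose `G`, and the intracellular switch fields `M` (miR-451) and
#' `A` (AMPK complex). Length is scaled to a 1 cm domain and time to
#' hours.
#'
#' Rate constants `r_growth`, `d_rho`, `r_rho`, `a_P`, `d_P` and
#' `lambda_G` default to the published dimensionless values. The
#' transport coefficients (`D_n`, `D_P`, `D_G`, `chi`, `h_hapto`) and the
#' glucose coupling scale default to estimates from dimensional diffusion
#' data, calibrated so that the default scenarios reproduce the expected
#' qualitative regimes (see the methods vignette).
#'
#' @param D_n Tumor cell random motility coefficient (dimensionless).
#' @param D_P MMP diffusion coefficient; small, so MMP stays localized at
#'   the invasive front.
#' @param D_G Glucose diffusion coefficient.
#' @param r_growth Tumor logistic growth rate (carrying capacity 1).
#' @param d_rho ECM degradation rate by MMP.
#' @param r_rho ECM remodeling/reconstruction rate (logistic, capacity 1).
#' @param a_P MMP production rate by invasive cells in presence of ECM.
#' @param d_P MMP decay rate.
#' @param lambda_G Glucose consumption rate by tumor cells.
#' @param chi Chemotactic sensitivity toward glucose gradients.
#' @param chi_sat Saturation parameter of the chemotactic velocity,
#'   `v = chi / (1 + chi_sat * G) * dG/dx`.
#' @param h_hapto Haptotactic coefficient toward ECM gradients.
#' @param hapto_sat Saturation parameter of the haptotactic velocity,
#'   `v = h_hapto / (1 + hapto_sat * rho) * drho/dx`.
#' @param switch A [switch_params()] object with the intracellular
#'   network parameters.
#' @param smoothing_width Width (in miR-451 units) of the smoothed
#'   growth/invasion indicator functions.
#' @param G_signal_scale Glucose concentration (in PDE units) that
#'   corresponds to one unit of the switch's dimensionless glucose input;
#'   couples the extracellular glucose field to the intracellular network.
#' @param G_init Initial uniform glucose level of the default scenario.
#' @param tumor_width Initial tumor support width (left-adjacent plateau).
#' @param front_width Smoothing width of the initial tumor front.
#' @param rho_inside Initial ECM density inside the tumor support.
#' @param mmp_invasion_gated Logical; if `TRUE` (default) MMP production
#'   is gated by the invasion indicator, so only migratory cells secrete
#'   MMP.
#'
#' @return An object of class `pde_params` (a named list).
#' @examples
#' pde_params()$r_growth
#' @export
pde_params <- function(D_n = 1e-4, D_P = 3e-5, D_G = 2.4e-2,
                       r_growth = 0.1, d_rho = 0.508, r_rho = 0.18,
                       a_P = 2.5, d_P = 0.18, lambda_G = 1.0,
                       chi = 0.15, chi_sat = 10, h_hapto = 2e-3,
                       hapto_sat = 1, switch = switch_params(),
                       smoothing_width = 0.05, G_signal_scale = 0.00215,
                       G_init = 0.001, tumor_width = 0.1,
                       front_width = 0.02, rho_inside = 0.5,
                       mmp_invasion_gated = TRUE) {
  if (!is_switch_params(switch)) {
    abort("pde_params: `switch` must be a switch_params object")
  }
  num <- list(D_n = D_n, D_P = D_P, D_G = D_G, r_growth = r_growth,
              d_rho = d_rho, r_rho = r_rho, a_P = a_P, d_P = d_P,
              lambda_G = lambda_G, chi = chi, chi_sat = chi_sat,
              h_hapto = h_hapto, hapto_sat = hapto_sat,
              smoothing_width = smoothing_width,
              G_signal_scale = G_signal_scale, G_init = G_init,
              tumor_width = tumor_width, front_width = front_width,
              rho_inside = rho_inside)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(sprintf("pde_params: `%s` must be a nonnegative finite scalar", nm))
    }
  }
  if (smoothing_width <= 0) abort("pde_params: `smoothing_width` must be > 0")
  if (G_signal_scale <= 0) abort("pde_params: `G_signal_scale` must be > 0")
  p <- c(num, list(switch = switch,
                   mmp_invasion_gated = isTRUE(mmp_invasion_gated)))
  structure(p, class = "pde_params")
}

#' @export
print.pde_params <- function(x, ...) {
  cat("<pde_params>\n")
  cat(sprintf("  diffusion: D_n = %g, D_P = %g, D_G = %g\n", x$D_n, x$D_P, x$D_G))
  cat(sprintf("  rates: r_growth = %g, d_rho = %g, r_rho = %g, a_P = %g, d_P = %g, lambda_G = %g\n",
              x$r_growth, x$d_rho, x$r_rho, x$a_P, x$d_P, x$lambda_G))
  cat(sprintf("  taxis: chi = %g (sat %g), h_hapto = %g (sat %g)\n",
              x$chi, x$chi_sat, x$h_hapto, x$hapto_sat))
  cat(sprintf("  coupling: G_signal_scale = %g, smoothing_width = %g\n",
              x$G_signal_scale, x$smoothing_width))
  cat("  switch: "); print(x$switch)
  invisible(x)
}

is_pde_params <- function(x) inherits(x, "pde_params")
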