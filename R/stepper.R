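#' Time-stepping controls
#'
#' The full system is advanced by Strang operator splitting: a half step
#' of transport (upwinded taxis and explicit motility for the tumor
#' field, implicit diffusion for MMP and glucose), a full step of the
#' local reactions (classical RK4 with substepping, split exactly at
#' injection pulse edges), and a second transport half step. The step
#' size is fixed within each output interval -- which keeps runs
#' bit-reproducible and independent of the output cadence -- and is
#' halved and the interval retried when a sub-step produces negative or
#' non-finite values, down to `dt_min`.
#'
#' @param dt Nominal step size in hours.
#' @param dt_min Smallest step size before the run aborts.
#' @param cfl Advective CFL number bounding `|v| dt / dx`.
#' @param rk_max_h Largest RK4 substep for the local reactions.
#' @return An object of class `time_stepper`.
#' @examples
#' time_stepper()
#' @export
time_stepper <- function(dt = 0.01, dt_min = 1e-6, cfl = 0.9, rk_max_h = 0.02) {
  if (dt <= 0 || dt_min <= 0 || dt < dt_min) {
    abort("time_stepper: need dt >= dt_min > 0")
  }
  if (cfl <= 0 || cfl > 1) abort("time_stepper: `cfl` must be in (0, 1]")
  structure(list(dt = dt, dt_min = dt_min, cfl = cfl, rk_max_h = rk_max_h),
            class = "time_stepper")
}

#' @export
print.time_stepper <- function(x, ...) {
  cat(sprintf("<time_stepper> Strang splitting, dt = %g h (min %g), CFL %g\n",
              x$dt, x$dt_min, x$cfl))
  invisible(x)
}

# Backward-Euler diffusion solver with cached dense inverses. The
# finite-volume Laplacian with zero-flux boundaries has zero column sums,
# so the implicit update conserves the field total to round-off and, being
# an M-matrix solve, preserves positivity.
make_diffusion_solver <- function(grid) {
  cache <- new.env(parent = emptyenv())
  nc <- grid$n_cells
  dx2 <- grid$dx^2
  L <- diag(-2, nc)
  L[cbind(1:(nc - 1), 2:nc)] <- 1
  L[cbind(2:nc, 1:(nc - 1))] <- 1
  L[1, 1] <- -1
  L[nc, nc] <- -1
  function(field, D, h) {
    if (D == 0 || h == 0) return(field)
    key <- paste(D, h, sep = "|")
    Ainv <- cache[[key]]
    if (is.null(Ainv)) {
      Ainv <- solve(diag(nc) - (h * D / dx2) * L)
      cache[[key]] <- Ainv
    }
    as.vector(Ainv %*% field)
  }
}

# Transport half step: tumor movement (gated by the invasion indicator at
# faces) plus MMP and glucose diffusion.
transport_substep <- function(fields, h, grid, params, diffuse) {
  w <- phase_indicators(fields$M, params$switch$M_th, params$smoothing_width)
  nc <- grid$n_cells
  w_face <- (w$invasion[-1] + w$invasion[-nc]) / 2
  flux <- movement_flux(fields$n, fields$G, fields$rho, grid, params)
  flux[2:nc] <- flux[2:nc] * w_face
  fields$n <- fields$n - h / grid$dx * diff(flux)
  fields$P <- diffuse(fields$P, params$D_P, h)
  fields$G <- diffuse(fields$G, params$D_G, h)
  fields
}

# Largest advective face speed after gating; 0 for uniform fields.
max_face_speed <- function(fields, grid, params) {
  w <- phase_indicators(fields$M, params$switch$M_th, params$smoothing_width)
  nc <- grid$n_cells
  w_face <- (w$invasion[-1] + w$invasion[-nc]) / 2
  v <- taxis_velocity(fields$G, fields$rho, grid, params)
  max(abs(v * w_face), 0)
}

# One classical RK4 substep of the local reactions, tracking the glucose
# consumption integral alongside the state for budget diagnostics.
rk4_react <- function(fields, h, src, params, dx) {
  lam <- params$lambda_G
  stage <- function(f) {
    d <- reaction_terms(f, params, src)
    d$consumed <- lam * sum(f$n * f$G) * dx
    d
  }
  adv <- function(f, d, a) {
    list(n = f$n + a * d$dn, rho = f$rho + a * d$drho, P = f$P + a * d$dP,
         G = f$G + a * d$dG, M = f$M + a * d$dM, A = f$A + a * d$dA)
  }
  f0 <- fields
  d1 <- stage(f0)
  d2 <- stage(adv(f0, d1, h / 2))
  d3 <- stage(adv(f0, d2, h / 2))
  d4 <- stage(adv(f0, d3, h))
  out <- list(
    n = f0$n + h / 6 * (d1$dn + 2 * d2$dn + 2 * d3$dn + d4$dn),
    rho = f0$rho + h / 6 * (d1$drho + 2 * d2$drho + 2 * d3$drho + d4$drho),
    P = f0$P + h / 6 * (d1$dP + 2 * d2$dP + 2 * d3$dP + d4$dP),
    G = f0$G + h / 6 * (d1$dG + 2 * d2$dG + 2 * d3$dG + d4$dG),
    M = f0$M + h / 6 * (d1$dM + 2 * d2$dM + 2 * d3$dM + d4$dM),
    A = f0$A + h / 6 * (d1$dA + 2 * d2$dA + 2 * d3$dA + d4$dA)
  )
  attr(out, "consumed") <- h / 6 *
    (d1$consumed + 2 * d2$consumed + 2 * d3$consumed + d4$consumed)
  out
}

# Full reaction step over [t0, t0 + dt]: split at pulse edges so the
# glucose source is constant on every RK4 piece, making the injected dose
# exact to round-off.
reaction_substep <- function(fields, t0, dt, grid, params, schedule, rk_max_h) {
  edges <- c(t0, pulse_breakpoints(t0, t0 + dt, schedule), t0 + dt)
  consumed <- 0
  injected <- 0
  for (k in seq_len(length(edges) - 1L)) {
    a <- edges[k]; b <- edges[k + 1L]
    len <- b - a
    if (len <= 0) next
    src <- schedule$g_in * injection_source((a + b) / 2, schedule, grid)
    n_sub <- max(1L, ceiling(len / rk_max_h))
    h <- len / n_sub
    for (s in seq_len(n_sub)) {
      fields <- rk4_react(fields, h, src, params, grid$dx)
      consumed <- consumed + attr(fields, "consumed")
    }
    injected <- injected + sum(src) * grid$dx * len
  }
  attr(fields, "consumed") <- consumed
  attr(fields, "injected") <- injected
  fields
}

# Clamp round-off negatives; larger undershoots are a step failure.
sanitize_fields <- function(fields) {
  for (nm in c("n", "rho", "P", "G", "M", "A")) {
    v <- fields[[nm]]
    if (any(!is.finite(v)) || any(v < -1e-9)) return(NULL)
    v[v < 0] <- 0
    fields[[nm]] <- v
  }
  fields
}

#' Advance the full system by one composite step
#'
#' Performs one Strang-split step `transport(dt/2) - reactions(dt) -
#' transport(dt/2)` of the six-field model. Exposed mainly for testing;
#' scenario runs use [run_scenario()].
#'
#' @param fields A [field_set()] (or plain list of the six fields).
#' @param t Current time in hours.
#' @param dt Step size.
#' @param grid A [grid1d()].
#' @param params A [pde_params()].
#' @param schedule An [injection_schedule()].
#' @param stepper A [time_stepper()] (supplies the RK substep cap).
#' @param diffuse Optional diffusion solver from an enclosing run; built
#'   on the fly when missing.
#' @return The updated fields with attributes `consumed` and `injected`
#'   (glucose amounts over the step), or `NULL` if the step failed and
#'   should be retried with a smaller `dt`.
#' @examples
#' g <- grid1d(20)
#' f <- initial_conditions("default", g, pde_params())
#' f2 <- step_fields(f, 0, 0.01, g, pde_params(), injection_schedule())
#' @export
step_fields <- function(fields, t, dt, grid, params = pde_params(),
                        schedule = injection_schedule(),
                        stepper = time_stepper(), diffuse = NULL) {
  if (is.null(diffuse)) diffuse <- make_diffusion_solver(grid)
  f <- transport_substep(fields, dt / 2, grid, params, diffuse)
  f <- sanitize_fields(f)
  if (is.null(f)) return(NULL)
  f <- reaction_substep(f, t, dt, grid, params, schedule, stepper$rk_max_h)
  consumed <- attr(f, "consumed"); injected <- attr(f, "injected")
  f <- sanitize_fields(f)
  if (is.null(f)) return(NULL)
  f <- transport_substep(f, dt / 2, grid, params, diffuse)
  f <- sanitize_fields(f)
  if (is.null(f)) return(NULL)
  attr(f, "consumed") <- consumed
  attr(f, "injected") <- injected
  f
}
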