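#' Scenario configuration
#'
#' Bundles everything a simulation run needs: grid, model parameters,
#' glucose supply schedule, initial-condition name, horizon and output
#' cadence. The model is fully deterministic, so identical configurations
#' produce identical results.
#'
#' @param grid A [grid1d()].
#' @param params A [pde_params()].
#' @param schedule An [injection_schedule()].
#' @param scenario Initial-condition name (see [initial_conditions()]).
#' @param t_end Simulation horizon in hours.
#' @param output_dt Cadence of recorded domain totals, in hours; must be
#'   a multiple of the stepper `dt`.
#' @param snapshot_dt Cadence of recorded full spatial profiles; must be
#'   a multiple of `output_dt` (use `Inf` to keep only the final state).
#' @param stepper A [time_stepper()].
#' @param label Optional run label carried into summaries.
#' @return An object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(t_end = 10)
#' @export
scenario_config <- function(grid = grid1d(), params = pde_params(),
                            schedule = injection_schedule(),
                            scenario = "default", t_end = 100,
                            output_dt = 0.5, snapshot_dt = 10,
                            stepper = time_stepper(), label = NULL) {
  if (!inherits(grid, "grid1d")) abort("scenario_config: `grid` must be grid1d")
  if (!is_pde_params(params)) abort("scenario_config: `params` must be pde_params")
  if (!inherits(schedule, "injection_schedule")) {
    abort("scenario_config: `schedule` must be an injection_schedule")
  }
  if (!inherits(stepper, "time_stepper")) {
    abort("scenario_config: `stepper` must be a time_stepper")
  }
  if (t_end <= 0) abort("scenario_config: `t_end` must be positive")
  if (output_dt <= 0 || output_dt > t_end) {
    abort("scenario_config: `output_dt` must lie in (0, t_end]")
  }
  if (!is.infinite(snapshot_dt) &&
      abs(snapshot_dt / output_dt - round(snapshot_dt / output_dt)) > 1e-9) {
    abort("scenario_config: `snapshot_dt` must be a multiple of `output_dt`")
  }
  structure(list(grid = grid, params = params, schedule = schedule,
                 scenario = scenario, t_end = t_end, output_dt = output_dt,
                 snapshot_dt = snapshot_dt, stepper = stepper, label = label),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", if (!is.null(x$label)) x$label else "", "\n")
  cat(sprintf("  scenario '%s', t_end = %g h, output every %g h\n",
              x$scenario, x$t_end, x$output_dt))
  print(x$grid); print(x$schedule); print(x$stepper)
  invisible(x)
}

# One row of domain totals + phase diagnostics.
totals_row <- function(t, fields, grid, params, injected, consumed) {
  dx <- grid$dx
  wsum <- sum(fields$n) * dx + 1e-6  # floor avoids empty-support division
  mean_M <- sum(fields$n * fields$M) * dx / wsum
  tibble(
    time = t,
    n_total = sum(fields$n) * dx,
    rho_total = sum(fields$rho) * dx,
    P_total = sum(fields$P) * dx,
    G_total = sum(fields$G) * dx,
    M_total = sum(fields$M) * dx,
    A_total = sum(fields$A) * dx,
    mean_M = mean_M,
    phase = if (mean_M > params$switch$M_th) "growth" else "invasion",
    injected_cum = injected,
    consumed_cum = consumed
  )
}

snapshot_rows <- function(t, fields, grid) {
  tibble(time = t, x = grid$centers, n = fields$n, rho = fields$rho,
         P = fields$P, G = fields$G, M = fields$M, A = fields$A)
}

#' Run a full growth-invasion scenario
#'
#' Advances the six-field model from its initial conditions to `t_end`,
#' recording domain totals (midpoint rule), the tumor-weighted mean
#' miR-451 level with its growth/invasion phase label, cumulative glucose
#' injection and consumption, and periodic spatial snapshots.
#'
#' @param config A [scenario_config()].
#' @return An object of class `scenario_result`: a list with `totals`
#'   (tibble, one row per output time), `snapshots` (long tibble of
#'   spatial profiles), `final` (the final [field_set()]), `config`,
#'   `partial` (TRUE when the stepper failed before `t_end`) and
#'   `diagnostics`.
#' @examples
#' res <- run_scenario(scenario_config(grid = grid1d(25), t_end = 2,
#'                                     output_dt = 0.5, snapshot_dt = 1))
#' res$totals$phase[1]
#' @export
run_scenario <- function(config) {
  if (!inherits(config, "scenario_config")) {
    abort("run_scenario: `config` must be a scenario_config")
  }
  grid <- config$grid; params <- config$params; schedule <- config$schedule
  stepper <- config$stepper
  diffuse <- make_diffusion_solver(grid)
  fields <- initial_conditions(config$scenario, grid, params)
  injected <- 0; consumed <- 0
  n_steps_total <- 0L; n_retries <- 0L
  out_times <- seq(0, config$t_end, by = config$output_dt)
  snap_every <- if (is.infinite(config$snapshot_dt)) NA_integer_ else
    as.integer(round(config$snapshot_dt / config$output_dt))
  totals_list <- vector("list", length(out_times))
  snaps_list <- list()
  totals_list[[1]] <- totals_row(0, fields, grid, params, injected, consumed)
  if (!is.na(snap_every)) snaps_list[["0"]] <- snapshot_rows(0, fields, grid)
  partial <- FALSE
  for (k in seq_len(length(out_times) - 1L)) {
    t0 <- out_times[k]; t1 <- out_times[k + 1L]
    interval <- t1 - t0
    # fixed dt within the interval, capped by the advective CFL condition
    v <- max_face_speed(fields, grid, params)
    dt_cap <- if (v > 0) stepper$cfl * grid$dx / v else Inf
    dt_try <- min(stepper$dt, dt_cap)
    repeat {
      n_sub <- max(1L, ceiling(interval / dt_try - 1e-12))
      dt <- interval / n_sub
      f <- fields; inj <- 0; cons <- 0; ok <- TRUE
      for (s in seq_len(n_sub)) {
        f2 <- step_fields(f, t0 + (s - 1L) * dt, dt, grid, params, schedule,
                          stepper, diffuse)
        if (is.null(f2)) { ok <- FALSE; break }
        inj <- inj + attr(f2, "injected")
        cons <- cons + attr(f2, "consumed")
        f <- f2
      }
      if (ok) {
        n_steps_total <- n_steps_total + n_sub
        break
      }
      n_retries <- n_retries + 1L
      dt_try <- dt_try / 2
      if (dt_try < stepper$dt_min) {
        warn(sprintf("run_scenario: step failure at t = %g below dt_min; returning partial result", t0))
        partial <- TRUE
        break
      }
    }
    if (partial) break
    fields <- f; injected <- injected + inj; consumed <- consumed + cons
    totals_list[[k + 1L]] <- totals_row(t1, fields, grid, params, injected, consumed)
    if (!is.na(snap_every) && (k %% snap_every == 0L)) {
      snaps_list[[as.character(t1)]] <- snapshot_rows(t1, fields, grid)
    }
  }
  totals <- dplyr::bind_rows(totals_list)
  snapshots <- if (length(snaps_list)) dplyr::bind_rows(snaps_list) else
    snapshot_rows(max(totals$time), fields, grid)[0, ]
  structure(list(totals = totals, snapshots = snapshots,
                 final = fields, config = config, partial = partial,
                 diagnostics = list(n_steps = n_steps_total,
                                    n_retries = n_retries,
                                    injected = injected,
                                    consumed = consumed)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>",
      if (!is.null(x$config$label)) x$config$label else "", "\n")
  tf <- tail(x$totals, 1)
  cat(sprintf("  t in [0, %g] h, %d output rows%s\n", tf$time,
              nrow(x$totals), if (x$partial) " (PARTIAL)" else ""))
  cat(sprintf("  final totals: n = %.4f, G = %.4f, mean M = %.3f (%s)\n",
              tf$n_total, tf$G_total, tf$mean_M, tf$phase))
  cat(sprintf("  glucose budget: injected %.5f, consumed %.5f\n",
              x$diagnostics$injected, x$diagnostics$consumed))
  invisible(x)
}

#' Equal-dose constant-supply twin of a pulsed scenario
#'
#' Returns a configuration identical to `config` except that the pulsed
#' glucose schedule is replaced by a continuous supply on the same band
#' delivering the same dose per period: rate `g_in * duration / tau`.
#' Comparing a scenario against its twin isolates the effect of glucose
#' *fluctuation* from the total amount supplied.
#'
#' @param config A [scenario_config()] with a pulsed schedule.
#' @return A [scenario_config()] with a constant schedule.
#' @examples
#' twin <- run_constant_supply_twin(scenario_config(t_end = 10))
#' twin$schedule$mode
#' @export
run_constant_supply_twin <- function(config) {
  if (!inherits(config, "scenario_config")) {
    abort("run_constant_supply_twin: `config` must be a scenario_config")
  }
  if (config$schedule$mode != "pulsed") {
    abort("run_constant_supply_twin: `config` must have a pulsed schedule")
  }
  sch <- config$schedule
  config$schedule <- injection_schedule(tau = sch$tau, g_in = sch$g_in,
                                        duration = sch$duration,
                                        band_width = sch$band_width,
                                        mode = "constant")
  config$label <- paste0(if (!is.null(config$label)) config$label else "run",
                         " (constant-supply twin)")
  config
}
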