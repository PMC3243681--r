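# Resolved configuration as a plain nested list of scalars (for YAML
# round-trips and run manifests).
config_to_list <- function(config) {
  sw <- config$params$switch
  pde <- config$params
  list(
    schema = "glioswitch/1",
    model = list(
      switch = sw[c("k1", "k2", "alpha", "k3", "k4", "beta", "S", "eps", "M_th")],
      pde = pde[c("D_n", "D_P", "D_G", "r_growth", "d_rho", "r_rho", "a_P",
                  "d_P", "lambda_G", "chi", "chi_sat", "h_hapto", "hapto_sat",
                  "smoothing_width", "G_signal_scale", "G_init", "tumor_width",
                  "front_width", "rho_inside", "mmp_invasion_gated")]
    ),
    grid = list(n_cells = config$grid$n_cells),
    schedule = config$schedule[c("tau", "g_in", "duration", "band_width", "mode")],
    scenario = list(name = config$scenario, t_end = config$t_end,
                    output_dt = config$output_dt,
                    snapshot_dt = config$snapshot_dt,
                    label = config$label),
    stepper = config$stepper[c("dt", "dt_min", "cfl", "rk_max_h")]
  )
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    abort(sprintf("load_config: unknown key(s) %s in `%s` (allowed: %s)",
                  paste0("'", bad, "'", collapse = ", "), where,
                  paste(allowed, collapse = ", ")))
  }
}

#' Load a scenario configuration from YAML
#'
#' Parses a structured YAML document into a fully defaulted
#' [scenario_config()]. Every field is optional -- an empty document
#' yields the canonical defaults -- but unknown keys are rejected with
#' the offending key named, and physically inconsistent combinations
#' (e.g. an injection `duration` not smaller than the period `tau`) fail
#' validation in the underlying constructors.
#'
#' @param path Path to a YAML file, or `NULL` when `text` is given.
#' @param text YAML source text (overrides `path`).
#' @return A [scenario_config()].
#' @examples
#' cfg <- load_config(text = "schedule: {tau: 20, g_in: 30}")
#' cfg$schedule$tau
#' @export
load_config <- function(path = NULL, text = NULL) {
  doc <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  check_keys(doc, c("schema", "model", "grid", "schedule", "scenario", "stepper"),
             "top level")
  model <- doc$model %||% list()
  check_keys(model, c("switch", "pde"), "model")
  check_keys(model$switch %||% list(),
             c("k1", "k2", "alpha", "k3", "k4", "beta", "S", "eps", "M_th"),
             "model.switch")
  pde_keys <- c("D_n", "D_P", "D_G", "r_growth", "d_rho", "r_rho", "a_P",
                "d_P", "lambda_G", "chi", "chi_sat", "h_hapto", "hapto_sat",
                "smoothing_width", "G_signal_scale", "G_init", "tumor_width",
                "front_width", "rho_inside", "mmp_invasion_gated")
  check_keys(model$pde %||% list(), pde_keys, "model.pde")
  check_keys(doc$grid %||% list(), "n_cells", "grid")
  check_keys(doc$schedule %||% list(),
             c("tau", "g_in", "duration", "band_width", "mode"), "schedule")
  check_keys(doc$scenario %||% list(),
             c("name", "t_end", "output_dt", "snapshot_dt", "label"), "scenario")
  check_keys(doc$stepper %||% list(),
             c("dt", "dt_min", "cfl", "rk_max_h"), "stepper")
  sw <- do.call(switch_params, model$switch %||% list())
  params <- do.call(pde_params, c(model$pde %||% list(), list(switch = sw)))
  grid <- do.call(grid1d, doc$grid %||% list())
  schedule <- do.call(injection_schedule, doc$schedule %||% list())
  sc <- doc$scenario %||% list()
  args <- list(grid = grid, params = params, schedule = schedule,
               stepper = do.call(time_stepper, doc$stepper %||% list()))
  if (!is.null(sc$name)) args$scenario <- sc$name
  for (nm in c("t_end", "output_dt", "snapshot_dt", "label")) {
    if (!is.null(sc[[nm]])) args[[nm]] <- sc[[nm]]
  }
  do.call(scenario_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a scenario configuration to YAML
#'
#' Inverse of [load_config()]: the emitted YAML reloads to an identical
#' configuration.
#'
#' @param config A [scenario_config()].
#' @return A YAML string.
#' @examples
#' cat(serialize_config(scenario_config(t_end = 10)))
#' @export
serialize_config <- function(config) {
  lst <- config_to_list(config)
  lst$scenario$label <- lst$scenario$label %||% NULL
  yaml::as.yaml(lst, precision = 15)
}

fmt_tbl <- function(tb) {
  as.data.frame(lapply(tb, function(col) {
    if (is.numeric(col)) sprintf("%.10g", col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a scenario result to tabular text files
#'
#' Writes `totals.tsv` (per-time domain totals and phase labels),
#' `snapshots.tsv` (spatial profiles) and `manifest.json` (the fully
#' resolved configuration, package version and a partial-run flag) into
#' `dir`. Column order and float formatting are fixed, so two runs of the
#' same configuration produce byte-identical files.
#'
#' @param result A [run_scenario()] result (complete or flagged partial).
#' @param dir Destination directory; created if missing.
#' @return Invisibly, the paths written.
#' @export
write_series <- function(result, dir) {
  if (!inherits(result, "scenario_result")) {
    abort("write_series: `result` must be a scenario_result")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("write_series: cannot create '%s'", dir))
  paths <- c(totals = file.path(dir, "totals.tsv"),
             snapshots = file.path(dir, "snapshots.tsv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.table(fmt_tbl(result$totals), paths["totals"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fmt_tbl(result$snapshots), paths["snapshots"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    config = config_to_list(result$config),
    package_version = as.character(utils::packageVersion("glioswitch")),
    partial = result$partial,
    diagnostics = result$diagnostics[c("n_steps", "n_retries")]
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             paths["manifest"])
  invisible(paths)
}

#' Canonical figure-style fixture scenarios
#'
#' Named, fully specified setups used throughout the tests and examples.
#' Switch-level fixtures return parameter lists; spatial fixtures return
#' [scenario_config()] objects (or named lists of them for sweeps).
#'
#' * `"fig4_branch"`: equilibrium continuation over glucose in `[0, 1]`.
#' * `"fig5_deprivation"`: normal- vs low-glucose protocol (ratio
#'   0.3/4.5).
#' * `"fig7_periodic"`: periodic far-field injections, `tau` = 10 h,
#'   `g_in` = 5, 100 h horizon.
#' * `"fig9_twin"`: the periodic scenario plus its equal-dose
#'   constant-supply twin.
#' * `"fig10_alpha_sweep"`: inhibition of miR-451 by AMPK lowered from
#'   the control `alpha` = 1.6.
#' * `"fig11_beta_sweep"`: inhibition of AMPK by miR-451 raised from the
#'   control `beta` = 1.0.
#' * `"fig12_grid"`: the four injection regimes `tau` in \{10, 50\} h by
#'   `g_in` in \{5, 30\}.
#'
#' @param name Fixture name.
#' @return See above; sweeps carry a `control` attribute.
#' @examples
#' names(fixture("fig12_grid"))
#' @export
fixture <- function(name) {
  all_names <- c("fig4_branch", "fig5_deprivation", "fig7_periodic",
                 "fig9_twin", "fig10_alpha_sweep", "fig11_beta_sweep",
                 "fig12_grid")
  if (!name %in% all_names) {
    abort(sprintf("fixture: unknown fixture '%s'; available: %s",
                  name, paste(all_names, collapse = ", ")))
  }
  base <- function(tau, g_in, label, params = pde_params()) {
    scenario_config(schedule = injection_schedule(tau = tau, g_in = g_in),
                    params = params, t_end = 100, label = label)
  }
  switch(name,
    fig4_branch = list(kind = "branch", params = switch_params(),
                       G_range = c(0, 1), G_resolution = 0.002),
    fig5_deprivation = list(kind = "deprivation", params = switch_params(),
                            G_high = 1.0, G_low = 1.0 * 0.3 / 4.5),
    fig7_periodic = base(10, 5, "fig7_periodic"),
    fig9_twin = {
      pulsed <- base(10, 5, "fig9_pulsed")
      list(pulsed = pulsed, constant = run_constant_supply_twin(pulsed))
    },
    fig10_alpha_sweep = {
      alphas <- c(0.8, 1.2, 1.6)
      out <- lapply(alphas, function(a) {
        base(10, 5, sprintf("fig10_alpha_%g", a),
             params = pde_params(switch = switch_params(alpha = a)))
      })
      names(out) <- alphas
      attr(out, "control") <- 1.6
      out
    },
    fig11_beta_sweep = {
      betas <- c(1.0, 1.4, 2.0)
      out <- lapply(betas, function(b) {
        base(10, 5, sprintf("fig11_beta_%g", b),
             params = pde_params(switch = switch_params(beta = b)))
      })
      names(out) <- betas
      attr(out, "control") <- 1.0
      out
    },
    fig12_grid = {
      combos <- expand.grid(tau = c(10, 50), g_in = c(5, 30))
      out <- lapply(seq_len(nrow(combos)), function(i) {
        base(combos$tau[i], combos$g_in[i],
             sprintf("fig12_tau%g_gin%g", combos$tau[i], combos$g_in[i]))
      })
      names(out) <- sprintf("tau%g_gin%g", combos$tau, combos$g_in)
      out
    }
  )
}
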