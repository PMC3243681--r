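#' Domain totals of the spatial fields
#'
#' Midpoint-rule integrals over the unit domain: `sum(field) * dx`.
#' Linear in each field.
#'
#' @param fields A [field_set()] (or list of the six fields).
#' @param grid A [grid1d()].
#' @return A one-row tibble with columns `n`, `rho`, `P`, `G`, `M`, `A`.
#' @examples
#' g <- grid1d(50)
#' totals(initial_conditions("default", g, pde_params()), g)
#' @export
totals <- function(fields, grid) {
  dx <- grid$dx
  tibble(n = sum(fields$n) * dx, rho = sum(fields$rho) * dx,
         P = sum(fields$P) * dx, G = sum(fields$G) * dx,
         M = sum(fields$M) * dx, A = sum(fields$A) * dx)
}

#' Classify growth/invasion phases and count cycles
#'
#' Thresholds the tumor-weighted mean miR-451 level at `M_th`: times with
#' mean `M > M_th` are in the growth (proliferative) phase, the rest in
#' the invasion (migratory) phase. Phase intervals shorter than
#' `debounce` are merged into their neighbours, and a completed cycle is
#' one full invasion-growth-invasion alternation, i.e.
#' `floor(transitions / 2)`.
#'
#' @param x A [run_scenario()] result, or a data frame with columns
#'   `time` and `mean_M` sampled uniformly in time.
#' @param M_th Switching threshold; defaults to the threshold stored in
#'   the result's parameters (2.0 otherwise).
#' @param debounce Minimum phase dwell time in hours (default 0.5);
#'   shorter excursions across the threshold are ignored.
#' @return An object of class `cycle_report`: list with `intervals`
#'   (tibble `phase`, `t_start`, `t_end`), `n_cycles`, `M_th`,
#'   `debounce`.
#' @examples
#' tb <- data.frame(time = seq(0, 40, 0.5),
#'                  mean_M = 2 + sin(seq(0, 40, 0.5) / 3))
#' classify_phases(tb)$n_cycles
#' @export
classify_phases <- function(x, M_th = NULL, debounce = 0.5) {
  if (inherits(x, "scenario_result")) {
    if (is.null(M_th)) M_th <- x$config$params$switch$M_th
    tb <- x$totals
  } else {
    tb <- as.data.frame(x)
    if (is.null(M_th)) M_th <- 2.0
  }
  if (!all(c("time", "mean_M") %in% names(tb))) {
    abort("classify_phases: need columns `time` and `mean_M`")
  }
  if (nrow(tb) == 0L) abort("classify_phases: empty series")
  phase <- ifelse(tb$mean_M > M_th, "growth", "invasion")
  runs <- rle(phase)
  dtime <- if (nrow(tb) > 1L) diff(tb$time[1:2]) else 0
  # merge sub-debounce runs into their neighbours, shortest first
  repeat {
    if (length(runs$lengths) <= 1L) break
    dur <- runs$lengths * dtime
    inner <- which(dur < debounce)
    if (length(inner) == 0L) break
    j <- inner[which.min(dur[inner])]
    runs$values[j] <- if (j > 1L) runs$values[j - 1L] else runs$values[j + 1L]
    runs <- rle(inverse.rle(runs))
  }
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  intervals <- tibble(phase = runs$values,
                      t_start = tb$time[starts],
                      t_end = tb$time[ends])
  n_cycles <- (length(runs$values) - 1L) %/% 2L
  structure(list(intervals = intervals, n_cycles = n_cycles,
                 M_th = M_th, debounce = debounce),
            class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  cat(sprintf("<cycle_report> %d completed growth-invasion cycle(s), threshold M_th = %g\n",
              x$n_cycles, x$M_th))
  print(x$intervals, n = Inf)
  invisible(x)
}

#' Summarise a parameter sweep
#'
#' Collates one row per sweep point: the final total tumor population,
#' the number of completed growth-invasion cycles, and the time-mean
#' total AMPK level. The control value (e.g. `alpha = 1.6` or
#' `beta = 1.0`) must be among the sweep points and is flagged.
#'
#' @param runs A named list of [run_scenario()] results, or a data frame
#'   with columns `value` and `result` (a list column).
#' @param values Numeric sweep values; defaults to `as.numeric(names(runs))`.
#' @param control The control parameter value; must match one sweep point.
#' @param debounce Passed to [classify_phases()].
#' @return A tibble with columns `value`, `final_tumor`, `n_cycles`,
#'   `mean_A`, `is_control`, ordered by `value`.
#' @export
sweep_summary <- function(runs, values = NULL, control, debounce = 0.5) {
  if (is.data.frame(runs)) {
    values <- runs$value
    runs <- runs$result
  }
  if (is.null(values)) values <- as.numeric(names(runs))
  if (length(values) != length(runs) || any(is.na(values))) {
    abort("sweep_summary: need one numeric value per run")
  }
  if (length(runs) < 2L) abort("sweep_summary: need at least 2 sweep points")
  if (!any(abs(values - control) < 1e-12)) {
    abort(sprintf("sweep_summary: control value %g missing from the sweep", control))
  }
  rows <- purrr::map2(runs, values, function(r, v) {
    if (!inherits(r, "scenario_result")) {
      abort("sweep_summary: runs must be scenario_result objects")
    }
    cr <- classify_phases(r, debounce = debounce)
    tibble(value = v,
           final_tumor = tail(r$totals$n_total, 1),
           n_cycles = cr$n_cycles,
           mean_A = mean(r$totals$A_total),
           is_control = abs(v - control) < 1e-12)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$value)
}
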