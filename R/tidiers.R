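#' Tidy an equilibrium branch
#'
#' @param x An [continue_branch()] result.
#' @param ... Unused.
#' @return The points tibble (`G`, `M`, `A`, `stability`, `branch`).
#' @method tidy equilibrium_branch
#' @export
tidy.equilibrium_branch <- function(x, ...) x$points

#' One-row summary of an equilibrium branch
#'
#' @param x An [continue_branch()] result.
#' @param ... Unused.
#' @return A tibble with `fold_low`, `fold_high`, `bistable_width`,
#'   `n_points`.
#' @method glance equilibrium_branch
#' @export
glance.equilibrium_branch <- function(x, ...) {
  tibble(fold_low = x$fold_low, fold_high = x$fold_high,
         bistable_width = x$fold_high - x$fold_low,
         n_points = nrow(x$points))
}

#' Tidy a scenario result
#'
#' @param x A [run_scenario()] result.
#' @param ... Unused.
#' @return The per-time totals tibble.
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) x$totals

#' One-row summary of a scenario result
#'
#' @param x A [run_scenario()] result.
#' @param ... Passed to [classify_phases()].
#' @return A tibble with the final tumor total, glucose budget closure
#'   and cycle count.
#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  tf <- tail(x$totals, 1)
  cr <- classify_phases(x, ...)
  tibble(t_end = tf$time, final_tumor = tf$n_total, final_G = tf$G_total,
         final_mean_M = tf$mean_M, n_cycles = cr$n_cycles,
         injected = x$diagnostics$injected,
         consumed = x$diagnostics$consumed, partial = x$partial)
}

#' Tidy a cycle report
#'
#' @param x A [classify_phases()] result.
#' @param ... Unused.
#' @return The phase-interval tibble.
#' @method tidy cycle_report
#' @export
tidy.cycle_report <- function(x, ...) x$intervals

#' One-row summary of a cycle report
#'
#' @param x A [classify_phases()] result.
#' @param ... Unused.
#' @return A tibble with `n_cycles`, `M_th`, `debounce`.
#' @method glance cycle_report
#' @export
glance.cycle_report <- function(x, ...) {
  tibble(n_cycles = x$n_cycles, M_th = x$M_th, debounce = x$debounce)
}

#' Plot the S-shaped equilibrium curve
#'
#' Draws `M*(G)` with stable branches as solid lines, the unstable middle
#' branch dashed, and the saddle-node folds marked.
#'
#' @param object An [continue_branch()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot equilibrium_branch
#' @export
autoplot.equilibrium_branch <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$G, y = .data$M,
                                         group = .data$branch,
                                         linetype = .data$stability)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dashed")) +
    ggplot2::labs(x = "glucose input G", y = "equilibrium miR-451 level",
                  linetype = NULL)
  if (!is.na(object$fold_low)) {
    p <- p + ggplot2::geom_vline(xintercept = c(object$fold_low,
                                                object$fold_high),
                                 linetype = "dotted", colour = "grey40")
  }
  p
}

#' Plot domain totals of a scenario
#'
#' Time courses of the total tumor population, glucose, miR-451 and AMPK
#' levels, faceted by quantity.
#'
#' @param object A [run_scenario()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$totals[, c("time", "n_total", "G_total", "M_total", "A_total")],
    -"time", names_to = "quantity", values_to = "total")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$total)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "domain total")
}

#' Plot spatial snapshots of a scenario
#'
#' Spatial profiles of all six fields at the recorded snapshot times,
#' coloured by time.
#'
#' @param result A [run_scenario()] result with snapshots.
#' @return A ggplot.
#' @export
plot_snapshots <- function(result) {
  if (!inherits(result, "scenario_result") || nrow(result$snapshots) == 0L) {
    abort("plot_snapshots: result has no snapshots")
  }
  long <- tidyr::pivot_longer(result$snapshots, -c("time", "x"),
                              names_to = "field", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value,
                                     colour = .data$time,
                                     group = .data$time)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~field, scales = "free_y") +
    ggplot2::labs(x = "position x", y = NULL, colour = "time (h)")
}
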