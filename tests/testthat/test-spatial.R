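test_that("phase indicators are a smooth partition of unity around the threshold", {
  w <- phase_indicators(c(2, 2, 2), M_th = 2, smoothing_width = 0.05)
  expect_equal(w$growth, c(0.5, 0.5, 0.5))
  expect_equal(w$invasion, c(0.5, 0.5, 0.5))
  # saturation far from the threshold
  expect_gt(phase_indicators(2 + 20 * 0.05, 2, 0.05)$growth, 1 - 1e-6)
  expect_gt(phase_indicators(2 - 20 * 0.05, 2, 0.05)$invasion, 1 - 1e-6)
  # partition of unity on an arbitrary profile
  M <- seq(0, 4, by = 0.01)
  w <- phase_indicators(M)
  expect_equal(w$growth + w$invasion, rep(1, length(M)))
  # shrinking width converges pointwise to the sharp indicator
  sharp <- as.numeric(M > 2)
  err <- vapply(c(0.1, 0.02, 0.004), function(wd) {
    max(abs(phase_indicators(M, 2, wd)$growth - sharp)[abs(M - 2) > 0.2])
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-10)
  expect_error(phase_indicators(1, 2, 0), "smoothing_width")
})

test_that("movement flux vanishes without gradients and telescopes to zero net mass flux", {
  g <- grid1d(50)
  p <- pde_params()
  f0 <- movement_flux(rep(0.3, 50), rep(0.7, 50), rep(1, 50), g, p)
  expect_equal(f0, rep(0, 51))
  set.seed(3)
  fl <- movement_flux(runif(50), cumsum(runif(50, 0, 0.01)), runif(50), g, p)
  expect_identical(fl[1], 0); expect_identical(fl[51], 0)
  expect_lt(abs(sum(diff(fl))), 1e-14)  # zero-flux boundaries telescope
  expect_error(movement_flux(-runif(50), runif(50), runif(50), g, p),
               "nonnegative")
})

test_that("a pulse chemotaxes up a fixed linear glucose gradient at the analytic speed", {
  g <- grid1d(100)
  p <- transport_only_params(chi = 0.02)
  x <- g$centers
  n0 <- exp(-((x - 0.25) / 0.05)^2)
  G <- x                    # unit gradient; frozen (D_G = 0, no consumption)
  eq <- steady_states(mean(G), p$switch)
  f <- field_set(n = n0, rho = rep(1, 100), P = rep(0, 100), G = G,
                 M = rep(eq$M[1], 100), A = rep(eq$A[1], 100))
  sch <- injection_schedule(g_in = 0)
  com <- function(fl) sum(fl$n * x) / sum(fl$n)
  t_end <- 10; dt <- 0.01
  for (s in seq_len(t_end / dt)) {
    f <- step_fields(f, (s - 1) * dt, dt, g, p, sch)
  }
  speed <- (com(f) - com(list(n = n0))) / t_end
  expect_equal(speed, p$chi * 1, tolerance = 0.02)
})

test_that("pure transport conserves tumor mass to round-off every step", {
  g <- grid1d(80)
  p <- transport_only_params(chi = 0.05, D_n = 1e-4)
  x <- g$centers
  G <- 0.5 + 0.4 * sin(2 * pi * x)
  eq <- steady_states(0.5, p$switch)
  f <- field_set(n = exp(-((x - 0.4) / 0.1)^2), rho = rep(1, 80),
                 P = rep(0, 80), G = G, M = rep(eq$M[1], 80),
                 A = rep(eq$A[1], 80))
  sch <- injection_schedule(g_in = 0)
  mass0 <- sum(f$n) * g$dx
  for (s in 1:50) {
    f_prev <- f
    f <- step_fields(f, s * 0.01, 0.01, g, p, sch)
    expect_lt(abs(sum(f$n) - sum(f_prev$n)) * g$dx, 1e-12)
  }
  expect_lt(abs(sum(f$n) * g$dx - mass0), 1e-12)
  expect_gte(min(f$n), 0)
})

test_that("reaction terms reproduce closed-form logistic ECM remodeling and growth saturation", {
  g <- grid1d(10)
  p <- pde_params()
  # no cells, no MMP: rho follows the logistic solution toward capacity 1
  eq <- steady_states(0, p$switch)
  f <- field_set(n = rep(0, 10), rho = rep(0.5, 10), P = rep(0, 10),
                 G = rep(0, 10), M = rep(eq$M[1], 10), A = rep(eq$A[1], 10))
  sch <- injection_schedule(g_in = 0)
  r <- p$r_rho
  for (s in 1:2000) f <- step_fields(f, (s - 1) * 0.01, 0.01, g, p, sch)
  t <- 20
  rho_exact <- 1 / (1 + (1 / 0.5 - 1) * exp(-r * t))
  expect_lt(max(abs(f$rho - rho_exact)), 1e-6)
  # carrying capacity: growth-mode cell at n = 1 has dn/dt = 0
  f1 <- list(n = 1, rho = 1, P = 0, G = 0.002, M = 5, A = 0.5)
  d <- reaction_terms(f1, p)
  expect_equal(d$dn, 0)
  # growth term switches sign around capacity
  expect_gt(reaction_terms(list(n = 0.5, rho = 1, P = 0, G = 0.002,
                                M = 5, A = 0.5), p)$dn, 0)
})

test_that("split stepping matches a tight-tolerance ODE oracle on uniform fields", {
  # uniform fields make transport inert, so the composite step must agree
  # with a high-accuracy integration of the bare reaction system
  g <- grid1d(4)
  p <- pde_params(D_n = 0, D_P = 0, D_G = 0, chi = 0, h_hapto = 0)
  sch <- injection_schedule(tau = 10, g_in = 5, mode = "constant")
  y0 <- c(n = 0.4, rho = 0.7, P = 0.05, G = 0.003, M = 1.2, A = 1.5)
  f <- field_set(n = rep(y0["n"], 4), rho = rep(y0["rho"], 4),
                 P = rep(y0["P"], 4), G = rep(y0["G"], 4),
                 M = rep(y0["M"], 4), A = rep(y0["A"], 4))
  t_end <- 5
  for (s in seq_len(t_end / 0.01)) {
    f <- step_fields(f, (s - 1) * 0.01, 0.01, g, p, sch)
  }
  # oracle: plain-formula RHS integrated with lsoda at 1e-12
  sw <- p$switch
  rhs <- function(t, y, parms) {
    wg <- plogis((y[5] - sw$M_th) / p$smoothing_width)
    gsig <- y[4] / p$G_signal_scale
    list(c(
      wg * p$r_growth * y[1] * (1 - y[1]),
      -p$d_rho * y[3] * y[2] + p$r_rho * y[2] * (1 - y[2]),
      p$a_P * (1 - wg) * y[1] * y[2] - p$d_P * y[3],
      -p$lambda_G * y[1] * y[4] + parms$src,
      gsig + sw$k1 * sw$k2^2 / (sw$k2^2 + sw$alpha * y[6]^2) - y[5],
      sw$eps * (sw$S + sw$k3 * sw$k4^2 / (sw$k4^2 + sw$beta * y[5]^2) - y[6])
    ))
  }
  for (cell in c(1, 4)) {
    src_cell <- sch$g_in * injection_source(1, sch, g)[cell]
    sol <- deSolve::ode(y0, c(0, t_end), rhs, list(src = src_cell),
                        rtol = 1e-12, atol = 1e-14)
    got <- vapply(c("n", "rho", "P", "G", "M", "A"), function(nm) f[[nm]][cell],
                  numeric(1))
    expect_lt(max(abs(got - sol[2, -1])), 1e-8)
  }
})

test_that("injection source is on in the far-field band during pulses and measures exactly", {
  g <- grid1d(100)
  sch <- injection_schedule(tau = 10, g_in = 5, duration = 0.01,
                            band_width = 0.08)
  s_on <- injection_source(10 + 0.005, sch, g)
  expect_equal(s_on[g$centers > 0.92][1], 1)   # x = 0.925, inside the band
  expect_equal(s_on[abs(g$centers - 0.965) < 1e-9], 1)
  expect_equal(s_on[g$centers < 0.92], rep(0, sum(g$centers < 0.92)))
  expect_equal(injection_source(5, sch, g), rep(0, 100))     # between pulses
  expect_equal(injection_source(0.005, sch, g), rep(0, 100)) # no pulse at t = 0
  # space-time measure of one pulse equals duration * band
  tt <- seq(9.95, 10.05, by = 1e-5)
  meas <- sum(vapply(tt, function(t) sum(injection_source(t, sch, g)) * g$dx,
                     numeric(1))) * 1e-5
  expect_equal(meas, 0.01 * 0.08, tolerance = 0.01)
  # partial-overlap weighting where the band edge splits a cell
  g2 <- grid1d(60)   # dx = 1/60: band edge 0.92 lies inside a cell
  s2 <- sort(unique(round(injection_source(10.005, sch, g2), 9)))
  expect_equal(length(s2), 3L)
  expect_equal(s2[1], 0)
  expect_equal(s2[3], 1)
  expect_true(s2[2] > 0 && s2[2] < 1)
})

test_that("default initial conditions start a left plateau of migratory cells in intact ECM", {
  g <- grid1d(100)
  p <- pde_params()
  f <- initial_conditions("default", g, p)
  expect_equal(sum(f$n) * g$dx, p$tumor_width, tolerance = 0.01)
  expect_equal(max(f$n), 1, tolerance = 1e-3)
  expect_equal(f$rho[100], 1, tolerance = 1e-6)
  expect_equal(f$rho[1], p$rho_inside, tolerance = 1e-3)
  expect_equal(f$P, rep(0, 100))
  # intracellular fields start at the local switch steady state
  d <- switch_rhs(f$M, f$A, f$G / p$G_signal_scale, p$switch)
  expect_lt(max(abs(d$dM)), 1e-8)
  expect_lt(max(abs(d$dA)), 1e-8)
  # low glucose everywhere: all cells begin below the invasion threshold
  expect_true(all(f$M < p$switch$M_th))
  expect_error(initial_conditions("unknown"), "unknown scenario")
})

test_that("glucose budget closes: injected minus consumed equals the change in total glucose", {
  res <- run_scenario(scenario_config(t_end = 25, output_dt = 0.5))
  tb <- res$totals
  dG <- tail(tb$G_total, 1) - tb$G_total[1]
  closure <- res$diagnostics$injected - res$diagnostics$consumed
  expect_lt(abs(dG - closure) / max(abs(res$diagnostics$consumed), 1e-12),
            1e-3)
  # two pulses (t = 10, 20) delivered exactly
  expect_equal(res$diagnostics$injected, 2 * 5 * 0.01 * 0.08,
               tolerance = 1e-10)
  # positivity throughout
  expect_true(all(vapply(res$final, function(v) min(v) >= 0, logical(1))))
})

test_that("MMP stays localized at the invasive front", {
  res <- run_fig7()
  sn <- res$snapshots[res$snapshots$time == 50, ]
  x_mmp <- sn$x[which.max(sn$P)]
  grad_n <- abs(diff(sn$n))
  x_front <- sn$x[which.max(grad_n)]
  w <- phase_indicators(sn$M[which.max(sn$P)])
  expect_gt(w$invasion, 0.5)              # MMP peak sits in migratory tissue
  expect_lt(abs(x_mmp - x_front), 0.2)    # and near the steepest tumor front
})
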