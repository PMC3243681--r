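test_that("switch right-hand side: identities, bounds and input checks", {
  # origin is an equilibrium when production and inputs are all off
  d0 <- switch_rhs(0, 0, 0, switch_params(k1 = 0, k3 = 0, S = 0))
  expect_identical(c(d0$dM, d0$dA), c(0, 0))
  # bounded production forces decay above the box
  p <- switch_params()
  set.seed(11)
  for (i in 1:25) {
    G <- runif(1, 0, 2)
    A <- runif(1, 0, 6)
    d <- switch_rhs(G + p$k1 + runif(1, 1e-6, 3), A, G, p)
    expect_lt(d$dM, 0)
    d2 <- switch_rhs(runif(1, 0, 5), p$S + p$k3 + runif(1, 1e-6, 3), G, p)
    expect_lt(d2$dA, 0)
  }
  # vanishes at the computed upper-branch equilibrium
  d <- switch_rhs(frozen$G05$M[3], frozen$G05$A[3], 0.5, p)
  expect_lt(abs(d$dM), 1e-10)
  expect_lt(abs(d$dA), 1e-10)
  expect_error(switch_rhs(-1, 0, 0.5), "nonnegative")
  expect_error(switch_rhs(1, 1, -0.1), "nonnegative")
  expect_error(switch_params(alpha = -1), "nonnegative")
  expect_error(switch_params(eps = 0), "positive")
})

test_that("steady states match the frozen dense-scan oracle", {
  ss <- steady_states(0.5)
  expect_equal(nrow(ss), 3L)
  expect_equal(ss$M, frozen$G05$M, tolerance = 1e-8)
  expect_equal(ss$A, frozen$G05$A, tolerance = 1e-8)
  expect_identical(ss$stability, c("stable", "unstable", "stable"))
  ss8 <- steady_states(0.8)
  expect_equal(nrow(ss8), 1L)
  expect_equal(ss8$M, frozen$G08$M, tolerance = 1e-8)
  expect_identical(ss8$stability, "stable")
  # all production off: single stable equilibrium at the origin
  ss0 <- steady_states(0, switch_params(k1 = 0, k3 = 0, S = 0))
  expect_equal(nrow(ss0), 1L)
  expect_equal(c(ss0$M, ss0$A), c(0, 0), tolerance = 1e-10)
  expect_identical(ss0$stability, "stable")
})

test_that("steady states agree with a 2-D residual-grid scan on random parameter sets", {
  set.seed(42)
  for (i in 1:50) {
    p <- switch_params(k1 = runif(1, 0.5, 5), k2 = runif(1, 0.5, 2),
                       alpha = runif(1, 0.2, 2.5), k3 = runif(1, 0.5, 5),
                       k4 = runif(1, 0.5, 2), beta = runif(1, 0.2, 2.5),
                       S = runif(1, 0, 0.5), eps = 0.02)
    G <- runif(1, 0, 1.2)
    got <- steady_states(G, p)
    want <- oracle_equilibria_2d(G, p)
    expect_equal(nrow(got), nrow(want),
                 info = sprintf("set %d: G=%.3f", i, G))
    if (nrow(got) == nrow(want)) {
      expect_equal(got$M, want[, 1], tolerance = 1e-5)
      expect_equal(got$A, want[, 2], tolerance = 1e-5)
    }
  }
})

test_that("trajectories stay at equilibria, stay nonnegative and respect production bounds", {
  p <- switch_params()
  # fixed point: constant G = 0.8, start at the unique equilibrium
  tr <- integrate_switch(c(M = frozen$G08$M, A = frozen$G08$A), 0.8,
                         t_span = c(0, 100))
  expect_lt(max(abs(tr$M - frozen$G08$M)), 1e-6)
  expect_lt(max(abs(tr$A - frozen$G08$A)), 1e-6)
  # positivity and lim-sup bounds over random trajectories
  set.seed(7)
  for (i in 1:100) {
    g0 <- runif(1, 0, 1.5); g1 <- runif(1, 0, 1.5); om <- runif(1, 0.1, 2)
    gfun <- function(t) g0 + g1 * (1 + sin(om * t)) / 2
    tr <- integrate_switch(c(M = runif(1, 0, 6), A = runif(1, 0, 6)),
                           gfun, p, t_span = c(0, 250), n_out = 100,
                           rtol = 1e-6, atol = 1e-8)
    expect_gte(min(tr$M), -1e-8)
    expect_gte(min(tr$A), -1e-8)
    late <- tr[tr$time > 200, ]
    expect_lte(max(late$M), g0 + g1 + p$k1 + 0.05)
    expect_lte(max(late$A), p$S + p$k3 + 0.05)
  }
})

test_that("bistable basins: perturbations off the middle equilibrium split to the outer branches", {
  p <- switch_params()
  mid_M <- frozen$G05$M[2]; mid_A <- frozen$G05$A[2]
  up <- integrate_switch(c(M = mid_M + 0.1, A = mid_A), 0.5, p, c(0, 6000))
  dn <- integrate_switch(c(M = mid_M - 0.1, A = mid_A), 0.5, p, c(0, 6000))
  expect_equal(tail(up$M, 1), frozen$G05$M[3], tolerance = 1e-4)
  expect_equal(tail(dn$M, 1), frozen$G05$M[1], tolerance = 1e-4)
})

test_that("slow glucose sweep traces a hysteresis loop with distinct jump points", {
  p <- switch_params()
  Tq <- 4000  # quasi-static relative to the slow AMPK time scale 1/eps
  gfun <- function(t) ifelse(t <= Tq, t / Tq, pmax(0, 2 - t / Tq))
  eq0 <- steady_states(0, p)
  tr <- integrate_switch(c(M = eq0$M[1], A = eq0$A[1]), gfun, p,
                         t_span = c(0, 2 * Tq), n_out = 4000)
  up_leg <- tr[tr$time <= Tq, ]
  down_leg <- tr[tr$time > Tq, ]
  G_jump_up <- up_leg$G[min(which(up_leg$M > p$M_th))]
  G_jump_down <- down_leg$G[min(which(down_leg$M < p$M_th))]
  expect_gt(G_jump_up, G_jump_down)
  # enclosed area in (G, M): difference of the two legs on a common G grid
  Gg <- seq(0.05, 0.95, by = 0.005)
  M_up <- approx(up_leg$G, up_leg$M, Gg)$y
  M_dn <- approx(rev(down_leg$G), rev(down_leg$M), Gg)$y
  area <- sum(M_dn - M_up) * 0.005
  expect_gt(area, 0.1)
})

test_that("as eps shrinks the dynamics converge to the reduced slow-manifold model", {
  # miR-451 is the fast variable: the reduced model slaves M to its
  # nullcline while the AMPK complex evolves slowly
  G <- 0.5
  err <- vapply(c(0.02, 0.002, 0.0002), function(eps) {
    p <- switch_params(eps = eps)
    A0 <- 3.5
    M0 <- G + p$k1 * p$k2^2 / (p$k2^2 + p$alpha * A0^2)
    t_end <- 5 / eps  # fixed horizon in slow time
    full <- integrate_switch(c(M = M0, A = A0), G, p, c(0, t_end), n_out = 200)
    red_rhs <- function(t, y, parms) {
      A <- y[1]
      M <- G + p$k1 * p$k2^2 / (p$k2^2 + p$alpha * A^2)
      list(eps * (p$S + p$k3 * p$k4^2 / (p$k4^2 + p$beta * M^2) - A))
    }
    red <- deSolve::ode(c(A = A0), full$time, red_rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
    A_red <- red[, 2]
    M_red <- G + p$k1 * p$k2^2 / (p$k2^2 + p$alpha * A_red^2)
    keep <- full$time > 2  # discard the initial fast layer
    max(abs(full$M[keep] - M_red[keep]))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
})

test_that("equilibrium continuation finds the folds and the bistable window", {
  br <- continue_branch()
  expect_s3_class(br, "equilibrium_branch")
  # folds agree with the brute-force root-count scan bracketing at dG = 1e-4
  expect_gte(br$fold_low, frozen$fold_low[1] - 1e-4)
  expect_lte(br$fold_low, frozen$fold_low[2] + 1e-4)
  expect_gte(br$fold_high, frozen$fold_high[1] - 1e-4)
  expect_lte(br$fold_high, frozen$fold_high[2] + 1e-4)
  # exactly 3 equilibria strictly inside, 1 outside
  for (G in seq(br$fold_low + 0.01, br$fold_high - 0.01, length.out = 7)) {
    expect_equal(nrow(steady_states(G)), 3L)
  }
  for (G in c(br$fold_low - 0.05, br$fold_high + 0.05, 0.05, 1.0)) {
    expect_equal(nrow(steady_states(G)), 1L)
  }
  # stability pattern: upper/lower stable, middle unstable throughout
  pts <- tidy(br)
  expect_true(all(pts$stability[pts$branch %in% c("lower", "upper")] == "stable"))
  expect_true(all(pts$stability[pts$branch == "middle"] == "unstable"))
  # with both inhibitions off the curve is monotone: no folds
  br0 <- continue_branch(switch_params(alpha = 0, beta = 0),
                         G_resolution = 0.01)
  expect_true(is.na(br0$fold_low) && is.na(br0$fold_high))
  expect_true(all(tidy(br0)$stability == "stable"))
})

test_that("glucose deprivation reduces equilibrium miR-451, consistently with relaxation", {
  resp <- glucose_deprivation_response()
  expect_equal(resp$M_high, frozen$G10$M, tolerance = 1e-6)
  expect_gt(resp$percent_reduction, 80)
  # identity case: no deprivation, no reduction
  same <- suppressWarnings(glucose_deprivation_response(G_high = 1, G_low = 1))
  expect_equal(same$percent_reduction, 0)
  expect_false(same$distinct_state)
  # relaxation oracle: step glucose down from the high state and integrate
  tr <- integrate_switch(c(M = resp$M_high,
                           A = steady_states(1.0)$A[1]),
                         resp$G_low, t_span = c(0, 3000), n_out = 100)
  oracle_pct <- 100 * (1 - tail(tr$M, 1) / resp$M_high)
  expect_lt(abs(resp$percent_reduction - oracle_pct), 0.1)
  # G_low inside the bistable window: history keeps the upper branch
  hist_resp <- glucose_deprivation_response(G_high = 1, G_low = 0.5)
  expect_equal(hist_resp$M_low, frozen$G05$M[3], tolerance = 1e-6)
})
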