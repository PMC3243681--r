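# Independent oracles, written from the model equations directly rather
# than through the package's solution paths.

# Right-hand sides of the switch, plain formulas.
oracle_rhs <- function(M, A, G, p) {
  c(G + p$k1 * p$k2^2 / (p$k2^2 + p$alpha * A^2) - M,
    p$eps * (p$S + p$k3 * p$k4^2 / (p$k4^2 + p$beta * M^2) - A))
}

# All equilibria by a dense two-dimensional residual-grid scan over the
# production-bounded box, polished with a finite-difference 2-D Newton.
# Independent of the package's nullcline-elimination route.
oracle_equilibria_2d <- function(G, p, n_grid = 300) {
  M_box <- seq(0, G + p$k1 + 1e-9, length.out = n_grid)
  A_box <- seq(0, p$S + p$k3 + 1e-9, length.out = n_grid)
  f1 <- outer(M_box, A_box, function(M, A) G + p$k1 * p$k2^2 / (p$k2^2 + p$alpha * A^2) - M)
  f2 <- outer(M_box, A_box, function(M, A) p$S + p$k3 * p$k4^2 / (p$k4^2 + p$beta * M^2) - A)
  s1 <- sign(f1); s2 <- sign(f2)
  nm <- length(M_box); na <- length(A_box)
  # cells where both residual components change sign among the 4 corners
  chg <- function(s) {
    c00 <- s[-nm, -na]; c10 <- s[-1, -na]; c01 <- s[-nm, -1]; c11 <- s[-1, -1]
    (pmin(c00, c10, c01, c11) < 0) & (pmax(c00, c10, c01, c11) > 0)
  }
  hits <- which(chg(s1) & chg(s2), arr.ind = TRUE)
  newton <- function(M, A) {
    for (i in 1:60) {
      F <- oracle_rhs(M, A, G, p)
      if (max(abs(F)) < 1e-12) break
      h <- 1e-7
      J <- cbind((oracle_rhs(M + h, A, G, p) - F) / h,
                 (oracle_rhs(M, A + h, G, p) - F) / h)
      d <- tryCatch(solve(J, F), error = function(e) c(0, 0))
      M <- M - d[1]; A <- A - d[2]
      if (!is.finite(M) || !is.finite(A)) return(NULL)
    }
    if (max(abs(oracle_rhs(M, A, G, p))) < 1e-8) c(M, A) else NULL
  }
  out <- NULL
  for (k in seq_len(nrow(hits))) {
    r <- newton(mean(M_box[hits[k, 1] + 0:1]), mean(A_box[hits[k, 2] + 0:1]))
    if (!is.null(r) && r[1] >= -1e-9 && r[2] >= -1e-9) out <- rbind(out, pmax(r, 0))
  }
  if (is.null(out)) return(matrix(numeric(0), 0, 2))
  # merge duplicates
  out <- out[order(out[, 1]), , drop = FALSE]
  keep <- c(TRUE, diff(out[, 1]) > 1e-6 | abs(diff(out[, 2])) > 1e-6)
  out[keep, , drop = FALSE]
}

# Trapezoid-rule quadrature on face-reconstructed values; an independent
# route to the domain integral of a cell-centred field.
oracle_trapz <- function(field, grid) {
  faces <- c(field[1], (field[-1] + field[-length(field)]) / 2,
             field[length(field)])
  sum((faces[-1] + faces[-length(faces)]) / 2) * grid$dx
}

# Default-parameter equilibria frozen from a dense-scan/bisection oracle
# run at 1e-15 root tolerance.
frozen <- list(
  G05 = list(M = c(0.869652187223, 1.827487120867, 3.131088478727),
             A = c(2.477521809747, 1.121720750612, 0.570243011518)),
  G08 = list(M = 3.785053451759, A = 0.460983666720),
  G10 = list(M = 4.106815096676),
  fold_low = c(0.39920, 0.39930),   # brute-force bracketing at dG = 1e-4
  fold_high = c(0.57970, 0.57980),
  deprivation_pct = 94.754581450118
)
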