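test_that("linear steady state matches the scalar bracketing oracle", {
  p <- fixture("fig1_linear")             # h = 1, K = 100, J_max = 2
  # independent oracle: bracketed root of J(P) - mu(P) = 0
  f <- function(P) 2 / (1 + P / 100) - 1 / (1 + 1 / P)
  oracle <- uniroot(f, c(1e-9, 1e6), tol = 1e-12)$root

  expect_equal(as.numeric(analytic_pool_linear(p)), oracle, tolerance = 1e-9)
  ss <- find_steady_state(p)
  expect_true(ss$converged)
  expect_equal(unname(ss$pools[["P"]]), oracle, tolerance = 1e-6)
  # residual of the rhs at the analytic root is numerically zero
  expect_lt(abs(module_rhs(c(P = oracle), p)$derivatives[["P"]]), 1e-9)

  # asymptote: mu_max-limited pool ~ K (J_max/mu_max - 1)
  expect_equal(unname(attr(analytic_pool_linear(p), "asymptotes")["mu_max_limited"]),
               100 * (2 - 1))
  # input-limited regime: pool far below K
  p_small <- set_bound(p, "J_max", 0.05)
  expect_lt(analytic_pool_linear(p_small), 0.1 * 100)
  expect_error(analytic_pool_linear(fixture("fig1_linear", hill = 4)), "h = 1")
})

test_that("integration approaches the analytic root monotonically from below", {
  p <- fixture("fig1_linear")
  tr <- integrate_module(p, initial = c(P = 1e-6), t_end = 6000)
  oracle <- as.numeric(analytic_pool_linear(p))
  P <- tr$pools[, "P"]
  expect_true(all(diff(P) > -1e-9))
  expect_equal(unname(P[length(P)]), oracle, tolerance = 1e-5)
  expect_true(tr$steady)
  expect_gte(min(tr$pools), -1e-9)
})

test_that("zero input drains every module to the zero-growth state", {
  set.seed(3)
  for (mod in c("linear", "bidirectional", "cycle", "integration")) {
    p <- rand_module(mod)
    for (nm in names(p$flux_bounds))
      if (nm %in% c("J_max", "J1_max", "J2_max", "J_in_max", "J_C_max",
                    "J_N1_max", "J_N2_max"))
        p <- set_bound(p, nm, 0)
    tr <- integrate_module(p, initial = rand_state(p, max = 2), t_end = 5000)
    expect_lt(tr$mu[length(tr$mu)], 1e-3)
    expect_gte(min(tr$pools), -1e-9)
  }
})

test_that("without feedback inhibition the pool grows without limit", {
  p <- module_params("linear", list(J_max = 2),
                     list(input = feedback_term(enabled = FALSE)),
                     growth = growth_params(1, c(P = 1)))
  ss <- find_steady_state(p, t_max = 2000)
  expect_false(ss$converged)
})

test_that("root-finding and integration agree across the fixture catalog", {
  for (nm in c("fig1_linear", "fig1_bidirectional", "fig2_cycle",
               "fig2_integration")) {
    p <- fixture(nm)
    ss_i <- find_steady_state(p)
    expect_true(ss_i$converged)
    ss_r <- find_steady_state(p, initial_guess = ss_i$pools * 1.3,
                              method = "root")
    expect_true(ss_r$converged)
    expect_equal(unname(ss_i$pools), unname(ss_r$pools), tolerance = 1e-6)
  }
})

test_that("symmetric bidirectional parameters give a symmetric steady state", {
  p <- fixture("fig1_bidirectional")
  p <- set_bound(p, "J1_max", p$flux_bounds$J2_max)
  ss <- find_steady_state(p)
  expect_true(ss$converged)
  expect_equal(ss$pools[["P1"]], ss$pools[["P2"]], tolerance = 1e-8)
})

test_that("steady-state flux balance holds term by term for the cycle", {
  p <- set_bound(fixture("fig2_cycle"), "J_in_max", 0.5)
  ss <- find_steady_state(p)
  expect_true(ss$converged)
  fl <- ss$fluxes; rho <- p$growth$rho
  expect_lt(abs(fl[["nitrogen_input"]] - fl[["conversion"]] -
                  rho[["Q"]] * ss$mu), 1e-8)
  expect_lt(abs(-fl[["nitrogen_input"]] + 2 * fl[["conversion"]] +
                  fl[["biosynthetic_return"]] - rho[["E"]] * ss$mu), 1e-8)
})

test_that("steady-state carbon balance holds for the integration module", {
  p <- set_bound(fixture("fig2_integration"), "J_C_max", 1)
  ss <- find_steady_state(p)
  expect_true(ss$converged)
  fl <- ss$fluxes
  expect_lt(abs(fl[["carbon_input"]] - ss$mu - fl[["carbon_cost"]]), 1e-8)
})

test_that("stability verdicts are robust to the Jacobian step size", {
  p <- fixture("fig2_cycle")
  ss <- find_steady_state(p)
  verdicts <- vapply(c(1e-6, 1e-5, 1e-4), function(h) {
    fd <- function(fn, x) {
      n <- length(x)
      J <- matrix(0, n, n)
      for (j in seq_len(n)) {
        dx <- numeric(n); dx[j] <- h * max(1, abs(x[j]))
        J[, j] <- (fn(x + dx) - fn(x - dx)) / (2 * dx[j])
      }
      J
    }
    Jm <- fd(function(z) module_rhs(pmax(z, 0), p, clip = TRUE)$derivatives,
             as.numeric(ss$pools))
    max(Re(eigen(Jm, only.values = TRUE)$values)) < -1e-8
  }, logical(1))
  expect_true(all(verdicts == isTRUE(ss$stable)))
})

test_that("linear steady growth is non-decreasing in the feedback constant", {
  mus <- vapply(c(3, 10, 30, 100, 300, 1000), function(K) {
    p <- module_params("linear", list(J_max = 2),
                       list(input = feedback_term(K = K, h = 1)),
                       growth = growth_params(1, c(P = 1)))
    find_steady_state(p)$mu
  }, numeric(1))
  expect_true(all(diff(mus) >= -1e-10))
})

test_that("stability() refuses a state that is not steady", {
  p <- fixture("fig1_linear")
  expect_error(stability(p, c(P = 1)), "requires a steady state")
})
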