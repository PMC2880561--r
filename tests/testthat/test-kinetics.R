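test_that("module parameter validation names the offending component", {
  gp <- growth_params(mu_max = 1, sigma = c(P = 1))
  expect_error(module_params("linear", list(), list(input = feedback_term(1)),
                             growth = gp), "missing flux bound")
  expect_error(module_params("linear", list(J_max = -1),
                             list(input = feedback_term(1)), growth = gp),
               "J_max")
  expect_error(module_params("linear", list(J_max = 1, bogus = 2),
                             list(input = feedback_term(1)), growth = gp),
               "unknown flux bound")
  expect_error(module_params("linear", list(J_max = 1), list(), growth = gp),
               "missing feedback")
  # pool labels of the growth law must match the module
  expect_error(module_params("cycle", list(J_in_max = 1, Jc_max = 1),
                             list(input = feedback_term(1),
                                  conversion = feedback_term(1)),
                             list(input = saturation_term(1),
                                  conversion = saturation_term(1)),
                             growth = gp), "E, Q")
})

test_that("linear pathway derivatives match the rate-law transcription", {
  p <- module_params("linear", list(J_max = 1.2),
                     list(input = feedback_term(K = 3, h = 2)),
                     growth = growth_params(mu_max = 0.9, sigma = c(P = 1.1)))
  # independent term-by-term evaluation at P = 2
  J_in <- 1.2 / (1 + (2 / 3)^2)
  mu <- 0.9 / (1 + 1.1 / 2)
  r <- module_rhs(c(P = 2), p)
  expect_equal(unname(r$derivatives), J_in - mu, tolerance = 1e-12)
  expect_equal(unname(r$fluxes[["input"]]), J_in)
  expect_equal(r$mu, mu)

  # no input: pure consumption; empty pool: pure uninhibited input
  p0 <- set_bound(p, "J_max", 0)
  expect_lt(module_rhs(c(P = 2), p0)$derivatives[["P"]], 0)
  r0 <- module_rhs(c(P = 0), p)
  expect_equal(unname(r0$derivatives), 1.2)
  expect_error(module_rhs(c(P = -1), p), "negative pool")
})

test_that("bidirectional derivatives follow the 2:1 interconversion stoichiometry", {
  p <- module_params(
    "bidirectional",
    list(J1_max = 1, J2_max = 0.5, Jc_max = 2),
    list(input1 = feedback_term(K = 10, h = 2),
         input2 = feedback_term(K = 20, h = 2),
         J12 = feedback_term(K = 5, h = 2), J21 = feedback_term(K = 7, h = 2)),
    list(J12 = saturation_term(K_M = 4, hill_order = 2L),
         J21 = saturation_term(K_M = 6, hill_order = 2L)),
    growth_params(mu_max = 1, sigma = c(P1 = 1, P2 = 1)))
  P1 <- 3; P2 <- 8
  # independent spreadsheet-style evaluation
  J1 <- 1 / (1 + (3 / 10)^2)
  J2 <- 0.5 / (1 + (8 / 20)^2)
  J12 <- 2 * (9 / (9 + 16)) * (1 / (1 + (8 / 5)^2))
  J21 <- 2 * (64 / (64 + 36)) * (1 / (1 + (3 / 7)^2))
  mu <- 1 / (1 + 1 / 3 + 1 / 8)
  r <- module_rhs(c(P1 = P1, P2 = P2), p)
  expect_equal(unname(r$derivatives["P1"]), J1 - 2 * J12 + J21 - mu,
               tolerance = 1e-12)
  expect_equal(unname(r$derivatives["P2"]), J2 + J12 - 2 * J21 - mu,
               tolerance = 1e-12)

  # no substrate, no interconversion flux
  expect_identical(module_rhs(c(P1 = 3, P2 = 0), p)$fluxes[["J21"]], 0)

  # exact symmetry under symmetric parameters and equal pools
  ps <- fixture("fig1_bidirectional")
  ps <- set_bound(ps, "J1_max", ps$flux_bounds$J2_max)
  rs <- module_rhs(c(P1 = 1.7, P2 = 1.7), ps)
  expect_equal(rs$derivatives[["P1"]], rs$derivatives[["P2"]])
  expect_equal(rs$fluxes[["J12"]], rs$fluxes[["J21"]])
})

test_that("cycle derivatives balance glutamine production, conversion and return", {
  p <- fixture("fig2_cycle")
  E <- 2; Q <- 5
  # independent evaluation of the Full-FI rate laws
  J_in <- 2 * (2 / (2 + 0.1)) * (1 / (1 + 5 / 100))
  J_c <- 2 * (5 / (5 + 1)) * (1 / (1 + 2 / 100))
  mu <- 1 / (1 + 0.85 / 2 + 0.15 / 5)
  r <- module_rhs(c(E = E, Q = Q), p)
  expect_equal(unname(r$derivatives["Q"]), J_in - J_c - 0.15 * mu,
               tolerance = 1e-12)
  expect_equal(unname(r$derivatives["E"]),
               -J_in + 2 * J_c + 0.15 * mu - 0.85 * mu, tolerance = 1e-12)

  # the cycle's defining property: no glutamate, no nitrogen input
  expect_identical(module_rhs(c(E = 0, Q = 5), p)$fluxes[["nitrogen_input"]], 0)
  # conversion saturates at its bound for large glutamine
  expect_lt(abs(module_rhs(c(E = 1e-9, Q = 1e9), p)$fluxes[["conversion"]] - 2),
            1e-6)
})

test_that("integration module spends carbon on GS/GOGAT nitrogen import", {
  p <- fixture("fig2_integration")
  C <- 3; N <- 7
  J_C <- 2 / (1 + (3 / 100)^4)
  J_N1 <- 0.3 / (1 + (7 / 1000)^4)
  J_N2 <- 2 / (1 + (7 / 50)^4)
  mu <- 1 / (1 + 1 / 3 + 1 / 7)
  r <- module_rhs(c(C = C, N = N), p)
  expect_equal(unname(r$derivatives["C"]), J_C - mu - J_N2, tolerance = 1e-12)
  expect_equal(unname(r$derivatives["N"]), J_N1 + J_N2 - mu, tolerance = 1e-12)

  # strong-inhibition limit: all inputs nearly shut
  rr <- module_rhs(c(C = 1e4, N = 1e5), p)
  expect_lt(rr$fluxes[["carbon_input"]], 0.01 * 2)
  expect_lt(rr$fluxes[["nitrogen_gdh"]] + rr$fluxes[["nitrogen_gsgogat"]],
            0.01 * 2.3)
  # empty nitrogen pool: no inhibition anywhere on nitrogen inputs
  r0 <- module_rhs(c(C = 3, N = 0), p)
  expect_equal(r0$fluxes[["nitrogen_gdh"]] + r0$fluxes[["nitrogen_gsgogat"]],
               0.3 + 2)
})

test_that("leak and knockout variants modify exactly their terms", {
  ko <- fixture("fig3_upshift_ko")
  wt <- fixture("fig3_upshift_wt")
  N <- 40; C <- 5
  # knockout: GS/GOGAT flux at its bound regardless of N
  expect_equal(module_rhs(c(C = C, N = N), ko)$fluxes[["nitrogen_gsgogat"]],
               ko$flux_bounds$J_N2_max)
  expect_lt(module_rhs(c(C = C, N = N), wt)$fluxes[["nitrogen_gsgogat"]],
            wt$flux_bounds$J_N2_max)
  # first-order leak on the nitrogen pool only
  expect_equal(module_rhs(c(C = C, N = N), ko)$fluxes[["leak_N"]], 0.01 * N)
  expect_equal(module_rhs(c(C = C, N = N), ko)$fluxes[["leak_C"]], 0)
})

test_that("full-FI with disabled brackets reproduces min-FI bit-for-bit", {
  base <- fixture("fig1_bidirectional")
  minfi <- fixture("fig1_bidirectional", scheme = "min_fi")
  nofb <- module_params("bidirectional", base$flux_bounds,
                        feedback = base$feedback,
                        saturation = base$saturation,
                        growth = base$growth, scheme = "full_fi",
                        knockout = c("J12", "J21"))
  set.seed(11)
  for (i in 1:20) {
    x <- rand_state(base)
    expect_identical(module_rhs(x, nofb)$derivatives,
                     module_rhs(x, minfi)$derivatives)
  }
})

test_that("every reported flux respects its configured bound", {
  set.seed(5)
  for (mod in c("linear", "bidirectional", "cycle", "integration")) {
    p <- rand_module(mod)
    bound_of <- function(nm) {
      b <- p$flux_bounds
      switch(p$module,
        linear = c(input = b$J_max)[nm],
        bidirectional = c(input_1 = b$J1_max, input_2 = b$J2_max,
                          J12 = b$Jc_max, J21 = b$Jc_max)[nm],
        cycle = c(nitrogen_input = b$J_in_max, conversion = b$Jc_max)[nm],
        integration = c(carbon_input = b$J_C_max, nitrogen_gdh = b$J_N1_max,
                        nitrogen_gsgogat = b$J_N2_max)[nm])
    }
    for (i in 1:30) {
      fl <- flux_record(rand_state(p), p)
      expect_true(all(fl >= 0))
      for (nm in names(fl)) {
        b <- bound_of(nm)
        if (!is.null(b) && !is.na(b)) expect_lte(fl[[nm]], b + 1e-12)
      }
    }
  }
})
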