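gp1 <- function(mu_max = 1) growth_params(mu_max = mu_max, sigma = c(P = 1))

lin <- function(J_max, mu_max = 1)
  module_params("linear", list(J_max = J_max),
                list(input = feedback_term(100)), growth = gp1(mu_max))

bid <- function(J1, J2, Jc, mu_max = 1)
  module_params("bidirectional", list(J1_max = J1, J2_max = J2, Jc_max = Jc),
                list(input1 = feedback_term(50), input2 = feedback_term(50),
                     J12 = feedback_term(10), J21 = feedback_term(10)),
                list(J12 = saturation_term(10, 2L),
                     J21 = saturation_term(10, 2L)),
                growth_params(mu_max, sigma = c(P1 = 1, P2 = 1)))

test_that("linear FBA follows the input bound up to the growth cap", {
  expect_equal(fba_optimum(lin(0.5))$mu_opt, 0.5)
  expect_equal(fba_optimum(lin(0.5))$limiting_resource, "input_flux")
  expect_equal(fba_optimum(lin(5))$mu_opt, 1)
  expect_equal(fba_optimum(lin(5))$limiting_resource, "mu_max")
  # kink point: growth cap and input bound coincide; cap label wins
  expect_equal(fba_optimum(lin(1))$mu_opt, 1)
  expect_equal(fba_optimum(lin(1))$limiting_resource, "mu_max")
})

test_that("bidirectional FBA converts at 2:1 and avoids futile cycling", {
  # symmetric inputs, ample conversion: no interconversion needed
  r <- fba_optimum(bid(0.4, 0.4, 5))
  expect_equal(r$mu_opt, 0.4)
  expect_equal(unname(r$fluxes[c("J12", "J21")]), c(0, 0))

  # all of P1 derived from P2 at a 2:1 cost
  r2 <- fba_optimum(bid(0, 9, 5))
  expect_equal(r2$mu_opt, 1)                    # min(mu_max, 9/3, 5)
  r3 <- fba_optimum(bid(0, 0.9, 5, mu_max = 10))
  expect_equal(r3$mu_opt, 0.3)                  # J2/3 binds
  r4 <- fba_optimum(bid(0, 9, 0.2, mu_max = 10))
  expect_equal(r4$mu_opt, 0.2)                  # interconversion binds
  expect_equal(r4$limiting_resource, "interconversion")
  # futile-cycle-free representative in every case
  for (r in list(r2, r3, r4))
    expect_equal(min(r$fluxes[["J12"]], r$fluxes[["J21"]]), 0)

  # symmetric instance with input slack admits multiple optima
  expect_true(fba_optimum(bid(2, 2, 5))$degenerate)
  expect_true(fba_lp(bid(2, 2, 5))$degenerate)
  expect_false(fba_optimum(bid(0.4, 0.4, 5))$degenerate)
})

test_that("cycle FBA realizes its three regimes", {
  p <- fixture("fig2_cycle")
  small <- set_bound(p, "J_in_max", 0.3)
  r <- fba_optimum(small)
  expect_equal(r$mu_opt, 0.3 / (0.15 + 0.85))   # proportional to input bound
  expect_equal(r$limiting_resource, "input_flux")

  conv <- set_bound(set_bound(p, "J_in_max", 50), "Jc_max", 0.5)
  r2 <- fba_optimum(conv)
  expect_equal(r2$mu_opt, 0.5 / 0.85)
  expect_equal(r2$limiting_resource, "conversion")

  r3 <- fba_optimum(set_bound(p, "J_in_max", 50))
  expect_equal(r3$mu_opt, 1)
  expect_equal(r3$limiting_resource, "mu_max")
})

test_that("integration FBA reproduces the carbon/co-/nitrogen-limited sequence", {
  p <- fixture("fig2_integration")   # J_N1_max = 0.3, J_N2_max = 2, e = 1
  # deep carbon limitation: GS/GOGAT off, GDH matches the carbon flux
  r <- fba_optimum(set_bound(p, "J_C_max", 0.1))
  expect_equal(r$mu_opt, 0.1)
  expect_equal(unname(r$fluxes[["nitrogen_gsgogat"]]), 0)
  expect_equal(unname(r$fluxes[["nitrogen_gdh"]]), 0.1)
  expect_equal(r$limiting_resource, "carbon")

  # co-limitation: GDH at its bound, GS/GOGAT active
  r2 <- fba_optimum(set_bound(p, "J_C_max", 1))
  expect_equal(r2$mu_opt, (1 + 0.3) / 2)
  expect_equal(unname(r2$fluxes[["nitrogen_gdh"]]), 0.3)
  expect_gt(r2$fluxes[["nitrogen_gsgogat"]], 0)
  expect_equal(r2$limiting_resource, "both_C_and_N")

  # ample carbon: the growth cap binds
  r3 <- fba_optimum(set_bound(p, "J_C_max", 10))
  expect_equal(r3$mu_opt, 1)
  # nitrogen-limited when the nitrogen bounds are small
  pn <- set_bound(set_bound(p, "J_N1_max", 0.05), "J_N2_max", 0.15)
  r4 <- fba_optimum(pn)
  expect_equal(r4$mu_opt, 0.2)
  expect_equal(r4$limiting_resource, "nitrogen")
})

test_that("piecewise-analytic FBA equals the LP oracle on random draws", {
  set.seed(101)
  for (mod in c("linear", "bidirectional", "cycle", "integration")) {
    for (i in 1:60) {
      p <- rand_module(mod)
      a <- fba_optimum(p); l <- fba_lp(p)
      expect_lt(abs(a$mu_opt - l$mu_opt) / max(1, a$mu_opt), 1e-8)
      # LP representative is futile-free for the bidirectional module
      if (mod == "bidirectional")
        expect_lt(min(l$fluxes[["J12"]], l$fluxes[["J21"]]), 1e-9)
    }
  }
  # degenerate LP corner: every bound zero
  p0 <- bid(0, 0, 0)
  expect_equal(fba_lp(p0)$mu_opt, 0)
  expect_equal(fba_optimum(p0)$mu_opt, 0)
})

test_that("the FBA optimum is monotone in every bound and in mu_max", {
  set.seed(33)
  for (i in 1:20) {
    p <- rand_module(sample(c("linear", "bidirectional", "cycle",
                              "integration"), 1))
    base <- fba_optimum(p)$mu_opt
    for (nm in names(p$flux_bounds)) {
      up <- set_bound(p, nm, p$flux_bounds[[nm]] * 1.5 + 0.1)
      expect_gte(fba_optimum(up)$mu_opt, base - 1e-12)
    }
    p2 <- p; p2$growth$mu_max <- p$growth$mu_max * 2
    expect_gte(fba_optimum(p2)$mu_opt, base - 1e-12)
  }
})

test_that("FBA flux assignments satisfy exact stationarity", {
  set.seed(77)
  for (mod in c("bidirectional", "cycle", "integration")) {
    for (i in 1:20) {
      p <- rand_module(mod); r <- fba_optimum(p)
      fl <- r$fluxes; mu <- r$mu_opt
      resid <- switch(mod,
        bidirectional = c(fl[["input_1"]] - 2 * fl[["J12"]] + fl[["J21"]] - mu,
                          fl[["input_2"]] + fl[["J12"]] - 2 * fl[["J21"]] - mu),
        cycle = {
          rho <- p$growth$rho
          c(fl[["nitrogen_input"]] - fl[["conversion"]] - rho[["Q"]] * mu,
            -fl[["nitrogen_input"]] + 2 * fl[["conversion"]] +
              rho[["Q"]] * mu - rho[["E"]] * mu)
        },
        integration = c(fl[["carbon_input"]] - mu -
                          p$carbon_cost * fl[["nitrogen_gsgogat"]],
                        fl[["nitrogen_gdh"]] + fl[["nitrogen_gsgogat"]] - mu))
      expect_lt(max(abs(resid)), 1e-10)
    }
  }
})
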