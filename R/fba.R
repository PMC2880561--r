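#' Flux-balance optimum of a module (piecewise-analytic)
#'
#' Maximizes the steady-state growth rate subject to exact stationarity of
#' every pool, the module's stoichiometry, and the linear bounds on fluxes
#' and growth. These small problems admit closed-form piecewise solutions:
#'
#' * linear: `mu = min(J_max, mu_max)`;
#' * bidirectional: transfer from the larger-input pool to the smaller at a
#'   2:1 cost, `mu = min(mu_max, (2a + b)/3, a + Jc_max)` with
#'   `a = min(J1_max, J2_max)`, `b = max(...)`;
#' * cycle: `mu = min(mu_max, J_in_max/(rho_Q + rho_E), Jc_max/rho_E)`
#'   (nitrogen balance including the biosynthetic glutamate return);
#' * integration: `mu = min(mu_max, J_N1_max + J_N2_max, f(J_C_max))` where
#'   `f = J_C_max` while carbon-limited (`J_N2 = 0`) and
#'   `f = (J_C_max + e J_N1_max)/(1 + e)` once the carbon-independent
#'   nitrogen flux is saturated and carbon is spent to import nitrogen.
#'
#' The reported flux assignment is the futile-cycle-free, minimal-input
#' representative (at most one interconversion direction active; the
#' carbon-independent nitrogen flux used before the carbon-dependent one).
#'
#' @param params A [module_params()] object. Regulation parameters are
#'   ignored: FBA sees only bounds, stoichiometries and the growth cap.
#' @return An object of class `"fba_result"`: `mu_opt`, `fluxes` (optimal
#'   assignment, named as in [flux_record()]), `limiting_resource`,
#'   `degenerate` (multiple optimal flux assignments exist), `method`.
#' @seealso [fba_lp()] for the generic linear-programming cross-check.
#' @export
fba_optimum <- function(params) {
  stopifnot(inherits(params, "module_params"))
  b <- params$flux_bounds
  mu_max <- params$growth$mu_max
  tol <- 1e-12

  res <- switch(params$module,
    linear = {
      mu <- min(b$J_max, mu_max)
      list(mu_opt = mu,
           fluxes = c(input = mu),
           limiting_resource = if (mu_max <= b$J_max) "mu_max" else "input_flux",
           degenerate = FALSE)
    },
    bidirectional = {
      a <- min(b$J1_max, b$J2_max); bb <- max(b$J1_max, b$J2_max)
      f <- min((2 * a + bb) / 3, a + b$Jc_max)
      mu <- min(mu_max, f)
      t <- max(0, mu - a)                    # transfer toward the a-side pool
      recv1 <- b$J1_max <= b$J2_max          # pool 1 receives on ties
      Ja <- min(a, mu); Jb <- mu + 2 * t
      fl <- if (recv1)
        c(input_1 = Ja, input_2 = Jb, J12 = 0, J21 = t)
      else
        c(input_1 = Jb, input_2 = Ja, J12 = t, J21 = 0)
      lim <- if (mu >= mu_max - tol) "mu_max"
        else if (a + b$Jc_max < (2 * a + bb) / 3 - tol) "interconversion"
        else "input_flux"
      slack1 <- b$J1_max - fl[["input_1"]]; slack2 <- b$J2_max - fl[["input_2"]]
      deg <- (min(slack1, slack2) > 1e-9) && (b$Jc_max > t + 1e-9)
      list(mu_opt = mu, fluxes = fl, limiting_resource = lim, degenerate = deg)
    },
    cycle = {
      rho <- params$growth$rho
      cand <- c(mu_max = mu_max,
                input_flux = b$J_in_max / (rho[["Q"]] + rho[["E"]]),
                conversion = b$Jc_max / rho[["E"]])
      mu <- min(cand)
      lim <- names(cand)[which(cand <= mu + tol)][1]
      list(mu_opt = mu,
           fluxes = c(nitrogen_input = (rho[["Q"]] + rho[["E"]]) * mu,
                      conversion = rho[["E"]] * mu,
                      biosynthetic_return = rho[["Q"]] * mu),
           limiting_resource = lim, degenerate = FALSE)
    },
    integration = {
      e <- params$carbon_cost
      fC <- if (b$J_C_max <= b$J_N1_max) b$J_C_max
            else (b$J_C_max + e * b$J_N1_max) / (1 + e)
      cand <- c(mu_max = mu_max,
                nitrogen = b$J_N1_max + b$J_N2_max,
                carbon = fC)
      mu <- min(cand)
      lim <- names(cand)[which(cand <= mu + tol)][1]
      if (lim == "carbon" && b$J_C_max > b$J_N1_max) lim <- "both_C_and_N"
      JN1 <- min(b$J_N1_max, mu); JN2 <- mu - JN1
      fl <- c(carbon_input = mu + e * JN2, nitrogen_gdh = JN1,
              nitrogen_gsgogat = JN2)
      if (lim == "mu_max") {
        lo <- max(0, mu - b$J_N1_max)
        hi <- min(b$J_N2_max, if (e > 0) (b$J_C_max - mu) / e else Inf, mu)
        deg <- hi > lo + 1e-9
      } else deg <- FALSE
      if (any(params$leak > 0) &&
          (b$J_N1_max + b$J_N2_max > JN1 + JN2 + 1e-9)) deg <- TRUE
      list(mu_opt = mu, fluxes = fl, limiting_resource = lim, degenerate = deg)
    })

  structure(c(res, list(method = "analytic", module = params$module)),
            class = "fba_result")
}

# Build the module's LP: variables (mu, fluxes...), equality stationarity
# rows, upper bounds. Leak appears as a free non-negative drain variable, so
# the optimizer sets it to zero and the optimum upper-bounds leaky kinetics.
build_lp_ <- function(params) {
  b <- params$flux_bounds
  mu_max <- params$growth$mu_max
  switch(params$module,
    linear = list(
      vars = c("mu", "input"),
      A3 = matrix(c(-1, 1), 1), b3 = 0,
      ub = c(mu = mu_max, input = b$J_max),
      futile = character(), inputs = "input"),
    bidirectional = list(
      vars = c("mu", "input_1", "input_2", "J12", "J21"),
      A3 = rbind(c(-1, 1, 0, -2,  1),
                 c(-1, 0, 1,  1, -2)), b3 = c(0, 0),
      ub = c(mu = mu_max, input_1 = b$J1_max, input_2 = b$J2_max,
             J12 = b$Jc_max, J21 = b$Jc_max),
      futile = c("J12", "J21"), inputs = c("input_1", "input_2")),
    cycle = {
      rho <- params$growth$rho
      list(
        vars = c("mu", "nitrogen_input", "conversion"),
        # Q: J_in - J_conv - rho_Q mu = 0 ; E: -J_in + 2 J_conv + (rho_Q - rho_E) mu = 0
        A3 = rbind(c(-rho[["Q"]], 1, -1),
                   c(rho[["Q"]] - rho[["E"]], -1, 2)), b3 = c(0, 0),
        ub = c(mu = mu_max, nitrogen_input = b$J_in_max, conversion = b$Jc_max),
        futile = character(), inputs = "nitrogen_input")
    },
    integration = {
      e <- params$carbon_cost
      leaky <- params$leak[["N"]] > 0
      if (leaky) list(
        vars = c("mu", "carbon_input", "nitrogen_gdh", "nitrogen_gsgogat", "leak_N"),
        A3 = rbind(c(-1, 1, 0, -e, 0),
                   c(-1, 0, 1,  1, -1)), b3 = c(0, 0),
        ub = c(mu = mu_max, carbon_input = b$J_C_max, nitrogen_gdh = b$J_N1_max,
               nitrogen_gsgogat = b$J_N2_max, leak_N = NA),
        futile = "leak_N",
        inputs = c("carbon_input", "nitrogen_gdh", "nitrogen_gsgogat"))
      else list(
        vars = c("mu", "carbon_input", "nitrogen_gdh", "nitrogen_gsgogat"),
        A3 = rbind(c(-1, 1, 0, -e),
                   c(-1, 0, 1,  1)), b3 = c(0, 0),
        ub = c(mu = mu_max, carbon_input = b$J_C_max, nitrogen_gdh = b$J_N1_max,
               nitrogen_gsgogat = b$J_N2_max),
        futile = character(),
        inputs = c("carbon_input", "nitrogen_gdh", "nitrogen_gsgogat"))
    })
}

simplex_solve_ <- function(obj, lp, A2 = NULL, b2 = NULL, extra_A1 = NULL,
                           extra_b1 = NULL, maxi = TRUE) {
  nv <- length(lp$vars)
  ubs <- lp$ub[!is.na(lp$ub)]
  A1 <- diag(nv)[match(names(ubs), lp$vars), , drop = FALSE]
  b1 <- unname(ubs)
  if (!is.null(extra_A1)) { A1 <- rbind(A1, extra_A1); b1 <- c(b1, extra_b1) }
  s <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                     A3 = lp$A3, b3 = lp$b3, maxi = maxi, n.iter = 200,
                     eps = 1e-12)
  if (s$solved < 0)
    stop("LP solver reported infeasibility for module constraints:\n",
         paste(utils::capture.output(print(lp)), collapse = "\n"))
  s
}

#' Flux-balance optimum by linear programming (generic oracle)
#'
#' Solves the same growth-maximization problem as [fba_optimum()] with a
#' generic simplex solver, independent of the piecewise-analytic formulas:
#' maximize `mu` over `(mu, fluxes)` subject to stationarity of every pool
#' and the flux bounds. Among optimal solutions, a lexicographic secondary
#' pass minimizes total interconversion (futile) flux and then total input
#' flux, so the reported assignment is the deterministic, biologically
#' efficient representative with `min(J12, J21) = 0`. A final pass checks
#' whether any other optimal flux assignment exists (`degenerate`).
#'
#' @inheritParams fba_optimum
#' @return An `"fba_result"` (see [fba_optimum()]), `method = "lp"`.
#' @export
fba_lp <- function(params) {
  stopifnot(inherits(params, "module_params"))
  lp <- build_lp_(params)
  nv <- length(lp$vars)
  e_mu <- as.numeric(lp$vars == "mu")

  # fully degenerate corner: every flux bound zero forces the zero solution
  # (stationarity with all fluxes zero implies mu = 0)
  flux_ub <- lp$ub[setdiff(names(lp$ub), "mu")]
  if (all(flux_ub[!is.na(flux_ub)] == 0)) {
    fl <- stats::setNames(numeric(nv - 1L), setdiff(lp$vars, "mu"))
    return(structure(list(mu_opt = 0, fluxes = fl,
                          limiting_resource = lp_limiting_(params, 0, fl),
                          degenerate = FALSE, method = "lp",
                          module = params$module),
                     class = "fba_result"))
  }

  s1 <- simplex_solve_(e_mu, lp)
  mu_opt <- max(0, s1$value)
  mu_floor <- mu_opt - 1e-9 * max(1, mu_opt)
  A2 <- matrix(e_mu, 1); b2 <- max(0, mu_floor)

  e_fut <- as.numeric(lp$vars %in% lp$futile)
  e_inp <- as.numeric(lp$vars %in% lp$inputs)
  sol <- stats::setNames(unname(s1$soln), lp$vars)
  if (any(e_fut > 0)) {
    s2 <- simplex_solve_(e_fut, lp, A2 = A2, b2 = b2, maxi = FALSE)
    fut_min <- s2$value
    s3 <- simplex_solve_(e_inp, lp, A2 = A2, b2 = b2,
                         extra_A1 = matrix(e_fut, 1),
                         extra_b1 = fut_min + 1e-9 * max(1, fut_min),
                         maxi = FALSE)
    sol <- stats::setNames(unname(s3$soln), lp$vars)
  } else {
    s3 <- simplex_solve_(e_inp, lp, A2 = A2, b2 = b2, maxi = FALSE)
    sol <- stats::setNames(unname(s3$soln), lp$vars)
    fut_min <- 0
  }
  # degeneracy probe: can total (futile + input) flux differ at the optimum?
  s4 <- simplex_solve_(e_fut + e_inp, lp, A2 = A2, b2 = b2, maxi = TRUE)
  tot_min <- sum((e_fut + e_inp) * sol)
  degenerate <- (s4$value - tot_min) > 1e-7 * max(1, tot_min)

  fluxes <- sol[setdiff(lp$vars, "mu")]
  lim <- lp_limiting_(params, mu_opt, fluxes)
  structure(list(mu_opt = mu_opt, fluxes = fluxes, limiting_resource = lim,
                 degenerate = degenerate, method = "lp",
                 module = params$module),
            class = "fba_result")
}

# label the binding resource from the LP solution's tight bounds
lp_limiting_ <- function(params, mu, fluxes, tol = 1e-8) {
  b <- params$flux_bounds
  mu_max <- params$growth$mu_max
  if (mu >= mu_max - tol * max(1, mu_max)) return("mu_max")
  switch(params$module,
    linear = "input_flux",
    bidirectional = {
      a <- min(b$J1_max, b$J2_max)
      if (a + b$Jc_max < (2 * a + max(b$J1_max, b$J2_max)) / 3 - tol)
        "interconversion" else "input_flux"
    },
    cycle = {
      if (fluxes[["conversion"]] >= b$Jc_max - tol) "conversion" else "input_flux"
    },
    integration = {
      nlim <- fluxes[["nitrogen_gdh"]] >= b$J_N1_max - tol &&
        fluxes[["nitrogen_gsgogat"]] >= b$J_N2_max - tol
      if (nlim) return("nitrogen")
      if (fluxes[["nitrogen_gsgogat"]] > tol) "both_C_and_N" else "carbon"
    })
}

#' @export
print.fba_result <- function(x, ...) {
  cat(sprintf("<FBA optimum, %s module (%s)> mu_opt = %.6g\n",
              x$module, x$method, x$mu_opt))
  cat("  limiting resource:", x$limiting_resource,
      if (x$degenerate) "(degenerate optimum)" else "", "\n")
  fl <- x$fluxes
  cat("  fluxes:", paste(sprintf("%s = %.6g", names(fl), fl), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.fba_result <- function(x, ...) {
  data.frame(module = x$module, method = x$method, mu_opt = x$mu_opt,
             limiting_resource = x$limiting_resource,
             degenerate = x$degenerate,
             t(x$fluxes), check.names = FALSE)
}
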