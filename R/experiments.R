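#' Sweep a flux bound: kinetic steady states against the FBA envelope
#'
#' For each grid value of the named maximum flux, computes the kinetic
#' steady state (warm-started from the previous grid point), the FBA
#' optimum, the growth-rate deficit `mu_FBA - mu`, the regime label, pool
#' sizes and (for the bidirectional module) the futile-cycle index. A small
#' number of cold-start spot checks re-solve selected points from the
#' default initial state to flag multistability.
#'
#' @param params A [module_params()] object.
#' @param bound_name Name of the flux bound to sweep.
#' @param grid Increasing, non-negative grid of bound values.
#' @param cold_checks Number of evenly spaced grid indices re-solved from
#'   [default_initial()] (0 to disable).
#' @return A `"module_sweep"` data frame: one row per grid point with
#'   columns `value`, `mu`, `mu_fba`, `deficit`, `regime`, `converged`,
#'   `stable`, one `pool_<name>` column per pool, `futile_index`
#'   (bidirectional, else `NA`) and `multistable_flag`.
#' @export
sweep_input_flux <- function(params, bound_name, grid, cold_checks = 10) {
  stopifnot(inherits(params, "module_params"))
  if (!bound_name %in% names(params$flux_bounds))
    stop("'", bound_name, "' is not a flux bound of the ", params$module,
         " module")
  if (length(grid) < 1 || any(grid < 0) || is.unsorted(grid, strictly = FALSE))
    stop("'grid' must be non-negative and increasing")
  pools <- module_pools(params)
  init <- default_initial(params)
  rows <- vector("list", length(grid))
  states <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    pp <- set_bound(params, bound_name, grid[i])
    ss <- find_steady_state(pp, init)
    fb <- fba_optimum(pp)
    if (ss$converged) init <- ss$pools
    fi <- if (params$module == "bidirectional" && ss$converged)
      futile_cycle_index(ss) else NA_real_
    regime <- if (ss$converged) regime_classify(pp, ss) else NA_character_
    pr <- stats::setNames(as.list(if (ss$converged) ss$pools
                                  else rep(NA_real_, length(pools))),
                          paste0("pool_", pools))
    rows[[i]] <- data.frame(value = grid[i],
                            mu = if (ss$converged) ss$mu else NA_real_,
                            mu_fba = fb$mu_opt,
                            deficit = if (ss$converged) fb$mu_opt - ss$mu else NA_real_,
                            regime = regime,
                            converged = ss$converged,
                            stable = isTRUE(ss$stable),
                            pr,
                            futile_index = fi,
                            multistable_flag = FALSE,
                            check.names = FALSE)
    states[[i]] <- ss
  }
  out <- do.call(rbind, rows)
  if (cold_checks > 0 && length(grid) > 1) {
    idx <- unique(round(seq(1, length(grid), length.out = min(cold_checks, length(grid)))))
    for (i in idx) {
      if (!out$converged[i]) next
      pp <- set_bound(params, bound_name, grid[i])
      ss2 <- find_steady_state(pp, default_initial(params))
      if (ss2$converged &&
          max(abs(ss2$pools - states[[i]]$pools) /
                pmax(1, abs(states[[i]]$pools))) > 1e-4)
        out$multistable_flag[i] <- TRUE
    }
  }
  attr(out, "bound_name") <- bound_name
  attr(out, "params") <- params
  attr(out, "states") <- states
  class(out) <- c("module_sweep", "data.frame")
  out
}

#' Pool-size / growth-rate trade-off surface
#'
#' Evaluates the linear pathway (or any single-feedback module bound) on a
#' grid of feedback-inhibition constants `K` and Hill coefficients `h`, in a
#' fixed scenario, recording the steady pool size and growth deficit. Two
#' log-log scaling slopes are fitted per Hill coefficient:
#'
#' * `slope_K`: pool size versus `K` at fixed input-flux bound in the
#'   growth-saturated regime -- analytically 1 for every `h`, since
#'   inverting the inhibition law at `mu = mu_max` gives
#'   `P = K (J_max/mu_max - 1)^(1/h)`;
#' * `slope_J`: pool size versus the input-flux excess
#'   `J_max/mu_max - 1` at fixed `K` -- the ultrasensitivity scaling `1/h`,
#'   the sublinear growth of the non-limiting pool with increasing input
#'   capacity.
#'
#' @param params Linear-module [module_params()] defining the scenario
#'   (its `J_max` is the fixed growth-saturated operating point).
#' @param K_grid Feedback-constant grid (positive).
#' @param h_list Hill coefficients to evaluate.
#' @param J_grid Input-bound grid for the `slope_J` fit; default
#'   `params$J_max * (2, 4, 8, 16, 32)` to stay in the growth-saturated
#'   regime.
#' @return A data frame (`K`, `h`, `pool`, `mu`, `deficit`) with attribute
#'   `"slopes"`: per-`h` fitted `slope_K` and `slope_J`.
#' @export
tradeoff_surface <- function(params, K_grid, h_list, J_grid = NULL) {
  stopifnot(inherits(params, "module_params"))
  if (params$module != "linear")
    stop("the trade-off surface is defined for the linear module")
  if (any(K_grid <= 0) || any(h_list < 1))
    stop("'K_grid' must be positive and 'h_list' >= 1")
  if (is.null(J_grid))
    J_grid <- params$flux_bounds$J_max * c(2, 4, 8, 16, 32)

  with_fb <- function(K, h) {
    module_params("linear", flux_bounds = params$flux_bounds,
                  feedback = list(input = feedback_term(K = K, h = h)),
                  growth = params$growth)
  }
  rows <- list()
  slopes <- list()
  for (h in h_list) {
    pool_K <- numeric(length(K_grid))
    for (i in seq_along(K_grid)) {
      pp <- with_fb(K_grid[i], h)
      ss <- find_steady_state(pp)
      fb <- fba_optimum(pp)
      pool_K[i] <- ss$pools[["P"]]
      rows[[length(rows) + 1]] <-
        data.frame(K = K_grid[i], h = h, pool = ss$pools[["P"]],
                   mu = ss$mu, deficit = fb$mu_opt - ss$mu)
    }
    slope_K <- stats::coef(stats::lm(log(pool_K) ~ log(K_grid)))[[2]]
    pool_J <- vapply(J_grid, function(J) {
      pp <- set_bound(with_fb(K_grid[1], h), "J_max", J)
      find_steady_state(pp)$pools[["P"]]
    }, numeric(1))
    # regress on the flux excess J/mu_max - 1: the inversion of the
    # inhibition law at mu = mu_max gives pool = K * excess^(1/h) exactly
    excess <- J_grid / params$growth$mu_max - 1
    slope_J <- stats::coef(stats::lm(log(pool_J) ~ log(excess)))[[2]]
    slopes[[length(slopes) + 1]] <-
      data.frame(h = h, slope_K = slope_K, slope_J = slope_J)
  }
  out <- do.call(rbind, rows)
  attr(out, "slopes") <- do.call(rbind, slopes)
  out
}

#' Futile-cycle index of a bidirectional steady state
#'
#' `min(J12, J21) / max(J12, J21, eps)`: 0 when at most one interconversion
#' direction carries flux (no futile cycling), 1 when both directions carry
#' equal flux.
#'
#' @param result A `steady_state` (bidirectional module) or a named flux
#'   vector containing `J12` and `J21`.
#' @param eps Guard against 0/0 (default `1e-12`).
#' @return Index in \[0, 1\].
#' @export
futile_cycle_index <- function(result, eps = 1e-12) {
  fl <- if (inherits(result, "steady_state")) {
    if (result$params$module != "bidirectional")
      stop("futile_cycle_index applies to the bidirectional module")
    result$fluxes
  } else if (inherits(result, "fba_result")) {
    if (result$module != "bidirectional")
      stop("futile_cycle_index applies to the bidirectional module")
    result$fluxes
  } else result
  if (!all(c("J12", "J21") %in% names(fl)))
    stop("fluxes must contain J12 and J21")
  min(fl[["J12"]], fl[["J21"]]) / max(fl[["J12"]], fl[["J21"]], eps)
}

#' Classify the operating regime of a converged steady state
#'
#' Combines the FBA limiting resource at the same parameters with the
#' growth-limiting status of each pool into the regime vocabulary of the
#' module: `input-limited`, `interconversion-limited`,
#' `conversion-limited`, `carbon-limited`, `co-limited`,
#' `nitrogen-limited` or `mu_max-limited`.
#'
#' @param params The [module_params()] the state was computed under.
#' @param result A converged `steady_state`.
#' @return Character regime label.
#' @export
regime_classify <- function(params, result) {
  stopifnot(inherits(params, "module_params"), inherits(result, "steady_state"))
  if (!result$converged)
    stop("regime classification requires a converged steady state")
  fb <- fba_optimum(params)
  switch(fb$limiting_resource,
         mu_max = "mu_max-limited",
         input_flux = "input-limited",
         interconversion = "interconversion-limited",
         conversion = "conversion-limited",
         carbon = "carbon-limited",
         both_C_and_N = "co-limited",
         nitrogen = "nitrogen-limited")
}

#' Nitrogen-upshift protocol: wild-type versus feedback-defective module
#'
#' Equilibrates both parameter sets to their pre-shift steady state,
#' instantaneously raises the named flux bounds at `t = 0`, and integrates
#' the post-shift dynamics. Reports per-pool fold changes relative to the
#' pre-shift steady state and the normalized cumulative-biomass growth
#' curve `exp(integral of mu dt)` (biomass normalized to 1 at the shift),
#' for both variants.
#'
#' @param params_wt Wild-type-like [module_params()] (all feedbacks).
#' @param params_ko Feedback-defective variant (e.g. GS-feedback knockout
#'   with a nitrogen-pool leak).
#' @param shift Named list of new bound values applied at `t = 0`.
#' @param t_end Post-shift simulation horizon.
#' @param n_out Output time points.
#' @return A list of two `"upshift_result"` objects (`wt`, `ko`), each with
#'   `pre_shift` (steady state), `trajectory`, `fold_changes` (matrix),
#'   `growth_curve` (normalized biomass), `peak_fold` (per pool, max of
#'   `|log2 fold|` over time, signed by direction).
#' @export
nitrogen_upshift <- function(params_wt, params_ko, shift, t_end = 400,
                             n_out = 400) {
  run_one <- function(params, label) {
    pre <- find_steady_state(params)
    if (!pre$converged)
      stop("pre-shift steady state did not converge for the ", label,
           " variant")
    pp <- params
    for (nm in names(shift)) pp <- set_bound(pp, nm, shift[[nm]])
    tr <- integrate_module(pp, initial = pre$pools, t_end = t_end,
                           record = TRUE, n_out = n_out)
    fold <- sweep(tr$pools, 2, pre$pools, "/")
    # cumulative biomass: trapezoidal integral of mu(t)
    dt <- diff(tr$times)
    cum <- c(0, cumsum((tr$mu[-1] + tr$mu[-length(tr$mu)]) / 2 * dt))
    growth_curve <- exp(cum)
    peak <- apply(fold, 2, function(f) {
      lf <- log2(pmax(f, 1e-12)); lf[which.max(abs(lf))]
    })
    structure(list(variant = label, pre_shift = pre, trajectory = tr,
                   fold_changes = fold, growth_curve = growth_curve,
                   times = tr$times, peak_fold = peak,
                   mu_final = tr$mu[length(tr$mu)]),
              class = "upshift_result")
  }
  list(wt = run_one(params_wt, "wt"), ko = run_one(params_ko, "ko"))
}

#' Robustness of the upshift orderings to parameter perturbation
#'
#' Repeats [nitrogen_upshift()] under multiplicative perturbations (uniform
#' in `1 +/- rel`) of every kinetic parameter (flux bounds, feedback
#' constants, leak), applied identically to the wild-type and knockout
#' variants, and records for each draw whether (a) the knockout's peak
#' fold changes of both pools exceed the wild type's and (b) the wild
#' type's post-shift growth gain is at least the knockout's.
#'
#' @inheritParams nitrogen_upshift
#' @param n Number of perturbation draws.
#' @param rel Relative perturbation half-width (default 0.2).
#' @param seed RNG seed (single deterministic generator).
#' @return Data frame of per-draw logicals with attribute
#'   `"fraction_ok"` (fraction of draws satisfying both orderings).
#' @export
upshift_robustness <- function(params_wt, params_ko, shift, n = 50,
                               rel = 0.2, t_end = 400, seed = 20100603) {
  perturb <- function(params, fac) {
    i <- 0
    nxt <- function() { i <<- i + 1; fac[i] }
    for (nm in names(params$flux_bounds))
      params$flux_bounds[[nm]] <- params$flux_bounds[[nm]] * nxt()
    for (nm in names(params$feedback)) {
      f <- params$feedback[[nm]]
      if (f$enabled) params$feedback[[nm]] <- feedback_term(f$K * nxt(), f$h)
      else nxt()
    }
    params$leak <- params$leak * nxt()
    params
  }
  n_fac <- length(params_wt$flux_bounds) + length(params_wt$feedback) + 1
  set.seed(seed)
  facs <- matrix(stats::runif(n * (n_fac + length(shift)), 1 - rel, 1 + rel),
                 nrow = n)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    fac <- facs[k, seq_len(n_fac)]
    sh_fac <- facs[k, n_fac + seq_along(shift)]
    sh <- stats::setNames(as.list(unlist(shift) * sh_fac), names(shift))
    ok <- tryCatch({
      up <- nitrogen_upshift(perturb(params_wt, fac), perturb(params_ko, fac),
                             sh, t_end = t_end, n_out = 200)
      pk_wt <- abs(up$wt$peak_fold); pk_ko <- abs(up$ko$peak_fold)
      folds_ok <- all(pk_ko > pk_wt)
      gain_wt <- up$wt$mu_final - up$wt$pre_shift$mu
      gain_ko <- up$ko$mu_final - up$ko$pre_shift$mu
      c(folds_ok, gain_wt >= gain_ko)
    }, error = function(e) c(NA, NA))
    rows[[k]] <- data.frame(draw = k, folds_amplified_in_ko = ok[1],
                            wt_growth_gain_ge_ko = ok[2])
  }
  out <- do.call(rbind, rows)
  both <- out$folds_amplified_in_ko & out$wt_growth_gain_ge_ko
  attr(out, "fraction_ok") <- mean(both, na.rm = FALSE)
  out
}

#' @export
print.upshift_result <- function(x, ...) {
  cat(sprintf("<upshift, %s variant> pre-shift mu = %.4g, final mu = %.4g\n",
              x$variant, x$pre_shift$mu, x$mu_final))
  cat("  peak |log2 fold| per pool:",
      paste(sprintf("%s = %.3g", names(x$peak_fold), x$peak_fold),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.module_sweep <- function(x, ...) {
  graphics::plot(x$value, x$mu_fba, type = "l", col = "grey50", lwd = 2,
                 xlab = attr(x, "bound_name"), ylab = "growth rate", ...)
  graphics::lines(x$value, x$mu, col = "black", lwd = 1.5)
  graphics::legend("bottomright", legend = c("FBA optimum", "kinetic"),
                   col = c("grey50", "black"), lwd = c(2, 1.5), bty = "n")
  invisible(x)
}

#' @export
plot.upshift_result <- function(x, log = "y", ...) {
  graphics::matplot(x$times, x$fold_changes, type = "l", lty = 1,
                    xlab = "time after shift", ylab = "fold change",
                    log = log, ...)
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topright", legend = colnames(x$fold_changes),
                   col = seq_len(ncol(x$fold_changes)), lty = 1, bty = "n")
  invisible(x)
}

#' Stability scan of the assimilation cycle across its three regimes
#'
#' For each regime-defining set of flux bounds, integrates the cycle from
#' the common default initial state and classifies the outcome:
#' `"stable"` (converged to a Jacobian-stable steady state with positive
#' growth), `"unstable"` (a steady state exists at the endpoint but has a
#' positive leading eigenvalue), `"collapsed"` (converged to the stalled
#' cycle with essentially zero growth -- a pool shrank to zero), or
#' `"diverged"` (a pool grows without bound / no steady state reached).
#'
#' @param params Cycle [module_params()] (any scheme).
#' @param regimes Named list of bound settings, each a named vector over
#'   `J_in_max` / `Jc_max`. Default: the input-, conversion- and
#'   mu_max-limited operating points of the standard cycle scenario.
#' @param t_budget Integration time budget per regime.
#' @param mu_floor Growth rate below which a converged state counts as
#'   collapsed (fraction of `mu_max`).
#' @param diverge_at Pool size treated as unbounded growth.
#' @return Data frame: regime, verdict, mu, mu_fba, pools, leading
#'   eigenvalue real part.
#' @export
cycle_stability_scan <- function(params,
                                 regimes = list(
                                   input = c(J_in_max = 0.3, Jc_max = 2),
                                   conversion = c(J_in_max = 5, Jc_max = 0.5),
                                   mu_max = c(J_in_max = 5, Jc_max = 2)),
                                 t_budget = 2e4, mu_floor = 1e-3,
                                 diverge_at = 1e6) {
  stopifnot(inherits(params, "module_params"))
  if (params$module != "cycle")
    stop("the stability scan applies to the cycle module")
  rows <- vector("list", length(regimes))
  for (i in seq_along(regimes)) {
    pp <- params
    for (nm in names(regimes[[i]])) pp <- set_bound(pp, nm, regimes[[i]][[nm]])
    fb <- fba_optimum(pp)
    ss <- find_steady_state(pp, t_max = t_budget)
    verdict <- if (ss$converged && all(is.finite(ss$pools))) {
      if (ss$mu <= mu_floor * pp$growth$mu_max) "collapsed"
      else if (isTRUE(ss$stable)) "stable"
      else "unstable"
    } else if (any(!is.finite(ss$pools)) || max(ss$pools) > diverge_at) {
      "diverged"
    } else "diverged"
    rows[[i]] <- data.frame(regime = names(regimes)[i], verdict = verdict,
                            mu = ss$mu, mu_fba = fb$mu_opt,
                            pool_E = ss$pools[[1]], pool_Q = ss$pools[[2]],
                            eigen_max_real = ss$eigen_max_real)
  }
  do.call(rbind, rows)
}
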