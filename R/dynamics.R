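#' Default initial pool state
#'
#' All pools at 0.1 (in growth-saturating-pool-size units): small but
#' positive, avoiding the absorbing boundary at zero growth.
#'
#' @param params A [module_params()] object.
#' @return Named numeric vector.
#' @export
default_initial <- function(params) {
  stats::setNames(rep(0.1, length(module_pools(params))), module_pools(params))
}

#' Integrate a module to (or towards) steady state
#'
#' Adaptive stiff integration (`deSolve::lsodar`) of the module kinetics.
#' A root function stops the integration early once the scaled residual
#' `max|dP/dt| / max(1, ||P||)` stays below `ss_tol`; the steady state is
#' then confirmed by continuing for a further `confirm_window` time units.
#'
#' @param params A [module_params()] object.
#' @param initial Non-negative initial pool vector (default
#'   [default_initial()]).
#' @param t_end Maximum integration time (> 0).
#' @param record If `TRUE` (default) return the full trajectory on `n_out`
#'   points; otherwise only the first and last state.
#' @param n_out Number of output times when recording.
#' @param ss_tol Steady-state residual tolerance.
#' @param confirm_window Time units the residual must stay below `ss_tol`.
#' @param rtol,atol Integrator relative/absolute tolerances.
#' @return An object of class `"module_trajectory"`: `times`, `pools`
#'   (matrix, one column per pool), `mu`, `fluxes` (matrix), `steady`
#'   (logical: residual criterion met), `clipped` (negative-state clipping
#'   triggered), `params`.
#' @export
integrate_module <- function(params, initial = default_initial(params),
                             t_end = 1000, record = TRUE, n_out = 400,
                             ss_tol = 1e-8, confirm_window = 10,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "module_params"), t_end > 0)
  pools <- module_pools(params)
  if (length(initial) != length(pools) || any(initial < 0))
    stop("'initial' must be a non-negative vector of length ", length(pools))
  y0 <- stats::setNames(as.numeric(initial), pools)

  clip_env <- new.env(parent = emptyenv()); clip_env$clipped <- FALSE
  deriv_fn <- function(t, y, p) {
    r <- module_rhs(y, params, clip = TRUE)
    if (r$clipped) clip_env$clipped <- TRUE
    list(r$derivatives)
  }
  root_fn <- function(t, y, p) {
    r <- module_rhs(y, params, clip = TRUE)
    max(abs(r$derivatives)) / max(1, sqrt(sum(pmax(y, 0)^2))) - ss_tol
  }

  run <- function(y0, t0, t1) {
    times <- if (record) seq(t0, t1, length.out = max(2L, ceiling(n_out * (t1 - t0) / t_end)))
             else c(t0, t1)
    deSolve::lsodar(y = y0, times = times, func = deriv_fn, parms = NULL,
                    rtol = rtol, atol = atol, rootfunc = root_fn,
                    maxsteps = 50000)
  }

  out <- run(y0, 0, t_end)
  t_last <- out[nrow(out), 1]
  rooted <- !is.null(attr(out, "iroot")) || t_last < t_end - 1e-9
  steady <- FALSE
  if (rooted && t_last < t_end) {
    # confirm the steady state over a sustained window
    y_last <- out[nrow(out), pools, drop = TRUE]
    out2 <- run(pmax(as.numeric(y_last), 0) |> stats::setNames(pools),
                t_last, min(t_end, t_last + confirm_window))
    resid2 <- root_fn(0, out2[nrow(out2), pools], NULL)
    steady <- resid2 <= 0
    out <- rbind(out, out2[-1, , drop = FALSE])
  } else {
    resid <- root_fn(0, out[nrow(out), pools], NULL)
    steady <- resid <= 0
  }

  times <- out[, 1]
  pm <- pmax(out[, pools, drop = FALSE], 0)
  eval_pt <- function(x) module_rhs(x, params, clip = TRUE)
  recs <- apply(pm, 1, function(x) {
    r <- eval_pt(x); c(r$mu, r$fluxes)
  })
  recs <- t(recs)
  structure(list(times = times,
                 pools = pm,
                 mu = recs[, 1],
                 fluxes = recs[, -1, drop = FALSE],
                 steady = steady,
                 clipped = clip_env$clipped,
                 params = params),
            class = "module_trajectory")
}

# Damped Newton iteration on the module rhs, with backtracking line search
# and non-negativity clipping. Returns the polished state (possibly not
# converged) or NULL on numerical breakdown.
newton_polish_ <- function(params, x0, max_iter = 60) {
  fn <- function(x) module_rhs(pmax(x, 0), params, clip = TRUE)$derivatives
  x <- pmax(as.numeric(x0), 0)
  f <- tryCatch(fn(x), error = function(e) NULL)
  if (is.null(f)) return(NULL)
  for (it in seq_len(max_iter)) {
    nf <- max(abs(f))
    if (nf < 1e-14 * max(1, max(abs(x)))) break
    Jm <- tryCatch(pracma::jacobian(fn, x), error = function(e) NULL)
    if (is.null(Jm) || any(!is.finite(Jm))) return(x)
    step <- tryCatch(solve(Jm, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(x)
    lam <- 1
    improved <- FALSE
    for (k in 1:25) {
      x_new <- pmax(x + lam * step, 0)
      f_new <- tryCatch(fn(x_new), error = function(e) NULL)
      if (!is.null(f_new) && all(is.finite(f_new)) && max(abs(f_new)) < nf) {
        x <- x_new; f <- f_new; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  x
}

#' Steady state of a module
#'
#' Finds a steady state of the module kinetics: the system is first relaxed
#' by stiff integration from `initial_guess`, then the root of the
#' right-hand side is polished by a damped Newton iteration
#' (`pracma::fsolve`). The result carries the residual, a convergence flag
#' and the local stability verdict from [stability()].
#'
#' Non-convergence is a first-class outcome, not an error: in regimes where
#' a pool grows without limit (e.g. no feedback inhibition with input
#' exceeding the growth cap) the result has `converged = FALSE`.
#'
#' @param params A [module_params()] object.
#' @param initial_guess Non-negative starting state.
#' @param t_max Total integration time budget for the relaxation phase.
#' @param tol Residual tolerance `max|dP/dt| <= tol * max(1, ||P||)`.
#' @return An object of class `"steady_state"`: `pools`, `mu`, `fluxes`,
#'   `stable`, `eigen_max_real`, `marginal`, `converged`, `residual`,
#'   `method` (`"root"` or `"integration"`).
#' @export
find_steady_state <- function(params, initial_guess = default_initial(params),
                              t_max = 1e5, tol = 1e-8,
                              method = c("auto", "root")) {
  stopifnot(inherits(params, "module_params"))
  method <- match.arg(method)
  pools <- module_pools(params)
  scaled_resid <- function(x) {
    d <- module_rhs(x, params, clip = TRUE)$derivatives
    max(abs(d)) / max(1, sqrt(sum(x^2)))
  }

  if (method == "root") {
    # direct Newton from the guess (finds unstable roots too); a few scaled
    # restarts guard against bad basins
    best <- NULL
    for (scale in c(1, 0.1, 10, 100)) {
      g <- pmax(as.numeric(initial_guess), 1e-6) * scale
      cand <- newton_polish_(params, g)
      if (!is.null(cand) && all(is.finite(cand)) &&
          (is.null(best) || scaled_resid(cand) < scaled_resid(best)))
        best <- cand
      if (!is.null(best) && scaled_resid(best) <= tol) break
    }
    y <- if (is.null(best)) pmax(as.numeric(initial_guess), 0) else best
    y <- stats::setNames(y, pools)
    resid <- scaled_resid(y)
    converged <- resid <= tol
    r <- module_rhs(y, params, clip = TRUE)
    st <- if (converged) stability(params, y, .checked = TRUE)
          else list(stable = NA, eigen_max_real = NA_real_, marginal = NA)
    return(structure(list(pools = y, mu = r$mu, fluxes = r$fluxes,
                          stable = st$stable,
                          eigen_max_real = st$eigen_max_real,
                          marginal = st$marginal, converged = converged,
                          residual = resid, method = "root",
                          params = params),
                     class = "steady_state"))
  }

  # relaxation: geometric ladder of integration horizons
  y <- stats::setNames(pmax(as.numeric(initial_guess), 0), pools)
  method <- "integration"
  t_done <- 0; t_chunk <- 100
  diverged <- FALSE
  while (t_done < t_max) {
    tr <- tryCatch(
      integrate_module(params, y, t_end = min(t_chunk, t_max - t_done),
                       record = FALSE, ss_tol = tol),
      error = function(e) NULL)
    if (is.null(tr)) { diverged <- TRUE; break }
    y_new <- tr$pools[nrow(tr$pools), ]
    if (any(!is.finite(y_new)) || max(y_new) > 1e12) { diverged <- TRUE; y <- y_new; break }
    y <- y_new
    t_done <- t_done + t_chunk
    if (tr$steady) break
    t_chunk <- t_chunk * 4
  }

  if (!diverged) {
    # Newton polish on the raw state
    xs <- newton_polish_(params, as.numeric(y))
    if (!is.null(xs) && all(is.finite(xs)) &&
        scaled_resid(xs) < scaled_resid(y)) {
      method <- "root"
      y <- stats::setNames(xs, pools)
    }
  }

  resid <- if (all(is.finite(y))) scaled_resid(y) else Inf
  converged <- is.finite(resid) && resid <= tol
  r <- if (all(is.finite(y))) module_rhs(y, params, clip = TRUE) else NULL

  st <- if (converged) stability(params, y, .checked = TRUE)
        else list(stable = NA, eigen_max_real = NA_real_, marginal = NA)
  structure(list(pools = if (!is.null(r)) stats::setNames(y, pools) else y,
                 mu = if (!is.null(r)) r$mu else NA_real_,
                 fluxes = if (!is.null(r)) r$fluxes else NULL,
                 stable = st$stable,
                 eigen_max_real = st$eigen_max_real,
                 marginal = st$marginal,
                 converged = converged,
                 residual = resid,
                 method = method,
                 params = params),
            class = "steady_state")
}

#' Closed-form steady-state pool of the linear pathway (h = 1)
#'
#' For non-cooperative feedback the stationarity condition
#' `J_max / (1 + P/K) = mu_max / (1 + sigma/P)` is a quadratic in `P` with
#' the positive root
#' \deqn{P^* = \frac{K}{2\mu_{max}}\left[(J_{max}-\mu_{max}) +
#'   \sqrt{(J_{max}-\mu_{max})^2 + 4 J_{max}\mu_{max}\sigma/K}\right].}
#' The two asymptotes are attached as attributes: `input_limited`
#' (`P ~ sigma J_max/(mu_max - J_max)`, small when `J_max << mu_max`) and
#' `mu_max_limited` (`P ~ K (J_max/mu_max - 1)`, proportional to the
#' feedback-inhibition constant when `J_max >> mu_max`).
#'
#' @param params Linear-module [module_params()] with `h = 1` input feedback.
#' @return Steady-state pool size (numeric scalar) with attribute
#'   `"asymptotes"`.
#' @export
analytic_pool_linear <- function(params) {
  stopifnot(inherits(params, "module_params"))
  if (params$module != "linear")
    stop("closed form applies to the linear module only")
  fb <- params$feedback$input
  if (!fb$enabled || abs(fb$h - 1) > 1e-12)
    stop("closed form requires an enabled input feedback with h = 1")
  J <- params$flux_bounds$J_max
  mu <- params$growth$mu_max
  K <- fb$K
  sigma <- params$growth$sigma[["P"]] * params$growth$rho[["P"]]
  P <- K / (2 * mu) * ((J - mu) + sqrt((J - mu)^2 + 4 * J * mu * sigma / K))
  attr(P, "asymptotes") <- c(
    input_limited = if (J < mu) sigma * J / (mu - J) else NA_real_,
    mu_max_limited = if (J > mu) K * (J / mu - 1) else NA_real_)
  P
}

#' Local stability of a steady state
#'
#' Finite-difference Jacobian of the module right-hand side at the state,
#' classified by the largest real part of its eigenvalues: stable iff all
#' real parts are below `-stability_tol`. States within `stability_tol` of
#' the imaginary axis are reported unstable with `marginal = TRUE`.
#'
#' @param params A [module_params()] object.
#' @param pools A steady state (scaled residual within `resid_tol`).
#' @param stability_tol Margin on eigenvalue real parts.
#' @param resid_tol Precondition tolerance on the residual at `pools`.
#' @param .checked Internal: skip the precondition test.
#' @return List with `stable`, `eigen_max_real`, `marginal`, `eigenvalues`.
#' @export
stability <- function(params, pools, stability_tol = 1e-8, resid_tol = 1e-6,
                      .checked = FALSE) {
  stopifnot(inherits(params, "module_params"))
  x <- pmax(as.numeric(pools), 0)
  if (!.checked) {
    d <- module_rhs(x, params, clip = TRUE)$derivatives
    if (max(abs(d)) / max(1, sqrt(sum(x^2))) > resid_tol)
      stop("stability() requires a steady state (residual above tolerance)")
  }
  fn <- function(z) module_rhs(pmax(z, 0), params, clip = TRUE)$derivatives
  Jm <- pracma::jacobian(fn, x)
  ev <- eigen(Jm, only.values = TRUE)$values
  emax <- max(Re(ev))
  list(stable = emax < -stability_tol,
       eigen_max_real = emax,
       marginal = abs(emax) <= stability_tol,
       eigenvalues = ev)
}

#' @export
print.module_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory, %s module> t in [%g, %g], %d points%s\n",
              x$params$module, min(x$times), max(x$times), length(x$times),
              if (x$steady) ", reached steady state" else ""))
  last <- x$pools[nrow(x$pools), ]
  cat("  final pools:", paste(sprintf("%s = %.4g", colnames(x$pools), last),
                              collapse = ", "),
      sprintf("; mu = %.4g\n", x$mu[length(x$mu)]))
  invisible(x)
}

#' @export
as.data.frame.module_trajectory <- function(x, ...) {
  wide <- data.frame(time = x$times, x$pools, mu = x$mu, x$fluxes,
                     check.names = FALSE)
  vars <- setdiff(names(wide), "time")
  data.frame(time = rep(wide$time, length(vars)),
             variable = rep(vars, each = nrow(wide)),
             value = unlist(wide[vars], use.names = FALSE))
}

#' @export
plot.module_trajectory <- function(x, log = "", ...) {
  pools <- colnames(x$pools)
  graphics::matplot(x$times, x$pools, type = "l", lty = 1,
                    col = seq_along(pools), xlab = "time",
                    ylab = "pool size", log = log, ...)
  graphics::legend("topright", legend = pools, col = seq_along(pools), lty = 1,
                   bty = "n")
  invisible(x)
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady state, %s module> %s\n", x$params$module,
              if (x$converged) sprintf("converged (%s), residual = %.2e",
                                       x$method, x$residual)
              else "NOT converged"))
  if (x$converged) {
    cat("  pools:", paste(sprintf("%s = %.5g", names(x$pools), x$pools),
                          collapse = ", "), "\n")
    cat(sprintf("  mu = %.6g; %s (max Re eigenvalue = %.3g)\n", x$mu,
                if (isTRUE(x$stable)) "stable" else "unstable",
                x$eigen_max_real))
  }
  invisible(x)
}
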