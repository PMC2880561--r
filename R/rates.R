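#' Hill-type product-feedback inhibition term
#'
#' Describes the multiplicative attenuation of a bounded flux by the pool of
#' its downstream product: `factor = 1 / (1 + (P/K)^h)`. The factor is 1 when
#' the pool is empty, 1/2 when the pool equals the inhibition constant `K`,
#' and approaches 0 for pools far above `K`, so an inhibited flux
#' `J_max * factor` always respects the bound `J <= J_max`.
#'
#' `h = 1` models simple (non-cooperative) feedback inhibition; `h > 1`
#' models ultrasensitive feedback as produced by, e.g., covalent-modification
#' cascades or cooperative transcriptional control. `h` need not be an
#' integer: it is an effective Hill coefficient. A disabled term (feedback
#' knockout) evaluates identically to 1 and carries no constant.
#'
#' @param K Feedback-inhibition constant (concentration, > 0). May be `NA`
#'   when `enabled = FALSE`.
#' @param h Effective Hill coefficient (>= 1).
#' @param enabled If `FALSE` the term is a knockout: the factor is exactly 1.
#' @return An object of class `"feedback_term"`.
#' @seealso [inhibition_factor()]
#' @export
feedback_term <- function(K, h = 1, enabled = TRUE) {
  stopifnot(is.logical(enabled), length(enabled) == 1L)
  if (enabled) {
    if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
      stop("feedback-inhibition constant 'K' must be a single finite value > 0")
    if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h < 1)
      stop("Hill coefficient 'h' must be a single finite value >= 1")
  } else {
    K <- NA_real_
    h <- NA_real_
  }
  structure(list(K = as.numeric(K), h = as.numeric(h), enabled = enabled),
            class = "feedback_term")
}

#' Michaelis-Menten saturation term
#'
#' Saturation of an enzymatic flux in its substrate:
#' `factor = P^n / (P^n + K_M^n)` with `n = hill_order`. The order-2 form is
#' used for interconversions that consume two substrate molecules per product
#' molecule.
#'
#' @param K_M Michaelis-Menten constant of the enzyme-substrate pair (> 0).
#' @param hill_order Substrate exponent, 1 or 2.
#' @return An object of class `"saturation_term"`.
#' @seealso [saturation_factor()]
#' @export
saturation_term <- function(K_M, hill_order = 1L) {
  if (!is.numeric(K_M) || length(K_M) != 1L || !is.finite(K_M) || K_M <= 0)
    stop("Michaelis-Menten constant 'K_M' must be a single finite value > 0")
  if (!hill_order %in% c(1L, 2L))
    stop("'hill_order' must be 1 or 2")
  structure(list(K_M = as.numeric(K_M), hill_order = as.integer(hill_order)),
            class = "saturation_term")
}

#' Growth-law parameters
#'
#' Parameters of the multi-pool growth-rate function used by every module
#' (see [growth_rate()]). Each essential metabolite pool has a growth-
#' saturating pool size `sigma` above which growth becomes asymptotically
#' independent of that pool, and a dimensionless stoichiometry weight `rho`
#' giving its relative consumption per unit of growth (all 1 except the
#' glutamine/glutamate weights of the nitrogen-assimilation cycle).
#'
#' By convention all concentrations are measured in units of the growth-
#' saturating pool size, so `sigma = 1` by default, and rates in units of the
#' maximum growth rate.
#'
#' @param mu_max Maximum growth rate (> 0).
#' @param sigma Named vector of growth-saturating pool sizes, one per pool.
#' @param rho Stoichiometry weights, one per pool (recycled if length 1).
#' @return An object of class `"growth_params"`.
#' @export
growth_params <- function(mu_max = 1, sigma = c(P = 1), rho = 1) {
  if (!is.numeric(mu_max) || length(mu_max) != 1L || !is.finite(mu_max) || mu_max <= 0)
    stop("'mu_max' must be a single finite value > 0")
  if (!is.numeric(sigma) || length(sigma) < 1L || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all growth-saturating pool sizes 'sigma' must be finite and > 0")
  if (is.null(names(sigma)) || any(!nzchar(names(sigma))))
    stop("'sigma' must be a named vector (one entry per metabolite pool)")
  rho <- rep_len(as.numeric(rho), length(sigma))
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("all stoichiometry weights 'rho' must be finite and > 0")
  names(rho) <- names(sigma)
  structure(list(mu_max = as.numeric(mu_max), sigma = as.numeric(sigma) |>
                   stats::setNames(names(sigma)), rho = rho),
            class = "growth_params")
}

#' Feedback-inhibition factor
#'
#' Evaluates the Hill-type attenuation `1 / (1 + (P/K)^h)` of a flux by its
#' product pool `P`. Returns exactly 1 for a disabled (knocked-out) term.
#'
#' @param P Product pool size(s), >= 0 (vectorised).
#' @param term A [feedback_term()].
#' @return Dimensionless factor(s) in (0, 1].
#' @examples
#' inhibition_factor(0, feedback_term(K = 2))          # 1: no product
#' inhibition_factor(2, feedback_term(K = 2))          # 1/2: half-maximal
#' inhibition_factor(4, feedback_term(K = 2, h = 4))   # strong ultrasensitive inhibition
#' @export
inhibition_factor <- function(P, term) {
  stopifnot(inherits(term, "feedback_term"))
  if (any(!is.finite(P)) || any(P < 0))
    stop("pool size 'P' must be finite and >= 0")
  if (!term$enabled) return(rep_len(1, length(P)))
  1 / (1 + (P / term$K)^term$h)
}

#' Substrate-saturation factor
#'
#' Evaluates `P^n / (P^n + K_M^n)` for a [saturation_term()]: 0 with no
#' substrate, approaching 1 at enzyme saturation, and 1/2 at `P = K_M`.
#'
#' @param P Substrate pool size(s), >= 0 (vectorised).
#' @param term A [saturation_term()].
#' @return Dimensionless factor(s) in \[0, 1).
#' @export
saturation_factor <- function(P, term) {
  stopifnot(inherits(term, "saturation_term"))
  if (any(!is.finite(P)) || any(P < 0))
    stop("pool size 'P' must be finite and >= 0")
  Pn <- P^term$hill_order
  Pn / (Pn + term$K_M^term$hill_order)
}

#' Growth rate as a function of metabolite pools
#'
#' The growth law of a heteropolymer (biomass) assembled from essential
#' monomers with pool sizes `P_i`:
#' \deqn{\mu(\{P_i\}) = \frac{\mu_{max}}{1 + \sum_i \rho_i \sigma_i / P_i}.}
#' It is strictly increasing in every pool, vanishes as any pool vanishes,
#' approaches `mu_max` when every pool is far above its saturating size
#' `sigma_i`, and becomes asymptotically independent of pool `i` once
#' `P_i >> sigma_i`. The stoichiometry weights `rho_i` rescale each pool's
#' effective contribution (a heavily used monomer must be more abundant to
#' sustain the same growth rate).
#'
#' @param pools Named or ordered vector of pool sizes, >= 0, one per pool in
#'   `gp$sigma`.
#' @param gp A [growth_params()] object.
#' @return Growth rate in (0, `mu_max`\]; 0 if any pool is 0.
#' @export
growth_rate <- function(pools, gp) {
  stopifnot(inherits(gp, "growth_params"))
  if (length(pools) != length(gp$sigma))
    stop("'pools' must have one entry per pool in the growth law (",
         length(gp$sigma), ")")
  if (any(!is.finite(pools)) || any(pools < 0))
    stop("all pool sizes must be finite and >= 0")
  if (any(pools == 0)) return(0)
  gp$mu_max / (1 + sum(gp$rho * gp$sigma / pools))
}

#' Is a pool growth-limiting?
#'
#' A pool is classified as growth-limiting when its size is at or below its
#' growth-saturating size (`P <= sigma`, inclusive boundary), i.e. when
#' increasing it would still appreciably increase the growth rate. Used for
#' regime reporting only; it has no effect on the dynamics.
#'
#' @param pool_index Index of the pool within `gp$sigma`.
#' @param pools Pool-size vector as in [growth_rate()].
#' @param gp A [growth_params()] object.
#' @return `TRUE` if the pool is growth-limiting.
#' @export
is_growth_limiting <- function(pool_index, pools, gp) {
  stopifnot(inherits(gp, "growth_params"))
  if (!is.numeric(pool_index) || length(pool_index) != 1L ||
      pool_index < 1 || pool_index > length(gp$sigma))
    stop("'pool_index' out of range")
  if (length(pools) != length(gp$sigma))
    stop("'pools' must have one entry per pool in the growth law")
  pools[[pool_index]] <= gp$sigma[[pool_index]]
}

#' @export
print.feedback_term <- function(x, ...) {
  if (x$enabled)
    cat(sprintf("<feedback term> K = %g, h = %g\n", x$K, x$h))
  else
    cat("<feedback term> disabled (factor = 1)\n")
  invisible(x)
}

#' @export
print.saturation_term <- function(x, ...) {
  cat(sprintf("<saturation term> K_M = %g, order = %d\n", x$K_M, x$hill_order))
  invisible(x)
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("<growth law> mu_max = %g\n", x$mu_max))
  cat("  pools:", paste(sprintf("%s (sigma = %g, rho = %g)", names(x$sigma),
                                x$sigma, x$rho), collapse = ", "), "\n")
  invisible(x)
}
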