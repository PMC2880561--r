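#' Module right-hand side: pool derivatives and instantaneous fluxes
#'
#' Evaluates the kinetic equations of the selected module at a pool state:
#' every input flux is its bound times its feedback-inhibition factor, every
#' enzymatic conversion is its bound times a substrate-saturation factor
#' (times a product-feedback factor under the Full-FI scheme), and growth
#' drains each pool in proportion to the growth rate and the pool's
#' stoichiometry weight. No dilution-by-growth term is included: the growth
#' efflux is purely stoichiometric consumption.
#'
#' Stoichiometries: the bidirectional interconversion consumes two molecules
#' of the source pool per molecule of the target pool produced (`J12` is the
#' production rate of `P2` from `P1`); the cycle's nitrogen input consumes
#' one glutamate per glutamine formed, its conversion flux consumes one
#' glutamine and yields two glutamates, and glutamine consumed for
#' biosynthesis (`rho_Q * mu`) credits one glutamate back per molecule; the
#' integration module's carbon-dependent nitrogen flux spends `carbon_cost`
#' units of carbon per unit of nitrogen imported and is unconstrained by the
#' carbon pool size (high ATP affinity).
#'
#' @param state Named or ordered numeric vector of pool sizes (>= 0; see
#'   [module_pools()] for order).
#' @param params A [module_params()] object.
#' @param clip If `TRUE`, small negative pool values (as produced transiently
#'   by an adaptive integrator) are clipped to 0 instead of raising an
#'   error; the returned list then reports `clipped = TRUE` when clipping
#'   occurred.
#' @return A list with `derivatives` (named, d(pool)/dt), `fluxes` (named
#'   instantaneous fluxes, all >= 0 and within their bounds), `mu` (growth
#'   rate) and `clipped`.
#' @export
module_rhs <- function(state, params, clip = FALSE) {
  stopifnot(inherits(params, "module_params"))
  pools <- module_pools(params)
  if (length(state) != length(pools))
    stop("state must have ", length(pools), " entries (", paste(pools, collapse = ", "), ")")
  x <- as.numeric(state)
  clipped <- FALSE
  if (any(x < 0)) {
    if (!clip) stop("negative pool size in state")
    clipped <- any(x < 0)
    x <- pmax(x, 0)
  }
  names(x) <- pools
  out <- switch(params$module,
                linear        = rhs_linear_(x, params),
                bidirectional = rhs_bidirectional_(x, params),
                cycle         = rhs_cycle_(x, params),
                integration   = rhs_integration_(x, params))
  out$clipped <- clipped
  out
}

# dP/dt = J_max/(1+(P/K)^h) - mu(P)
rhs_linear_ <- function(x, params) {
  J_in <- params$flux_bounds$J_max * inhibition_factor(x[["P"]], params$feedback$input)
  mu <- growth_rate(x, params$growth)
  leak <- params$leak * x
  d <- c(P = J_in - mu - leak[["P"]])
  list(derivatives = d,
       fluxes = c(input = J_in, growth_efflux = mu, leak_P = leak[["P"]]),
       mu = mu)
}

# dP1/dt = J1 - 2 J12 + J21 - mu ; dP2/dt = J2 + J12 - 2 J21 - mu
# J12 = Jc_max * sat2(P1) * [fb by P2], J21 mirrored; brackets off under min-FI.
rhs_bidirectional_ <- function(x, params) {
  fb <- params$feedback; st <- params$saturation; b <- params$flux_bounds
  J1 <- b$J1_max * inhibition_factor(x[["P1"]], fb$input1)
  J2 <- b$J2_max * inhibition_factor(x[["P2"]], fb$input2)
  full <- params$scheme == "full_fi"
  J12 <- b$Jc_max * saturation_factor(x[["P1"]], st$J12) *
    (if (full) inhibition_factor(x[["P2"]], fb$J12) else 1)
  J21 <- b$Jc_max * saturation_factor(x[["P2"]], st$J21) *
    (if (full) inhibition_factor(x[["P1"]], fb$J21) else 1)
  mu <- growth_rate(x, params$growth)
  leak <- params$leak * x
  d <- c(P1 = J1 - 2 * J12 + J21 - mu - leak[["P1"]],
         P2 = J2 + J12 - 2 * J21 - mu - leak[["P2"]])
  list(derivatives = d,
       fluxes = c(input_1 = J1, input_2 = J2, J12 = J12, J21 = J21,
                  growth_efflux_1 = mu, growth_efflux_2 = mu,
                  leak_P1 = leak[["P1"]], leak_P2 = leak[["P2"]]),
       mu = mu)
}

# dE/dt = -J_in + 2 J_conv + rho_Q mu - rho_E mu ; dQ/dt = J_in - J_conv - rho_Q mu
# J_in saturates in E and is inhibited by Q (or by E for the from_E Min-FI
# variant); J_conv saturates in Q and is inhibited by E under Full-FI.
rhs_cycle_ <- function(x, params) {
  fb <- params$feedback; st <- params$saturation; b <- params$flux_bounds
  E <- x[["E"]]; Q <- x[["Q"]]
  full <- params$scheme == "full_fi"
  inh_pool <- if (!full && params$min_fi_input == "from_E") E else Q
  J_in <- b$J_in_max * saturation_factor(E, st$input) *
    inhibition_factor(inh_pool, fb$input)
  J_conv <- b$Jc_max * saturation_factor(Q, st$conversion) *
    (if (full) inhibition_factor(E, fb$conversion) else 1)
  mu <- growth_rate(x, params$growth)
  rho <- params$growth$rho
  ret <- rho[["Q"]] * mu                    # glutamate returned by biosynthesis
  leak <- params$leak * x
  d <- c(E = -J_in + 2 * J_conv + ret - rho[["E"]] * mu - leak[["E"]],
         Q = J_in - J_conv - rho[["Q"]] * mu - leak[["Q"]])
  list(derivatives = d,
       fluxes = c(nitrogen_input = J_in, conversion = J_conv,
                  growth_efflux_E = rho[["E"]] * mu,
                  growth_efflux_Q = rho[["Q"]] * mu,
                  biosynthetic_return = ret,
                  leak_E = leak[["E"]], leak_Q = leak[["Q"]]),
       mu = mu)
}

# dC/dt = J_C - mu - e J_N2 ; dN/dt = J_N1 + J_N2 - mu - leak_N N
rhs_integration_ <- function(x, params) {
  fb <- params$feedback; b <- params$flux_bounds
  C <- x[["C"]]; N <- x[["N"]]
  J_C  <- b$J_C_max  * inhibition_factor(C, fb$C)
  J_N1 <- b$J_N1_max * inhibition_factor(N, fb$N1)
  J_N2 <- b$J_N2_max * inhibition_factor(N, fb$N2)
  mu <- growth_rate(x, params$growth)
  e <- params$carbon_cost
  leak <- params$leak * x
  d <- c(C = J_C - mu - e * J_N2 - leak[["C"]],
         N = J_N1 + J_N2 - mu - leak[["N"]])
  list(derivatives = d,
       fluxes = c(carbon_input = J_C, nitrogen_gdh = J_N1,
                  nitrogen_gsgogat = J_N2, carbon_cost = e * J_N2,
                  growth_efflux_C = mu, growth_efflux_N = mu,
                  leak_C = leak[["C"]], leak_N = leak[["N"]]),
       mu = mu)
}

#' Instantaneous fluxes at a state
#'
#' All instantaneous fluxes of the module at the given pool state, without
#' the derivatives. Used for reporting, futile-cycle metrics and regime
#' classification.
#'
#' @inheritParams module_rhs
#' @return Named numeric vector of fluxes.
#' @export
flux_record <- function(state, params) {
  module_rhs(state, params)$fluxes
}
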