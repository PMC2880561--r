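#' Parameters of a metabolic module
#'
#' Builds the full parameter set for one of the four feedback-regulated
#' modules:
#'
#' * `"linear"` -- one pool `P`; a bounded, product-inhibited input flux
#'   feeds the pool, growth drains it.
#' * `"bidirectional"` -- pools `P1`, `P2`; two product-inhibited input
#'   fluxes plus costly interconversion (2 molecules in per 1 molecule out,
#'   both directions, shared bound `Jc_max`).
#' * `"cycle"` -- the glutamine-glutamate nitrogen-assimilation cycle, pools
#'   `E` (glutamate) and `Q` (glutamine); nitrogen input converts one E into
#'   one Q, the bounded conversion flux converts one Q into two E, and
#'   glutamine consumed for biosynthesis returns a glutamate.
#' * `"integration"` -- carbon/nitrogen integration, pools `C` and `N`; one
#'   carbon input and two nitrogen inputs (GDH-like, carbon-independent, and
#'   GS/GOGAT-like, which spends carbon), all product-inhibited.
#'
#' Regulation schemes: `scheme = "full_fi"` places feedback on every flux
#' (inputs and interconversion/conversion); `scheme = "min_fi"` keeps only
#' the input feedbacks. For the cycle's Min-FI scheme, `min_fi_input`
#' selects whether glutamine (`"from_Q"`) or glutamate (`"from_E"`)
#' inhibits the nitrogen input. Named feedbacks can additionally be knocked
#' out with `knockout` (e.g. `"N2"` removes the feedback on the GS/GOGAT
#' flux, the glnE-deletion analogue).
#'
#' Unless stated otherwise, all concentrations are in units of the growth-
#' saturating pool size and all rates in units of `mu_max`.
#'
#' @param module One of `"linear"`, `"bidirectional"`, `"cycle"`,
#'   `"integration"`.
#' @param flux_bounds Named list/vector of maximum fluxes. Names by module:
#'   linear `J_max`; bidirectional `J1_max`, `J2_max`, `Jc_max`; cycle
#'   `J_in_max`, `Jc_max`; integration `J_C_max`, `J_N1_max`, `J_N2_max`.
#' @param feedback Named list of [feedback_term()]s. Names by module:
#'   linear `input`; bidirectional `input1`, `input2`, `J12`, `J21`
#'   (the last two act only under `full_fi`); cycle `input`, `conversion`;
#'   integration `C`, `N1`, `N2`.
#' @param saturation Named list of [saturation_term()]s: bidirectional
#'   `J12`, `J21` (order 2); cycle `input` (substrate E), `conversion`
#'   (substrate Q).
#' @param growth A [growth_params()] whose pools match the module.
#' @param scheme `"full_fi"` or `"min_fi"`.
#' @param min_fi_input For the cycle only: `"from_Q"` or `"from_E"`.
#' @param carbon_cost Integration only: units of carbon spent per unit of
#'   nitrogen imported through the carbon-dependent flux (default 1).
#' @param leak Named vector of first-order leak coefficients per pool
#'   (default none). Applied as `-leak * pool`.
#' @param knockout Character vector of feedback names forced to disabled.
#' @return An object of class `c("module_params_<module>", "module_params")`.
#' @export
module_params <- function(module,
                          flux_bounds,
                          feedback,
                          saturation = list(),
                          growth,
                          scheme = c("full_fi", "min_fi"),
                          min_fi_input = c("from_Q", "from_E"),
                          carbon_cost = 1,
                          leak = NULL,
                          knockout = character()) {
  module <- match.arg(module, c("linear", "bidirectional", "cycle", "integration"))
  scheme <- match.arg(scheme)
  min_fi_input <- match.arg(min_fi_input)
  stopifnot(inherits(growth, "growth_params"))

  pools <- switch(module,
                  linear        = "P",
                  bidirectional = c("P1", "P2"),
                  cycle         = c("E", "Q"),
                  integration   = c("C", "N"))
  if (!identical(names(growth$sigma), pools))
    stop("growth law pools must be ", paste(pools, collapse = ", "),
         " for the ", module, " module")

  need_bounds <- switch(module,
                        linear        = "J_max",
                        bidirectional = c("J1_max", "J2_max", "Jc_max"),
                        cycle         = c("J_in_max", "Jc_max"),
                        integration   = c("J_C_max", "J_N1_max", "J_N2_max"))
  flux_bounds <- as.list(flux_bounds)
  missing_b <- setdiff(need_bounds, names(flux_bounds))
  if (length(missing_b))
    stop("missing flux bound(s): ", paste(missing_b, collapse = ", "))
  extra_b <- setdiff(names(flux_bounds), need_bounds)
  if (length(extra_b))
    stop("unknown flux bound(s): ", paste(extra_b, collapse = ", "))
  for (nm in need_bounds) {
    b <- flux_bounds[[nm]]
    if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0)
      stop("flux bound '", nm, "' must be a single value >= 0")
  }

  need_fb <- switch(module,
                    linear        = "input",
                    bidirectional = c("input1", "input2", "J12", "J21"),
                    cycle         = c("input", "conversion"),
                    integration   = c("C", "N1", "N2"))
  missing_f <- setdiff(need_fb, names(feedback))
  if (length(missing_f))
    stop("missing feedback term(s): ", paste(missing_f, collapse = ", "))
  for (nm in need_fb)
    if (!inherits(feedback[[nm]], "feedback_term"))
      stop("feedback '", nm, "' is not a feedback_term")

  bad_ko <- setdiff(knockout, need_fb)
  if (length(bad_ko))
    stop("knockout names not among this module's feedbacks: ",
         paste(bad_ko, collapse = ", "))
  for (nm in knockout) feedback[[nm]] <- feedback_term(enabled = FALSE)

  need_sat <- switch(module,
                     linear        = character(),
                     bidirectional = c("J12", "J21"),
                     cycle         = c("input", "conversion"),
                     integration   = character())
  missing_s <- setdiff(need_sat, names(saturation))
  if (length(missing_s))
    stop("missing saturation term(s): ", paste(missing_s, collapse = ", "))
  for (nm in need_sat)
    if (!inherits(saturation[[nm]], "saturation_term"))
      stop("saturation '", nm, "' is not a saturation_term")

  if (!is.numeric(carbon_cost) || length(carbon_cost) != 1L || carbon_cost < 0)
    stop("'carbon_cost' must be a single value >= 0")

  leak_full <- stats::setNames(numeric(length(pools)), pools)
  if (!is.null(leak)) {
    if (is.null(names(leak)) || any(!names(leak) %in% pools))
      stop("'leak' must be named by pool (", paste(pools, collapse = ", "), ")")
    if (any(leak < 0)) stop("leak coefficients must be >= 0")
    leak_full[names(leak)] <- leak
  }

  structure(list(module = module,
                 flux_bounds = lapply(flux_bounds[need_bounds], as.numeric),
                 feedback = feedback[need_fb],
                 saturation = saturation[need_sat],
                 growth = growth,
                 scheme = scheme,
                 min_fi_input = if (module == "cycle") min_fi_input else NA_character_,
                 carbon_cost = as.numeric(carbon_cost),
                 leak = leak_full,
                 knockout = knockout),
            class = c(paste0("module_params_", module), "module_params"))
}

#' Pool labels of a module
#'
#' @param params A [module_params()] object.
#' @return Character vector of pool names, in state-vector order.
#' @export
module_pools <- function(params) {
  stopifnot(inherits(params, "module_params"))
  names(params$growth$sigma)
}

#' Replace a flux bound
#'
#' Convenience for parameter sweeps and upshift protocols: returns a copy of
#' `params` with the named maximum flux replaced.
#'
#' @param params A [module_params()] object.
#' @param name Name of the bound (e.g. `"J_max"`, `"J_N1_max"`).
#' @param value New value (>= 0).
#' @return Modified `module_params` object.
#' @export
set_bound <- function(params, name, value) {
  stopifnot(inherits(params, "module_params"))
  if (!name %in% names(params$flux_bounds))
    stop("'", name, "' is not a flux bound of the ", params$module, " module")
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0)
    stop("bound value must be a single value >= 0")
  params$flux_bounds[[name]] <- as.numeric(value)
  params
}

#' @export
print.module_params <- function(x, ...) {
  cat(sprintf("<%s module> scheme = %s\n", x$module, x$scheme))
  b <- unlist(x$flux_bounds)
  cat("  bounds:", paste(sprintf("%s = %g", names(b), b), collapse = ", "), "\n")
  fb <- vapply(x$feedback, function(f)
    if (f$enabled) sprintf("K=%g,h=%g", f$K, f$h) else "off", character(1))
  cat("  feedback:", paste(sprintf("%s [%s]", names(fb), fb), collapse = ", "), "\n")
  if (length(x$saturation)) {
    st <- vapply(x$saturation, function(s)
      sprintf("K_M=%g,n=%d", s$K_M, s$hill_order), character(1))
    cat("  saturation:", paste(sprintf("%s [%s]", names(st), st), collapse = ", "), "\n")
  }
  if (x$module == "cycle" && x$scheme == "min_fi")
    cat("  min-FI input feedback:", x$min_fi_input, "\n")
  if (any(x$leak > 0))
    cat("  leak:", paste(sprintf("%s = %g", names(x$leak)[x$leak > 0],
                                 x$leak[x$leak > 0]), collapse = ", "), "\n")
  print(x$growth)
  invisible(x)
}
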