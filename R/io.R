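#' Load and validate a scenario configuration
#'
#' Reads a JSON or YAML scenario description, validates it against the
#' known keys, fills defaults, and builds the corresponding
#' [module_params()] object from the fixture catalog plus overrides.
#' Unknown keys, unknown fixtures/protocols and invalid values are rejected
#' with an error naming the offending key.
#'
#' Recognized keys: `fixture` (catalog name, required), `protocol`
#' (`"sweep"`, `"tradeoff"`, `"upshift"`, `"stability-scan"`; required),
#' `hill`, `scheme`, `min_fi_input`, `bounds` (named overrides),
#' `bound_name`, `grid` (either a list of `values` or `from`/`to`/`n` with
#' optional `log = true`), `K_grid`, `h_list`, `shift`, `t_end`,
#' `n_perturb`, `seed`, `formats` (subset of `"csv"`, `"json"`).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `"scenario_config"` list with elements `params` (the built
#'   `module_params`), `protocol`, protocol arguments, `seed`, `formats`
#'   and the raw `config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else stop("config must be .json, .yaml or .yml: ", path)

  known <- c("fixture", "protocol", "hill", "scheme", "min_fi_input",
             "bounds", "bound_name", "grid", "K_grid", "h_list", "shift",
             "t_end", "n_perturb", "seed", "formats")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$fixture))
    stop("config key 'fixture' is required (one of: ",
         paste(fixture_catalog()$name, collapse = ", "), ")")
  if (!cfg$fixture %in% fixture_catalog()$name)
    stop("unknown fixture in key 'fixture': ", cfg$fixture)
  if (is.null(cfg$protocol))
    stop("config key 'protocol' is required")
  protocol <- match.arg(cfg$protocol,
                        c("sweep", "tradeoff", "upshift", "stability-scan"))

  params <- fixture(cfg$fixture,
                    hill = cfg$hill,
                    scheme = cfg$scheme,
                    min_fi_input = if (is.null(cfg$min_fi_input)) "from_Q"
                                   else cfg$min_fi_input)
  if (!is.null(cfg$bounds)) {
    for (nm in names(cfg$bounds)) {
      if (!nm %in% names(params$flux_bounds))
        stop("config key 'bounds': '", nm, "' is not a bound of the ",
             params$module, " module")
      if (!is.numeric(cfg$bounds[[nm]]) || cfg$bounds[[nm]] < 0)
        stop("config key 'bounds': '", nm, "' must be a number >= 0")
      params <- set_bound(params, nm, cfg$bounds[[nm]])
    }
  }

  grid <- NULL
  if (!is.null(cfg$grid)) {
    g <- cfg$grid
    grid <- if (!is.null(g$values)) as.numeric(g$values)
    else if (!is.null(g$from) && !is.null(g$to) && !is.null(g$n)) {
      if (isTRUE(g$log)) 10^seq(log10(g$from), log10(g$to), length.out = g$n)
      else seq(g$from, g$to, length.out = g$n)
    } else stop("config key 'grid' needs either 'values' or 'from'/'to'/'n'")
    if (length(grid) < 1 || any(grid < 0) || is.unsorted(grid))
      stop("config key 'grid' must define a non-negative increasing grid")
  }

  formats <- if (is.null(cfg$formats)) c("csv", "json") else cfg$formats
  bad_fmt <- setdiff(formats, c("csv", "json"))
  if (length(bad_fmt))
    stop("config key 'formats': unknown format(s) ",
         paste(bad_fmt, collapse = ", "))

  structure(list(params = params,
                 fixture = cfg$fixture,
                 protocol = protocol,
                 bound_name = cfg$bound_name,
                 grid = grid,
                 K_grid = if (is.null(cfg$K_grid)) NULL else as.numeric(cfg$K_grid),
                 h_list = if (is.null(cfg$h_list)) NULL else as.numeric(cfg$h_list),
                 shift = cfg$shift,
                 t_end = if (is.null(cfg$t_end)) 400 else as.numeric(cfg$t_end),
                 n_perturb = if (is.null(cfg$n_perturb)) 0L else as.integer(cfg$n_perturb),
                 seed = if (is.null(cfg$seed)) 20100603L else as.integer(cfg$seed),
                 formats = formats,
                 config = cfg),
            class = "scenario_config")
}

result_tables_ <- function(result) {
  to_long <- function(df, keep = "value") {
    id <- df[[keep]]
    vars <- setdiff(names(df), keep)
    data.frame(point = rep(id, length(vars)),
               variable = rep(vars, each = nrow(df)),
               value = as.character(unlist(df[vars], use.names = FALSE)),
               stringsAsFactors = FALSE)
  }
  if (inherits(result, "module_sweep")) {
    list(csv = to_long(as.data.frame(result)),
         json = list(protocol = "sweep",
                     bound = attr(result, "bound_name"),
                     n_points = nrow(result),
                     max_deficit = max(result$deficit, na.rm = TRUE),
                     all_below_envelope = all(result$deficit > -1e-8, na.rm = TRUE),
                     table = as.data.frame(result)))
  } else if (is.data.frame(result) && !is.null(attr(result, "slopes"))) {
    list(csv = to_long(cbind(value = seq_len(nrow(result)), result)),
         json = list(protocol = "tradeoff",
                     slopes = attr(result, "slopes"),
                     table = result))
  } else if (is.list(result) && inherits(result$wt, "upshift_result")) {
    mk <- function(u) data.frame(time = u$times,
                                 u$fold_changes,
                                 growth_curve = u$growth_curve,
                                 check.names = FALSE)
    csv <- rbind(cbind(variant = "wt", to_long(mk(result$wt), keep = "time")),
                 cbind(variant = "ko", to_long(mk(result$ko), keep = "time")))
    list(csv = csv,
         json = list(protocol = "upshift",
                     peak_fold_wt = as.list(result$wt$peak_fold),
                     peak_fold_ko = as.list(result$ko$peak_fold),
                     mu_final_wt = result$wt$mu_final,
                     mu_final_ko = result$ko$mu_final,
                     pre_shift_mu_wt = result$wt$pre_shift$mu,
                     pre_shift_mu_ko = result$ko$pre_shift$mu))
  } else if (is.data.frame(result) && "verdict" %in% names(result)) {
    list(csv = to_long(cbind(value = result$regime,
                             result[setdiff(names(result), "regime")])),
         json = list(protocol = "stability-scan", table = result))
  } else stop("unsupported result type for serialization")
}

#' Write protocol results to disk
#'
#' Serializes a protocol result (sweep, trade-off surface, upshift pair or
#' stability scan) as a long-format CSV table and/or a JSON summary, and
#' writes a manifest listing every file with its MD5 content hash. Output
#' is bit-stable: the same result writes identical files.
#'
#' @param result A result object from [sweep_input_flux()],
#'   [tradeoff_surface()], [nitrogen_upshift()] or
#'   [cycle_stability_scan()].
#' @param out_dir Output directory (created if missing).
#' @param formats Subset of `c("csv", "json")`.
#' @param stem File-name stem (default `"result"`).
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
write_results <- function(result, out_dir, formats = c("csv", "json"),
                          stem = "result") {
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  tabs <- result_tables_(result)
  files <- character()
  if ("csv" %in% formats) {
    f <- file.path(out_dir, paste0(stem, ".csv"))
    utils::write.csv(tabs$csv, f, row.names = FALSE)
    files <- c(files, f)
  }
  if ("json" %in% formats) {
    f <- file.path(out_dir, paste0(stem, ".json"))
    jsonlite::write_json(tabs$json, f, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    files <- c(files, f)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out_dir, paste0(stem, "_manifest.csv")),
                   row.names = FALSE)
  invisible(manifest)
}

run_protocol_ <- function(sc) {
  stopifnot(inherits(sc, "scenario_config"))
  set.seed(sc$seed)
  switch(sc$protocol,
    sweep = {
      if (is.null(sc$bound_name) || is.null(sc$grid))
        stop("protocol 'sweep' requires config keys 'bound_name' and 'grid'")
      sweep_input_flux(sc$params, sc$bound_name, sc$grid)
    },
    tradeoff = {
      if (is.null(sc$K_grid) || is.null(sc$h_list))
        stop("protocol 'tradeoff' requires config keys 'K_grid' and 'h_list'")
      tradeoff_surface(sc$params, sc$K_grid, sc$h_list)
    },
    upshift = {
      if (is.null(sc$shift))
        stop("protocol 'upshift' requires config key 'shift'")
      wt <- fixture("fig3_upshift_wt")
      ko <- fixture("fig3_upshift_ko")
      for (nm in names(sc$config$bounds %||% list())) {
        wt <- set_bound(wt, nm, sc$config$bounds[[nm]])
        ko <- set_bound(ko, nm, sc$config$bounds[[nm]])
      }
      nitrogen_upshift(wt, ko, sc$shift, t_end = sc$t_end)
    },
    `stability-scan` = cycle_stability_scan(sc$params))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Implements the subcommands `sweep`, `tradeoff`, `upshift`,
#' `stability-scan` (each taking `--config <file>`, `--out <dir>`,
#' optional `--seed <int>`, `--plot`) and `list-fixtures`. Configuration
#' errors exit with status 2, numerical failures with status 3. Intended
#' to be called by the `inst/cli/feedbackmod` Rscript wrapper; returns the
#' exit code instead of quitting so it can be tested in-process.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code (0 on success).
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: feedbackmod <subcommand> [--config FILE] [--out DIR]",
    "[--seed INT] [--plot]\n",
    "subcommands: sweep | tradeoff | upshift | stability-scan | list-fixtures")
  if (length(argv) < 1) { message(usage); return(invisible(2L)) }
  sub <- argv[1]
  if (sub == "list-fixtures") {
    cat(fixture_catalog()$name, sep = "\n")
    return(invisible(0L))
  }
  if (!sub %in% c("sweep", "tradeoff", "upshift", "stability-scan")) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(2L))
  }
  opt <- list(config = NULL, out = NULL, seed = NULL, plot = FALSE)
  i <- 2
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--plot") { opt$plot <- TRUE; i <- i + 1 }
    else if (a %in% c("--config", "--out", "--seed")) {
      if (i == length(argv)) { message("missing value for ", a); return(invisible(2L)) }
      opt[[sub("^--", "", a)]] <- argv[i + 1]; i <- i + 2
    } else { message("unknown argument: ", a, "\n", usage); return(invisible(2L)) }
  }
  if (is.null(opt$config) || is.null(opt$out)) {
    message("--config and --out are required for '", sub, "'")
    return(invisible(2L))
  }

  sc <- tryCatch(load_config(opt$config), error = function(e) e)
  if (inherits(sc, "error")) {
    message("config error: ", conditionMessage(sc))
    return(invisible(2L))
  }
  if (sc$protocol != sub) {
    message("config protocol '", sc$protocol, "' does not match subcommand '",
            sub, "'")
    return(invisible(2L))
  }
  if (!is.null(opt$seed)) sc$seed <- as.integer(opt$seed)

  message(sprintf("[feedbackmod] %s: fixture %s, seed %d", sub, sc$fixture,
                  sc$seed))
  res <- tryCatch(run_protocol_(sc), error = function(e) e)
  if (inherits(res, "error")) {
    message("numerical failure: ", conditionMessage(res))
    return(invisible(3L))
  }
  man <- tryCatch({
    if (sub == "upshift") {
      m1 <- write_results(res, opt$out, sc$formats, stem = "upshift")
      if (opt$plot) {
        grDevices::png(file.path(opt$out, "upshift_%d.png"), width = 700,
                       height = 500)
        plot(res$wt); plot(res$ko)
        grDevices::dev.off()
      }
      m1
    } else {
      m <- write_results(res, opt$out, sc$formats, stem = sub)
      if (opt$plot && inherits(res, "module_sweep")) {
        grDevices::png(file.path(opt$out, "sweep.png"), width = 700,
                       height = 500)
        plot(res)
        grDevices::dev.off()
      }
      m
    }
  }, error = function(e) e)
  if (inherits(man, "error")) {
    message("I/O failure writing to '", opt$out, "': ",
            conditionMessage(man))
    return(invisible(3L))
  }
  message(sprintf("[feedbackmod] wrote %d file(s) to %s", nrow(man) + 1L,
                  opt$out))
  invisible(0L)
}
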