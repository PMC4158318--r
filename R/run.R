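# Run drivers behind the command-line interface: verification, single
# buckling analysis, and parameter sweeps.  All outputs are deterministic
# for a fixed configuration (modulo the recorded timestamp).

.tool_version <- function() {
  as.character(utils::packageVersion("mtbuckle"))
}

.notices <- function(config, verbose) {
  env <- config$problem$environment
  if (env$sigma_user && verbose) {
    message("note: foundation constant sigma set explicitly (",
            signif(env$sigma, 4), " Pa) and overrides 2.7*Ec = ",
            signif(2.7 * env$Ec, 4), " Pa")
  }
  if (verbose) {
    message("note: modulus ratio k1 is the circumferential-to-axial ratio E2/E1")
  }
}

.out_path <- function(config, suffix) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$out_dir,
            paste0(if (is.null(config$prefix)) config$name else config$prefix,
                   suffix))
}

#' Run the variational verification for a configuration
#'
#' Drives [verify_euler_lagrange()] for the configured problem and writes a
#' JSON report with the per-channel symbolic status, numeric residual
#' bound, and the seed.
#'
#' @param config an `mt_config` (or a path to one).
#' @param verbose emit informational notes.
#' @return the `mt_verification`, invisibly; the report path is attached as
#'   attribute `"path"`.
#' @export
run_verify <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "mt_config"))
  .notices(config, verbose)
  groups <- derive_groups(config$problem)
  set.seed(config$seed)
  ver <- verify_euler_lagrange(groups = groups, NK = 0.1, n_fields = 10L)
  report <- list(
    tool = "mtbuckle", version = .tool_version(), config = config$name,
    seed = config$seed,
    channels = lapply(names(ver$symbolic_zero), function(y) list(
      channel = y, symbolic_zero = ver$symbolic_zero[[y]],
      residual = ver$residual_terms[[y]])),
    max_rel_numeric_residual = ver$max_rel_numeric,
    n_random_fields = ver$n_fields,
    pass = ver$verified)
  path <- .out_path(config, "_verify.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(ver, "path") <- path
  invisible(ver)
}

#' Run a buckling analysis for a configuration
#'
#' Drives [critical_load()] over the configured mode ranges and writes the
#' per-mode table as CSV (columns `m`, `n`, `lambda`, `N_dimless`,
#' `N_dimensional`, `is_critical`) plus a JSON summary with the critical
#' load, mode, amplitude vector, parameter echo and tool version.
#'
#' @inheritParams run_verify
#' @return the `mt_buckling`, invisibly, with output paths attached as
#'   attribute `"paths"`.  A search range in which no mode buckles is a
#'   regular result (`no_buckling = TRUE`), reported in the summary.
#' @export
run_buckle <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "mt_config"))
  .notices(config, verbose)
  groups <- derive_groups(config$problem)
  res <- critical_load(groups, m_range = config$m_range, n_range = config$n_range)
  csv_path <- .out_path(config, "_modes.csv")
  utils::write.csv(res$table, csv_path, row.names = FALSE)
  summary <- list(
    tool = "mtbuckle", version = .tool_version(), config = config$name,
    seed = config$seed,
    groups = unclass(groups)[c("k1", "k2", "c2", "mu1", "eta", "l", "sK", "K")],
    no_buckling = res$no_buckling,
    N_cr_dimless = res$N_cr, N_cr_dimensional = res$N_cr_dimensional,
    critical_mode = if (res$no_buckling) NULL else
      list(m = res$mode$m, n = res$mode$n, lambda = res$mode$lambda),
    eigenvector = res$eigenvector,
    m_range = range(config$m_range), n_range = range(config$n_range),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  json_path <- .out_path(config, "_summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  attr(res, "paths") <- c(csv = csv_path, json = json_path)
  invisible(res)
}

# apply one sweep-axis value to a problem, returning new groups
.sweep_problem <- function(problem, axis, value) {
  g <- problem$geometry
  m <- problem$material
  e <- problem$environment
  switch(axis,
    eta = {
      e$ea0 <- value * g$R
    },
    Ec = {
      if (e$sigma_user) stop("sweeping Ec has no effect while sigma is user-set")
      e$Ec <- value
      e$sigma <- 2.7 * value
    },
    L_over_R = {
      g$L <- value * g$R
    },
    E2_over_E1 = {
      m <- orthotropic_material(m$E1, value * m$E1, m$G, m$mu1, m$mu2)
    },
    stop("unknown sweep axis '", axis, "'"))
  derive_groups(shell_problem(g, m, e))
}

#' Sweep the critical load along a parameter axis
#'
#' Re-solves the buckling problem at every grid point of the configured
#' sweep axis (`eta`, `Ec`, `L_over_R` or `E2_over_E1`) and writes a
#' long-format CSV with one row per grid point: the axis value, `N_cr`
#' (dimensionless and dimensional) and the critical mode.
#'
#' @inheritParams run_verify
#' @return the sweep table (data frame), invisibly, with the CSV path
#'   attached as attribute `"path"`.
#' @export
run_sweep <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "mt_config"))
  if (is.null(config$sweep)) stop("config has no sweep block")
  .notices(config, verbose)
  rows <- lapply(config$sweep$values, function(val) {
    groups <- .sweep_problem(config$problem, config$sweep$axis, val)
    res <- critical_load(groups, config$m_range, config$n_range)
    data.frame(axis = config$sweep$axis, value = val,
               N_cr_dimless = res$N_cr,
               N_cr_dimensional = res$N_cr_dimensional,
               m = if (res$no_buckling) NA_integer_ else res$mode$m,
               n = if (res$no_buckling) NA_integer_ else res$mode$n)
  })
  tab <- do.call(rbind, rows)
  path <- .out_path(config, "_sweep.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  attr(tab, "path") <- path
  invisible(tab)
}
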