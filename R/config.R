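# Run configuration: a single human-editable YAML document with unit
# annotations, converted to SI at parse time.  Microtubule literature mixes
# GPa, MPa, nm and um freely, so values may be plain numbers (SI assumed)
# or strings like "1.5 GPa" / "11.2 nm".

.unit_table <- c(
  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6, "nm" = 1e-9, "pm" = 1e-12,
  "Pa" = 1, "kPa" = 1e3, "MPa" = 1e6, "GPa" = 1e9,
  "N/m" = 1, "nN/nm" = 1
)

#' Parse a quantity with an optional unit annotation
#'
#' @param x a number (taken as SI) or a string like `"2.7 nm"`.
#' @param what name used in error messages.
#' @return the value in SI units.
#' @export
parse_quantity <- function(x, what = "value") {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L) {
    stop("cannot parse ", what, ": expected a number or 'value unit' string")
  }
  parts <- strsplit(trimws(x), "\\s+")[[1L]]
  val <- suppressWarnings(as.numeric(parts[1L]))
  if (is.na(val)) stop("cannot parse ", what, ": '", x, "' is not numeric")
  if (length(parts) == 1L) return(val)
  unit <- parts[2L]
  if (!unit %in% names(.unit_table)) {
    stop("unknown unit '", unit, "' in ", what, "; known: ",
         paste(names(.unit_table), collapse = ", "))
  }
  val * .unit_table[[unit]]
}

.known_keys <- list(
  top = c("geometry", "material", "environment", "modes", "sweep", "output",
          "seed", "name"),
  geometry = c("L", "R", "h", "h0"),
  material = c("E1", "E2", "G", "mu1", "mu2"),
  environment = c("Ec", "sigma", "ea0", "pressure", "kappa", "pressure_value"),
  modes = c("m_max", "n_max", "m_min", "n_min"),
  sweep = c("axis", "values"),
  output = c("dir", "prefix")
)

.check_keys <- function(block, section) {
  unknown <- setdiff(names(block), .known_keys[[section]])
  if (length(unknown)) {
    stop("config validation error in '", section, "': unknown key(s) ",
         paste(unknown, collapse = ", "))
  }
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration describing one shell problem (geometry,
#' material and environment blocks with unit-annotated values), the mode
#' search range, an optional sweep axis, the output location and the seed
#' for randomized checks.  Unknown keys are rejected; all values are
#' validated through the domain constructors, so a configuration that
#' parses is guaranteed to describe a physical problem.
#'
#' @param path path to a YAML file (or a pre-parsed list).
#' @return an object of class `mt_config` with the validated `mt_problem`,
#'   mode ranges, optional sweep, output settings, and the seed.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  .check_keys(cfg, "top")
  for (sec in c("geometry", "material")) {
    if (is.null(cfg[[sec]])) stop("config validation error: missing '", sec, "' block")
  }
  .check_keys(cfg$geometry, "geometry")
  .check_keys(cfg$material, "material")
  g <- cfg$geometry
  geometry <- shell_geometry(
    L = parse_quantity(g$L, "geometry.L"), R = parse_quantity(g$R, "geometry.R"),
    h = parse_quantity(g$h, "geometry.h"),
    h0 = if (is.null(g$h0)) parse_quantity(g$h, "geometry.h")
         else parse_quantity(g$h0, "geometry.h0"))
  m <- cfg$material
  material <- orthotropic_material(
    E1 = parse_quantity(m$E1, "material.E1"), E2 = parse_quantity(m$E2, "material.E2"),
    G = parse_quantity(m$G, "material.G"),
    mu1 = parse_quantity(m$mu1, "material.mu1"),
    mu2 = parse_quantity(m$mu2, "material.mu2"))
  e <- if (is.null(cfg$environment)) list() else cfg$environment
  .check_keys(e, "environment")
  pressure <- switch(if (is.null(e$pressure)) "zero" else e$pressure,
    zero = pressure_zero(),
    proportional = pressure_proportional(parse_quantity(e$kappa, "environment.kappa")),
    constant = pressure_constant(parse_quantity(e$pressure_value,
                                                "environment.pressure_value")),
    stop("config validation error: unknown pressure model '", e$pressure, "'"))
  environment <- shell_environment(
    Ec = if (is.null(e$Ec)) 0 else parse_quantity(e$Ec, "environment.Ec"),
    sigma = if (is.null(e$sigma)) NULL else parse_quantity(e$sigma, "environment.sigma"),
    ea0 = if (is.null(e$ea0)) 0 else parse_quantity(e$ea0, "environment.ea0"),
    pressure = pressure)
  md <- if (is.null(cfg$modes)) list() else cfg$modes
  .check_keys(md, "modes")
  m_range <- seq(if (is.null(md$m_min)) 1L else as.integer(md$m_min),
                 if (is.null(md$m_max)) 5L else as.integer(md$m_max))
  n_range <- seq(if (is.null(md$n_min)) 0L else as.integer(md$n_min),
                 if (is.null(md$n_max)) 8L else as.integer(md$n_max))
  sweep <- NULL
  if (!is.null(cfg$sweep)) {
    .check_keys(cfg$sweep, "sweep")
    axis <- cfg$sweep$axis
    if (!axis %in% c("eta", "Ec", "L_over_R", "E2_over_E1")) {
      stop("config validation error: unknown sweep axis '", axis, "'")
    }
    values <- vapply(cfg$sweep$values, parse_quantity, numeric(1), what = "sweep.values")
    if (!length(values)) stop("config validation error: empty sweep grid")
    sweep <- list(axis = axis, values = values)
  }
  out <- if (is.null(cfg$output)) list() else cfg$output
  .check_keys(out, "output")
  structure(list(
    name = if (is.null(cfg$name)) "run" else cfg$name,
    problem = shell_problem(geometry, material, environment),
    m_range = m_range, n_range = n_range, sweep = sweep,
    out_dir = if (is.null(out$dir)) "." else out$dir,
    prefix = if (is.null(out$prefix)) NULL else out$prefix,
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  ), class = "mt_config")
}

#' Serialize a validated configuration back to YAML
#'
#' Writes SI values (no unit strings), so that
#' `read_run_config(write_run_config(cfg))` round-trips to an identical
#' validated object.
#'
#' @param config an `mt_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "mt_config"))
  p <- config$problem
  env <- p$environment
  e_block <- list(Ec = env$Ec, ea0 = env$ea0, pressure = env$pressure$model)
  if (env$sigma_user) e_block$sigma <- env$sigma
  if (env$pressure$model == "proportional") e_block$kappa <- env$pressure$kappa
  if (env$pressure$model == "constant") e_block$pressure_value <- env$pressure$value
  doc <- list(
    name = config$name,
    geometry = p$geometry[c("L", "R", "h", "h0")],
    material = p$material[c("E1", "E2", "G", "mu1", "mu2")],
    environment = e_block,
    modes = list(m_min = min(config$m_range), m_max = max(config$m_range),
                 n_min = min(config$n_range), n_max = max(config$n_range)),
    output = list(dir = config$out_dir),
    seed = config$seed)
  if (!is.null(config$sweep)) {
    doc$sweep <- list(axis = config$sweep$axis,
                      values = as.list(config$sweep$values))
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Illustrative microtubule parameter sets
#'
#' Named fixtures spanning the regimes the solver covers: local (`eta = 0`)
#' and nonlocal, isotropic and strongly orthotropic walls, with and without
#' the filament-network foundation.  The numbers are illustrative values in
#' the range used for microtubule shell models (radius ~11 nm, wall
#' ~2.7 nm with a smaller effective bending thickness, GPa axial vs MPa
#' circumferential moduli, kPa-scale cytoplasm); they are not measurements,
#' and every fixture passes full validation.
#'
#' @return a named list of `mt_config` objects.
#' @export
mt_fixtures <- function() {
  base <- list(
    geometry = list(L = "112 nm", R = "11.2 nm", h = "2.7 nm", h0 = "1.6 nm"),
    material = list(E1 = "1.5 GPa", E2 = "3 MPa", G = "1.5 MPa",
                    mu1 = 0.3, mu2 = 0.3),
    environment = list(Ec = "1 kPa", ea0 = 0),
    modes = list(m_max = 25, n_max = 8),
    seed = 1)
  fx <- list()
  f <- base; f$name <- "isotropic_local"
  f$material <- list(E1 = "1 GPa", E2 = "1 GPa", G = "0.385 GPa",
                     mu1 = 0.3, mu2 = 0.3)
  f$environment <- list(Ec = 0, ea0 = 0)
  fx$isotropic_local <- read_run_config(f)
  f <- base; f$name <- "orthotropic_local"
  f$environment <- list(Ec = 0, ea0 = 0)
  fx$orthotropic_local <- read_run_config(f)
  f <- base; f$name <- "orthotropic_nonlocal"
  f$environment <- list(Ec = 0, ea0 = "1.12 nm")
  fx$orthotropic_nonlocal <- read_run_config(f)
  f <- base; f$name <- "orthotropic_foundation"
  f$environment <- list(Ec = "1 kPa", ea0 = "1.12 nm")
  fx$orthotropic_foundation <- read_run_config(f)
  fx
}

#' @export
print.mt_config <- function(x, ...) {
  p <- x$problem
  cat(sprintf("mtbuckle run config '%s'\n", x$name))
  cat(sprintf("  geometry: L=%.3g m  R=%.3g m  h=%.3g m  h0=%.3g m\n",
              p$geometry$L, p$geometry$R, p$geometry$h, p$geometry$h0))
  cat(sprintf("  material: E1=%.3g Pa  E2=%.3g Pa  G=%.3g Pa  mu=(%.2f, %.2f)\n",
              p$material$E1, p$material$E2, p$material$G,
              p$material$mu1, p$material$mu2))
  cat(sprintf("  environment: Ec=%.3g Pa  sigma=%.3g Pa%s  ea0=%.3g m  pressure=%s\n",
              p$environment$Ec, p$environment$sigma,
              if (p$environment$sigma_user) " (user)" else " (= 2.7 Ec)",
              p$environment$ea0, p$environment$pressure$model))
  cat(sprintf("  modes: m in [%d, %d], n in [%d, %d]; seed %d\n",
              min(x$m_range), max(x$m_range), min(x$n_range), max(x$n_range),
              x$seed))
  if (!is.null(x$sweep)) {
    cat(sprintf("  sweep: %s over {%s}\n", x$sweep$axis,
                paste(signif(x$sweep$values, 4), collapse = ", ")))
  }
  invisible(x)
}
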