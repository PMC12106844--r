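#' @useDynLib colonysim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm median predict quantile rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Internal parameter registry: every tunable constant, its section, unit and
# provenance ("literature-default" = standard E. coli value from the literature,
# "model-default" = a choice of this model's own, "measured" = directly measured
# quantity for E. coli K12 on glucose minimal medium).
.param_registry <- local({
  reg <- rbind(
    # --- metabolism -----------------------------------------------------------
    c("lambda_g_aer", "metabolism", "1/h",        "1.0",   "literature-default"),
    c("lambda_g_ana", "metabolism", "1/h",        "0.6",   "literature-default"),
    c("lambda_a_aer", "metabolism", "1/h",        "0.4",   "literature-default"),
    c("K_g",          "metabolism", "mM",         "0.1",   "literature-default"),
    c("K_o",          "metabolism", "mM",         "0.005", "literature-default"),
    c("K_a",          "metabolism", "mM",         "5",     "measured"),
    c("D_g_agar",     "metabolism", "um^2/s",     "600",   "literature-default"),
    c("D_g_colony",   "metabolism", "um^2/s",     "300",   "literature-default"),
    c("D_o_agar",     "metabolism", "um^2/s",     "2000",  "literature-default"),
    c("D_o_colony",   "metabolism", "um^2/s",     "1000",  "literature-default"),
    c("D_a_agar",     "metabolism", "um^2/s",     "1000",  "literature-default"),
    c("D_a_colony",   "metabolism", "um^2/s",     "500",   "literature-default"),
    c("q_g_aer",      "metabolism", "mmol/gdw",   "11",    "literature-default"),
    c("q_g_ana",      "metabolism", "mmol/gdw",   "35",    "literature-default"),
    c("q_o_g",        "metabolism", "mmol/gdw",   "25",    "literature-default"),
    c("q_o_a",        "metabolism", "mmol/gdw",   "30",    "literature-default"),
    c("p_a_aer",      "metabolism", "mmol/gdw",   "4",     "model-default"),
    c("p_a_ana",      "metabolism", "mmol/gdw",   "40",    "literature-default"),
    c("q_a_aer",      "metabolism", "mmol/gdw",   "60",    "literature-default"),
    c("m_carbon",     "metabolism", "mmol C/gdw/h", "1.8", "literature-default"),
    c("acetate_per_glucose_maint", "metabolism", "mol/mol", "2", "model-default"),
    c("rho_cell",     "metabolism", "gdw/L",      "200",   "literature-default"),
    c("C_o_ambient",  "metabolism", "mM",         "0.25",  "literature-default"),
    c("C_g_init",     "metabolism", "mM",         "20",    "measured"),
    c("C_a_init",     "metabolism", "mM",         "0",     "measured"),
    c("delta_aer",    "metabolism", "1/day",      "0.2",   "measured"),
    c("delta_ana",    "metabolism", "1/day",      "2",     "measured"),
    c("growth_threshold", "metabolism", "1/h",    "0.01",  "model-default"),
    c("anoxia_cutoff_factor", "metabolism", "x K_o", "1",  "model-default"),
    # --- mechanics ------------------------------------------------------------
    c("r0",           "mechanics", "um",          "0.5",   "measured"),
    c("l_div",        "mechanics", "um",          "4",     "literature-default"),
    c("div_noise",    "mechanics", "fraction",    "0.1",   "model-default"),
    c("kick_angle",   "mechanics", "rad",         "0.01",  "model-default"),
    c("k_cc",         "mechanics", "um^(1/2)/h",  "2000",  "model-default"),
    c("k_wall",       "mechanics", "um^(1/2)/h",  "4000",  "model-default"),
    c("drag",         "mechanics", "h/um^2 (unit drag)", "1", "model-default"),
    c("surface_tension", "mechanics", "1/h",      "400",   "model-default"),
    c("f_settle",     "mechanics", "um^2/h per um", "30",  "model-default"),
    c("vertical_cutoff", "mechanics", "rad",      as.character(pi / 4), "model-default"),
    # --- numerics -------------------------------------------------------------
    c("grid_h",       "numerics",  "um",          "5",     "model-default"),
    c("dt_macro",     "numerics",  "h",           as.character(1 / 30), "model-default"),
    c("dt_mech",      "numerics",  "h",           "0.001", "model-default"),
    c("mech_safety",  "numerics",  "fraction",    "0.4",   "model-default"),
    c("pde_tol",      "numerics",  "relative",    "1e-6",  "model-default"),
    c("pde_maxit",    "numerics",  "iterations",  "1e5",   "model-default"),
    c("n_subcycle",   "numerics",  "substeps",    "3",     "model-default"),
    c("domain_width", "numerics",  "um",          "1000",  "model-default"),
    c("agar_depth",   "numerics",  "um",          "150",   "model-default"),
    c("air_height",   "numerics",  "um",          "40",    "model-default"),
    c("closing_radius", "numerics", "grid cells", "1",     "model-default"),
    # --- run ------------------------------------------------------------------
    c("seed",         "run",       "integer",     "1",     "model-default"),
    c("t_end",        "run",       "h",           "16",    "model-default"),
    c("snapshot_every", "run",     "h",           "1",     "model-default")
  )
  data.frame(name = reg[, 1], section = reg[, 2], unit = reg[, 3],
             default = as.numeric(reg[, 4]), provenance = reg[, 5],
             stringsAsFactors = FALSE)
})

#' Construct a colony simulation parameter set
#'
#' Returns the full set of metabolic, mechanical, numerical and run-control
#' constants used by the simulator, with any named overrides applied. Units are
#' fixed internally: lengths in micrometres, time in hours (diffusivities are
#' accepted in the conventional um^2/s and converted where used), concentrations
#' in mM, biomass in grams dry weight (gdw). The registry of defaults with
#' provenance labels is available via [param_registry()].
#'
#' @param ... named numeric overrides of registry defaults (e.g. `C_g_init = 10`).
#' @param .validate if `TRUE` (default) the resulting set is checked with
#'   [validate_params()] and an error is raised on any violation.
#' @return An object of class `colony_params`: a named list of numeric values
#'   with a `source` attribute marking each entry `"default"` or `"user"`.
#' @examples
#' p <- colony_params(C_g_init = 10)
#' p$C_g_init
#' @export
colony_params <- function(..., .validate = TRUE) {
  overrides <- list(...)
  if (length(overrides) && (is.null(names(overrides)) || any(names(overrides) == "")))
    stop("all parameter overrides must be named")
  unknown <- setdiff(names(overrides), .param_registry$name)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- as.list(setNames(.param_registry$default, .param_registry$name))
  src <- setNames(rep("default", length(p)), names(p))
  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("parameter '", nm, "' must be a single finite number")
    p[[nm]] <- as.numeric(val)
    src[[nm]] <- "user"
  }
  attr(p, "source") <- src
  class(p) <- "colony_params"
  if (.validate) {
    v <- validate_params(p)
    if (nrow(v))
      stop("invalid parameter set:\n", paste0("  ", v$field, " = ", v$value,
                                              ": ", v$bound, collapse = "\n"))
  }
  p
}

#' Parameter registry with units and provenance
#'
#' @return data.frame with columns `name`, `section`, `unit`, `default`,
#'   `provenance`.
#' @export
param_registry <- function() .param_registry

#' Validate a parameter set
#'
#' Checks every invariant the model assumes: strict positivity of rates,
#' Monod constants, diffusivities, densities and lengths (initial acetate may
#' be zero); anaerobic starvation killing at least as fast as aerobic
#' (`delta_ana >= delta_aer`); and the growing-cell classification threshold
#' lying below every maximal growth rate.
#'
#' @param p a `colony_params` object (or plain named list with the same fields).
#' @return A data.frame of violations with columns `field`, `value`, `bound`;
#'   zero rows when the set is valid. Always returns, never errors.
#' @export
validate_params <- function(p) {
  bad <- list()
  flag <- function(field, value, bound)
    bad[[length(bad) + 1L]] <<- data.frame(field = field, value = value,
                                           bound = bound)
  nonneg_ok <- c("C_a_init", "f_settle", "kick_angle", "surface_tension",
                 "closing_radius")
  for (nm in .param_registry$name) {
    val <- p[[nm]]
    if (is.null(val) || !is.finite(val)) {
      flag(nm, NA_real_, "must be present and finite")
      next
    }
    if (nm %in% nonneg_ok) {
      if (val < 0) flag(nm, val, "must be >= 0")
    } else if (val <= 0) {
      flag(nm, val, "must be > 0")
    }
  }
  has <- function(nm) !is.null(p[[nm]]) && is.finite(p[[nm]])
  if (has("delta_aer") && has("delta_ana") && p$delta_ana < p$delta_aer)
    flag("delta_ana", p$delta_ana, paste0("must be >= delta_aer (", p$delta_aer,
                                          "): anaerobic starvation kills faster"))
  if (all(vapply(c("growth_threshold", "lambda_g_aer", "lambda_g_ana",
                   "lambda_a_aer"), has, logical(1)))) {
    lam_min <- min(p$lambda_g_aer, p$lambda_g_ana, p$lambda_a_aer)
    if (p$growth_threshold >= lam_min)
      flag("growth_threshold", p$growth_threshold,
           paste0("must be < min maximal growth rate (", lam_min, ")"))
  }
  if (has("div_noise") && p$div_noise >= 1)
    flag("div_noise", p$div_noise, "must be < 1")
  if (has("m_carbon") && has("q_g_aer") && has("lambda_g_aer")) {
    # maintenance must be coverable by saturating glucose uptake (6 C / glucose)
    cap <- 6 * p$q_g_aer * p$lambda_g_aer
    if (p$m_carbon >= cap)
      flag("m_carbon", p$m_carbon,
           paste0("must be < maximal glucose carbon uptake (", cap, ")"))
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(field = character(), value = numeric(), bound = character())
}

#' Load a simulation configuration file
#'
#' Reads a YAML configuration (flat keys, optionally grouped under the sections
#' `metabolism`, `mechanics`, `numerics`, `run`), fills unspecified keys with
#' registry defaults, and validates the result. An empty file yields the
#' all-defaults parameter set.
#'
#' @param path path to a YAML file.
#' @param quiet suppress the per-key source log (default `TRUE`).
#' @return A validated `colony_params` object.
#' @export
load_config <- function(path, quiet = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must parse to a YAML mapping")
  flat <- list()
  sections <- unique(.param_registry$section)
  for (nm in names(raw)) {
    if (nm %in% sections) {
      sub <- raw[[nm]]
      if (!is.list(sub)) stop("section '", nm, "' must be a mapping")
      for (k in names(sub)) flat[[k]] <- sub[[k]]
    } else {
      flat[[nm]] <- raw[[nm]]
    }
  }
  unknown <- setdiff(names(flat), .param_registry$name)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  p <- do.call(colony_params, flat)
  if (!quiet) {
    src <- attr(p, "source")
    for (nm in names(src))
      message(sprintf("  %-28s = %-12g [%s]", nm, p[[nm]], src[[nm]]))
  }
  p
}

#' Write a parameter set to a YAML configuration file
#'
#' Values are written with 17 significant digits so that a write/reload
#' round-trip reproduces every numeric field bit-for-bit.
#'
#' @param p a `colony_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  reg <- .param_registry
  lines <- character()
  for (sec in unique(reg$section)) {
    lines <- c(lines, paste0(sec, ":"))
    for (nm in reg$name[reg$section == sec]) {
      val <- p[[nm]]
      lines <- c(lines, sprintf("  %s: %s", nm,
                                formatC(val, digits = 17, format = "g")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.colony_params <- function(x, ...) {
  src <- attr(x, "source")
  n_user <- sum(src == "user")
  cat("Colony simulation parameters (", length(x), " values, ",
      n_user, " user-set)\n", sep = "")
  reg <- .param_registry
  for (sec in unique(reg$section)) {
    cat(sec, ":\n", sep = "")
    for (nm in reg$name[reg$section == sec]) {
      mark <- if (identical(src[[nm]], "user")) " *" else ""
      cat(sprintf("  %-26s %-12g %s%s\n", nm, x[[nm]], reg$unit[reg$name == nm],
                  mark))
    }
  }
  if (n_user) cat("(* = user override)\n")
  invisible(x)
}
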