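# JSON run configuration: schema with defaults, full-path validation that
# collects every violation, and a canonical round-trippable form.

config_defaults <- function() {
  list(
    patient = list(source = "healthy_femur", csv = NULL),
    scenario = "natural",
    time = list(start = 0, end = 180, step = 6),
    density_law = list(rho_max = 1.909, bmd_max = 1610, lambda = 9 / 25),
    damage = list(d_cri = 0.38, eps_cri = 0.0174, eps_0 = 0.0015, beta = 5),
    load_case = list(head_magnitude = 3110, abductor_magnitude = 1360,
      head_angle_deg = 13, abductor_angle_deg = 21, patch_radius = 8,
      clamp_fraction = 0.1),
    geometry = list(head_radius = 24, neck_radius = 15, neck_length = 48,
      neck_shaft_angle = 127, shaft_radius = 15, shaft_length = 110,
      canal_radius = 7.5, cortical_thickness = 5,
      cortical_thickness_proximal = 2.5),
    mesh = list(target_edge = 4, order = 1),
    offset_space = "bmd",
    irreversible = FALSE,
    seed = 1
  )
}

#' Load and validate a JSON run configuration
#'
#' Reads a JSON file, fills every omitted key with its default, rejects
#' unknown keys, and validates values; all violations are reported together,
#' each named by its full key path (e.g. `damage.eps_0`).
#'
#' @param path Path to a JSON file.
#' @return A validated config list of class `osteofem_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Config file '%s' does not exist.", path),
      class = "osteofem_input_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(raw, origin = path)
}

#' Validate a configuration list
#'
#' @param raw A (possibly partial) configuration list.
#' @param origin Label used in error messages.
#' @return A complete config of class `osteofem_config`.
#' @export
validate_config <- function(raw, origin = "config") {
  defaults <- config_defaults()
  problems <- character()
  if (!is.list(raw)) {
    rlang::abort("Config must be a JSON object.", class = "osteofem_config_error")
  }
  unknown_top <- setdiff(names(raw), names(defaults))
  if (length(unknown_top) > 0L) {
    problems <- c(problems, sprintf("unknown key '%s'", unknown_top))
  }
  cfg <- defaults
  for (nm in intersect(names(raw), names(defaults))) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(raw[[nm]])) {
        problems <- c(problems, sprintf("'%s' must be an object", nm))
        next
      }
      unknown <- setdiff(names(raw[[nm]]), names(defaults[[nm]]))
      if (length(unknown) > 0L) {
        problems <- c(problems, sprintf("unknown key '%s.%s'", nm, unknown))
      }
      for (sub in intersect(names(raw[[nm]]), names(defaults[[nm]]))) {
        cfg[[nm]][[sub]] <- raw[[nm]][[sub]]
      }
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  num_rules <- list(
    c("time.start", "time$start >= 0"),
    c("time.step", "time$step > 0"),
    c("time.end", "time$end > time$start"),
    c("density_law.rho_max", "density_law$rho_max > 0"),
    c("density_law.bmd_max", "density_law$bmd_max > 0"),
    c("density_law.lambda", "density_law$lambda > 0 && density_law$lambda < 1"),
    c("damage.d_cri", "damage$d_cri > 0 && damage$d_cri < 1"),
    c("damage.eps_0", "damage$eps_0 > 0 && damage$eps_0 < damage$eps_cri"),
    c("damage.eps_cri", "damage$eps_cri > 0"),
    c("damage.beta", "damage$beta > 2"),
    c("load_case.head_magnitude", "load_case$head_magnitude >= 0"),
    c("load_case.abductor_magnitude", "load_case$abductor_magnitude >= 0"),
    c("load_case.clamp_fraction",
      "load_case$clamp_fraction > 0 && load_case$clamp_fraction < 1"),
    c("geometry.neck_shaft_angle",
      "geometry$neck_shaft_angle >= 110 && geometry$neck_shaft_angle <= 140"),
    c("geometry.cortical_thickness", "geometry$cortical_thickness > 0"),
    c("mesh.target_edge", "mesh$target_edge > 0"),
    c("mesh.order", "mesh$order %in% c(1, 2)")
  )
  env <- list2env(cfg)
  for (rule in num_rules) {
    ok <- tryCatch(isTRUE(eval(parse(text = rule[2]), envir = env)),
      error = function(e) FALSE)
    if (!ok) problems <- c(problems, sprintf("invalid value for '%s'", rule[1]))
  }
  known_scen <- c("natural", "alendronate_like", "ibandronate_like",
    "pth_switch_like")
  if (is.character(cfg$scenario) &&
    !cfg$scenario %in% known_scen) {
    problems <- c(problems, sprintf(
      "invalid value for 'scenario' (known: %s)",
      paste(known_scen, collapse = ", ")))
  }
  if (!cfg$offset_space %in% c("bmd", "density")) {
    problems <- c(problems, "invalid value for 'offset_space'")
  }
  if (!is.null(cfg$patient$csv) && !file.exists(cfg$patient$csv)) {
    problems <- c(problems, sprintf(
      "'patient.csv' path '%s' is not resolvable", cfg$patient$csv))
  }
  if (length(problems) > 0L) {
    rlang::abort(paste0("Invalid configuration (", origin, "):\n",
      paste0("- ", problems, collapse = "\n")),
      class = "osteofem_config_error")
  }
  # canonical form: drop NULL-valued optional keys so dump(load(x)) is a
  # fixed point (JSON null round-trips as an absent key)
  drop_nulls <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, drop_nulls)
    x[!vapply(x, is.null, logical(1))]
  }
  cfg <- drop_nulls(cfg)
  structure(cfg, class = c("osteofem_config", "list"))
}

#' Write a configuration in canonical JSON form
#'
#' The canonical form has all defaults filled, keys in schema order and
#' numbers unrounded, so `write_config(load_config(x))` is a fixed point.
#'
#' @param config An `osteofem_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "osteofem_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a BMD CSV file
#'
#' Understands two layouts: a time series (columns `time_months`, `bmd`,
#' optional `device`, defaulting to `standardized`) and a per-zone baseline
#' table (columns `zone`, `device`, `bmd`). European decimal commas are
#' supported via `decimal_mark = ","` (with `;` as separator).
#'
#' @param path CSV file path.
#' @param decimal_mark `"."` (default) or `","`.
#' @return A tibble; series are sorted checked for duplicate times.
#' @export
read_bmd_csv <- function(path, decimal_mark = ".") {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File '%s' does not exist.", path),
      class = "osteofem_input_error")
  }
  loc <- readr::locale(decimal_mark = decimal_mark,
    grouping_mark = if (decimal_mark == ",") "." else ",")
  df <- if (decimal_mark == ",") {
    readr::read_csv2(path, locale = loc, show_col_types = FALSE,
      progress = FALSE)
  } else {
    readr::read_csv(path, locale = loc, show_col_types = FALSE,
      progress = FALSE)
  }
  is_series <- all(c("time_months", "bmd") %in% names(df))
  is_zone <- all(c("zone", "bmd") %in% names(df))
  if (!is_series && !is_zone) {
    rlang::abort(paste0(
      "CSV must have columns time_months,bmd[,device] (series) or ",
      "zone,device,bmd (baseline table); found: ",
      paste(names(df), collapse = ", ")), class = "osteofem_input_error")
  }
  if (!"device" %in% names(df)) df$device <- "standardized"
  bad <- which(!is.finite(df$bmd) | df$bmd <= 0)
  if (length(bad) > 0L) {
    rlang::abort(sprintf("Non-positive BMD in row(s) %s.",
      paste(bad, collapse = ", ")), class = "osteofem_input_error")
  }
  if (is_series) {
    dup <- which(duplicated(df$time_months))
    if (length(dup) > 0L) {
      rlang::abort(sprintf("Duplicate time_months in row(s) %s.",
        paste(dup, collapse = ", ")), class = "osteofem_input_error")
    }
    df <- df[order(df$time_months), ]
  } else {
    dup <- which(duplicated(df$zone))
    if (length(dup) > 0L) {
      rlang::abort(sprintf("Duplicate zone in row(s) %s.",
        paste(dup, collapse = ", ")), class = "osteofem_input_error")
    }
  }
  tibble::as_tibble(df)
}

#' Write a BMD table to CSV
#'
#' @param data Series or zone table as returned by [read_bmd_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bmd_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Write a plain-text simulation report
#'
#' A deterministic, human-readable summary: the derived damage constants,
#' the patient's baseline zone table (standardized BMD, apparent density and
#' modulus at presentation precision), and the femoral-neck evolution of
#' probability and probability increase at every grid time.
#'
#' @param result An [run_evolution()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "evolution_result"))
  dp <- result$damage_params
  base <- add_material_properties(result$baseline, law = result$law)
  lines <- c(
    "osteofem simulation report",
    "==========================",
    "",
    sprintf("Damage model: d_cri = %g, eps_cri = %g, eps_0 = %g, beta = %g",
      dp$d_cri, dp$eps_cri, dp$eps_0, dp$beta),
    sprintf("Derived constants: gamma = %.6f, kappa = %.6f",
      dp$gamma, dp$kappa),
    "",
    "Baseline Gruen-zone table",
    "zone  bmd(device)  sBMD  density  modulus",
    sprintf("%4d  %11.0f  %4.0f  %7.3f  %7.0f",
      base$zone, base$bmd, round(base$sbmd), base$density,
      round(base$modulus)),
    "",
    "Femoral neck evolution",
    "t_months     P    deltaP(%)"
  )
  neck <- result$region_curves[result$region_curves$region == "neck", ]
  lines <- c(lines,
    sprintf("%8g  %6.4f  %8.1f", neck$time_months, neck$probability,
      100 * neck$delta_p))
  writeLines(lines, path)
  invisible(path)
}
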