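#' Cross-calibration coefficients between densitometer manufacturers
#'
#' Linear maps from device-reported areal BMD to standardized BMD (sBMD).
#' The slopes act on BMD in g/cm2; intercepts are stored in mg/cm2, the unit
#' the package carries internally. The `standardized` row is the identity.
#'
#' @return A tibble with columns `device`, `slope`, `intercept_mg`.
#' @seealso [standardize_bmd()]
#' @export
#' @examples
#' device_calibrations()
device_calibrations <- function() {
  tibble::tibble(
    device = c("hologic", "lunar", "norland", "standardized"),
    slope = c(1.008, 0.979, 1.012, 1),
    intercept_mg = c(6, -31, 26, 0)
  )
}

#' Convert device-reported BMD to standardized BMD
#'
#' Applies the linear cross-calibration for the reporting densitometer so
#' that measurements from Hologic, Lunar and Norland scanners become
#' comparable. Values are carried unrounded; round only for presentation.
#'
#' @param bmd Areal BMD in mg/cm2 (positive, finite). Vectorized.
#' @param device Device tag, one of `"hologic"`, `"lunar"`, `"norland"`,
#'   `"standardized"`. Recycled against `bmd`.
#' @param calibration Calibration table in the format of
#'   [device_calibrations()].
#' @return Standardized BMD in mg/cm2, same length as `bmd`.
#' @export
#' @examples
#' standardize_bmd(782, "hologic")    # 794.256
#' standardize_bmd(1000, "standardized")
standardize_bmd <- function(bmd, device, calibration = device_calibrations()) {
  if (!is.numeric(bmd) || any(!is.finite(bmd)) || any(bmd <= 0)) {
    rlang::abort("`bmd` must be positive and finite.", class = "osteofem_input_error")
  }
  device <- as.character(device)
  if (length(device) == 1L) device <- rep(device, length(bmd))
  if (length(device) != length(bmd)) {
    rlang::abort("`device` must have length 1 or length(bmd).",
      class = "osteofem_input_error")
  }
  idx <- match(device, calibration$device)
  if (anyNA(idx)) {
    bad <- unique(device[is.na(idx)])
    rlang::abort(
      sprintf(
        "Unknown densitometer device tag(s): %s. Known tags: %s.",
        paste0("'", bad, "'", collapse = ", "),
        paste0("'", calibration$device, "'", collapse = ", ")
      ),
      class = "osteofem_device_error"
    )
  }
  calibration$slope[idx] * bmd + calibration$intercept_mg[idx]
}

#' Parameters of the BMD to apparent-density power law
#'
#' The apparent density of bone is obtained from standardized BMD through
#' `rho = rho_max * (sBMD / bmd_max)^lambda`. The default reference point
#' (`rho_max` = 1.909 g/cm3 at `bmd_max` = 1610 mg/cm2) is the densest Gruen
#' zone of the healthy reference femur, and `lambda` = 9/25 calibrates the
#' law to the reference densitometric data; all three can be overridden per
#' patient.
#'
#' @param rho_max Apparent density at the reference BMD, g/cm3 (> 0).
#' @param bmd_max Reference standardized BMD, mg/cm2 (> 0).
#' @param lambda Dimensionless exponent in (0, 1).
#' @return An object of class `density_law`.
#' @export
density_law <- function(rho_max = 1.909, bmd_max = 1610, lambda = 9 / 25) {
  stopifnot(is.numeric(rho_max), length(rho_max) == 1L,
    is.numeric(bmd_max), length(bmd_max) == 1L,
    is.numeric(lambda), length(lambda) == 1L)
  if (!(rho_max > 0)) rlang::abort("`rho_max` must be > 0.", class = "osteofem_input_error")
  if (!(bmd_max > 0)) rlang::abort("`bmd_max` must be > 0.", class = "osteofem_input_error")
  if (!(lambda > 0 && lambda < 1)) {
    rlang::abort("`lambda` must lie strictly between 0 and 1.",
      class = "osteofem_input_error")
  }
  structure(list(rho_max = rho_max, bmd_max = bmd_max, lambda = lambda),
    class = "density_law")
}

#' @export
print.density_law <- function(x, ...) {
  cat(sprintf(
    "<density_law> rho = %.4g * (sBMD / %.4g)^%.4g  [g/cm3; sBMD in mg/cm2]\n",
    x$rho_max, x$bmd_max, x$lambda))
  invisible(x)
}

#' Convert standardized BMD to apparent density
#'
#' @param sbmd Standardized BMD in mg/cm2 (positive). Vectorized.
#' @param law A [density_law()] object.
#' @return Apparent density in g/cm3.
#' @export
#' @examples
#' bmd_to_density(1610)   # reference point: 1.909
#' bmd_to_density(794)
bmd_to_density <- function(sbmd, law = density_law()) {
  stopifnot(inherits(law, "density_law"))
  if (!is.numeric(sbmd) || any(!is.finite(sbmd)) || any(sbmd <= 0)) {
    rlang::abort("`sbmd` must be positive and finite.", class = "osteofem_input_error")
  }
  law$rho_max * (sbmd / law$bmd_max)^law$lambda
}

#' Convert apparent density to Young's modulus (cubic law)
#'
#' `E = coefficient * rho^exponent`, the Carter-Hayes relation for low strain
#' rates, with `rho` in g/cm3 and `E` in MPa.
#'
#' @param rho Apparent density in g/cm3 (>= 0). Vectorized.
#' @param coefficient Multiplier in MPa, default 2875.
#' @param exponent Power on density, default 3.
#' @return Young's modulus in MPa.
#' @export
#' @examples
#' density_to_modulus(1.909)  # ~20000 MPa
#' density_to_modulus(1)      # 2875 MPa
density_to_modulus <- function(rho, coefficient = 2875, exponent = 3) {
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(rho < 0)) {
    rlang::abort("`rho` must be non-negative and finite.",
      class = "osteofem_input_error")
  }
  coefficient * rho^exponent
}

#' Back out mechanical damage from stiffness loss
#'
#' Damage is the relative stiffness deficit `D = 1 - E / E0` of bone with
#' current modulus `E` against the healthy modulus `E0`.
#'
#' @param E Current Young's modulus, MPa, with `0 <= E <= E0`. Vectorized.
#' @param E0 Healthy (reference) Young's modulus, MPa (> 0).
#' @return Damage in \[0, 1\].
#' @export
stiffness_to_damage <- function(E, E0) {
  if (!is.numeric(E0) || any(!is.finite(E0)) || any(E0 <= 0)) {
    rlang::abort("`E0` must be positive and finite.", class = "osteofem_input_error")
  }
  if (!is.numeric(E) || any(!is.finite(E)) || any(E < 0)) {
    rlang::abort("`E` must be non-negative and finite.", class = "osteofem_input_error")
  }
  if (any(E > E0 * (1 + 1e-12))) {
    rlang::abort("`E` exceeds `E0`: negative damage is unphysical here.",
      class = "osteofem_input_error")
  }
  1 - E / E0
}

#' Add standardized BMD, density and modulus columns to a zone table
#'
#' Takes a data frame with per-zone densitometer readings (columns `bmd` and
#' `device`) and appends the full material pipeline: standardized BMD
#' (`sbmd`, mg/cm2), apparent density (`density`, g/cm3) and Young's modulus
#' (`modulus`, MPa). All values are carried at full precision.
#'
#' @param data Data frame with numeric `bmd` and character `device` columns.
#' @param law A [density_law()] object.
#' @param calibration Device calibration table, see [device_calibrations()].
#' @return A tibble: `data` plus `sbmd`, `density`, `modulus`.
#' @export
#' @examples
#' add_material_properties(healthy_femur_bmd())
add_material_properties <- function(data, law = density_law(),
                                    calibration = device_calibrations()) {
  if (!is.data.frame(data) || !all(c("bmd", "device") %in% names(data))) {
    rlang::abort("`data` must be a data frame with columns `bmd` and `device`.",
      class = "osteofem_input_error")
  }
  data |>
    tibble::as_tibble() |>
    dplyr::mutate(
      sbmd = standardize_bmd(.data$bmd, .data$device, calibration),
      density = bmd_to_density(.data$sbmd, law),
      modulus = density_to_modulus(.data$density)
    )
}

#' Gruen-zone BMD of the healthy reference femur
#'
#' Hologic areal BMD of the seven Gruen zones of a healthy adult femur, used
#' as the default patient baseline throughout the package.
#'
#' @return A tibble with columns `zone` (1-7), `device`, `bmd` (mg/cm2).
#' @export
healthy_femur_bmd <- function() {
  tibble::tibble(
    zone = 1:7,
    device = "hologic",
    bmd = c(782, 1093, 1429, 1591, 1530, 1302, 1192)
  )
}

#' Head contact force from body weight
#'
#' Peak hip-joint reaction during heel strike / double support, modelled as a
#' multiple of body weight. The default 4 x 79.3 kg gives 3110.67 N, i.e.
#' 3110 N when rounded to the nearest 10 N.
#'
#' @param mass_kg Body mass in kg.
#' @param factor Load factor (multiples of body weight), default 4.
#' @param g Gravitational acceleration, m/s2.
#' @return Force in newtons (unrounded).
#' @export
head_load_from_weight <- function(mass_kg = 79.3, factor = 4, g = 9.80665) {
  stopifnot(mass_kg > 0, factor > 0, g > 0)
  factor * mass_kg * g
}
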