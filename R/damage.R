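#' Derive the damage-law constants from its anchor points
#'
#' The damage law `D = 1 - kappa * eps^gamma` is anchored so that damage is
#' zero at the strain threshold `eps_0` and equals the critical damage
#' `d_cri` at the critical strain `eps_cri`:
#' `gamma = log(1 / (1 - d_cri)) / log(eps_0 / eps_cri)` and
#' `kappa = eps_0^(-gamma)`. With the cortical-bone defaults `gamma` is
#' negative (about -0.19504), which still yields damage increasing in strain
#' because `kappa * eps^gamma` is then decreasing.
#'
#' @param d_cri Critical damage, in (0, 1).
#' @param eps_cri Critical equivalent strain, with `eps_cri > eps_0`.
#' @param eps_0 Strain threshold below which no damage occurs (> 0).
#' @return A list with elements `gamma` and `kappa` satisfying
#'   `kappa * eps_0^gamma = 1` and `1 - kappa * eps_cri^gamma = d_cri`.
#' @export
#' @examples
#' derive_damage_constants(0.38, 0.0174, 0.0015)
derive_damage_constants <- function(d_cri, eps_cri, eps_0) {
  if (!(is.numeric(d_cri) && length(d_cri) == 1L && d_cri > 0 && d_cri < 1)) {
    rlang::abort("`d_cri` must lie strictly between 0 and 1.",
      class = "osteofem_input_error")
  }
  if (!(is.numeric(eps_0) && length(eps_0) == 1L && eps_0 > 0)) {
    rlang::abort("`eps_0` must be > 0.", class = "osteofem_input_error")
  }
  if (!(is.numeric(eps_cri) && length(eps_cri) == 1L && eps_cri > eps_0)) {
    rlang::abort("`eps_cri` must exceed `eps_0`.", class = "osteofem_input_error")
  }
  gamma <- log(1 / (1 - d_cri)) / log(eps_0 / eps_cri)
  list(gamma = gamma, kappa = eps_0^(-gamma))
}

#' Continuum damage model parameters
#'
#' Bundles the threshold strain, critical strain, critical damage and the
#' Paris exponent `beta`, together with the derived law constants `gamma`
#' and `kappa` (see [derive_damage_constants()]). Defaults are the
#' cortical-bone values: `d_cri` = 0.38, `eps_cri` = 0.0174,
#' `eps_0` = 0.0015 and `beta` = 5.
#'
#' @param d_cri Critical damage, in (0, 1).
#' @param eps_cri Critical equivalent strain.
#' @param eps_0 Strain threshold (no damage below it).
#' @param beta Paris-law exponent (> 2); the default 5 is a cortical-bone
#'   value, supply your own to model cancellous bone.
#' @return An object of class `damage_params`.
#' @export
damage_params <- function(d_cri = 0.38, eps_cri = 0.0174, eps_0 = 0.0015,
                          beta = 5) {
  if (!(is.numeric(beta) && length(beta) == 1L && beta > 2)) {
    rlang::abort("`beta` must be > 2.", class = "osteofem_input_error")
  }
  dc <- derive_damage_constants(d_cri, eps_cri, eps_0)
  structure(
    list(d_cri = d_cri, eps_cri = eps_cri, eps_0 = eps_0, beta = beta,
      gamma = dc$gamma, kappa = dc$kappa),
    class = "damage_params"
  )
}

#' @export
print.damage_params <- function(x, ...) {
  cat(sprintf(
    paste0("<damage_params> d_cri=%.4g  eps_cri=%.4g  eps_0=%.4g  beta=%.4g\n",
      "  derived: gamma=%.6g  kappa=%.6g\n"),
    x$d_cri, x$eps_cri, x$eps_0, x$beta, x$gamma, x$kappa))
  invisible(x)
}

#' Equivalent strain from principal strains
#'
#' Scalar strain invariant
#' `sqrt(e1^2 + e2^2 + e3^2 - e1 e2 - e1 e3 - e2 e3)`; symmetric in its
#' arguments, non-negative, zero exactly for hydrostatic states.
#'
#' @param eps_1,eps_2,eps_3 Principal strains (dimensionless). Vectorized.
#' @return Equivalent strain, `>= 0`.
#' @export
#' @examples
#' equivalent_strain(0.002, 0, 0)        # uniaxial: |e|
#' equivalent_strain(0.001, 0.001, 0.001)  # hydrostatic: 0
equivalent_strain <- function(eps_1, eps_2, eps_3) {
  q <- eps_1^2 + eps_2^2 + eps_3^2 - eps_1 * eps_2 - eps_1 * eps_3 - eps_2 * eps_3
  sqrt(pmax(q, 0)) # the form is PSD; clamp rounding noise
}

# Equivalent strain straight from Voigt strain rows
# (exx, eyy, ezz, gxy, gyz, gxz) with engineering shears. Uses the invariant
# identity eps_c^2 = (3 tr(eps^2) - tr(eps)^2) / 2, avoiding an eigensolve.
equivalent_strain_voigt <- function(strain) {
  strain <- rbind(strain)
  i1 <- strain[, 1] + strain[, 2] + strain[, 3]
  tr2 <- strain[, 1]^2 + strain[, 2]^2 + strain[, 3]^2 +
    (strain[, 4]^2 + strain[, 5]^2 + strain[, 6]^2) / 2
  sqrt(pmax((3 * tr2 - i1^2) / 2, 0))
}

#' Mechanical damage as a function of equivalent strain
#'
#' `D = 0` for `eps_c <= eps_0`, else `D = 1 - kappa * eps_c^gamma`. The law
#' is continuous at the threshold and strictly increasing above it. Values
#' beyond `d_cri` are not clamped; flag them with [is_supercritical()].
#'
#' @param eps_c Equivalent strain (>= 0). Vectorized.
#' @param params A [damage_params()] object.
#' @return Damage values (0 at and below threshold).
#' @export
#' @examples
#' p <- damage_params()
#' damage_from_strain(c(0.0015, 0.0174), p)  # 0 and 0.38
damage_from_strain <- function(eps_c, params = damage_params()) {
  stopifnot(inherits(params, "damage_params"))
  if (!is.numeric(eps_c) || any(!is.finite(eps_c)) || any(eps_c < 0)) {
    rlang::abort("`eps_c` must be non-negative and finite.",
      class = "osteofem_input_error")
  }
  d <- 1 - params$kappa * eps_c^params$gamma
  d[eps_c <= params$eps_0] <- 0
  d
}

#' Flag damage beyond the critical value
#'
#' @param D Damage values.
#' @param params A [damage_params()] object.
#' @return Logical vector, `TRUE` where `D > d_cri`.
#' @export
is_supercritical <- function(D, params = damage_params()) {
  D > params$d_cri
}

#' Paris-law material and geometry constants
#'
#' Constants of the fatigue crack-growth law `da/dN = alpha *
#' (delta_sigma * gamma_k * sqrt(a))^beta` with crack size tied to damage by
#' `a = omega * D`. None of these values is bone-specific here: they cancel
#' in the normalized fracture probability, and [cycles_between()] is exposed
#' for sensitivity studies only, so the defaults are unit values.
#'
#' @param alpha Paris coefficient (> 0).
#' @param delta_sigma Stress range per loading cycle (> 0).
#' @param gamma_k Stress-intensity geometry factor (> 0). Distinct from the
#'   damage-law exponent `gamma` of [damage_params()], which the literature
#'   denotes with the same symbol.
#' @param omega Damage-to-crack-size scale (> 0).
#' @return An object of class `paris_params`.
#' @export
paris_params <- function(alpha = 1, delta_sigma = 1, gamma_k = 1, omega = 1) {
  vals <- c(alpha = alpha, delta_sigma = delta_sigma, gamma_k = gamma_k,
    omega = omega)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("All Paris parameters must be strictly positive.",
      class = "osteofem_input_error")
  }
  structure(as.list(vals), class = "paris_params")
}

#' Loading cycles needed to grow damage between two levels
#'
#' Closed-form integral of the Paris law between damage `d_i` and `d_f`:
#' `N = ((omega d_i)^(1 - beta/2) - (omega d_f)^(1 - beta/2)) /
#'  (alpha delta_sigma^beta gamma_k^beta (beta/2 - 1))`.
#' The count is non-negative, zero for equal bounds, and additive over
#' intermediate damage levels. The formula diverges as `d_i -> 0` (an
#' undamaged solid never nucleates a crack under this law), so `d_i = 0`
#' is rejected.
#'
#' @param d_i,d_f Initial and final damage, `0 < d_i <= d_f`.
#' @param params A [damage_params()] object (supplies `beta`).
#' @param paris A [paris_params()] object.
#' @return Number of cycles (same shape as the recycled inputs).
#' @export
cycles_between <- function(d_i, d_f, params = damage_params(),
                           paris = paris_params()) {
  stopifnot(inherits(params, "damage_params"), inherits(paris, "paris_params"))
  if (any(!is.finite(d_i)) || any(d_i <= 0)) {
    rlang::abort("`d_i` must be > 0 (the Paris integral diverges at zero damage).",
      class = "osteofem_input_error")
  }
  if (any(!is.finite(d_f)) || any(d_f < d_i)) {
    rlang::abort("`d_f` must satisfy d_f >= d_i.", class = "osteofem_input_error")
  }
  beta <- params$beta
  p <- 1 - beta / 2 # negative for beta > 2
  pref <- paris$alpha * paris$delta_sigma^beta * paris$gamma_k^beta * (beta / 2 - 1)
  ((paris$omega * d_i)^p - (paris$omega * d_f)^p) / pref
}

#' Normalized fracture probability from damage
#'
#' `P = (D / d_cri)^(beta/2 - 1)`, clamped at 1, assigning probability 0 to
#' undamaged bone and 1 to critically damaged bone. Independent of the Paris
#' constants, which cancel in the normalization.
#'
#' @param D Damage (>= 0). Vectorized.
#' @param params A [damage_params()] object.
#' @return Probabilities in \[0, 1\].
#' @export
#' @examples
#' fracture_probability(c(0, 0.19, 0.38))
fracture_probability <- function(D, params = damage_params()) {
  stopifnot(inherits(params, "damage_params"))
  if (!is.numeric(D) || any(!is.finite(D)) || any(D < 0)) {
    rlang::abort("`D` must be non-negative and finite.",
      class = "osteofem_input_error")
  }
  pmin(1, (D / params$d_cri)^(params$beta / 2 - 1))
}
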