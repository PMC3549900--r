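#' Run the evolutionary fracture-probability simulation
#'
#' Steps a patient's per-Gruen-zone BMD along evolution curves and, at each
#' time, rebuilds the femur's material map (standardized BMD -> apparent
#' density -> Young's modulus), solves the linear-elastic stance load case,
#' and converts per-element equivalent strains to mechanical damage and
#' normalized fracture probability.
#'
#' Each zone's curve is translated so that it passes exactly through the
#' patient's measured standardized BMD at `t = 0` (population curves only
#' carry the trend; the offset personalizes them). Damage is evaluated as an
#' instantaneous function of the current strain, which lets damage recede
#' under therapy; set `irreversible = TRUE` to retain the running maximum
#' instead. Damage and probability are evaluated on cortical elements by
#' default (the Paris exponent is a cortical-bone value); other tissues carry
#' `NA` in those fields.
#'
#' @param patient Data frame with columns `zone` (1-7), `device`, `bmd`:
#'   baseline densitometry of every Gruen zone at `t = 0`.
#' @param scenario A template name (see [bmd_template_curve()]), a single
#'   [bmd_curve()] applied to all zones, or a list of 7 curves named or
#'   ordered by zone.
#' @param mesh A [generate_femur_mesh()] mesh.
#' @param times Simulation time grid in months, starting at 0.
#' @param law [density_law()] parameters.
#' @param damage [damage_params()].
#' @param loads [load_case()].
#' @param poisson Poisson ratio per tissue.
#' @param cancellous_density Apparent density assigned to cancellous bone,
#'   g/cm3 (stand-in: zone-wise cancellous densitometry is rarely available).
#' @param marrow_modulus Young's modulus of marrow elements, MPa.
#' @param offset_space `"bmd"` (default) applies the patient offset to
#'   standardized BMD before the density law; `"density"` applies it to
#'   apparent density after the law.
#' @param irreversible Keep the running maximum of damage over time.
#' @return An object of class `evolution_result`: element fields (`eps_c`,
#'   `damage`, `probability`, `delta_p`; time x element matrices), the
#'   per-zone material table, volume-weighted region curves, and the mesh.
#' @export
run_evolution <- function(patient, scenario, mesh,
                          times = seq(0, 180, by = 6),
                          law = density_law(),
                          damage = damage_params(),
                          loads = load_case(),
                          poisson = c(cortical = 0.3, cancellous = 0.3,
                            marrow = 0.45),
                          cancellous_density = 0.5,
                          marrow_modulus = 20,
                          offset_space = c("bmd", "density"),
                          irreversible = FALSE) {
  offset_space <- match.arg(offset_space)
  if (length(times) < 1L || times[1] != 0 || any(diff(times) <= 0)) {
    rlang::abort("`times` must start at 0 and increase strictly.",
      class = "osteofem_input_error")
  }
  if (!is.data.frame(patient) ||
    !all(c("zone", "device", "bmd") %in% names(patient))) {
    rlang::abort("`patient` needs columns `zone`, `device`, `bmd`.",
      class = "osteofem_input_error")
  }
  zones_in_mesh <- sort(unique(mesh$gruen_zone[!is.na(mesh$gruen_zone)]))
  missing_z <- setdiff(zones_in_mesh, patient$zone)
  if (length(missing_z) > 0L) {
    rlang::abort(sprintf("`patient` lacks baseline BMD for Gruen zone(s) %s.",
      paste(missing_z, collapse = ", ")), class = "osteofem_input_error")
  }
  curves <- resolve_scenario(scenario, zones_in_mesh)
  baseline <- patient |>
    dplyr::mutate(sbmd = standardize_bmd(.data$bmd, .data$device)) |>
    dplyr::arrange(.data$zone)

  # per-zone evaluated BMD/density for all times
  zone_tab <- purrr::map_dfr(zones_in_mesh, function(z) {
    sb0 <- baseline$sbmd[baseline$zone == z]
    curve <- curves[[as.character(z)]]
    if (offset_space == "bmd") {
      adapted <- adapt_to_patient(curve, 0, sb0)
      sbmd_t <- predict(adapted, times)
      rho_t <- bmd_to_density(sbmd_t, law)
    } else {
      rho_curve <- bmd_to_density(predict(curve, times), law)
      rho_t <- rho_curve + (bmd_to_density(sb0, law) - rho_curve[1])
      sbmd_t <- predict(curve, times) # trend, not offset (reported as-is)
    }
    if (any(rho_t <= 0)) {
      rlang::abort(sprintf(
        "Zone %d: evolved density became non-positive at t = %g months.",
        z, times[which(rho_t <= 0)[1]]), class = "osteofem_domain_error")
    }
    tibble::tibble(time_months = times, zone = z, bmd = sbmd_t,
      density = rho_t, modulus = density_to_modulus(rho_t))
  })

  fe <- fe_structure(mesh, poisson)
  lc <- apply_load_case(mesh, loads)
  m <- nrow(mesh$tets)
  nt <- length(times)
  is_cortical <- mesh$tissue == "cortical"
  is_cancellous <- mesh$tissue == "cancellous"
  is_marrow <- mesh$tissue == "marrow"
  E_cancellous <- density_to_modulus(cancellous_density)

  eps_mat <- matrix(NA_real_, nt, m)
  D_mat <- matrix(NA_real_, nt, m)
  P_mat <- matrix(NA_real_, nt, m)
  E_elem <- numeric(m)
  E_elem[is_cancellous] <- E_cancellous
  E_elem[is_marrow] <- marrow_modulus
  zone_of_elem <- mesh$gruen_zone

  for (k in seq_len(nt)) {
    zt <- zone_tab[zone_tab$time_months == times[k], ]
    E_zone <- stats::setNames(zt$modulus, zt$zone)
    E_elem[is_cortical] <- unname(E_zone[as.character(zone_of_elem[is_cortical])])
    if (any(!is.finite(E_elem)) || any(E_elem <= 0)) {
      rlang::abort(sprintf(
        "Non-positive element modulus at t = %g months (check curves).",
        times[k]), class = "osteofem_domain_error")
    }
    res <- solve_elasticity(mesh, E_elem, forces = lc$forces,
      fixed_nodes = lc$fixed_nodes, poisson = poisson, fe = fe)
    eps_mat[k, ] <- res$eps_c
    d <- rep(NA_real_, m)
    d[is_cortical] <- damage_from_strain(res$eps_c[is_cortical], damage)
    if (irreversible && k > 1L) {
      d <- pmax(d, D_mat[k - 1L, ])
    }
    D_mat[k, ] <- d
    P_mat[k, ] <- ifelse(is.na(d), NA_real_, fracture_probability(
      ifelse(is.na(d), 0, d), damage))
  }
  delta_P <- sweep(P_mat, 2, P_mat[1, ])

  regions <- c("head", "neck", "trochanteric", "subtrochanteric", "diaphysis")
  regions <- regions[regions %in% unique(mesh$region)]
  zone_bmd_elem <- function(k) {
    zt <- zone_tab[zone_tab$time_months == times[k], ]
    v <- stats::setNames(zt$bmd, zt$zone)
    unname(v[as.character(zone_of_elem)])
  }
  zone_E_elem <- function(k) {
    zt <- zone_tab[zone_tab$time_months == times[k], ]
    v <- stats::setNames(zt$modulus, zt$zone)
    unname(v[as.character(zone_of_elem)])
  }
  region_curves <- purrr::map_dfr(seq_len(nt), function(k) {
    purrr::map_dfr(regions, function(rg) {
      tibble::tibble(
        time_months = times[k], region = rg,
        bmd = region_average(zone_bmd_elem(k), mesh, rg),
        modulus = region_average(zone_E_elem(k), mesh, rg),
        eps_c = region_average(eps_mat[k, ], mesh, rg),
        damage = region_average(D_mat[k, ], mesh, rg),
        probability = region_average(P_mat[k, ], mesh, rg),
        delta_p = region_average(delta_P[k, ], mesh, rg)
      )
    })
  })

  structure(list(
    times = times, zone_table = zone_tab, region_curves = region_curves,
    eps_c = eps_mat, damage = D_mat, probability = P_mat, delta_p = delta_P,
    supercritical = is_supercritical(
      ifelse(is.na(D_mat), 0, D_mat), damage),
    mesh = mesh, damage_params = damage, law = law,
    baseline = baseline, irreversible = irreversible,
    offset_space = offset_space
  ), class = "evolution_result")
}

resolve_scenario <- function(scenario, zones) {
  if (is.character(scenario) && length(scenario) == 1L) {
    template <- scenario
    out <- lapply(zones, function(z) bmd_template_curve(template))
    return(stats::setNames(out, zones))
  }
  if (inherits(scenario, "bmd_curve")) {
    return(stats::setNames(lapply(zones, function(z) scenario), zones))
  }
  if (is.list(scenario)) {
    nm <- names(scenario) %||% as.character(seq_along(scenario))
    miss <- setdiff(as.character(zones), nm)
    if (length(miss) > 0L) {
      rlang::abort(sprintf("Scenario list lacks curves for zone(s) %s.",
        paste(miss, collapse = ", ")), class = "osteofem_input_error")
    }
    if (!all(vapply(scenario, inherits, logical(1), "bmd_curve"))) {
      rlang::abort("All scenario entries must be `bmd_curve` objects.",
        class = "osteofem_input_error")
    }
    return(scenario[as.character(zones)])
  }
  rlang::abort("`scenario` must be a template name, a bmd_curve, or a per-zone list.",
    class = "osteofem_input_error")
}

#' @export
print.evolution_result <- function(x, ...) {
  cat(sprintf(
    "<evolution_result> %d time steps (0-%g months), %d elements\n",
    length(x$times), max(x$times), ncol(x$eps_c)))
  neck <- x$region_curves[x$region_curves$region == "neck", ]
  if (nrow(neck) > 0) {
    cat(sprintf("  femoral neck: P %.4f -> %.4f  (delta %.4f)\n",
      neck$probability[1], neck$probability[nrow(neck)],
      neck$delta_p[nrow(neck)]))
  }
  if (any(x$supercritical)) cat("  note: supercritical damage reached in some elements\n")
  invisible(x)
}

#' Fracture-probability increase over baseline
#'
#' `delta P(t) = P(t) - P(0)`, elementwise and volume-averaged per region.
#'
#' @param result An [run_evolution()] result.
#' @return A list with `elements` (time x element matrix) and `regions`
#'   (tibble `time_months`, `region`, `delta_p`).
#' @export
probability_increase <- function(result) {
  stopifnot(inherits(result, "evolution_result"))
  dP <- sweep(result$probability, 2, result$probability[1, ])
  list(
    elements = dP,
    regions = result$region_curves[, c("time_months", "region", "delta_p")]
  )
}

#' Export damage / probability maps at one time step to VTK
#'
#' Writes the requested per-element fields at time `t` as VTK cell data for
#' inspection in ParaView and the like. `delta_p` is exported in percent.
#'
#' @param result An [run_evolution()] result.
#' @param t A time present in the simulation grid.
#' @param fields Subset of `c("eps_c", "damage", "probability", "delta_p")`.
#' @param path Output `.vtk` file path.
#' @return `path`, invisibly.
#' @export
export_maps <- function(result, t,
                        fields = c("eps_c", "damage", "probability", "delta_p"),
                        path) {
  stopifnot(inherits(result, "evolution_result"))
  bad <- setdiff(fields, c("eps_c", "damage", "probability", "delta_p"))
  if (length(bad) > 0L) {
    rlang::abort(sprintf("Unknown field(s): %s.", paste(bad, collapse = ", ")),
      class = "osteofem_input_error")
  }
  k <- match(TRUE, abs(result$times - t) < 1e-9)
  if (is.na(k)) {
    rlang::abort(sprintf("t = %g is not on the simulation grid (%s).",
      t, paste(result$times, collapse = ", ")),
      class = "osteofem_input_error")
  }
  cd <- list()
  for (f in fields) {
    v <- result[[f]][k, ]
    if (f == "delta_p") v <- 100 * v
    cd[[f]] <- v
  }
  cd$tissue <- result$mesh$tissue
  cd$gruen_zone <- ifelse(is.na(result$mesh$gruen_zone), -1,
    result$mesh$gruen_zone)
  cd$region <- result$mesh$region
  write_vtk(result$mesh, path, cell_data = cd,
    title = sprintf("osteofem fields at t=%g months", t))
}

#' @export
tidy.evolution_result <- function(x, ...) {
  x$region_curves
}

#' @export
glance.evolution_result <- function(x, ...) {
  neck <- x$region_curves[x$region_curves$region == "neck", ]
  last <- nrow(neck)
  tibble::tibble(
    n_times = length(x$times),
    t_end = max(x$times),
    n_elements = ncol(x$eps_c),
    neck_p_start = neck$probability[1],
    neck_p_end = neck$probability[last],
    neck_delta_p_end = neck$delta_p[last],
    any_supercritical = any(x$supercritical)
  )
}

#' @export
autoplot.evolution_result <- function(object, regions = "neck",
                                      metric = c("probability", "delta_p",
                                        "bmd", "modulus", "eps_c", "damage"),
                                      ...) {
  metric <- match.arg(metric)
  df <- object$region_curves[object$region_curves$region %in% regions, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_months,
    y = .data[[metric]], colour = .data$region)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Time (months)", y = metric) +
    ggplot2::theme_minimal()
}
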