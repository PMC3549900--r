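#' Stance loading of the proximal femur
#'
#' Defines the two-force load system used throughout: the joint reaction on
#' the femoral head (default 3110 N, the heel-strike / double-support peak of
#' 4 x body weight for a 79.3 kg reference subject) and the abductor muscle
#' pull on the greater trochanter (default 1360 N). Only the magnitudes are
#' clinically reported; the directions are conventional one-legged-stance
#' values and fully configurable: the head load acts downwards, tilted
#' `head_angle_deg` from the shaft axis in the frontal plane, and the
#' abductor force pulls the trochanter superomedially, tilted
#' `abductor_angle_deg` from vertical. Both are spread over small nodal
#' patches to avoid singular strain spikes, and the distal slab of the
#' modelled shaft (the mid-diaphyseal cut) is clamped.
#'
#' @param head_magnitude Head contact force, N.
#' @param abductor_magnitude Abductor force, N.
#' @param head_angle_deg Head-load tilt from the shaft axis, degrees.
#' @param abductor_angle_deg Abductor-pull tilt from the shaft axis, degrees.
#' @param head_direction,abductor_direction Optional explicit unit vectors
#'   overriding the angles.
#' @param patch_radius Radius of the load application patches, mm.
#' @param clamp_fraction Fraction of the shaft height (from the distal cut)
#'   whose nodes are clamped.
#' @return An object of class `load_case`.
#' @export
load_case <- function(head_magnitude = 3110, abductor_magnitude = 1360,
                      head_angle_deg = 13, abductor_angle_deg = 21,
                      head_direction = NULL, abductor_direction = NULL,
                      patch_radius = 8, clamp_fraction = 0.1) {
  if (head_magnitude < 0 || abductor_magnitude < 0) {
    rlang::abort("Load magnitudes must be non-negative.",
      class = "osteofem_input_error")
  }
  th <- head_angle_deg * pi / 180
  ta <- abductor_angle_deg * pi / 180
  hd <- head_direction %||% c(-sin(th), 0, -cos(th)) # press down, into the neck
  ad <- abductor_direction %||% c(sin(ta), 0, cos(ta)) # pull up, medially
  hd <- hd / sqrt(sum(hd^2))
  ad <- ad / sqrt(sum(ad^2))
  structure(list(
    head_magnitude = head_magnitude, abductor_magnitude = abductor_magnitude,
    head_direction = hd, abductor_direction = ad,
    patch_radius = patch_radius, clamp_fraction = clamp_fraction
  ), class = "load_case")
}

#' Turn a load case into nodal forces and constraints for a femur mesh
#'
#' Selects a nodal patch on the superior head surface (centred on the point
#' where the joint reaction enters the head), a patch on the lateral face of
#' the greater trochanter, and the clamped node set on the distal shaft
#' slab; forces are split evenly over their patch.
#'
#' @param mesh A [generate_femur_mesh()] mesh.
#' @param case A [load_case()].
#' @return A list with `forces` (corner-node load matrix, N), `fixed_nodes`
#'   (clamped node indices) and the two patch index vectors.
#' @export
apply_load_case <- function(mesh, case = load_case()) {
  stopifnot(inherits(case, "load_case"))
  geom <- mesh$geometry
  if (is.null(geom)) {
    rlang::abort("`mesh` carries no femur geometry (was it built by generate_femur_mesh()?).",
      class = "osteofem_input_error")
  }
  fr <- femur_frame(geom)
  nodes <- mesh$nodes
  n_corner <- if (mesh$order == 2L) {
    max(mesh$tets) # corner nodes come first; midside nodes appended after
  } else {
    nrow(nodes)
  }
  contact <- fr$head_centre - geom$head_radius * case$head_direction
  d_head <- sqrt(rowSums(sweep(nodes, 2, contact)^2))
  head_patch <- which(d_head <= case$patch_radius)
  head_patch <- head_patch[head_patch <= n_corner]
  troch_point <- fr$troch_centre +
    c(-fr$troch_semi[1] * 0.85, 0, fr$troch_semi[3] * 0.4)
  d_tr <- sqrt(rowSums(sweep(nodes, 2, troch_point)^2))
  troch_patch <- which(d_tr <= case$patch_radius)
  troch_patch <- troch_patch[troch_patch <= n_corner]
  if (length(head_patch) == 0L || length(troch_patch) == 0L) {
    rlang::abort("Load patch selection found no nodes; increase `patch_radius` or refine the mesh.",
      class = "osteofem_input_error")
  }
  clamp_z <- case$clamp_fraction * geom$shaft_length
  fixed_nodes <- which(nodes[, 3] <= clamp_z + 1e-9) # incl. midside nodes
  if (length(fixed_nodes) == 0L) {
    rlang::abort("Clamped node set is empty; increase `clamp_fraction`.",
      class = "osteofem_input_error")
  }
  forces <- matrix(0, nrow(nodes), 3)
  forces[head_patch, ] <- matrix(
    case$head_magnitude * case$head_direction / length(head_patch),
    length(head_patch), 3, byrow = TRUE)
  forces[troch_patch, ] <- forces[troch_patch, , drop = FALSE] + matrix(
    case$abductor_magnitude * case$abductor_direction / length(troch_patch),
    length(troch_patch), 3, byrow = TRUE)
  list(forces = forces, fixed_nodes = fixed_nodes,
    head_patch = head_patch, troch_patch = troch_patch)
}
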