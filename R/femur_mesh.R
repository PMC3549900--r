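#' Geometry parameters of the idealized proximal femur
#'
#' The synthetic femur is a union of simple solids in a consistent mm / N /
#' MPa unit system: a vertical shaft (axis = +z) with a medullary canal, a
#' cylindrical neck tilted medially (+x) by the neck-shaft angle, a spherical
#' head at the neck tip, and an ellipsoidal greater-trochanter bulge on the
#' lateral side. Cortical bone is the shell within the cortical thickness of
#' the outer surface (a thinner shell proximally, as in a real femur),
#' cancellous bone fills the interior, and the canal holds marrow.
#'
#' @param head_radius Femoral head radius, mm.
#' @param neck_radius Neck radius, mm.
#' @param neck_length Neck axis length from shaft exit to head centre, mm.
#' @param neck_shaft_angle Angle between shaft and neck axes, degrees
#'   (110-140).
#' @param shaft_radius Outer diaphysis radius, mm.
#' @param shaft_length Modelled shaft height (distal cut at z = 0), mm.
#' @param canal_radius Medullary canal radius, mm.
#' @param cortical_thickness Diaphyseal cortical shell thickness, mm.
#' @param cortical_thickness_proximal Cortical thickness of head, neck and
#'   trochanter, mm.
#' @return An object of class `femur_geometry`.
#' @export
femur_geometry <- function(head_radius = 24, neck_radius = 15,
                           neck_length = 48, neck_shaft_angle = 127,
                           shaft_radius = 15, shaft_length = 110,
                           canal_radius = 7.5, cortical_thickness = 5,
                           cortical_thickness_proximal = 2.5) {
  if (neck_shaft_angle < 110 || neck_shaft_angle > 140) {
    rlang::abort("`neck_shaft_angle` must lie in [110, 140] degrees.",
      class = "osteofem_input_error")
  }
  if (cortical_thickness <= 0 || cortical_thickness_proximal <= 0) {
    rlang::abort("Cortical thickness must be positive.",
      class = "osteofem_input_error")
  }
  if (canal_radius >= shaft_radius - cortical_thickness) {
    rlang::abort("Canal must fit inside the cancellous shaft interior.",
      class = "osteofem_input_error")
  }
  structure(list(
    head_radius = head_radius, neck_radius = neck_radius,
    neck_length = neck_length, neck_shaft_angle = neck_shaft_angle,
    shaft_radius = shaft_radius, shaft_length = shaft_length,
    canal_radius = canal_radius, cortical_thickness = cortical_thickness,
    cortical_thickness_proximal = cortical_thickness_proximal
  ), class = "femur_geometry")
}

# derived quantities shared by the inside tests and labelling
femur_frame <- function(geom) {
  phi <- (180 - geom$neck_shaft_angle) * pi / 180 # tilt of neck from +z
  u <- c(sin(phi), 0, cos(phi))                   # neck axis, medial-up
  origin <- c(0, 0, geom$shaft_length - 5)        # neck exits near shaft top
  head_centre <- origin + geom$neck_length * u
  troch_centre <- c(-(geom$shaft_radius + 2), 0, geom$shaft_length - 2)
  troch_semi <- c(12, 13, 16)
  list(u = u, neck_origin = origin, head_centre = head_centre,
    troch_centre = troch_centre, troch_semi = troch_semi)
}

# vectorized point-membership tests; pts is n x 3
femur_inside <- function(pts, geom, shrink = 0) {
  fr <- femur_frame(geom)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  tshaft <- if (shrink > 0) geom$cortical_thickness else 0
  tprox <- if (shrink > 0) geom$cortical_thickness_proximal else 0
  r_xy <- sqrt(x^2 + y^2)
  # bottom face (z = 0) is the diaphyseal cut, not an anatomical surface:
  # only the radial surface carries a cortical shell
  shaft <- r_xy <= geom$shaft_radius - tshaft & z >= 0 & z <= geom$shaft_length
  v <- sweep(pts, 2, fr$neck_origin)
  s <- drop(v %*% fr$u)
  rad2 <- rowSums(v^2) - s^2
  neck <- s >= 0 & s <= geom$neck_length &
    rad2 <= (geom$neck_radius - tprox)^2
  w <- sweep(pts, 2, fr$head_centre)
  head <- rowSums(w^2) <= (geom$head_radius - tprox)^2
  tv <- sweep(pts, 2, fr$troch_centre)
  troch <- (tv[, 1] / (fr$troch_semi[1] - tprox))^2 +
    (tv[, 2] / (fr$troch_semi[2] - tprox))^2 +
    (tv[, 3] / (fr$troch_semi[3] - tprox))^2 <= 1
  shaft | neck | head | troch
}

femur_in_canal <- function(pts, geom) {
  r_xy <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  r_xy <= geom$canal_radius & pts[, 3] >= 0 &
    pts[, 3] <= geom$shaft_length - 15
}

# Freudenthal (Kuhn) 6-tet decomposition of the unit cube, all sharing the
# main diagonal; conforming across neighbouring cubes without parity flips.
kuhn_tets <- function() {
  corner <- function(i, j, k) c(i, j, k)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
    c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    pts <- matrix(0, 4, 3)
    for (s in 1:3) {
      pts[s + 1, ] <- pts[s, ]
      pts[s + 1, p[s]] <- 1
    }
    pts
  })
}

# voxel tetrahedral mesher over an inside() predicate
voxel_tet_mesh <- function(inside_fun, bbox, h) {
  nx <- max(1L, ceiling((bbox[2, 1] - bbox[1, 1]) / h))
  ny <- max(1L, ceiling((bbox[2, 2] - bbox[1, 2]) / h))
  nz <- max(1L, ceiling((bbox[2, 3] - bbox[1, 3]) / h))
  ox <- bbox[1, 1]; oy <- bbox[1, 2]; oz <- bbox[1, 3]
  cx <- ox + (seq_len(nx) - 0.5) * h
  cy <- oy + (seq_len(ny) - 0.5) * h
  cz <- oz + (seq_len(nz) - 0.5) * h
  centres <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  keep <- inside_fun(centres)
  if (!any(keep)) {
    rlang::abort("Meshing failed: no voxel centres fall inside the solid.",
      class = "osteofem_mesh_error")
  }
  vox <- which(keep)
  ixyz <- cbind((vox - 1L) %% nx,
    ((vox - 1L) %/% nx) %% ny,
    (vox - 1L) %/% (nx * ny))
  node_id <- function(i, j, k) {
    1L + i + j * (nx + 1L) + k * ((nx + 1L) * (ny + 1L))
  }
  tets_unit <- kuhn_tets()
  m <- length(vox)
  conn <- matrix(0L, m * 6L, 4L)
  for (tt in 1:6) {
    pts <- tets_unit[[tt]]
    for (a in 1:4) {
      conn[seq_len(m) + (tt - 1L) * m, a] <- node_id(
        ixyz[, 1] + pts[a, 1], ixyz[, 2] + pts[a, 2], ixyz[, 3] + pts[a, 3])
    }
  }
  used <- sort(unique(as.vector(conn)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  conn <- matrix(remap[conn], ncol = 4L)
  gid <- used - 1L
  nodes <- cbind(
    ox + (gid %% (nx + 1L)) * h,
    oy + ((gid %/% (nx + 1L)) %% (ny + 1L)) * h,
    oz + (gid %/% ((nx + 1L) * (ny + 1L))) * h
  )
  # enforce positive orientation
  vol <- tet_volumes(nodes, conn)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- conn[flip, 3L]
    conn[flip, 3L] <- conn[flip, 4L]
    conn[flip, 4L] <- tmp
    vol[flip] <- -vol[flip]
  }
  if (any(vol <= 0)) {
    rlang::abort("Meshing produced degenerate (zero-volume) elements.",
      class = "osteofem_mesh_error")
  }
  list(nodes = nodes, tets = conn, volumes = vol)
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cc <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# anatomical region + Gruen zone labels from element centroids
label_femur_elements <- function(centroids, geom) {
  fr <- femur_frame(geom)
  Ls <- geom$shaft_length
  w <- sweep(centroids, 2, fr$head_centre)
  in_head <- rowSums(w^2) <= (geom$head_radius + 1e-9)^2
  v <- sweep(centroids, 2, fr$neck_origin)
  s <- drop(v %*% fr$u)
  rad2 <- rowSums(v^2) - s^2
  in_neck <- !in_head & s >= 0 & s <= geom$neck_length &
    rad2 <= (geom$neck_radius + 1e-9)^2
  z <- centroids[, 3]
  region <- dplyr::case_when(
    in_head ~ "head",
    in_neck ~ "neck",
    z > Ls - 25 ~ "trochanteric",
    z > Ls / 3 ~ "subtrochanteric",
    TRUE ~ "diaphysis"
  )
  # Gruen zones: 1 lateral / 7 medial proximally, 2/6 subtrochanteric,
  # 3/5 diaphyseal, 4 the distal-most band. Head and neck are split into the
  # superolateral (1) and inferomedial calcar (7) sides by the neck axis.
  d_inf <- c(fr$u[3], 0, -fr$u[1]) # inferomedial normal in the frontal plane
  wproj <- v - outer(s, fr$u)
  calcar_side <- drop(wproj %*% d_inf) >= 0
  medial <- centroids[, 1] >= 0
  zone <- integer(nrow(centroids))
  hd_nk <- in_head | in_neck
  zone[hd_nk] <- ifelse(calcar_side[hd_nk], 7L, 1L)
  tr <- !hd_nk & region == "trochanteric"
  zone[tr] <- ifelse(medial[tr], 7L, 1L)
  st <- region == "subtrochanteric"
  zone[st] <- ifelse(medial[st], 6L, 2L)
  di <- region == "diaphysis"
  zone[di & z <= 15] <- 4L
  zone[di & z > 15] <- ifelse(medial[di & z > 15], 5L, 3L)
  list(region = region, zone = zone)
}

#' Generate a labelled tetrahedral mesh of an idealized proximal femur
#'
#' Meshes the [femur_geometry()] solid with a structured Freudenthal
#' tetrahedralization at the requested element size, and labels every element
#' with a tissue type (`cortical`, `cancellous`, `marrow`), an anatomical
#' region (`head`, `neck`, `trochanteric`, `subtrochanteric`, `diaphysis`)
#' and a Gruen zone (1-7; `NA` for marrow). The mesh is fully deterministic
#' for fixed inputs.
#'
#' @param geometry A [femur_geometry()].
#' @param target_edge Structured grid spacing, mm (element edges are
#'   `target_edge` or its diagonals).
#' @param order Element order: 1 for 4-node, 2 for 10-node tetrahedra
#'   (midside nodes on straight edges).
#' @param seed Accepted for interface symmetry with the other generators;
#'   the construction uses no randomness.
#' @return An object of class `femur_mesh` with fields `nodes` (n x 3, mm),
#'   `tets` (m x 4 corner connectivity), `tets10` (m x 10, order 2 only),
#'   `tissue`, `region`, `gruen_zone`, `volumes` (mm3), `order`, `geometry`.
#' @export
#' @examples
#' mesh <- generate_femur_mesh(target_edge = 10)
#' table(mesh$tissue)
generate_femur_mesh <- function(geometry = femur_geometry(), target_edge = 4,
                                order = 1, seed = NULL) {
  stopifnot(inherits(geometry, "femur_geometry"), target_edge > 0,
    order %in% c(1, 2))
  fr <- femur_frame(geometry)
  pad <- 2
  xmax <- max(fr$head_centre[1] + geometry$head_radius,
    geometry$shaft_radius) + pad
  xmin <- min(fr$troch_centre[1] - fr$troch_semi[1],
    -geometry$shaft_radius) - pad
  ymax <- max(geometry$shaft_radius, geometry$head_radius,
    fr$troch_semi[2]) + pad
  zmax <- fr$head_centre[3] + geometry$head_radius + pad
  bbox <- rbind(c(xmin, -ymax, 0), c(xmax, ymax, zmax))
  raw <- voxel_tet_mesh(function(p) femur_inside(p, geometry), bbox,
    target_edge)
  centroids <- (raw$nodes[raw$tets[, 1], ] + raw$nodes[raw$tets[, 2], ] +
    raw$nodes[raw$tets[, 3], ] + raw$nodes[raw$tets[, 4], ]) / 4
  in_canal <- femur_in_canal(centroids, geometry)
  in_inner <- femur_inside(centroids, geometry, shrink = 1)
  tissue <- ifelse(in_canal, "marrow",
    ifelse(in_inner, "cancellous", "cortical"))
  lab <- label_femur_elements(centroids, geometry)
  zone <- lab$zone
  zone[tissue == "marrow"] <- NA_integer_
  mesh <- structure(list(
    nodes = raw$nodes, tets = raw$tets, tets10 = NULL,
    tissue = tissue, region = lab$region, gruen_zone = zone,
    volumes = raw$volumes, order = as.integer(order),
    target_edge = target_edge, geometry = geometry
  ), class = "femur_mesh")
  if (order == 2) mesh <- add_midside_nodes(mesh)
  mesh
}

#' @export
print.femur_mesh <- function(x, ...) {
  cat(sprintf("<femur_mesh> %d nodes, %d tet%d elements (edge ~%g mm)\n",
    nrow(x$nodes), nrow(x$tets), if (x$order == 2) 10 else 4, x$target_edge))
  cat("  tissue: ", paste(sprintf("%s=%d", names(table(x$tissue)),
    table(x$tissue)), collapse = ", "), "\n", sep = "")
  inv <- x$gruen_zone[!is.na(x$gruen_zone)]
  cat("  Gruen zones present: ", paste(sort(unique(inv)), collapse = " "),
    "\n", sep = "")
  invisible(x)
}

# insert unique midside nodes; tets10 columns 5-10 follow the edge order
# (1,2) (2,3) (1,3) (1,4) (2,4) (3,4)
add_midside_nodes <- function(mesh) {
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L), c(1L, 4L), c(2L, 4L),
    c(3L, 4L))
  tets <- mesh$tets
  n0 <- nrow(mesh$nodes)
  all_edges <- do.call(rbind, lapply(seq_len(nrow(edges)), function(e) {
    cbind(tets[, edges[e, 1]], tets[, edges[e, 2]])
  }))
  key_lo <- pmin(all_edges[, 1], all_edges[, 2])
  key_hi <- pmax(all_edges[, 1], all_edges[, 2])
  key <- paste(key_lo, key_hi)
  uk <- !duplicated(key)
  ids <- match(key, key[uk]) + n0
  mids <- (mesh$nodes[key_lo[uk], , drop = FALSE] +
    mesh$nodes[key_hi[uk], , drop = FALSE]) / 2
  m <- nrow(tets)
  tets10 <- cbind(tets, matrix(ids, nrow = m, ncol = 6))
  mesh$nodes <- rbind(mesh$nodes, mids)
  mesh$tets10 <- tets10
  mesh
}

#' Structured tetrahedral mesh of a rectangular block
#'
#' Verification fixture for the elasticity solver (patch tests, cantilever
#' benchmarks). The block spans `[0, lx] x [0, ly] x [0, lz]`.
#'
#' @param lx,ly,lz Block dimensions, mm.
#' @param nx,ny,nz Number of cells per direction.
#' @param order Element order (1 or 2).
#' @return A `femur_mesh`-classed object with uniform `cortical` tissue and
#'   region `"body"`.
#' @export
brick_mesh <- function(lx = 1, ly = 1, lz = 1, nx = 2, ny = 2, nz = 2,
                       order = 1) {
  stopifnot(lx > 0, ly > 0, lz > 0, nx >= 1, ny >= 1, nz >= 1,
    order %in% c(1, 2))
  hx <- lx / nx
  # voxel mesher requires a cubic grid; use anisotropic scaling afterwards
  raw <- voxel_tet_mesh(function(p) rep(TRUE, nrow(p)),
    rbind(c(0, 0, 0), c(nx, ny, nz)), 1)
  nodes <- cbind(raw$nodes[, 1] * lx / nx, raw$nodes[, 2] * ly / ny,
    raw$nodes[, 3] * lz / nz)
  vol <- tet_volumes(nodes, raw$tets)
  m <- nrow(raw$tets)
  mesh <- structure(list(
    nodes = nodes, tets = raw$tets, tets10 = NULL,
    tissue = rep("cortical", m), region = rep("body", m),
    gruen_zone = rep(NA_integer_, m), volumes = vol,
    order = as.integer(order), target_edge = hx, geometry = NULL
  ), class = "femur_mesh")
  if (order == 2) mesh <- add_midside_nodes(mesh)
  mesh
}

#' Check that a mesh is a valid solid
#'
#' Verifies positive element volumes, in-range connectivity, and that the
#' boundary is watertight: every triangular face belongs to one or two
#' tetrahedra and each boundary edge is shared by an even number (at least
#' two) of boundary faces, i.e. the boundary is a closed surface. Edges with
#' more than two boundary faces (pinch points, which structured meshes of
#' curved solids can produce at coarse resolution) are reported in
#' `nonmanifold_edges` without failing the check.
#'
#' @param mesh A mesh from [generate_femur_mesh()] or [brick_mesh()].
#' @return A list with logical `ok` plus diagnostic counts.
#' @export
check_mesh <- function(mesh) {
  tets <- mesh$tets
  nn <- nrow(mesh$nodes)
  faces_idx <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- do.call(rbind, lapply(1:4, function(f) tets[, faces_idx[f, ]]))
  faces_sorted <- t(apply(faces, 1, sort))
  key <- paste(faces_sorted[, 1], faces_sorted[, 2], faces_sorted[, 3])
  cnt <- table(key)
  boundary <- names(cnt)[cnt == 1]
  bf <- do.call(rbind, strsplit(boundary, " "))
  storage.mode(bf) <- "integer"
  bedges <- rbind(bf[, c(1, 2)], bf[, c(1, 3)], bf[, c(2, 3)])
  ekey <- paste(pmin(bedges[, 1], bedges[, 2]), pmax(bedges[, 1], bedges[, 2]))
  ecnt <- table(ekey)
  list(
    ok = all(mesh$volumes > 0) && all(tets >= 1 & tets <= nn) &&
      all(cnt <= 2) && all(ecnt >= 2 & ecnt %% 2 == 0),
    n_boundary_faces = length(boundary),
    max_face_multiplicity = max(cnt),
    nonmanifold_edges = sum(ecnt > 2),
    min_volume = min(mesh$volumes)
  )
}

#' Volume-weighted average of a per-element field over a region
#'
#' @param values Numeric vector, one value per element (`NA`s are dropped
#'   together with their volume weight).
#' @param mesh The mesh the field lives on.
#' @param region Region name (see [generate_femur_mesh()]) or `"all"`.
#' @return A scalar.
#' @export
region_average <- function(values, mesh, region = "all") {
  stopifnot(length(values) == nrow(mesh$tets))
  sel <- if (identical(region, "all")) rep(TRUE, length(values)) else
    mesh$region == region
  if (!any(sel)) {
    rlang::abort(sprintf("Region '%s' contains no elements.", region),
      class = "osteofem_input_error")
  }
  v <- mesh$volumes[sel]
  x <- values[sel]
  keep <- !is.na(x)
  if (!any(keep)) return(NA_real_)
  sum(v[keep] * x[keep]) / sum(v[keep])
}
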