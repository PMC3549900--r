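# Linear-elastic tetrahedral finite elements (tet4 and straight-edge tet10).
#
# Assembly is fully vectorized over elements. For fixed Poisson ratios the
# element stiffness scales linearly with the Young's modulus, so the
# structure precomputed by fe_structure() stores unit-modulus triplets that
# are rescaled at each material update -- the evolution engine re-assembles
# 31 stiffness matrices per scenario this way.

# barycentric gradients (constant over a straight-edge tet): list of 4
# n x 3 matrices, plus signed volumes
tet_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  cc <- nodes[tets[, 4], , drop = FALSE] - p1
  cross <- function(u, v) cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- cross(b, cc)
  detJ <- rowSums(a * bxc) # 6 V
  g2 <- bxc / detJ
  g3 <- cross(cc, a) / detJ
  g4 <- cross(a, b) / detJ
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), volume = detJ / 6)
}

# 4-point Gauss rule on the reference tet (degree-2 exact)
tet10_gauss <- function() {
  a <- 0.5854101966249685
  b <- 0.1381966011250105
  pts <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  list(lambda = pts, weight = rep(0.25, 4))
}

# gradients of the 10 tet10 shape functions at barycentric point lam,
# given corner barycentric gradients g (list of 4 n x 3)
tet10_shape_grads <- function(g, lam) {
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L), c(1L, 4L), c(2L, 4L),
    c(3L, 4L))
  out <- vector("list", 10L)
  for (a in 1:4) out[[a]] <- (4 * lam[a] - 1) * g[[a]]
  for (e in 1:6) {
    i <- edges[e, 1]; j <- edges[e, 2]
    out[[4L + e]] <- 4 * (lam[i] * g[[j]] + lam[j] * g[[i]])
  }
  out
}

#' Precompute the assembly structure of a mesh
#'
#' Builds unit-modulus stiffness triplets (element stiffness for E = 1 MPa at
#' each element's Poisson ratio) so that repeated solves with changing
#' Young's moduli only rescale and re-sum the triplets. Exposed because the
#' evolution engine reuses it across all time steps.
#'
#' @param mesh Mesh from [generate_femur_mesh()] or [brick_mesh()].
#' @param poisson Named vector of Poisson ratios per tissue, or a single
#'   number applied to all elements.
#' @return An opaque list used by [solve_elasticity()].
#' @export
fe_structure <- function(mesh, poisson = c(cortical = 0.3, cancellous = 0.3,
                                           marrow = 0.45)) {
  nu <- if (length(poisson) == 1L && is.null(names(poisson))) {
    rep(poisson, nrow(mesh$tets))
  } else {
    unname(poisson[mesh$tissue])
  }
  if (anyNA(nu)) {
    rlang::abort("`poisson` must cover every tissue present in the mesh.",
      class = "osteofem_input_error")
  }
  # Lame constants per unit modulus
  lam0 <- nu / ((1 + nu) * (1 - 2 * nu))
  mu0 <- 1 / (2 * (1 + nu))
  gr <- tet_gradients(mesh$nodes, mesh$tets)
  V <- gr$volume
  m <- nrow(mesh$tets)
  if (mesh$order == 1L) {
    conn <- mesh$tets
    nodal_grads <- gr$g
    nloc <- 4L
    combos <- nloc^2 * 9L
    ii <- matrix(0L, combos, m)
    jj <- matrix(0L, combos, m)
    xx <- matrix(0, combos, m)
    row_k <- 0L
    for (a in seq_len(nloc)) {
      ga <- nodal_grads[[a]]
      for (b in seq_len(nloc)) {
        gb <- nodal_grads[[b]]
        dot <- rowSums(ga * gb)
        for (r in 1:3) {
          for (s in 1:3) {
            row_k <- row_k + 1L
            val <- V * (lam0 * ga[, r] * gb[, s] + mu0 * gb[, r] * ga[, s])
            if (r == s) val <- val + V * mu0 * dot
            ii[row_k, ] <- 3L * (conn[, a] - 1L) + r
            jj[row_k, ] <- 3L * (conn[, b] - 1L) + s
            xx[row_k, ] <- val
          }
        }
      }
    }
  } else {
    conn <- mesh$tets10
    gauss <- tet10_gauss()
    nloc <- 10L
    combos <- nloc^2 * 9L
    ii <- matrix(0L, combos, m)
    jj <- matrix(0L, combos, m)
    xx <- matrix(0, combos, m)
    # accumulate over gauss points
    acc <- vector("list", 4L)
    for (gq in 1:4) {
      acc[[gq]] <- tet10_shape_grads(gr$g, gauss$lambda[gq, ])
    }
    row_k <- 0L
    for (a in seq_len(nloc)) {
      for (b in seq_len(nloc)) {
        blocks <- matrix(0, m, 9)
        for (gq in 1:4) {
          ga <- acc[[gq]][[a]]
          gb <- acc[[gq]][[b]]
          w <- gauss$weight[gq] * V
          dot <- rowSums(ga * gb)
          k <- 0L
          for (r in 1:3) {
            for (s in 1:3) {
              k <- k + 1L
              add <- w * (lam0 * ga[, r] * gb[, s] + mu0 * gb[, r] * ga[, s])
              if (r == s) add <- add + w * mu0 * dot
              blocks[, k] <- blocks[, k] + add
            }
          }
        }
        k <- 0L
        for (r in 1:3) {
          for (s in 1:3) {
            k <- k + 1L
            row_k <- row_k + 1L
            ii[row_k, ] <- 3L * (conn[, a] - 1L) + r
            jj[row_k, ] <- 3L * (conn[, b] - 1L) + s
            xx[row_k, ] <- blocks[, k]
          }
        }
      }
    }
  }
  list(
    i = as.vector(ii), j = as.vector(jj), x_unit = as.vector(xx),
    combos = combos, n_dof = 3L * nrow(mesh$nodes), n_elem = m,
    grads = gr$g, volume = V, conn = conn, order = mesh$order, nu = nu
  )
}

assemble_stiffness <- function(fe, youngs) {
  stopifnot(length(youngs) == fe$n_elem)
  Matrix::sparseMatrix(
    i = fe$i, j = fe$j, x = fe$x_unit * rep(youngs, each = fe$combos),
    dims = c(fe$n_dof, fe$n_dof)
  )
}

# per-element strain (Voigt: exx eyy ezz gxy gyz gxz) from displacements;
# evaluated at the centroid (exact for tet4, centroid value for tet10)
element_strains <- function(fe, u) {
  ux <- u[seq(1, fe$n_dof, by = 3)]
  uy <- u[seq(2, fe$n_dof, by = 3)]
  uz <- u[seq(3, fe$n_dof, by = 3)]
  m <- fe$n_elem
  exx <- eyy <- ezz <- gxy <- gyz <- gxz <- numeric(m)
  if (fe$order == 1L) {
    grads <- fe$grads
    nloc <- 4L
    conn <- fe$conn
    glist <- lapply(seq_len(nloc), function(a) grads[[a]])
  } else {
    # centroid: corner gradients vanish, edge functions give g_i + g_j
    conn <- fe$conn
    nloc <- 10L
    glist <- tet10_shape_grads(fe$grads, rep(0.25, 4))
  }
  for (a in seq_len(nloc)) {
    ga <- glist[[a]]
    na <- conn[, a]
    exx <- exx + ga[, 1] * ux[na]
    eyy <- eyy + ga[, 2] * uy[na]
    ezz <- ezz + ga[, 3] * uz[na]
    gxy <- gxy + ga[, 2] * ux[na] + ga[, 1] * uy[na]
    gyz <- gyz + ga[, 3] * uy[na] + ga[, 2] * uz[na]
    gxz <- gxz + ga[, 3] * ux[na] + ga[, 1] * uz[na]
  }
  cbind(exx = exx, eyy = eyy, ezz = ezz, gxy = gxy, gyz = gyz, gxz = gxz)
}

# analytic eigenvalues of symmetric 3x3 tensors, vectorized; rows of
# `strain` are Voigt with engineering shears; returns m x 3, descending
principal_strains_voigt <- function(strain) {
  strain <- rbind(strain)
  exx <- strain[, 1]; eyy <- strain[, 2]; ezz <- strain[, 3]
  exy <- strain[, 4] / 2; eyz <- strain[, 5] / 2; exz <- strain[, 6] / 2
  q <- (exx + eyy + ezz) / 3
  p1 <- exy^2 + eyz^2 + exz^2
  p2 <- (exx - q)^2 + (eyy - q)^2 + (ezz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  m <- length(q)
  e1 <- e2 <- e3 <- q
  nz <- p > 1e-300
  if (any(nz)) {
    bxx <- (exx - q) / p; byy <- (eyy - q) / p; bzz <- (ezz - q) / p
    bxy <- exy / p; byz <- eyz / p; bxz <- exz / p
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1 <- q + 2 * p * cos(phi)
    l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    l2 <- 3 * q - l1 - l3
    e1[nz] <- l1[nz]; e2[nz] <- l2[nz]; e3[nz] <- l3[nz]
  }
  cbind(e1, e2, e3)
}

#' Solve static linear elasticity on a tetrahedral mesh
#'
#' Small-strain static solution with nodal loads and (optionally non-zero)
#' Dirichlet conditions. Returns displacements, per-element strain tensors,
#' principal and equivalent strains, strain/potential energy and the global
#' equilibrium residual.
#'
#' @param mesh Mesh from [generate_femur_mesh()] or [brick_mesh()].
#' @param youngs Young's modulus per element (vector of length
#'   `nrow(mesh$tets)`), or a named vector per tissue, MPa.
#' @param forces Nodal load matrix, `n_nodes x 3`, N. Defaults to zero.
#' @param fixed_nodes Integer node indices with prescribed displacement.
#' @param fixed_values Prescribed displacements for `fixed_nodes`
#'   (`length(fixed_nodes) x 3` matrix, or 0).
#' @param poisson Poisson ratios per tissue (named) or a single value.
#' @param fe Optional precomputed [fe_structure()] (must match `mesh` and
#'   `poisson`).
#' @return An object of class `fe_result`.
#' @export
solve_elasticity <- function(mesh, youngs, forces = NULL,
                             fixed_nodes = integer(), fixed_values = 0,
                             poisson = c(cortical = 0.3, cancellous = 0.3,
                               marrow = 0.45),
                             fe = NULL) {
  m <- nrow(mesh$tets)
  if (!is.null(names(youngs))) {
    youngs <- unname(youngs[mesh$tissue])
  }
  if (length(youngs) == 1L) youngs <- rep(youngs, m)
  if (length(youngs) != m || any(!is.finite(youngs)) || any(youngs <= 0)) {
    rlang::abort("`youngs` must be positive and cover every element.",
      class = "osteofem_input_error")
  }
  if (length(fixed_nodes) == 0L) {
    rlang::abort("No Dirichlet constraints: the system is singular (rigid-body modes).",
      class = "osteofem_singular_error")
  }
  if (is.null(fe)) fe <- fe_structure(mesh, poisson)
  n_nodes_total <- fe$n_dof / 3L
  if (is.null(forces)) forces <- matrix(0, n_nodes_total, 3)
  if (nrow(forces) != n_nodes_total) {
    # order-2 meshes carry midside nodes; allow corner-sized load matrices
    forces <- rbind(forces,
      matrix(0, n_nodes_total - nrow(forces), 3))
  }
  if (any(!is.finite(forces))) {
    rlang::abort("`forces` must be finite.", class = "osteofem_input_error")
  }
  K <- assemble_stiffness(fe, youngs)
  f <- as.vector(t(forces))
  fixed_dofs <- as.vector(t(outer(3L * (fixed_nodes - 1L), 1:3, "+")))
  u <- numeric(fe$n_dof)
  if (is.matrix(fixed_values)) {
    u[fixed_dofs] <- as.vector(t(fixed_values))
  } else {
    u[fixed_dofs] <- fixed_values
  }
  free <- setdiff(seq_len(fe$n_dof), fixed_dofs)
  rhs <- f[free] - as.vector(K[free, fixed_dofs, drop = FALSE] %*% u[fixed_dofs])
  Kff <- K[free, free]
  # the constrained stiffness is SPD: sparse Cholesky (CHOLMOD) is much
  # faster than the default LU and doubles as a positive-definiteness check
  uf <- tryCatch({
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE,
      super = TRUE)
    as.vector(Matrix::solve(ch, rhs))
  },
    error = function(e) {
      rlang::abort(paste0("Singular stiffness system: ", conditionMessage(e),
        " (insufficient constraints?)"), class = "osteofem_singular_error")
    }
  )
  u[free] <- uf
  Ku <- as.vector(K %*% u)
  reactions <- Ku[fixed_dofs] - f[fixed_dofs]
  applied_sum <- colSums(matrix(f, ncol = 3, byrow = TRUE))
  # sum of reactions (Ku - f at fixed dofs, ~0 at free dofs) + applied loads
  react_sum <- colSums(matrix(Ku - f, ncol = 3, byrow = TRUE))
  imbalance <- sqrt(sum((react_sum + applied_sum)^2))
  denom <- sqrt(sum(applied_sum^2))
  equilibrium_residual <- if (denom > 0) imbalance / denom else imbalance
  strain <- element_strains(fe, u)
  principal <- principal_strains_voigt(strain)
  eps_c <- equivalent_strain_voigt(strain)
  strain_energy <- 0.5 * sum(u * Ku)
  structure(list(
    displacements = matrix(u, ncol = 3, byrow = TRUE),
    strain = strain,
    principal_strains = principal,
    eps_c = eps_c,
    strain_energy = strain_energy,
    potential_energy = strain_energy - sum(f * u),
    reactions = reactions,
    fixed_nodes = fixed_nodes,
    equilibrium_residual = equilibrium_residual,
    n_dof = fe$n_dof
  ), class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf(
    "<fe_result> %d dof;  strain energy %.6g N.mm;  max |u| %.4g mm\n",
    x$n_dof, x$strain_energy, max(abs(x$displacements))))
  cat(sprintf("  equilibrium residual %.3g;  max eps_c %.4g\n",
    x$equilibrium_residual, max(x$eps_c)))
  invisible(x)
}

#' @export
tidy.fe_result <- function(x, ...) {
  tibble::tibble(
    element = seq_along(x$eps_c),
    eps_1 = x$principal_strains[, 1],
    eps_2 = x$principal_strains[, 2],
    eps_3 = x$principal_strains[, 3],
    eps_c = x$eps_c
  )
}

#' @export
glance.fe_result <- function(x, ...) {
  tibble::tibble(
    n_dof = x$n_dof,
    strain_energy = x$strain_energy,
    potential_energy = x$potential_energy,
    equilibrium_residual = x$equilibrium_residual,
    max_displacement = max(abs(x$displacements)),
    max_eps_c = max(x$eps_c)
  )
}

#' Mesh-refinement convergence study on the potential energy
#'
#' Solves the same problem across a refinement sequence and reports the
#' total strain energy per level together with the relative change between
#' consecutive levels; the accepted level is the first whose change against
#' the previous mesh is below `tol` (1% by default).
#'
#' @param levels Vector identifying the refinement levels (passed to
#'   `build`).
#' @param build Function `level -> mesh`.
#' @param solve Function `mesh -> fe_result` (attach loads/constraints
#'   inside).
#' @param tol Relative energy-change tolerance.
#' @return A tibble with `level`, `n_elements`, `strain_energy`,
#'   `rel_change`, `converged` (flagging the accepted level only).
#' @export
mesh_convergence_study <- function(levels, build, solve, tol = 0.01) {
  if (length(levels) < 2L) {
    rlang::abort("A convergence study needs at least 2 refinement levels.",
      class = "osteofem_input_error")
  }
  energies <- numeric(length(levels))
  nelems <- integer(length(levels))
  for (k in seq_along(levels)) {
    mesh <- build(levels[k])
    res <- solve(mesh)
    energies[k] <- res$strain_energy
    nelems[k] <- nrow(mesh$tets)
  }
  rel <- c(NA_real_, abs(diff(energies)) / abs(energies[-1]))
  hit <- which(!is.na(rel) & rel < tol)
  converged <- rep(FALSE, length(levels))
  if (length(hit) > 0) converged[hit[1]] <- TRUE
  tibble::tibble(
    level = levels, n_elements = nelems, strain_energy = energies,
    rel_change = rel, converged = converged
  )
}
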