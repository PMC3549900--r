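test_that("patch test: prescribed linear field gives constant strain to machine precision", {
  mesh <- brick_mesh(1, 1, 1, 3, 3, 3)
  A <- matrix(c(1e-3, 4e-4, 2e-4,
                4e-4, -5e-4, 3e-4,
                2e-4, 3e-4, 8e-4), 3, 3, byrow = TRUE)
  bnd <- which(apply(mesh$nodes, 1, function(p)
    any(abs(p) < 1e-12 | abs(p - 1) < 1e-12)))
  res <- solve_elasticity(mesh, 1000, fixed_nodes = bnd,
    fixed_values = mesh$nodes[bnd, ] %*% A, poisson = 0.3)
  expected <- c(A[1, 1], A[2, 2], A[3, 3], 2 * A[1, 2], 2 * A[2, 3],
    2 * A[1, 3])
  expect_lt(max(abs(sweep(res$strain, 2, expected))), 1e-13)
  # principal strains match the eigenvalues of the prescribed tensor
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(res$principal_strains[1, ], ev, tolerance = 1e-10,
    ignore_attr = TRUE)
})

test_that("zero loads give zero displacements, strains and energy", {
  mesh <- brick_mesh(2, 1, 1, 2, 1, 1)
  fixed <- which(mesh$nodes[, 1] < 1e-9)
  res <- solve_elasticity(mesh, 5000, fixed_nodes = fixed, poisson = 0.25)
  expect_equal(max(abs(res$displacements)), 0)
  expect_equal(max(res$eps_c), 0)
  expect_equal(res$strain_energy, 0)
})

test_that("solution is linear in loads and inverse in stiffness", {
  mesh <- brick_mesh(4, 1, 1, 4, 2, 2)
  fixed <- which(mesh$nodes[, 1] < 1e-9)
  tip <- which(mesh$nodes[, 1] > 4 - 1e-9)
  f <- matrix(0, nrow(mesh$nodes), 3)
  f[tip, 3] <- -10 / length(tip)
  r1 <- solve_elasticity(mesh, 2000, forces = f, fixed_nodes = fixed,
    poisson = 0.3)
  r2 <- solve_elasticity(mesh, 2000, forces = 2 * f, fixed_nodes = fixed,
    poisson = 0.3)
  expect_equal(r2$displacements, 2 * r1$displacements, tolerance = 1e-10)
  expect_equal(r2$eps_c, 2 * r1$eps_c, tolerance = 1e-10)
  r3 <- solve_elasticity(mesh, 2000 * 4, forces = f, fixed_nodes = fixed,
    poisson = 0.3)
  expect_equal(r3$displacements, r1$displacements / 4, tolerance = 1e-10)
})

test_that("equivalent strain field is frame-indifferent under rigid rotation", {
  mesh <- brick_mesh(3, 1, 1, 3, 1, 1)
  fixed <- which(mesh$nodes[, 1] < 1e-9)
  tip <- which(mesh$nodes[, 1] > 3 - 1e-9)
  f <- matrix(0, nrow(mesh$nodes), 3)
  f[tip, 2] <- 2
  f[tip, 3] <- -5
  base <- solve_elasticity(mesh, 3000, forces = f, fixed_nodes = fixed,
    poisson = 0.3)
  # rotate mesh and loads by the same rotation
  th <- 0.7
  ax <- c(1, 2, 2) / 3
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
    byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  mesh_r <- mesh
  mesh_r$nodes <- mesh$nodes %*% t(R)
  rot <- solve_elasticity(mesh_r, 3000, forces = f %*% t(R),
    fixed_nodes = fixed, poisson = 0.3)
  expect_equal(rot$eps_c, base$eps_c, tolerance = 1e-8)
  expect_equal(rot$strain_energy, base$strain_energy, tolerance = 1e-8)
})

test_that("stiffness is symmetric, energy non-negative, rigid motion strain-free", {
  mesh <- brick_mesh(1, 1, 1, 2, 2, 2)
  fe <- fe_structure(mesh, 0.3)
  K <- osteofem:::assemble_stiffness(fe, rep(1000, nrow(mesh$tets)))
  expect_lt(max(abs(K - Matrix::t(K))), 1e-9)
  set.seed(5)
  u <- rnorm(nrow(mesh$nodes) * 3)
  expect_gte(sum(u * as.vector(K %*% u)), 0)
  # rigid translation + infinitesimal rotation produce zero strain
  w <- c(1e-3, -2e-3, 5e-4)
  W <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
    byrow = TRUE)
  u_rigid <- sweep(mesh$nodes %*% t(W), 2, c(0.1, -0.2, 0.3), "+")
  strains <- osteofem:::element_strains(fe, as.vector(t(u_rigid)))
  expect_lt(max(abs(strains)), 1e-12)
})

test_that("unconstrained systems are rejected as singular", {
  mesh <- brick_mesh(1, 1, 1, 1, 1, 1)
  expect_error(solve_elasticity(mesh, 1000, fixed_nodes = integer()),
    class = "osteofem_singular_error")
})

test_that("convergence study reports energies and flags the accepted level", {
  study <- mesh_convergence_study(1:3,
    build = function(k) brick_mesh(20, 4, 4, 5 * k, k, k, order = 2),
    solve = function(m) solve_cantilever(m, E = 1e4, load = 20))
  expect_equal(nrow(study), 3)
  expect_true(is.na(study$rel_change[1]))
  # refinement shrinks the energy change
  expect_lt(study$rel_change[3], study$rel_change[2])
  # the accepted level is the first below tolerance, not earlier
  hit <- which(study$rel_change < 0.01)
  expect_equal(which(study$converged), hit[1])
  expect_error(mesh_convergence_study(1, build = identity, solve = identity),
    class = "osteofem_input_error")
})

test_that("femur load case balances applied loads at the clamp", {
  mesh <- coarse_femur
  lc <- apply_load_case(mesh, load_case())
  expect_gt(length(lc$head_patch), 0)
  expect_gt(length(lc$troch_patch), 0)
  expect_gt(length(lc$fixed_nodes), 0)
  # total applied force equals the two load magnitudes along their directions
  total <- colSums(lc$forces)
  expected <- 3110 * load_case()$head_direction +
    1360 * load_case()$abductor_direction
  expect_equal(total, expected, tolerance = 1e-9)
  res <- solve_elasticity(mesh, c(cortical = 15000, cancellous = 350,
    marrow = 20), forces = lc$forces, fixed_nodes = lc$fixed_nodes)
  expect_lt(res$equilibrium_residual, 1e-8)
})
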