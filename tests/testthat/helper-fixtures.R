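# Shared fixtures, built once per test run. Meshes used by unit tests are
# deliberately coarse; the acceptance tests build their own finer meshes.

coarse_femur <- generate_femur_mesh(target_edge = 8)

# printed reference values of the healthy-femur zone table
reference_zone_table <- function() {
  read_reference <- system.file("extdata", "healthy_femur_reference.csv",
    package = "osteofem")
  readr::read_csv2(read_reference,
    locale = readr::locale(decimal_mark = ",", grouping_mark = "."),
    show_col_types = FALSE, progress = FALSE)
}

# small brick cantilever solve used by several FE tests
solve_cantilever <- function(mesh, E = 1e4, load = 100, nu = 0) {
  fixed <- which(mesh$nodes[, 1] < 1e-9)
  tip <- which(mesh$nodes[, 1] > max(mesh$nodes[, 1]) - 1e-9)
  f <- matrix(0, nrow(mesh$nodes), 3)
  f[tip, 3] <- -load / length(tip)
  solve_elasticity(mesh, E, forces = f, fixed_nodes = fixed, poisson = nu)
}
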