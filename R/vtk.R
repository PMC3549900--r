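# Legacy-ASCII VTK unstructured-grid I/O for tetrahedral meshes.
# Values are printed with %.17g so numeric round trips are exact.

#' Write a tetrahedral mesh (with optional cell fields) to a VTK file
#'
#' Emits a legacy ASCII `UNSTRUCTURED_GRID` file (cell type 10 for 4-node,
#' 24 for 10-node tetrahedra). Numeric cell fields are written as `double`
#' scalars; character/factor fields are encoded as integer codes with the
#' level order recorded in the header comment line.
#'
#' @param mesh Mesh from [generate_femur_mesh()] or [brick_mesh()].
#' @param path Output file path.
#' @param cell_data Named list of per-element vectors.
#' @param title Title line of the file.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), title = "osteofem mesh") {
  conn <- if (mesh$order == 2L) mesh$tets10 else mesh$tets
  npe <- ncol(conn)
  m <- nrow(conn)
  n <- nrow(mesh$nodes)
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", title, "ASCII", "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(sprintf("%.17g %.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2],
    mesh$nodes[, 3]))
  wl(sprintf("CELLS %d %d", m, m * (npe + 1L)))
  wl(do.call(sprintf, c(
    list(paste0("%d", strrep(" %d", npe))), list(rep(npe, m)),
    lapply(seq_len(npe), function(k) conn[, k] - 1L))))
  wl(sprintf("CELL_TYPES %d", m))
  wl(sprintf("%d", rep(if (npe == 10L) 24L else 10L, m)))
  if (length(cell_data) > 0L) {
    wl(sprintf("CELL_DATA %d", m))
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      stopifnot(length(v) == m)
      if (is.character(v) || is.factor(v)) {
        lev <- levels(factor(v))
        wl(sprintf("SCALARS %s int 1", nm),
          sprintf("LOOKUP_TABLE default_%s", paste(lev, collapse = "_")))
        wl(sprintf("%d", as.integer(factor(v, levels = lev))))
      } else {
        vv <- as.numeric(v)
        vv[is.na(vv)] <- -1
        wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
        wl(sprintf("%.17g", vv))
      }
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured-grid file
#'
#' @param path File path.
#' @return A list with `nodes` (n x 3), `cells` (m x k, 1-based),
#'   `cell_type`, and `cell_data` (named list of numeric vectors).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  find_kw <- function(kw) grep(paste0("^", kw, " ?"), lines)[1]
  ip <- find_kw("POINTS")
  n <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  pts <- scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- find_kw("CELLS")
  m <- as.integer(strsplit(lines[ic], " +")[[1]][2])
  cell_rows <- lapply(strsplit(trimws(lines[(ic + 1):(ic + m)]), " +"),
    as.integer)
  npe <- cell_rows[[1]][1]
  cells <- do.call(rbind, lapply(cell_rows, function(r) r[-1] + 1L))
  it <- find_kw("CELL_TYPES")
  cell_type <- as.integer(lines[(it + 1):(it + m)])
  cell_data <- list()
  id <- find_kw("CELL_DATA")
  if (!is.na(id)) {
    k <- id + 1L
    while (k <= length(lines)) {
      if (grepl("^SCALARS ", lines[k])) {
        parts <- strsplit(lines[k], " +")[[1]]
        nm <- parts[2]
        vals <- scan(text = lines[(k + 2):(k + 1 + m)], quiet = TRUE)
        cell_data[[nm]] <- vals
        k <- k + 2L + m
      } else {
        k <- k + 1L
      }
    }
  }
  list(nodes = nodes, cells = cells, cell_type = cell_type,
    cell_data = cell_data)
}
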