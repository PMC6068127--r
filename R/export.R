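#' Export a mesh (with optional cell fields) as legacy VTK
#'
#' ASCII legacy VTK unstructured grid (readable by ParaView): hexahedra as
#' cell type 12, quadratic tetrahedra as type 24. Per-element fields
#' (modulus, density, stress, region codes, ...) are written as CELL_DATA
#' scalars.
#'
#' @param mesh An `fe_mesh`.
#' @param path Output `.vtk` path.
#' @param cell_data Named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$conn)
  writeLines(c("# vtk DataFile Version 3.0", "tibiamech mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  npe <- ncol(mesh$conn)
  writeLines(sprintf("CELLS %d %d", ne, ne * (npe + 1)), con)
  utils::write.table(cbind(npe, mesh$conn - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  ctype <- if (mesh$type == "hex8") 12L else 24L
  writeLines(c(sprintf("CELL_TYPES %d", ne),
               as.character(rep(ctype, ne))), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", gsub("[^A-Za-z0-9_]", "_",
                                                       nm)),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], scientific = TRUE, digits = 9), con)
    }
  }
  invisible(path)
}

#' Export a mesh and materials as an Abaqus INP deck
#'
#' Interchange writer: nodes, C3D8 or C3D10 elements, and per-material-bin
#' element sets with `*SOLID SECTION` / `*MATERIAL` cards. Element moduli
#' are binned (equal-width in log E) to keep the deck size reasonable, the
#' usual practice for density-mapped bone models.
#'
#' @param mesh An `fe_mesh`.
#' @param materials A `material_field`.
#' @param path Output `.inp` path.
#' @param n_bins Number of modulus bins for bone elements (default 50).
#' @return `path`, invisibly.
#' @export
write_inp <- function(mesh, materials, path, n_bins = 50) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines("tibiamech QCT-FE model export", con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.6f, %.6f, %.6f", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  etype <- if (mesh$type == "hex8") "C3D8" else "C3D10"
  writeLines(sprintf("*ELEMENT, TYPE=%s", etype), con)
  writeLines(paste0(seq_len(nrow(mesh$conn)), ", ",
                    apply(mesh$conn, 1, paste, collapse = ", ")), con)
  # bin elements by (E, nu) so each bin is one section/material
  logE <- log10(materials$E)
  brk <- seq(min(logE) - 1e-9, max(logE) + 1e-9, length.out = n_bins + 1)
  bin <- cut(logE, brk, labels = FALSE)
  key <- paste0(bin, "_", signif(materials$nu, 6))
  for (k in unique(key)) {
    sel <- which(key == k)
    Ebin <- mean(materials$E[sel])
    nubin <- materials$nu[sel[1]]
    setname <- paste0("MAT_", gsub("[^A-Za-z0-9]", "_", k))
    writeLines(sprintf("*ELSET, ELSET=%s", setname), con)
    writeLines(vapply(split(sel, ceiling(seq_along(sel) / 10)),
                      paste, "", collapse = ", "), con)
    writeLines(sprintf("*SOLID SECTION, ELSET=%s, MATERIAL=%s",
                       setname, setname), con)
    writeLines(sprintf("*MATERIAL, NAME=%s", setname), con)
    writeLines("*ELASTIC", con)
    writeLines(sprintf("%.6g, %.4f", Ebin, nubin), con)
  }
  for (s in names(mesh$node_sets)) {
    nds <- mesh$node_sets[[s]]
    if (!length(nds)) next
    writeLines(sprintf("*NSET, NSET=%s", toupper(s)), con)
    writeLines(vapply(split(nds, ceiling(seq_along(nds) / 10)),
                      paste, "", collapse = ", "), con)
  }
  invisible(path)
}

#' Export a region map legend and labels as JSON + VTK
#'
#' @param map A `region_map`.
#' @param mesh The matching `fe_mesh`.
#' @param path_vtk Output VTK path (cell scalar = region code).
#' @param path_json Output JSON legend path (code -> region name).
#' @return Invisibly, the legend as a named integer vector.
#' @export
write_region_map <- function(map, mesh, path_vtk, path_json) {
  codes <- as.integer(map$region)
  legend <- stats::setNames(seq_along(levels(map$region)),
                            levels(map$region))
  write_vtk(mesh, path_vtk, cell_data = list(region_code = codes))
  jsonlite::write_json(as.list(legend), path_json, auto_unbox = TRUE)
  invisible(legend)
}
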