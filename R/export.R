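## Plain-text exports: VTK fields, profile CSVs, metric tables.

#' Export a solved case as a legacy-ASCII VTK file
#'
#' Axisymmetric meshes are written as an unstructured triangle grid in the
#' meridional (r, z) plane with pressure, concentration and the region tag
#' attached; radial meshes are written as a polyline over radius.  The
#' format is the legacy ASCII `.vtk` flavour readable by ParaView/VTK and
#' meshio.
#'
#' @param fit an `ip_nodule` from [run_case()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(fit, path) {
  stopifnot(inherits(fit, "ip_nodule"))
  mesh <- fit$mesh
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("ipchemo case %s", fit$scenario$label)
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  if (mesh$mode == "radial_1d") {
    n <- mesh$n_nodes
    w("POINTS %d double", n)
    writeLines(sprintf("%.9g 0 0", mesh$r), con)
    nc <- n - 1L
    w("CELLS %d %d", nc, 3L * nc)
    writeLines(sprintf("2 %d %d", 0:(nc - 1L), 1:(nc)), con)
    w("CELL_TYPES %d", nc)
    writeLines(rep("3", nc), con)     # VTK_LINE
    region <- fit$region
  } else {
    n <- mesh$n_nodes
    w("POINTS %d double", n)
    writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
    nc <- nrow(mesh$tri)
    w("CELLS %d %d", nc, 4L * nc)
    writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                       mesh$tri[, 3] - 1L), con)
    w("CELL_TYPES %d", nc)
    writeLines(rep("5", nc), con)     # VTK_TRIANGLE
    region <- fit$region
  }
  w("POINT_DATA %d", n)
  w("SCALARS pressure_Pa double 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g", fit$pressure$P), con)
  w("SCALARS concentration_mol_m3 double 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g", fit$transport$C), con)
  w("CELL_DATA %d", nc)
  w("SCALARS region int 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%d", as.integer(region == "necrotic")), con)
  invisible(path)
}

#' Export axis profiles of a solved case as CSV
#'
#' One file per axis and field with columns `distance_m`,
#' `normalized_distance`, the field value and its normalized value.
#'
#' @param fit an `ip_nodule`.
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
export_profiles <- function(fit, dir) {
  stopifnot(inherits(fit, "ip_nodule"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (axn in names(fit$mesh$axes)) {
    pp <- extract_profile(fit$pressure, axis = axn)
    fp <- file.path(dir, sprintf("%s_%s_pressure.csv",
                                 gsub("[^A-Za-z0-9]+", "_", fit$scenario$label), axn))
    utils::write.csv(data.frame(distance_m = pp$pos,
                                normalized_distance = pp$npos,
                                P_Pa = pp$values,
                                normalized_P = pp$values / max(pp$values)),
                     fp, row.names = FALSE)
    cp <- extract_profile(fit$transport, axis = axn)
    fc <- file.path(dir, sprintf("%s_%s_concentration.csv",
                                 gsub("[^A-Za-z0-9]+", "_", fit$scenario$label), axn))
    utils::write.csv(data.frame(distance_m = cp$pos,
                                normalized_distance = cp$npos,
                                C_mol_per_m3 = cp$values,
                                normalized_C = cp$values / fit$transport$C0),
                     fc, row.names = FALSE)
    files <- c(files, fp, fc)
  }
  invisible(files)
}

#' Write the metric table of a study to CSV
#'
#' @param study an `ip_study`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(study, path) {
  stopifnot(inherits(study, "ip_study"))
  utils::write.csv(study$metrics, path, row.names = FALSE)
  invisible(path)
}
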