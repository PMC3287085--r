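## File formats: binary STL export of the lumen surface (the 2-D domain
## extruded to a 1 mm slab so standard mesh tools can open it), legacy
## ASCII VTK unstructured output of flow fields, CSV profile/log output,
## and JSON serialization of the study summary.

#' Export the lumen surface as binary STL
#'
#' Extrudes the triangulated 2-D lumen to a slab of \code{thickness} mm:
#' top and bottom caps reuse the domain triangulation and the side wall is
#' built from the boundary edges, so every edge is shared by exactly two
#' facets (watertight).
#'
#' @param x A \code{vessel_mesh}, or a \code{lumen_outline} (meshed at
#'   \code{h} first).
#' @param path Output file.
#' @param thickness Extrusion thickness, mm.
#' @param h Mesh size used when \code{x} is an outline.
#' @return \code{path}, invisibly.
#' @export
export_stl <- function(x, path, thickness = 1, h = 0.3) {
  if (inherits(x, "lumen_outline")) x <- generate_mesh(x, h = h)
  stopifnot(inherits(x, "vessel_mesh"))
  X <- x$nodes; tri <- x$tri; ed <- x$edges
  nt <- nrow(tri); nb <- nrow(ed)
  nfac <- 2L * nt + 2L * nb
  v1 <- matrix(0, nfac, 3); v2 <- v1; v3 <- v1
  k <- seq_len(nt)
  # bottom cap (z = 0, outward normal -z: reverse orientation)
  v1[k, ] <- cbind(X[tri[, 1], ], 0)
  v2[k, ] <- cbind(X[tri[, 3], ], 0)
  v3[k, ] <- cbind(X[tri[, 2], ], 0)
  # top cap (z = thickness, outward +z)
  v1[nt + k, ] <- cbind(X[tri[, 1], ], thickness)
  v2[nt + k, ] <- cbind(X[tri[, 2], ], thickness)
  v3[nt + k, ] <- cbind(X[tri[, 3], ], thickness)
  # sides: boundary edges (interior on the left) -> outward-facing quads
  j <- seq_len(nb)
  a <- X[ed$n1, , drop = FALSE]; b <- X[ed$n2, , drop = FALSE]
  v1[2 * nt + j, ] <- cbind(a, 0)
  v2[2 * nt + j, ] <- cbind(b, thickness)
  v3[2 * nt + j, ] <- cbind(b, 0)
  v1[2 * nt + nb + j, ] <- cbind(a, 0)
  v2[2 * nt + nb + j, ] <- cbind(a, thickness)
  v3[2 * nt + nb + j, ] <- cbind(b, thickness)
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nl <- sqrt(rowSums(nrm^2)); nrm <- nrm / pmax(nl, 1e-300)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(utf8ToInt("coroflow lumen surface"),
                    rep(0L, 80 - nchar("coroflow lumen surface")))), con)
  writeBin(as.integer(nfac), con, size = 4, endian = "little")
  dat <- t(cbind(nrm, v1, v2, v3))  # 12 floats per facet, column-per-facet
  for (i in seq_len(nfac)) {
    writeBin(dat[, i], con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' Minimal reader for round-trip checks of [export_stl()].
#'
#' @param path STL file.
#' @return List with \code{normals} and \code{vertices} (nfac x 3 and
#'   3*nfac x 3 matrices).
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nfac <- readBin(con, "integer", 1, size = 4, endian = "little")
  nrm <- matrix(0, nfac, 3)
  vts <- matrix(0, 3 * nfac, 3)
  for (i in seq_len(nfac)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "integer", 1, size = 2, endian = "little")
    nrm[i, ] <- vals[1:3]
    vts[3 * i - 2, ] <- vals[4:6]
    vts[3 * i - 1, ] <- vals[7:9]
    vts[3 * i, ] <- vals[10:12]
  }
  list(normals = nrm, vertices = vts)
}

#' Write a flow state as legacy ASCII VTK
#'
#' Unstructured-grid VTK with the 2-D triangulation (z = 0), nodal velocity
#' vector (m/s), pressure (Pa), PSG (Pa/m) and per-node apparent viscosity.
#'
#' @param state A stored state (from \code{flow_history$states}) or
#'   \code{flow_state}.
#' @param mesh The \code{vessel_mesh}.
#' @param path Output .vtk file.
#' @return \code{path}, invisibly.
#' @export
export_vtk <- function(state, mesh, path) {
  X <- mesh$nodes; tri <- mesh$tri
  n <- nrow(X); nt <- nrow(tri)
  psg <- pressure_gradient_magnitude(state, mesh)$nodal
  mu_n <- if (!is.null(state$mu_e)) .recover_nodal(mesh, state$mu_e) else rep(NA_real_, n)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl(sprintf("coroflow flow state t = %g s", state$time))
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d float", n))
  writeLines(sprintf("%.9g %.9g 0", X[, 1], X[, 2]), con)
  wl(sprintf("CELLS %d %d", nt, 4 * nt))
  writeLines(sprintf("3 %d %d %d", tri[, 1] - 1, tri[, 2] - 1, tri[, 3] - 1), con)
  wl(sprintf("CELL_TYPES %d", nt))
  writeLines(rep("5", nt), con)
  wl(sprintf("POINT_DATA %d", n))
  wl("VECTORS velocity float")
  writeLines(sprintf("%.9g %.9g 0", state$u[, 1], state$u[, 2]), con)
  wl("SCALARS pressure float 1")
  wl("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g", state$p), con)
  wl("SCALARS psg float 1")
  wl("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g", psg), con)
  wl("SCALARS viscosity float 1")
  wl("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g", mu_n), con)
  invisible(path)
}

#' Serialize a summary report to JSON
#'
#' @param report A \code{summary_report}.
#' @param path Output JSON file.
#' @return \code{path}, invisibly.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a summary report back from JSON
#'
#' @param path JSON file written by [report_to_json()].
#' @return A \code{summary_report}.
#' @export
report_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (nm in c("velocity", "psg", "wss", "recirculation",
               "recirculation_cycle", "flow_split", "amplification",
               "comparisons"))
    x[[nm]] <- as.data.frame(x[[nm]])
  x$times <- as.numeric(x$times)
  structure(x, class = "summary_report")
}

#' Write the summary report tables as CSV files
#'
#' One CSV per table (velocity, psg, wss, recirculation, flow_split,
#' amplification, comparisons) in \code{dir}.
#'
#' @param report A \code{summary_report}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("velocity", "psg", "wss", "recirculation",
               "recirculation_cycle", "flow_split", "amplification",
               "comparisons")) {
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Write a section profile as CSV
#'
#' @param profile A \code{section_profile}.
#' @param path Output CSV.
#' @return \code{path}, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- as.data.frame(profile)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
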