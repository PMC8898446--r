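# Indexed triangle mesh assembly, watertightness validation, and writers for
# the standard mesh interchange formats (binary STL, ascii PLY, ascii OBJ).

vertex_key <- function(xyz) {
  paste(sprintf("%.17g", xyz[1L]), sprintf("%.17g", xyz[2L]),
        sprintf("%.17g", xyz[3L]), sep = "|")
}

#' Assemble tilings and caps into one indexed surface mesh
#'
#' Merges the per-pair tiling bands and the boundary caps into a single
#' vertex/face mesh. Vertices are deduplicated by exact coordinate equality:
#' contour points are shared between adjacent bands by construction (never
#' recomputed), so bitwise matching welds them without epsilon pitfalls.
#' Each face keeps a provenance tag.
#'
#' @param stack the source `contour_stack` (carried for provenance).
#' @param tilings list of `tiling_path` objects, one or more per consecutive
#'   slice pair.
#' @param caps list of `cap_triangulation` objects (possibly empty when the
#'   mesh is left unsealed).
#' @return object of class `surface_mesh`: `vertices` (V x 3 matrix), `faces`
#'   (F x 3 matrix of 1-based vertex indices, outward winding), `provenance`
#'   (character, per face).
#' @export
assemble_mesh <- function(stack, tilings, caps = list()) {
  if (length(tilings) == 0L) stop("no tilings to assemble")
  env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list()
  nv <- 0L
  get_idx <- function(xyz) {
    key <- vertex_key(xyz)
    hit <- env[[key]]
    if (!is.null(hit)) return(hit)
    nv <<- nv + 1L
    verts[[nv]] <<- xyz
    env[[key]] <- nv
    nv
  }
  faces <- list()
  prov <- character(0)
  fi <- 0L
  add_face <- function(a, b, c, tag) {
    ia <- get_idx(a); ib <- get_idx(b); ic <- get_idx(c)
    if (ia == ib || ib == ic || ia == ic) {
      stop("degenerate face: repeated vertex after welding")
    }
    fi <<- fi + 1L
    faces[[fi]] <<- c(ia, ib, ic)
    prov[fi] <<- tag
  }
  for (ti in seq_along(tilings)) {
    tp <- tilings[[ti]]
    tag <- attr(tp, "pair_tag")
    if (is.null(tag)) tag <- sprintf("tiling:%d", ti)
    for (tile in tp$tiles) {
      v <- tile$vertices
      add_face(v[1L, ], v[2L, ], v[3L, ], tag)
    }
  }
  for (ci in seq_along(caps)) {
    cap <- caps[[ci]]
    p3 <- contour_points3d(cap$contour)
    tag <- sprintf("cap:%s:%d", cap$orientation, ci)
    for (r in seq_len(nrow(cap$triangles))) {
      t <- cap$triangles[r, ]
      add_face(p3[t[1L], ], p3[t[2L], ], p3[t[3L], ], tag)
    }
  }
  structure(
    list(vertices = do.call(rbind, verts),
         faces = do.call(rbind, faces),
         provenance = prov),
    class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Watertightness and orientation report for a surface mesh
#'
#' Counts boundary edges (exactly one incident face), non-manifold edges
#' (more than two), the Euler characteristic V - E + F, and checks
#' orientation consistency (every two-face edge must be traversed in
#' opposite directions by its faces). A closed, consistently oriented
#' genus-0 surface has 0 boundary edges, 0 non-manifold edges and Euler
#' characteristic 2.
#'
#' @param mesh a `surface_mesh`.
#' @return object of class `watertight_report` with fields `n_vertices`,
#'   `n_edges`, `n_faces`, `boundary_edges`, `nonmanifold_edges`, `euler`,
#'   `orientation_consistent`, `watertight`.
#' @export
watertight_report <- function(mesh) {
  f <- mesh$faces
  a <- c(f[, 1L], f[, 2L], f[, 3L])
  b <- c(f[, 2L], f[, 3L], f[, 1L])
  undirected <- paste(pmin(a, b), pmax(a, b))
  counts <- table(undirected)
  boundary <- sum(counts == 1L)
  nonmanifold <- sum(counts > 2L)
  directed <- paste(a, b)
  dir_dup <- any(duplicated(directed))
  # consistent orientation: no directed edge repeats, and every 2-face edge
  # is covered by both directions (automatic given counts == 2 and no dups)
  consistent <- !dir_dup
  V <- length(unique(as.vector(f)))
  E <- length(counts)
  Fc <- nrow(f)
  structure(
    list(n_vertices = V, n_edges = E, n_faces = Fc,
         boundary_edges = as.integer(boundary),
         nonmanifold_edges = as.integer(nonmanifold),
         euler = V - E + Fc,
         orientation_consistent = consistent,
         watertight = boundary == 0L && nonmanifold == 0L && consistent),
    class = "watertight_report")
}

#' @export
print.watertight_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<watertight_report: V=%d E=%d F=%d | boundary=%d nonmanifold=%d ",
    "euler=%d oriented=%s watertight=%s>\n"),
    x$n_vertices, x$n_edges, x$n_faces, x$boundary_edges,
    x$nonmanifold_edges, x$euler, x$orientation_consistent, x$watertight))
  invisible(x)
}

#' Signed volume of a closed surface mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes
#' `dot(v1, cross(v2, v3)) / 6` over faces; positive for outward-oriented
#' closed meshes. Only meaningful when the mesh is watertight.
#'
#' @param mesh a `surface_mesh`.
#' @return signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  cx <- p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]
  cy <- p2[, 3L] * p3[, 1L] - p2[, 1L] * p3[, 3L]
  cz <- p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L]
  sum(p1[, 1L] * cx + p1[, 2L] * cy + p1[, 3L] * cz) / 6
}

#' Write a surface mesh to STL, PLY or OBJ
#'
#' PLY and OBJ are written as ascii and preserve the shared-vertex indexing;
#' STL is binary little-endian and, as the format requires, duplicates the
#' vertex coordinates per facet. OBJ indices are written 1-based, PLY
#' 0-based, per each format's convention.
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @param format `"stl"`, `"ply"` or `"obj"`; default guessed from the file
#'   extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  switch(format,
    stl = write_stl_binary(mesh, path),
    ply = write_ply_ascii(mesh, path),
    obj = write_obj_ascii(mesh, path),
    stop(sprintf("unknown mesh format \"%s\" (use stl, ply or obj)", format))
  )
  invisible(path)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("slicemesh binary STL", width = -80))
  length(header) <- 80L
  header[is.na(header)] <- as.raw(0L)
  writeBin(header, con)
  f <- mesh$faces
  writeBin(nrow(f), con, size = 4L, endian = "little")
  v <- mesh$vertices
  for (r in seq_len(nrow(f))) {
    p1 <- v[f[r, 1L], ]; p2 <- v[f[r, 2L], ]; p3 <- v[f[r, 3L], ]
    nvec <- c((p2[2L] - p1[2L]) * (p3[3L] - p1[3L]) - (p2[3L] - p1[3L]) * (p3[2L] - p1[2L]),
              (p2[3L] - p1[3L]) * (p3[1L] - p1[1L]) - (p2[1L] - p1[1L]) * (p3[3L] - p1[3L]),
              (p2[1L] - p1[1L]) * (p3[2L] - p1[2L]) - (p2[2L] - p1[2L]) * (p3[1L] - p1[1L]))
    nl <- sqrt(sum(nvec ^ 2))
    if (nl > 0) nvec <- nvec / nl
    writeBin(as.numeric(c(nvec, p1, p2, p3)), con, size = 4L, endian = "little")
    writeBin(0L, con, size = 2L, endian = "little")
  }
}

write_ply_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           "comment slicemesh surface",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  vl <- apply(v, 1L, function(p) paste(fmt_num(p), collapse = " "))
  fl <- apply(f, 1L, function(t) paste(c(3L, t - 1L), collapse = " "))
  writeLines(c(hdr, vl, fl), path)
}

write_obj_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  vl <- apply(v, 1L, function(p) paste("v", paste(fmt_num(p), collapse = " ")))
  fl <- apply(f, 1L, function(t) paste("f", paste(t, collapse = " ")))
  writeLines(c("# slicemesh surface", vl, fl), path)
}

#' Read an ascii PLY file written by [write_mesh()]
#'
#' Minimal reader for round-trip checks: ascii format, xyz vertex properties
#' and triangular faces.
#'
#' @param path path to an ascii PLY file.
#' @return a `surface_mesh` (provenance tags are not stored in PLY and come
#'   back empty).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "ply") stop("not a PLY file")
  end <- match("end_header", lines)
  if (is.na(end)) stop("PLY header not terminated")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1L]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)[1L]))
  vlines <- lines[(end + 1L):(end + nv)]
  flines <- lines[(end + nv + 1L):(end + nv + nf)]
  verts <- do.call(rbind, lapply(strsplit(vlines, " "), as.numeric))
  faces <- do.call(rbind, lapply(strsplit(flines, " "), function(x) {
    x <- as.integer(x)
    if (x[1L] != 3L) stop("only triangular faces are supported")
    x[2:4] + 1L
  }))
  structure(list(vertices = verts, faces = faces,
                 provenance = rep("", nrow(faces))),
            class = "surface_mesh")
}
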