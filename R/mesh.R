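#' Triangle mesh of a cortical hemisphere
#'
#' A `surf_mesh` is a closed (boundary-less) 2-manifold triangle mesh: the
#' discrete representation of one hemisphere's white surface, or of the unit
#' sphere for simulation work. Vertex indices are 0-based throughout the
#' package; the constructor checks face validity, and [validate_mesh()]
#' checks the closed-manifold invariants.
#'
#' @param vertices numeric M x 3 matrix of vertex coordinates.
#' @param faces integer T x 3 matrix of 0-based vertex indices with
#'   consistent counter-clockwise orientation.
#' @return An object of class `surf_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surf_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(faces) < 0L || max(faces) >= nrow(vertices))
    stop("face indices out of range (0-based indexing expected)")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3]))
    stop("degenerate face: repeated vertex index")
  structure(list(vertices = vertices, faces = faces), class = "surf_mesh")
}

#' @export
print.surf_mesh <- function(x, ...) {
  cat(sprintf("surf_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Check closed-manifold invariants of a mesh
#'
#' Verifies that every undirected edge is shared by exactly two faces, that
#' there are no duplicate faces, and (when `check_euler = TRUE`) that the
#' Euler characteristic V - E + T equals 2, as required for a sphere-topology
#' hemisphere surface.
#'
#' @param mesh a [surf_mesh()].
#' @param check_euler also require Euler characteristic 2 (default `TRUE`).
#' @return Invisibly `TRUE`; stops with a message on the first violated
#'   invariant.
#' @export
validate_mesh <- function(mesh, check_euler = TRUE) {
  f <- mesh$faces
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e <- c(key(f[, 1], f[, 2]), key(f[, 2], f[, 3]), key(f[, 3], f[, 1]))
  cnt <- table(e)
  if (any(cnt != 2L))
    stop("mesh is not a closed manifold: an edge is not shared by exactly 2 faces")
  fkey <- apply(f, 1, function(r) paste(sort(r), collapse = " "))
  if (anyDuplicated(fkey)) stop("duplicate faces present")
  if (check_euler) {
    V <- n_vertices(mesh); E <- length(cnt); T_ <- nrow(f)
    if (V - E + T_ != 2L)
      stop(sprintf("Euler characteristic V-E+T = %d, expected 2", V - E + T_))
  }
  invisible(TRUE)
}

# Vertices and faces of the regular icosahedron centered at the origin,
# scaled to the unit sphere. Ordering is fixed so that refined meshes nest.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  list(vertices = v, faces = f)
}

#' Generate a nested icosphere mesh
#'
#' Refines the regular icosahedron by `subdivisions` uniform 1-to-4 triangle
#' subdivisions, projecting each new vertex to the sphere of the given
#' radius. Parent vertices keep their indices, so the vertex set of level k
#' is a prefix of the vertex set of level k+1 (the nesting used by
#' fsaverage-icoN template meshes: ico4 has 2562 vertices, ico6 has 40,962).
#'
#' @param subdivisions non-negative integer number of refinement levels
#'   (at most 8).
#' @param radius sphere radius (default 1).
#' @return A [surf_mesh()] with `10 * 4^subdivisions + 2` vertices.
#' @export
generate_icosphere <- function(subdivisions, radius = 1) {
  stopifnot(subdivisions >= 0, subdivisions <= 8, radius > 0)
  base <- icosahedron()
  v <- base$vertices
  f <- base$faces
  for (lev in seq_len(subdivisions)) {
    res <- subdivide_once(v, f)
    v <- res$vertices
    f <- res$faces
  }
  surf_mesh(v * radius, f)
}

# One uniform 1-to-4 subdivision: midpoints of all edges are appended after
# the existing vertices (prefix nesting) and projected to the unit sphere.
subdivide_once <- function(v, f) {
  nv <- nrow(v)
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  ea <- cbind(pmin(i1, i2), pmax(i1, i2))
  eb <- cbind(pmin(i2, i3), pmax(i2, i3))
  ec <- cbind(pmin(i3, i1), pmax(i3, i1))
  alledges <- rbind(ea, eb, ec)
  ukey <- alledges[, 1] * nv + alledges[, 2]
  uu <- !duplicated(ukey)
  edges <- alledges[uu, , drop = FALSE]
  # stable order: by first occurrence in face traversal, matching common
  # nested-subdivision implementations
  mid_index <- match(ukey, ukey[uu]) - 1L + nv
  mids <- (v[edges[, 1] + 1L, , drop = FALSE] +
           v[edges[, 2] + 1L, , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  nf <- nrow(f)
  ma <- mid_index[seq_len(nf)]
  mb <- mid_index[nf + seq_len(nf)]
  mc <- mid_index[2L * nf + seq_len(nf)]
  newf <- rbind(
    cbind(i1, ma, mc),
    cbind(i2, mb, ma),
    cbind(i3, mc, mb),
    cbind(ma, mb, mc))
  list(vertices = rbind(v, mids), faces = newf)
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces + 1L
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Lumped vertex areas (barycentric mass weights)
#'
#' The lumped mass of vertex i is one third of the total area of its
#' incident faces; the masses sum exactly to the mesh surface area. These
#' weights discretize integration over the surface and enter every kernel
#' normalization and quadrature in the package.
#'
#' @param mesh a [surf_mesh()].
#' @return Numeric vector of length M with positive entries.
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh)
  if (any(fa <= 0)) stop("degenerate (zero-area) face")
  f1 <- mesh$faces + 1L
  m <- numeric(n_vertices(mesh))
  for (k in 1:3) {
    acc <- rowsum(fa, f1[, k])
    idx <- as.integer(rownames(acc))
    m[idx] <- m[idx] + acc[, 1]
  }
  m / 3
}

#' Snap points to their nearest mesh vertices
#'
#' Maps each point to the Euclidean-nearest mesh vertex (the endpoint
#' snapping step of the fast connectivity smoother). Exact ties are broken
#' by the lowest vertex index.
#'
#' @param points n x 3 numeric matrix of coordinates.
#' @param mesh a [surf_mesh()].
#' @return Integer vector of 0-based vertex indices, length n.
#' @export
snap_to_vertices <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) == 0L) return(integer(0))
  if (any(!is.finite(points))) stop("non-finite point coordinates")
  v <- mesh$vertices
  idx <- integer(nrow(points))
  # direct coordinate differences keep exact ties exact (e.g. edge midpoints)
  for (i in seq_len(nrow(points))) {
    d <- (v[, 1] - points[i, 1])^2 + (v[, 2] - points[i, 2])^2 +
         (v[, 3] - points[i, 3])^2
    idx[i] <- which.min(d) - 1L  # which.min takes the first (lowest) index on ties
  }
  idx
}

#' Vertex correspondence between nested meshes
#'
#' For meshes produced by [generate_icosphere()] from the same base, the
#' coarse vertex set is a prefix of the fine one; this function verifies the
#' prefix property by coordinate agreement and returns the mapping. It is
#' the mapping used to carry eigenvectors computed on a fine mesh down to a
#' coarse analysis mesh.
#'
#' @param coarse,fine [surf_mesh()] objects from the nesting subdivision
#'   scheme.
#' @param tol maximum allowed coordinate discrepancy (default 1e-8).
#' @return Integer vector `coarse_to_fine` of 0-based fine-mesh indices,
#'   length equal to the coarse vertex count.
#' @export
nested_correspondence <- function(coarse, fine, tol = 1e-8) {
  nc <- n_vertices(coarse)
  if (nc > n_vertices(fine)) stop("coarse mesh has more vertices than fine mesh")
  d <- abs(coarse$vertices - fine$vertices[seq_len(nc), , drop = FALSE])
  if (max(d) > tol)
    stop("meshes are not nested: coordinate mismatch beyond tolerance")
  seq_len(nc) - 1L
}

#' Read or write a mesh in OFF or ASCII PLY format
#'
#' Minimal readers/writers for the two plain-text mesh formats used for
#' fixtures and command-line interchange. Faces are stored 0-based in both
#' formats, matching the package convention.
#'
#' @param path file path; format chosen by extension (`.off` or `.ply`).
#' @return `read_mesh` returns a [surf_mesh()]; `write_mesh` invisibly
#'   returns `path`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    off = read_off(path),
    ply = read_ply(path),
    stop("unsupported mesh format: ", ext))
}

#' @rdname read_mesh
#' @param mesh a [surf_mesh()].
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    off = write_off(mesh, path),
    ply = write_ply(mesh, path),
    stop("unsupported mesh format: ", ext))
  invisible(path)
}

read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop("not an OFF file")
  hdr <- scan(text = lines[2], what = integer(), quiet = TRUE)
  nv <- hdr[1]; nf <- hdr[2]
  vals <- scan(text = lines[3:(2 + nv)], what = numeric(), quiet = TRUE)
  v <- matrix(vals, ncol = 3, byrow = TRUE)
  fvals <- scan(text = lines[(3 + nv):(2 + nv + nf)], what = integer(), quiet = TRUE)
  f <- matrix(fvals, ncol = 4, byrow = TRUE)
  if (any(f[, 1] != 3L)) stop("only triangle faces are supported")
  surf_mesh(v, f[, 2:4, drop = FALSE])
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", n_vertices(mesh), nrow(mesh$faces)), con)
  writeLines(apply(format(mesh$vertices, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "ply") stop("not a PLY file")
  endh <- which(trimws(lines) == "end_header")[1]
  hdr <- lines[seq_len(endh)]
  if (!any(grepl("^format ascii", trimws(hdr))))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex +", "", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face +", "", grep("element face", hdr, value = TRUE)[1]))
  vlines <- lines[(endh + 1):(endh + nv)]
  v <- matrix(scan(text = vlines, what = numeric(), quiet = TRUE), ncol = 3, byrow = TRUE)
  flines <- lines[(endh + nv + 1):(endh + nv + nf)]
  f <- matrix(scan(text = flines, what = integer(), quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(f[, 1] != 3L)) stop("only triangle faces are supported")
  surf_mesh(v, f[, 2:4, drop = FALSE])
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n_vertices(mesh)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(format(mesh$vertices, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

#' Read or write a vertex exclusion mask
#'
#' Masks (e.g. the medial wall) are stored as one flag per line, `1` for
#' excluded vertices and `0` otherwise.
#'
#' @param path file path.
#' @param n_expected optional expected length, checked if given.
#' @return Logical vector, `TRUE` = excluded.
#' @export
read_mask <- function(path, n_expected = NULL) {
  flags <- scan(path, what = integer(), quiet = TRUE)
  if (!is.null(n_expected) && length(flags) != n_expected)
    stop("mask length does not match vertex count")
  flags != 0L
}

#' @rdname read_mask
#' @param mask logical vector.
#' @export
write_mask <- function(mask, path) {
  writeLines(as.character(as.integer(mask)), path)
  invisible(path)
}
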