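#' Streamline endpoint sets
#'
#' An `endpoint_set` holds N streamline endpoint pairs, either as 0-based
#' global vertex indices (columns `v1`, `v2`) after snapping, or as raw xyz
#' coordinate pairs awaiting snapping. [endpoints_from_coords()] snaps
#' coordinates once at ingestion (retaining the raw coordinates) so that
#' the fast matrix smoother, which requires vertex-indexed endpoints, can
#' be applied.
#'
#' @param v1,v2 integer vectors of 0-based vertex indices, equal length.
#' @return An object of class `endpoint_set` with fields `v1`, `v2`, `n`.
#' @export
endpoint_set <- function(v1, v2) {
  v1 <- as.integer(v1); v2 <- as.integer(v2)
  stopifnot(length(v1) == length(v2), length(v1) >= 1)
  if (any(v1 < 0L) || any(v2 < 0L)) stop("negative vertex index")
  structure(list(v1 = v1, v2 = v2, n = length(v1)), class = "endpoint_set")
}

#' @export
print.endpoint_set <- function(x, ...) {
  cat(sprintf("endpoint_set: %d streamline endpoint pairs\n", x$n))
  invisible(x)
}

#' @rdname endpoint_set
#' @param xyz1,xyz2 n x 3 coordinate matrices of the two endpoints of each
#'   streamline.
#' @param mesh the [surf_mesh()] (or combined-vertex mesh) to snap onto.
#' @export
endpoints_from_coords <- function(xyz1, xyz2, mesh) {
  ep <- endpoint_set(snap_to_vertices(xyz1, mesh), snap_to_vertices(xyz2, mesh))
  ep$raw <- list(xyz1 = xyz1, xyz2 = xyz2)
  ep
}

#' Read or write endpoint pairs as TSV
#'
#' The tabular endpoint format has a header and either columns
#' `x1 y1 z1 x2 y2 z2` (coordinates, snapped on read when a mesh is given)
#' or `v1 v2` (0-based global vertex indices).
#'
#' @param path file path.
#' @param mesh required when the file stores coordinates.
#' @return An `endpoint_set`.
#' @export
read_endpoints <- function(path, mesh = NULL) {
  df <- utils::read.delim(path, sep = "\t")
  if (all(c("v1", "v2") %in% names(df))) {
    endpoint_set(df$v1, df$v2)
  } else if (all(c("x1", "y1", "z1", "x2", "y2", "z2") %in% names(df))) {
    if (is.null(mesh)) stop("coordinate endpoints require a mesh to snap onto")
    endpoints_from_coords(as.matrix(df[, c("x1", "y1", "z1")]),
                          as.matrix(df[, c("x2", "y2", "z2")]), mesh)
  } else stop("unrecognized endpoint file columns")
}

#' @rdname read_endpoints
#' @param endpoints an `endpoint_set`.
#' @export
write_endpoints <- function(endpoints, path) {
  utils::write.table(data.frame(v1 = endpoints$v1, v2 = endpoints$v2),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Streamline-count adjacency matrix
#'
#' Builds the symmetric vertex-by-vertex adjacency A = U V' + V U' from the
#' half-incidence matrices U, V that place each streamline's two endpoints:
#' A(i, j) counts streamlines between vertices i and j, and a streamline
#' with both endpoints at vertex i contributes 2 to A(i, i). The total sum
#' of A is 2N. This raw count matrix is the unsmoothed high-resolution
#' connectome, and the input to [smooth_fast()].
#'
#' @param endpoints an `endpoint_set` with vertex-indexed pairs.
#' @param n_vertices total vertex count M of the (combined) mesh.
#' @return Sparse symmetric M x M matrix (`dgCMatrix`) of counts.
#' @export
build_adjacency <- function(endpoints, n_vertices) {
  if (max(endpoints$v1, endpoints$v2) >= n_vertices)
    stop("vertex index out of range")
  i <- c(endpoints$v1, endpoints$v2) + 1L
  j <- c(endpoints$v2, endpoints$v1) + 1L
  Matrix::sparseMatrix(i = i, j = j, x = rep(1, 2L * endpoints$n),
                       dims = c(n_vertices, n_vertices))
}

#' Fast continuous-connectivity estimator
#'
#' Computes the kernel-smoothed connectivity matrix P = (1/2N) K A K',
#' which is algebraically identical to evaluating the symmetrized
#' endpoint-pair kernel density estimator at all vertex pairs (see
#' [smooth_exact()]) but costs three M x M matrix products instead of
#' O(M^2 N) kernel evaluations.
#'
#' @param kernel a `kernel_matrix` on the (combined) vertex set.
#' @param adjacency sparse streamline-count matrix from [build_adjacency()].
#' @param n_streamlines N, the number of streamlines behind `adjacency`.
#' @return An object of class `connectivity_matrix`: list with dense
#'   `values`, the kernel `spec`, `n_streamlines`, and `masked` flag.
#' @export
smooth_fast <- function(kernel, adjacency, n_streamlines) {
  if (n_streamlines < 1) stop("n_streamlines must be positive")
  K <- kernel$values
  if (nrow(K) != nrow(adjacency)) stop("kernel and adjacency are not conformable")
  P <- as.matrix(K %*% adjacency %*% K) / (2 * n_streamlines)
  P <- (P + t(P)) / 2
  structure(list(values = P, spec = kernel$spec,
                 n_streamlines = as.integer(n_streamlines), masked = FALSE),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d x %d from %d streamlines (%s)%s\n",
              nrow(x$values), ncol(x$values), x$n_streamlines,
              if (is.null(x$spec)) "unsmoothed" else x$spec$family,
              if (x$masked) ", masked" else ""))
  invisible(x)
}

#' Exact (reference) continuous-connectivity estimator
#'
#' Evaluates the symmetrized kernel density estimator
#' p(x, y) = (1/2N) sum_j [k(x, s1_j) k(y, s2_j) + k(x, s2_j) k(y, s1_j)]
#' on the vertex grid by an explicit loop over streamlines. This is the
#' O(M^2 N) reference oracle against which [smooth_fast()] is verified; the
#' two agree to machine precision on snapped endpoints.
#'
#' @param kernel a `kernel_matrix`.
#' @param endpoints vertex-indexed `endpoint_set`.
#' @return A `connectivity_matrix`.
#' @export
smooth_exact <- function(kernel, endpoints) {
  K <- kernel$values
  M <- nrow(K)
  if (max(endpoints$v1, endpoints$v2) >= M) stop("vertex index out of range")
  P <- matrix(0, M, M)
  for (j in seq_len(endpoints$n)) {
    ka <- K[, endpoints$v1[j] + 1L]
    kb <- K[, endpoints$v2[j] + 1L]
    P <- P + tcrossprod(ka, kb) + tcrossprod(kb, ka)
  }
  P <- P / (2 * endpoints$n)
  structure(list(values = P, spec = kernel$spec,
                 n_streamlines = endpoints$n, masked = FALSE),
            class = "connectivity_matrix")
}

#' Apply a medial-wall mask to a connectivity matrix
#'
#' Zeroes the rows and columns of excluded vertices, after estimation and
#' without renormalization (the pre-mask unit-mass property is the
#' normalization invariant). Idempotent.
#'
#' @param P a `connectivity_matrix`.
#' @param mask logical vector, `TRUE` = excluded; length must match.
#' @return The masked `connectivity_matrix`.
#' @export
apply_medial_mask <- function(P, mask) {
  if (length(mask) != nrow(P$values))
    stop("mask length does not match matrix size")
  P$values[mask, ] <- 0
  P$values[, mask] <- 0
  P$masked <- TRUE
  P
}

#' Mass-weighted total of a connectivity matrix
#'
#' The discrete double integral sum_ij P(i,j) m_i m_j; equals 1 for
#' unit-mass kernels before masking.
#'
#' @param P a `connectivity_matrix` (or plain matrix).
#' @param mass lumped vertex areas.
#' @return A single number.
#' @export
connectivity_mass <- function(P, mass) {
  V <- if (inherits(P, "connectivity_matrix")) P$values else P
  drop(crossprod(mass, V %*% mass))
}

#' Randomly downsample streamlines
#'
#' Simple random sample without replacement of `floor(rate * N)`
#' streamlines, reproducible under `seed`; used to study how many
#' streamlines stable connectivity estimates require.
#'
#' @param endpoints an `endpoint_set`.
#' @param rate retention fraction in (0, 1].
#' @param seed integer RNG seed.
#' @return An `endpoint_set` with `floor(rate * N)` pairs.
#' @export
downsample_streamlines <- function(endpoints, rate, seed) {
  if (rate <= 0 || rate > 1) stop("rate must be in (0, 1]")
  keep <- floor(rate * endpoints$n)
  if (keep < 1) stop("downsampling would leave no streamlines")
  idx <- with_seed(seed, sample.int(endpoints$n, keep))
  endpoint_set(endpoints$v1[idx], endpoints$v2[idx])
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
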