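#' Locally supported orthonormal patch basis
#'
#' Default reduced-rank basis for local inference: the mesh vertices are
#' partitioned into `K_b` contiguous patches by seeded farthest-point
#' sampling of patch seeds followed by nearest-seed assignment (chordal
#' distance), and basis function xi_k is the indicator of patch k
#' normalized to unit mass-norm. Disjoint supports make the basis exactly
#' mass-orthonormal. An externally estimated basis with the same structure
#' (`local_basis()`) can be used instead.
#'
#' @param mesh a [surf_mesh()].
#' @param mass lumped vertex areas of `mesh`.
#' @param K_b number of basis functions (patches), between 1 and M.
#' @param seed integer seed for the initial patch seed vertex.
#' @return An object of class `local_basis`: `functions` (M x K_b),
#'   `supports` (list of 0-based vertex index vectors), `mass`.
#' @export
build_patch_basis <- function(mesh, mass, K_b, seed) {
  M <- n_vertices(mesh)
  stopifnot(K_b >= 1, K_b <= M)
  v <- mesh$vertices
  seeds <- integer(K_b)
  seeds[1] <- with_seed(seed, sample.int(M, 1)) - 1L
  if (K_b > 1) {
    d2min <- rowSums((v - matrix(v[seeds[1] + 1L, ], M, 3, byrow = TRUE))^2)
    for (k in 2:K_b) {
      seeds[k] <- which.max(d2min) - 1L
      d2 <- rowSums((v - matrix(v[seeds[k] + 1L, ], M, 3, byrow = TRUE))^2)
      d2min <- pmin(d2min, d2)
    }
  }
  # assign each vertex to its nearest seed (ties to the lowest patch index)
  D <- matrix(0, M, K_b)
  for (k in seq_len(K_b))
    D[, k] <- rowSums((v - matrix(v[seeds[k] + 1L, ], M, 3, byrow = TRUE))^2)
  patch <- max.col(-D, ties.method = "first")
  if (length(unique(patch)) < K_b) stop("empty patch; try another seed")
  supports <- lapply(seq_len(K_b), function(k) which(patch == k) - 1L)
  local_basis_from_supports(supports, mass)
}

local_basis_from_supports <- function(supports, mass) {
  M <- length(mass)
  Xi <- matrix(0, M, length(supports))
  for (k in seq_along(supports)) {
    idx <- supports[[k]] + 1L
    Xi[idx, k] <- 1 / sqrt(sum(mass[idx]))
  }
  local_basis(Xi, supports, mass)
}

#' @rdname build_patch_basis
#' @param functions M x K_b matrix of basis functions at vertices,
#'   mass-orthonormal.
#' @param supports list of 0-based vertex index vectors, one per column.
#' @export
local_basis <- function(functions, supports, mass) {
  G <- crossprod(functions, functions * mass)
  if (max(abs(G - diag(ncol(functions)))) > 1e-8)
    stop("basis functions are not mass-orthonormal")
  structure(list(functions = functions, supports = supports, mass = mass),
            class = "local_basis")
}

#' @export
print.local_basis <- function(x, ...) {
  cat(sprintf("local_basis: %d functions on %d vertices\n",
              ncol(x$functions), length(x$mass)))
  invisible(x)
}

#' Reduced-rank coefficients of a connectivity matrix
#'
#' Projects a connectivity matrix onto the rank-one tensors xi_k (x) xi_k:
#' S_k = xi_k' diag(m) P diag(m) xi_k, the mass-weighted double projection.
#' These are the low-dimensional coordinates on which group tests are run;
#' they are invariant to basis sign flips.
#'
#' @param P a `connectivity_matrix` (or matrix).
#' @param basis a `local_basis`.
#' @return Numeric vector of length K_b.
#' @export
project_coefficients <- function(P, basis) {
  V <- if (inherits(P, "connectivity_matrix")) P$values else as.matrix(P)
  if (nrow(V) != length(basis$mass)) stop("matrix and basis sizes differ")
  Xm <- basis$functions * basis$mass
  colSums(Xm * (V %*% Xm))
}

#' Coefficient matrix for a list of subjects
#'
#' Stacks [project_coefficients()] over subjects into a subjects x K_b
#' matrix.
#'
#' @param matrices list of `connectivity_matrix` (or matrices).
#' @param basis a `local_basis`.
#' @return Numeric matrix, one row per subject.
#' @export
coefficient_matrix <- function(matrices, basis) {
  t(vapply(matrices, project_coefficients, numeric(ncol(basis$functions)),
           basis = basis))
}

#' Per-coefficient two-group test with multiplicity control
#'
#' Tests each reduced-rank coefficient for a group difference with Welch's
#' t-test (default) or a seeded permutation test of the mean difference,
#' then adjusts across the K_b coefficients (Benjamini-Hochberg by
#' default; Bonferroni available). Coefficients with zero variance in both
#' groups get p = 1. The significant set at level `alpha` determines the
#' combined support region on the surface via [support_region()].
#'
#' @param S1,S2 coefficient matrices (subjects x K_b) for the two groups.
#' @param method `"welch"` or `"permutation"`.
#' @param correction `"BH"` or `"bonferroni"`.
#' @param alpha significance level after adjustment (default 0.05).
#' @param n_perm permutations when `method = "permutation"`.
#' @param seed RNG seed for the permutation test.
#' @return List with `p_raw`, `p_adjusted`, `significant` (integer indices
#'   of significant coefficients), `alpha`, `method`, `correction`.
#' @export
group_test <- function(S1, S2, method = c("welch", "permutation"),
                       correction = c("BH", "bonferroni"), alpha = 0.05,
                       n_perm = 1000, seed = 1) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  S1 <- as.matrix(S1); S2 <- as.matrix(S2)
  stopifnot(ncol(S1) == ncol(S2), nrow(S1) >= 2, nrow(S2) >= 2)
  K_b <- ncol(S1)
  p_raw <- numeric(K_b)
  for (k in seq_len(K_b)) {
    a <- S1[, k]; b <- S2[, k]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      p_raw[k] <- 1
    } else if (method == "welch") {
      p_raw[k] <- stats::t.test(a, b)$p.value
    } else {
      obs <- abs(mean(a) - mean(b))
      pool <- c(a, b)
      na <- length(a)
      exceed <- with_seed(seed + k, {
        sum(vapply(seq_len(n_perm), function(r) {
          idx <- sample.int(length(pool), na)
          abs(mean(pool[idx]) - mean(pool[-idx])) >= obs
        }, logical(1)))
      })
      p_raw[k] <- (exceed + 1) / (n_perm + 1)
    }
  }
  p_adj <- stats::p.adjust(p_raw, method = if (correction == "BH") "BH" else "bonferroni")
  list(p_raw = p_raw, p_adjusted = p_adj,
       significant = which(p_adj <= alpha),
       alpha = alpha, method = method, correction = correction)
}

#' Combined support region of significant basis functions
#'
#' Union of the vertex supports of the significant coefficients, returned
#' as a vertex mask (`TRUE` = inside the detected region).
#'
#' @param basis a `local_basis`.
#' @param significant integer indices of significant coefficients (e.g.
#'   `group_test(...)$significant`).
#' @return Logical vector of length M.
#' @export
support_region <- function(basis, significant) {
  mask <- rep(FALSE, length(basis$mass))
  for (k in significant) mask[basis$supports[[k]] + 1L] <- TRUE
  mask
}
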