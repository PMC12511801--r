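#' Ground-truth bundle-mixture endpoint density
#'
#' Builds a known symmetric probability density p(x, y) on the vertex grid
#' as a mixture of fiber "bundles": component b connects surface locations
#' around center vertices (c1, c2) with spatial spread given by a diffusion
#' kernel bandwidth, contributing
#' w_b * (g_b(x|c1) g_b(y|c2) + g_b(x|c2) g_b(y|c1)) / 2
#' with g_b(.|c) the unit-mass diffusion-kernel column at c. Because the
#' bundles are built from the band-limited diffusion kernel, the truth is
#' exactly representable on the grid; it is renormalized so its
#' mass-weighted double sum is exactly 1.
#'
#' @param basis a `spectral_basis` of the mesh.
#' @param components list of components, each a list with `centers`
#'   (two 0-based vertex indices), `spread` (diffusion bandwidth kappa),
#'   and `weight` (positive).
#' @return An object of class `true_density`: list with dense `values`
#'   (M x M, symmetric, non-negative up to truncation), `mass`, and the
#'   `components`.
#' @export
make_bundle_mixture <- function(basis, components) {
  w <- vapply(components, function(cm) cm$weight, numeric(1))
  if (any(w <= 0) || sum(w) <= 0) stop("component weights must be positive")
  w <- w / sum(w)
  M <- length(basis$mass)
  P <- matrix(0, M, M)
  for (b in seq_along(components)) {
    cm <- components[[b]]
    if (any(cm$centers < 0L) || any(cm$centers >= M))
      stop("bundle center vertex out of range")
    K <- spectral_kernel(basis, kernel_spec("diffusion", cm$spread))
    g1 <- K$values[, cm$centers[1] + 1L]
    g2 <- K$values[, cm$centers[2] + 1L]
    P <- P + w[b] * (tcrossprod(g1, g2) + tcrossprod(g2, g1)) / 2
  }
  P <- pmax(P, 0)  # clip tiny truncation negatives before normalizing
  tot <- drop(crossprod(basis$mass, P %*% basis$mass))
  P <- P / tot
  P <- (P + t(P)) / 2
  structure(list(values = P, mass = basis$mass, components = components),
            class = "true_density")
}

#' @export
print.true_density <- function(x, ...) {
  cat(sprintf("true_density: %d x %d grid, %d bundle(s)\n",
              nrow(x$values), ncol(x$values), length(x$components)))
  invisible(x)
}

#' The packaged two-bundle scenario
#'
#' Default simulation scenario on the unit icosphere: two equal-weight
#' bundles with mid-grid spreads, centers spaced well apart. Used by the
#' consistency experiment and the synthetic scan-collection generator.
#'
#' @param mesh an icosphere [surf_mesh()] (default subdivision 3).
#' @param basis optional precomputed `spectral_basis` of `mesh`.
#' @return List with `mesh`, `basis`, `density` (a `true_density`), and
#'   `components`.
#' @export
two_bundle_scenario <- function(mesh = generate_icosphere(3),
                                basis = NULL) {
  if (is.null(basis)) basis <- compute_spectrum(mesh)
  v <- mesh$vertices
  # centers from the base icosahedron (present at every subdivision level):
  # bundle 1 connects vertices 0 and 3 (near-antipodal), bundle 2 connects
  # 1 and 10; spreads ~0.3 rad on the unit sphere, a mid-grid smoothness
  components <- list(
    list(centers = c(0L, 3L), spread = 0.3, weight = 0.5),
    list(centers = c(1L, 10L), spread = 0.3, weight = 0.5))
  list(mesh = mesh, basis = basis,
       density = make_bundle_mixture(basis, components),
       components = components)
}

#' Sample streamline endpoint pairs from a known density
#'
#' Draws N unordered vertex pairs i.i.d. from the discrete distribution
#' pi(i, j) proportional to p(i, j) m_i m_j over unordered pairs (matching
#' the symmetrized estimator, which is invariant to endpoint order).
#'
#' @param density a `true_density`.
#' @param N number of streamlines to draw.
#' @param seed integer RNG seed.
#' @return An `endpoint_set`.
#' @export
sample_endpoints <- function(density, N, seed) {
  stopifnot(N >= 1)
  P <- density$values
  m <- density$mass
  W <- P * outer(m, m)
  ut <- upper.tri(W, diag = TRUE)
  probs <- W[ut]
  pairs <- which(ut, arr.ind = TRUE)
  idx <- with_seed(seed,
    sample.int(length(probs), N, replace = TRUE, prob = probs))
  endpoint_set(pairs[idx, 1] - 1L, pairs[idx, 2] - 1L)
}

#' Mass-weighted L2 estimation error
#'
#' The discrete L2(Omega x Omega) distance between an estimated and the
#' true density: sqrt(sum_ij (P_est - P_true)^2 m_i m_j).
#'
#' @param P_est estimated `connectivity_matrix` (or matrix).
#' @param P_true `true_density` (or matrix).
#' @param mass lumped vertex areas.
#' @return A non-negative number.
#' @export
estimation_error <- function(P_est, P_true, mass) {
  a <- if (inherits(P_est, "connectivity_matrix")) P_est$values else as.matrix(P_est)
  b <- if (inherits(P_true, "true_density")) P_true$values else as.matrix(P_true)
  if (!all(dim(a) == dim(b))) stop("estimate and truth have different sizes")
  d2 <- (a - b)^2
  sqrt(drop(crossprod(mass, d2 %*% mass)))
}

#' Consistency experiment over sample sizes and kernels
#'
#' For each kernel and streamline count N, draws `replicates` independent
#' endpoint samples from the known density, estimates the connectivity via
#' [smooth_fast()], and records the mass-weighted L2 error against the
#' truth. A consistent estimator shows mean error decreasing in N for every
#' kernel.
#'
#' @param density a `true_density`.
#' @param kernels named list of `kernel_matrix` objects (precomputed on the
#'   same mesh/grid).
#' @param Ns increasing vector of streamline counts.
#' @param replicates replicates per (kernel, N) cell.
#' @param seed integer base seed; each replicate uses a derived seed.
#' @return Data frame with columns `kernel`, `N`, `replicate`, `error`,
#'   `seconds`; mean/sd summaries in attribute `"summary"`.
#' @export
consistency_experiment <- function(density, kernels, Ns, replicates, seed) {
  stopifnot(length(names(kernels)) == length(kernels))
  rows <- list()
  mass <- density$mass
  r <- 0L
  for (kn in names(kernels)) for (N in Ns) for (rep_i in seq_len(replicates)) {
    r <- r + 1L
    ep <- sample_endpoints(density, N, seed + 7L * r)
    t0 <- proc.time()[["elapsed"]]
    A <- build_adjacency(ep, length(mass))
    P <- smooth_fast(kernels[[kn]], A, ep$n)
    dt <- proc.time()[["elapsed"]] - t0
    rows[[r]] <- data.frame(kernel = kn, N = N, replicate = rep_i,
                            error = estimation_error(P, density, mass),
                            seconds = dt)
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(error ~ kernel + N, data = out,
                          FUN = function(e) c(mean = mean(e), sd = stats::sd(e)))
  summary_df <- data.frame(kernel = agg$kernel, N = agg$N,
                           mean_error = agg$error[, "mean"],
                           sd_error = agg$error[, "sd"])
  attr(out, "summary") <- summary_df[order(summary_df$kernel, summary_df$N), ]
  out
}

#' Synthetic multi-subject, multi-scan collection
#'
#' Generates a repeated-scan collection with controlled intra- and
#' inter-subject variation: each subject's density is the packaged mixture
#' with log-weights perturbed by N(0, subject_effect^2) and bundle centers
#' displaced by snapping a Gaussian jitter of scale
#' `subject_effect * radius/2` back to the mesh; each scan then samples an
#' independent endpoint set of size N from the subject's density and
#' smooths it with the supplied kernel. With `subject_effect = 0` all
#' subjects share one density and scans are exchangeable (dICC near 0);
#' large effects with small within-scan noise drive dICC toward 1.
#'
#' @param scenario result of [two_bundle_scenario()] (or a compatible list
#'   with `mesh`, `basis`, `components`).
#' @param kernel a `kernel_matrix` used to smooth every scan.
#' @param n_subjects,n_repeats collection dimensions.
#' @param subject_effect non-negative perturbation scale.
#' @param N streamlines per scan.
#' @param seed integer base seed.
#' @return List with `collection` (a [scan_collection()]), `densities`
#'   (per-subject `true_density`), and `truth` (per-subject perturbation
#'   record).
#' @export
make_scan_collection <- function(scenario, kernel, n_subjects, n_repeats,
                                 subject_effect, N, seed) {
  stopifnot(n_subjects >= 1, n_repeats >= 1, N >= 1, subject_effect >= 0)
  mesh <- scenario$mesh
  basis <- scenario$basis
  M <- length(basis$mass)
  radius <- sqrt(mean(rowSums(mesh$vertices^2)))
  densities <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  scans <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    comp <- with_seed(seed + 1000L * i, {
      lapply(scenario$components, function(cm) {
        cm$weight <- cm$weight * exp(stats::rnorm(1, 0, subject_effect))
        if (subject_effect > 0) {
          ctr <- mesh$vertices[cm$centers + 1L, , drop = FALSE]
          jit <- ctr + matrix(stats::rnorm(6, 0, subject_effect * radius / 2), 2, 3)
          cm$centers <- snap_to_vertices(jit, mesh)
        }
        cm
      })
    })
    densities[[i]] <- make_bundle_mixture(basis, comp)
    truth[[i]] <- comp
    scans[[i]] <- lapply(seq_len(n_repeats), function(j) {
      ep <- sample_endpoints(densities[[i]], N, seed + 1000L * i + j)
      smooth_fast(kernel, build_adjacency(ep, M), ep$n)
    })
  }
  list(collection = scan_collection(scans), densities = densities,
       truth = truth)
}
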