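#' Kernel specification
#'
#' Describes one of the three kernel families used for endpoint-density
#' smoothing:
#' \describe{
#'   \item{`diffusion`}{Riemannian diffusion (heat) kernel, spectral weights
#'     `exp(-kappa^2 * lambda / 2)`; bandwidth `kappa` in the mesh's length
#'     units.}
#'   \item{`matern`}{Riemannian Matern kernel in dimension 2, spectral
#'     weights `(2*nu/kappa^2 + lambda)^(-nu-1)`; bandwidth `kappa`,
#'     smoothness `nu > 0`.}
#'   \item{`spherical_heat`}{closed-form heat kernel on the unit sphere, a
#'     truncated Legendre series; bandwidth `sigma` (unitless).}
#' }
#' Under the default `unit_mass` normalization the spectral weights are
#' divided by their value at lambda = 0, which makes the kernel integrate to
#' exactly 1 over its hemisphere against the lumped mass weights — the
#' normalization a density-estimation kernel requires. `raw` exposes the
#' unnormalized spectral sum.
#'
#' @param family one of `"diffusion"`, `"matern"`, `"spherical_heat"`.
#' @param bandwidth kappa (diffusion/matern) or sigma (spherical_heat); > 0.
#' @param nu Matern smoothness, required when `family = "matern"`.
#' @param truncation spectral truncation M_T (`NULL` = use all available
#'   eigenpairs); for `spherical_heat` the series is truncated by `tol`.
#' @param tol series tail threshold for the spherical heat kernel
#'   (default 0.001).
#' @param normalization `"unit_mass"` (default) or `"raw"`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("diffusion", "matern", "spherical_heat"),
                        bandwidth, nu = NULL, truncation = NULL,
                        tol = 0.001, normalization = c("unit_mass", "raw")) {
  family <- match.arg(family)
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(bandwidth), length(bandwidth) == 1, bandwidth > 0)
  if (family == "matern") {
    if (is.null(nu)) stop("matern kernel requires a smoothness parameter nu")
    stopifnot(nu > 0)
  }
  structure(list(family = family, bandwidth = bandwidth, nu = nu,
                 truncation = truncation, tol = tol,
                 normalization = normalization),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("kernel_spec: %s, bandwidth %g%s, %s\n", x$family, x$bandwidth,
              if (!is.null(x$nu)) sprintf(", nu %g", x$nu) else "",
              x$normalization))
  invisible(x)
}

# spectral weight function Phi(lambda) of a diffusion/matern spec
spectral_weights <- function(spec, lambda) {
  switch(spec$family,
    diffusion = exp(-spec$bandwidth^2 * lambda / 2),
    matern = (2 * spec$nu / spec$bandwidth^2 + lambda)^(-spec$nu - 1),
    stop("not a spectral kernel family: ", spec$family))
}

#' Truncation index of the spherical heat kernel series
#'
#' The spherical heat kernel is an infinite Legendre series whose j-th
#' coefficient is (2j+1) exp(-j(j+1) sigma); since |P_j| <= 1 on [-1, 1],
#' the series is truncated at the smallest J >= 1 whose coefficient falls
#' below `tol`.
#'
#' @param sigma bandwidth, > 0.
#' @param tol coefficient threshold (default 0.001).
#' @return Integer J.
#' @export
shk_truncation <- function(sigma, tol = 0.001) {
  stopifnot(sigma > 0, tol > 0)
  J <- 1L
  while ((2 * J + 1) * exp(-J * (J + 1) * sigma) >= tol) J <- J + 1L
  J
}

#' Legendre polynomials by three-term recurrence
#'
#' Evaluates P_j(x) (degree j, order 0) on [-1, 1] via the recurrence
#' P_j = ((2j-1) x P_{j-1} - (j-1) P_{j-2}) / j, with P_0 = 1 and P_1 = x.
#'
#' @param j non-negative integer degree.
#' @param x numeric vector with |x| <= 1.
#' @return Numeric vector of P_j(x).
#' @export
legendre <- function(j, x) {
  if (any(abs(x) > 1 + 1e-12)) stop("|x| > 1")
  x <- pmin(1, pmax(-1, x))
  if (j == 0L) return(rep(1, length(x)))
  pm2 <- rep(1, length(x))
  pm1 <- x
  if (j == 1L) return(pm1)
  for (jj in 2:j) {
    p <- ((2 * jj - 1) * x * pm1 - (jj - 1) * pm2) / jj
    pm2 <- pm1
    pm1 <- p
  }
  pm1
}

#' Spherical heat kernel matrix
#'
#' Evaluates the truncated spherical-heat-kernel series
#' k_sigma(u, v) = (1/4pi) sum_{j=0}^{J} (2j+1) exp(-j(j+1) sigma) P_j(u'v)
#' at all pairs of unit vectors, with J from [shk_truncation()]. Rows are
#' processed in blocks so that only O(block x M) scratch is held at once.
#'
#' @param unit_vectors M x 3 matrix of unit-norm rows (e.g. icosphere
#'   vertices, or a spherical registration of a hemisphere).
#' @param sigma bandwidth, > 0.
#' @param tol series threshold (default 0.001).
#' @param block row-block size (default 2048).
#' @return An object of class `kernel_matrix` (dense M x M `values`, the
#'   generating `kernel_spec`, and `block_sizes`).
#' @export
shk_matrix <- function(unit_vectors, sigma, tol = 0.001, block = 2048L) {
  unit_vectors <- as.matrix(unit_vectors)
  nrm <- sqrt(rowSums(unit_vectors^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("rows must be unit vectors")
  M <- nrow(unit_vectors)
  J <- shk_truncation(sigma, tol)
  coefs <- (2 * (0:J) + 1) * exp(-(0:J) * ((0:J) + 1) * sigma) / (4 * pi)
  K <- matrix(0, M, M)
  for (lo in seq(1L, M, by = block)) {
    hi <- min(lo + block - 1L, M)
    G <- unit_vectors[lo:hi, , drop = FALSE] %*% t(unit_vectors)
    G <- pmin(1, pmax(-1, G))
    acc <- matrix(coefs[1], hi - lo + 1L, M)
    pm2 <- matrix(1, hi - lo + 1L, M)
    pm1 <- G
    if (J >= 1) acc <- acc + coefs[2] * pm1
    if (J >= 2) for (jj in 2:J) {
      p <- ((2 * jj - 1) * G * pm1 - (jj - 1) * pm2) / jj
      acc <- acc + coefs[jj + 1] * p
      pm2 <- pm1
      pm1 <- p
    }
    K[lo:hi, ] <- acc
  }
  K <- (K + t(K)) / 2  # exact symmetry despite blockwise rounding
  new_kernel_matrix(K, kernel_spec("spherical_heat", sigma, tol = tol), M)
}

new_kernel_matrix <- function(values, spec, block_sizes) {
  structure(list(values = values, spec = spec, block_sizes = block_sizes),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix: %d x %d (%s, bandwidth %g), min entry %.3g\n",
              nrow(x$values), ncol(x$values), x$spec$family, x$spec$bandwidth,
              min(x$values)))
  invisible(x)
}

#' Spectral Riemannian kernel matrix
#'
#' Builds the diffusion or Matern kernel matrix K = F Phi(Lambda) F' from a
#' Laplace-Beltrami spectral basis, with Phi the family's spectral weight
#' function. Under `unit_mass` normalization Phi is divided by Phi(0), so
#' the mass-weighted row sums of K are exactly 1 up to eigensolver error:
#' the kernel is a proper density-estimation kernel on the surface.
#' Truncation-induced small negative entries are retained (clamping would
#' break the normalization); the minimum entry is reported by `print`.
#'
#' @param basis a `spectral_basis` from [compute_spectrum()] or
#'   [downsample_basis()].
#' @param spec a [kernel_spec()] with family `diffusion` or `matern`.
#' @return A `kernel_matrix`.
#' @export
spectral_kernel <- function(basis, spec) {
  if (!spec$family %in% c("diffusion", "matern"))
    stop("spectral_kernel requires a diffusion or matern spec")
  M_T <- if (is.null(spec$truncation)) basis$M_T else spec$truncation
  if (M_T > basis$M_T)
    stop("requested truncation exceeds the basis size")
  phi <- spectral_weights(spec, basis$values[seq_len(M_T)])
  if (spec$normalization == "unit_mass")
    phi <- phi / spectral_weights(spec, 0)
  Fm <- basis$vectors[, seq_len(M_T), drop = FALSE]
  K <- tcrossprod(Fm * rep(phi, each = nrow(Fm)), Fm)
  K <- (K + t(K)) / 2
  new_kernel_matrix(K, spec, nrow(Fm))
}

#' Convergence of Matern spectral weights to the diffusion weights
#'
#' As nu grows, the normalized Matern weight (1 + lambda kappa^2 / (2 nu))
#' ^(-nu-1) converges to the diffusion weight exp(-kappa^2 lambda / 2).
#' Returns the absolute deviations along a nu sequence (they must decrease,
#' which callers can assert).
#'
#' @param lambda eigenvalue at which to compare (> 0 for a nontrivial
#'   check).
#' @param kappa bandwidth, > 0.
#' @param nu_sequence increasing vector of smoothness values.
#' @return Numeric vector of deviations, one per nu.
#' @export
matern_limit_check <- function(lambda, kappa, nu_sequence) {
  stopifnot(lambda >= 0, kappa > 0, all(nu_sequence > 0))
  target <- exp(-kappa^2 * lambda / 2)
  vapply(nu_sequence, function(nu) {
    ratio <- (1 + lambda * kappa^2 / (2 * nu))^(-nu - 1)
    abs(ratio - target)
  }, numeric(1))
}

#' Assemble a bi-hemispheric block-diagonal kernel
#'
#' Points on different hemispheres have kernel value zero, so the
#' whole-surface kernel matrix is block diagonal in the left and right
#' hemisphere blocks. Both blocks must share family and bandwidth.
#'
#' @param left,right `kernel_matrix` objects for the two hemispheres.
#' @return A `kernel_matrix` of size (M_L + M_R) squared with exactly zero
#'   off-diagonal blocks; `block_sizes` records `c(M_L, M_R)`.
#' @export
block_kernel <- function(left, right) {
  sl <- left$spec; sr <- right$spec
  if (sl$family != sr$family || sl$bandwidth != sr$bandwidth ||
      !identical(sl$nu, sr$nu) || sl$normalization != sr$normalization)
    stop("hemisphere kernel specs do not match")
  ml <- nrow(left$values); mr <- nrow(right$values)
  K <- matrix(0, ml + mr, ml + mr)
  K[seq_len(ml), seq_len(ml)] <- left$values
  K[ml + seq_len(mr), ml + seq_len(mr)] <- right$values
  new_kernel_matrix(K, sl, c(ml, mr))
}

#' Bandwidth grids for the two kernel families
#'
#' Ten log-spaced bandwidths per family: kappa from 0.6252 to 18.9204 for
#' the spectral kernels and sigma from 0.0001 to 0.05 for the spherical
#' heat kernel (endpoints chosen so the two kernels' influence radii on a
#' sphere are comparable). `spacing = "linear"` is available for the sigma
#' grid.
#'
#' @param family `"diffusion"`, `"matern"` (kappa grid) or
#'   `"spherical_heat"` (sigma grid).
#' @param spacing `"log"` (default) or `"linear"`.
#' @return Strictly increasing numeric vector of length 10.
#' @export
bandwidth_grid <- function(family = c("diffusion", "matern", "spherical_heat"),
                           spacing = c("log", "linear")) {
  family <- match.arg(family)
  spacing <- match.arg(spacing)
  lim <- if (family == "spherical_heat") c(0.0001, 0.05)
         else c(0.6252, 18.9204)
  if (spacing == "log") exp(seq(log(lim[1]), log(lim[2]), length.out = 10))
  else seq(lim[1], lim[2], length.out = 10)
}

#' Mass-weighted row sums of a kernel matrix
#'
#' Returns K %*% diag(mass) %*% 1, the discrete integral of the kernel from
#' each vertex over the surface; equal to 1 for exactly normalized kernels.
#'
#' @param kernel a `kernel_matrix`.
#' @param mass lumped vertex areas.
#' @return Numeric vector of length M.
#' @export
kernel_row_mass <- function(kernel, mass) {
  drop(kernel$values %*% mass)
}
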