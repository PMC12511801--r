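#' Repeated-scan collections
#'
#' A `scan_collection` holds connectivity matrices (or any equally sized
#' numeric matrices) for n subjects with repeated scans: element `[[i]]` is
#' the list of subject i's scans. Reliability metrics require at least two
#' subjects and at least one subject with two or more scans.
#'
#' @param scans list of lists of matrices; `scans[[i]][[j]]` is subject i's
#'   j-th scan.
#' @return An object of class `scan_collection`.
#' @export
scan_collection <- function(scans) {
  stopifnot(is.list(scans), length(scans) >= 1)
  scans <- lapply(scans, function(s) lapply(s, as_matrix_values))
  dims <- unique(t(vapply(unlist(scans, recursive = FALSE), dim, integer(2))))
  if (nrow(dims) != 1) stop("all scans must have identical dimensions")
  structure(list(scans = scans, n_subjects = length(scans),
                 n_repeats = vapply(scans, length, integer(1))),
            class = "scan_collection")
}

as_matrix_values <- function(x) {
  if (inherits(x, "connectivity_matrix")) x$values else as.matrix(x)
}

#' @export
print.scan_collection <- function(x, ...) {
  cat(sprintf("scan_collection: %d subjects, %s scans each\n", x$n_subjects,
              paste(range(x$n_repeats), collapse = "-")))
  invisible(x)
}

frobenius_distance <- function(a, b, upper_only = FALSE) {
  d <- a - b
  if (upper_only) d <- d[upper.tri(d, diag = TRUE)]
  sqrt(sum(d^2))
}

#' Distance-based intraclass correlation (dICC)
#'
#' Reliability of matrix-valued repeated measurements:
#' dICC = 1 - MSD_w / MSD_b, where MSD_w is the mean squared distance over
#' all within-subject scan pairs and MSD_b over all between-subject pairs,
#' each estimated by the sample averages over pairs. The default distance
#' is the Frobenius norm over the full matrix. A value below 0.4 is
#' conventionally flagged as poor reliability (see
#' [reliability_threshold]); dICC is at most 1 and can be negative.
#'
#' @param collection a [scan_collection()].
#' @param distance function of two matrices returning a scalar distance
#'   (default full-matrix Frobenius).
#' @param upper_only use only the upper triangle (incl. diagonal) in the
#'   default Frobenius distance.
#' @return A single number <= 1.
#' @export
dicc <- function(collection, distance = NULL, upper_only = FALSE) {
  if (is.null(distance))
    distance <- function(a, b) frobenius_distance(a, b, upper_only)
  sc <- collection$scans
  n <- collection$n_subjects
  if (n < 2) stop("dICC requires at least 2 subjects")
  sw <- 0; nw <- 0L
  for (i in seq_len(n)) {
    ni <- length(sc[[i]])
    if (ni >= 2) for (j1 in 1:(ni - 1)) for (j2 in (j1 + 1):ni) {
      sw <- sw + distance(sc[[i]][[j1]], sc[[i]][[j2]])^2
      nw <- nw + 1L
    }
  }
  if (nw == 0L) stop("no within-subject scan pair available")
  sb <- 0; nb <- 0L
  for (i1 in 1:(n - 1)) for (i2 in (i1 + 1):n)
    for (j1 in seq_along(sc[[i1]])) for (j2 in seq_along(sc[[i2]])) {
      sb <- sb + distance(sc[[i1]][[j1]], sc[[i2]][[j2]])^2
      nb <- nb + 1L
    }
  msd_w <- sw / nw
  msd_b <- sb / nb
  if (msd_b == 0) stop("between-subject mean squared distance is zero; dICC undefined")
  1 - msd_w / msd_b
}

#' dICC reliability threshold
#'
#' Conventional annotation: dICC below 0.4 suggests poor reliability.
#' Surfaced as a constant for reports; no computation depends on it.
#' @export
reliability_threshold <- 0.4

#' Similarity of two connectivity matrices
#'
#' Mean over rows of the Pearson correlation between corresponding rows.
#' Rows whose values are constant in either matrix carry no correlation
#' information and are excluded from the mean.
#'
#' @param Pa,Pb matrices (or `connectivity_matrix` objects) of equal size.
#' @return A single number in [-1, 1].
#' @export
similarity <- function(Pa, Pb) {
  a <- as_matrix_values(Pa)
  b <- as_matrix_values(Pb)
  if (!all(dim(a) == dim(b))) stop("matrices must have equal dimensions")
  sda <- apply(a, 1, stats::sd)
  sdb <- apply(b, 1, stats::sd)
  ok <- sda > 0 & sdb > 0
  if (!any(ok)) stop("all rows are degenerate (zero variance)")
  rs <- vapply(which(ok), function(i) stats::cor(a[i, ], b[i, ]), numeric(1))
  mean(rs)
}

#' Reliability and identifiability report
#'
#' Computes, over a repeated-scan collection: mu_intra, the mean similarity
#' over within-subject scan pairs; mu_inter, the mean over between-subject
#' pairs; the pooled standard deviation s of the two similarity samples
#' (two-sample pooled variance); and
#' identifiability = |mu_intra - mu_inter| / s. High mu_intra with high
#' identifiability indicates smoothing that preserves individual
#' differences while keeping within-subject consistency.
#'
#' @param collection a [scan_collection()].
#' @return List with `mu_intra`, `mu_inter`, `pooled_sd`,
#'   `identifiability`, `dicc` (computed alongside for the report), and
#'   `poor_reliability` (`dicc <` [reliability_threshold]).
#' @export
reliability_identifiability <- function(collection) {
  sc <- collection$scans
  n <- collection$n_subjects
  intra <- numeric(0)
  for (i in seq_len(n)) {
    ni <- length(sc[[i]])
    if (ni >= 2) for (j1 in 1:(ni - 1)) for (j2 in (j1 + 1):ni)
      intra <- c(intra, similarity(sc[[i]][[j1]], sc[[i]][[j2]]))
  }
  inter <- numeric(0)
  if (n >= 2) for (i1 in 1:(n - 1)) for (i2 in (i1 + 1):n)
    for (j1 in seq_along(sc[[i1]])) for (j2 in seq_along(sc[[i2]]))
      inter <- c(inter, similarity(sc[[i1]][[j1]], sc[[i2]][[j2]]))
  if (length(intra) == 0 || length(inter) == 0)
    stop("need at least one within-subject and one between-subject pair")
  nw <- length(intra); nb <- length(inter)
  pooled_var <- ((nw - 1) * stats::var(intra) + (nb - 1) * stats::var(inter)) /
    (nw + nb - 2)
  s <- sqrt(pooled_var)
  if (!is.finite(s) || s == 0)
    stop("pooled similarity standard deviation is zero; identifiability undefined")
  d <- tryCatch(dicc(collection), error = function(e) NA_real_)
  list(mu_intra = mean(intra), mu_inter = mean(inter), pooled_sd = s,
       identifiability = abs(mean(intra) - mean(inter)) / s,
       dicc = d,
       poor_reliability = is.finite(d) && d < reliability_threshold)
}
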