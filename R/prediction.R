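#' PCA reduction of vectorized connectivity matrices
#'
#' Vectorizes each subject's connectivity matrix over the upper triangle
#' (including the diagonal; the matrices are symmetric so the lower
#' triangle adds nothing), centers the features across subjects, and
#' returns principal-component scores ordered by decreasing variance. At
#' most n_subjects - 1 components carry variance.
#'
#' @param matrices list of `connectivity_matrix` (or plain matrices), one
#'   per subject.
#' @param max_pcs maximum number of components to keep (default
#'   n_subjects - 1).
#' @return List with `scores` (subjects x n_pcs), `rotation`, `center`,
#'   `sdev`.
#' @export
pca_reduce <- function(matrices, max_pcs = NULL) {
  n <- length(matrices)
  if (n < 2) stop("PCA requires at least 2 subjects")
  X <- t(vapply(matrices, function(P) {
    V <- if (inherits(P, "connectivity_matrix")) P$values else as.matrix(P)
    V[upper.tri(V, diag = TRUE)]
  }, numeric(sum(upper.tri(as_matrix_values(matrices[[1]]), diag = TRUE)))))
  k <- min(if (is.null(max_pcs)) n - 1L else max_pcs, n - 1L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  list(scores = pc$x, rotation = pc$rotation, center = pc$center,
       sdev = pc$sdev)
}

#' Ridge trait prediction over random train/test splits
#'
#' For each random 80/20 train-test split and each number of leading
#' principal components K, fits ridge regression of the trait on the first
#' K PC scores (penalty tuned by internal cross-validation on the training
#' split only) and records test mean squared error and prediction-outcome
#' correlation. Features are standardized on the training split by
#' default. All randomness (splits, CV folds) derives from `seed`.
#'
#' @param scores subjects x n_pcs PC score matrix from [pca_reduce()].
#' @param traits numeric trait vector, one value per subject.
#' @param K_grid numbers of leading PCs to evaluate.
#' @param n_splits number of random splits (default 50).
#' @param test_frac test fraction per split (default 0.2).
#' @param standardize z-score features on the training split (default
#'   `TRUE`).
#' @param seed integer RNG seed.
#' @return List with `results` (data frame: `split`, `K`, `mse`, `cor`)
#'   and `summary` (per-K mean MSE and mean correlation over splits).
#' @export
ridge_cv_predict <- function(scores, traits, K_grid, n_splits = 50,
                             test_frac = 0.2, standardize = TRUE, seed = 1) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(length(traits) == n, all(K_grid >= 2), max(K_grid) <= ncol(scores))
  if (any(!is.finite(traits))) stop("traits contain missing values")
  n_test <- max(1L, round(test_frac * n))
  rows <- list(); r <- 0L
  for (s in seq_len(n_splits)) {
    test_idx <- with_seed(seed + s, sample.int(n, n_test))
    tr <- setdiff(seq_len(n), test_idx)
    foldid <- with_seed(seed + 100000L + s,
                        sample(rep_len(1:5, length(tr))))
    for (K in K_grid) {
      Xtr <- scores[tr, seq_len(K), drop = FALSE]
      Xte <- scores[test_idx, seq_len(K), drop = FALSE]
      if (standardize) {
        mu <- colMeans(Xtr)
        sdv <- apply(Xtr, 2, stats::sd)
        sdv[sdv == 0] <- 1
        Xtr <- scale(Xtr, mu, sdv)
        Xte <- scale(Xte, mu, sdv)
      }
      cv <- glmnet::cv.glmnet(Xtr, traits[tr], alpha = 0, nfolds = 5,
                              foldid = foldid, standardize = FALSE)
      pred <- drop(stats::predict(cv, Xte, s = "lambda.min"))
      obs <- traits[test_idx]
      r <- r + 1L
      rows[[r]] <- data.frame(
        split = s, K = K, mse = mean((pred - obs)^2),
        cor = if (length(obs) >= 3 && stats::sd(obs) > 0 && stats::sd(pred) > 0)
          stats::cor(pred, obs) else NA_real_)
    }
  }
  results <- do.call(rbind, rows)
  summ <- stats::aggregate(cbind(mse, cor) ~ K, data = results,
                           FUN = function(x) mean(x, na.rm = TRUE),
                           na.action = stats::na.pass)
  names(summ) <- c("K", "mean_mse", "mean_cor")
  list(results = results, summary = summ)
}

#' Select a bandwidth by out-of-sample performance
#'
#' Given one prediction result per bandwidth on a common grid, selects the
#' bandwidth minimizing the mean test MSE (or maximizing mean correlation),
#' each at its best K; ties go to the smaller bandwidth.
#'
#' @param reports named list (names = bandwidth values as strings, in grid
#'   order) of [ridge_cv_predict()] results.
#' @param criterion `"mse"` (default) or `"cor"`.
#' @return List with `bandwidth` (numeric), `index` in the grid, and the
#'   per-bandwidth `score` used.
#' @export
bandwidth_selection <- function(reports, criterion = c("mse", "cor")) {
  criterion <- match.arg(criterion)
  score <- vapply(reports, function(rep_) {
    if (criterion == "mse") min(rep_$summary$mean_mse)
    else max(rep_$summary$mean_cor, na.rm = TRUE)
  }, numeric(1))
  idx <- if (criterion == "mse") which.min(score) else which.max(score)
  list(bandwidth = as.numeric(names(reports)[idx]), index = unname(idx),
       score = score)
}

#' Read a trait table
#'
#' TSV with a `subject` column and one or more numeric trait columns, one
#' row per subject.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_traits <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  if (!"subject" %in% names(df)) stop("trait table needs a 'subject' column")
  df
}
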