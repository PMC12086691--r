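#' Four-block partition for bi-cross-validation
#'
#' Randomly permutes rows and columns of `Y` and tiles it into four blocks
#' `A` (r x s, held out), `B` (r x (n-s)), `C` ((m-r) x s) and
#' `D` ((m-r) x (n-s), training). The four index products cover every cell
#' exactly once.
#'
#' @param Y numeric matrix (or [spot_expression()]).
#' @param row_frac,col_frac fraction of rows/columns assigned to the
#'   held-out side, strictly between 0 and 1 and producing non-empty blocks.
#' @param seed integer seed driving the permutation.
#' @return A list of class `bcv_partition`: blocks `A`, `B`, `C`, `D` and
#'   the index sets `row_split`, `col_split`.
#' @export
bcv_partition <- function(Y, row_frac = 0.5, col_frac = 0.5, seed = 1L) {
  Y <- value_matrix(Y)
  m <- nrow(Y); n <- ncol(Y)
  if (row_frac <= 0 || row_frac >= 1 || col_frac <= 0 || col_frac >= 1)
    stop("row_frac and col_frac must lie strictly between 0 and 1")
  r <- round(row_frac * m); s <- round(col_frac * n)
  if (r < 1 || r >= m || s < 1 || s >= n)
    stop("fractions produce an empty block (r = ", r, ", s = ", s,
         " for a ", m, " x ", n, " matrix)")
  perm <- with_seed(as.integer(seed),
                    list(rows = sample.int(m), cols = sample.int(n)))
  ridx <- perm$rows[seq_len(r)]; ridx2 <- perm$rows[(r + 1):m]
  cidx <- perm$cols[seq_len(s)]; cidx2 <- perm$cols[(s + 1):n]
  structure(list(A = Y[ridx, cidx, drop = FALSE],
                 B = Y[ridx, cidx2, drop = FALSE],
                 C = Y[ridx2, cidx, drop = FALSE],
                 D = Y[ridx2, cidx2, drop = FALSE],
                 row_split = list(held = ridx, train = ridx2),
                 col_split = list(held = cidx, train = cidx2)),
            class = "bcv_partition")
}

#' Held-out reconstruction error for one partition
#'
#' Factorizes the training block `D ~ W_D H_D` at rank `k` with the unimodal
#' A-HALS solver, then predicts the held-out block by the Owen-Perry
#' estimator `A_hat = B pinv(H_D) pinv(W_D) C` (pseudo-inverses via
#' least squares, robust to rank deficiency) and returns the per-cell mean
#' squared error `||A - A_hat||_F^2 / (r s)`. The estimator is invariant to
#' the diagonal scale ambiguity of `(W_D, H_D)`.
#'
#' @param partition a [bcv_partition()].
#' @param k rank at which to factorize `D`; must not exceed `min(dim(D))`.
#' @param fit_config a [fit_config()] template; its `k` is overridden.
#' @return A single non-negative number.
#' @export
bcv_heldout_error <- function(partition, k,
                              fit_config = bcv_default_config()) {
  stopifnot(inherits(partition, "bcv_partition"))
  D <- partition$D
  if (k > min(dim(D)))
    stop("k = ", k, " exceeds min(dim(D)) = ", min(dim(D)))
  fit_config$k <- as.integer(k)
  fit <- nmf_fit(D, fit_config)
  Ahat <- bcv_predict(partition, fit$W, fit$H_rna)
  sum((partition$A - Ahat)^2) / length(partition$A)
}

# Owen-Perry estimator A_hat = B pinv(H_D) pinv(W_D) C; invariant to the
# diagonal scale ambiguity of (W_D, H_D).
bcv_predict <- function(partition, WD, HD) {
  # B %*% pinv(HD): minimize ||B - Z HD||_F over Z
  Z <- t(MASS::ginv(t(HD)) %*% t(partition$B))
  # pinv(WD) %*% C: minimize ||C - WD V||_F over V
  V <- MASS::ginv(WD) %*% partition$C
  Z %*% V
}

# Deterministic NNDSVD refits inside folds keep the error curve free of
# initialization noise; override by passing an explicit fit_config.
bcv_default_config <- function() {
  fit_config(k = 2, init = "nndsvd", max_outer_iter = 100L, rel_tol = 1e-5,
             seed = 1L)
}

#' Select the number of factors by bi-cross-validation
#'
#' For each rank in `k_grid`, averages [bcv_heldout_error()] over `folds`
#' independent random partitions of the expression matrix; the selected rank
#' minimizes the mean held-out error, with ties broken toward the smaller
#' rank. Partitions are shared across ranks within a fold so the curve is
#' comparable.
#'
#' @param Y numeric matrix (or [spot_expression()]); per the method this is
#'   the expression matrix. To run on the weighted concatenation with an
#'   image block, `cbind` the weighted matrices yourself.
#' @param k_grid increasing vector of candidate ranks.
#' @param folds number of random partitions, default 5.
#' @param row_frac,col_frac see [bcv_partition()].
#' @param seed integer; fold seeds are derived from it.
#' @param fit_config a [fit_config()] template used for the inner fits.
#' @return A list of class `bcv_result`: `k_grid`, `errors` (folds x ranks
#'   matrix), `mean_errors`, `k_selected`, `folds`, `seed`.
#' @examples
#' sim <- simulate_joint_data(m = 50, n = 60, f = 10, k = 2, snr_rna = 50,
#'                            seed = 3)
#' sel <- select_rank(sim$expression, k_grid = 1:4, folds = 2, seed = 3)
#' sel$k_selected
#' @export
select_rank <- function(Y, k_grid, folds = 5L, row_frac = 0.5,
                        col_frac = 0.5, seed = 1L,
                        fit_config = bcv_default_config()) {
  Y <- value_matrix(Y)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 0L) stop("k_grid must be non-empty")
  folds <- as.integer(folds)
  errs <- matrix(NA_real_, folds, length(k_grid),
                 dimnames = list(paste0("fold", seq_len(folds)),
                                 paste0("k", k_grid)))
  for (fold in seq_len(folds)) {
    fold_seed <- (as.integer(seed) + 104729L * fold) %% 2147483629L
    part <- bcv_partition(Y, row_frac, col_frac, seed = fold_seed)
    if (max(k_grid) > min(dim(part$D)))
      stop("largest k in grid (", max(k_grid), ") exceeds the training ",
           "block size ", paste(dim(part$D), collapse = " x "))
    for (i in seq_along(k_grid))
      errs[fold, i] <- bcv_heldout_error(part, k_grid[i], fit_config)
  }
  mean_err <- colMeans(errs)
  k_selected <- k_grid[which.min(mean_err)]  # which.min takes the first min
  structure(list(k_grid = k_grid, errors = errs, mean_errors = mean_err,
                 k_selected = k_selected, folds = folds,
                 seed = as.integer(seed)),
            class = "bcv_result")
}

#' @export
print.bcv_result <- function(x, ...) {
  cat("bcv_result over", x$folds, "folds\n")
  print(round(x$mean_errors, 6))
  cat("selected rank:", x$k_selected, "\n")
  invisible(x)
}
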