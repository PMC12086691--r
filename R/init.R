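#' Half-normal random initialization
#'
#' Draws the three factor matrices with entries `|z| * scale * c`, where `z`
#' is standard normal and `c = sqrt(mean(Y_joint) / k)` is a data-dependent
#' magnitude chosen so the initial product `W0 %*% H0` has roughly the data's
#' mean magnitude. Sampling from a half-normal keeps every entry
#' non-negative; the draw is a pure function of `(dims, seed, scale, c)`.
#'
#' @param m,n,f,k dimensions: spots, genes, image features, rank. `f = 0`
#'   omits the image block (`H_img0` is a `k x 0` matrix).
#' @param seed integer seed; required, reproducibility is part of the
#'   contract.
#' @param scale positive multiplier for the draws, default 1.0.
#' @param data_magnitude the magnitude `c`; pass `mean(Y_joint)` based values
#'   via [jnmf_fit()], defaults to 1 when no data context is available.
#' @return list with `W0` (m x k), `H_rna0` (k x n), `H_img0` (k x f).
#' @export
init_random_halfnormal <- function(m, n, f, k, seed, scale = 1.0,
                                   data_magnitude = 1.0) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is required for half-normal initialization")
  if (min(m, n, k) < 1L || f < 0L) stop("all dimensions must be >= 1")
  cmag <- scale * data_magnitude
  out <- with_seed(as.integer(seed), {
    W0 <- matrix(abs(stats::rnorm(m * k)) * cmag, m, k)
    H_rna0 <- matrix(abs(stats::rnorm(k * n)) * cmag, k, n)
    H_img0 <- matrix(abs(stats::rnorm(k * f)) * cmag, k, f)
    list(W0 = W0, H_rna0 = H_rna0, H_img0 = H_img0)
  })
  out
}

# Evaluate an expression under a local RNG state so callers' streams are
# untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' NNDSVD initialization
#'
#' Non-negative double singular value decomposition: a deterministic
#' initialization built from the k leading singular triplets of a
#' non-negative matrix. For each triplet beyond the first, the positive and
#' negative parts of the singular vector pair are compared and the dominant
#' pair is kept, scaled to preserve the triplet's energy; the leading triplet
#' is non-negative up to sign (Perron-Frobenius). Zeros are left as zeros
#' (the plain variant; no mean or random filling).
#'
#' @param Y non-negative numeric matrix.
#' @param k rank, `k <= min(dim(Y))`.
#' @return list with `W0` (nrow x k) and `H0` (k x ncol), both non-negative.
#' @export
init_nndsvd <- function(Y, k) {
  Y <- as.matrix(Y)
  if (min(Y) < 0) stop("NNDSVD requires a non-negative matrix")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > min(dim(Y)))
    stop("k = ", k, " exceeds min(dim(Y)) = ", min(dim(Y)))
  sv <- svd(Y, nu = k, nv = k)
  W0 <- matrix(0, nrow(Y), k)
  H0 <- matrix(0, k, ncol(Y))
  # leading triplet: non-negative after a sign fix
  u1 <- sv$u[, 1L]; v1 <- sv$v[, 1L]
  if (sum(u1) < 0) { u1 <- -u1; v1 <- -v1 }
  u1 <- pmax(u1, 0); v1 <- pmax(v1, 0)
  W0[, 1L] <- sqrt(sv$d[1L]) * u1
  H0[1L, ] <- sqrt(sv$d[1L]) * v1
  if (k > 1L) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      termp <- nup * nvp; termn <- nun * nvn
      if (termp >= termn && termp > 0) {
        W0[, j] <- sqrt(sv$d[j] * termp) * up / nup
        H0[j, ] <- sqrt(sv$d[j] * termp) * vp / nvp
      } else if (termn > 0) {
        W0[, j] <- sqrt(sv$d[j] * termn) * un / nun
        H0[j, ] <- sqrt(sv$d[j] * termn) * vn / nvn
      } # both parts vanish only for a zero singular vector: leave zeros
    }
  }
  list(W0 = W0, H0 = H0)
}

# Joint initialization used by jnmf_fit(): run the chosen strategy on the
# weighted concatenation [sqrt(a) Y_rna | sqrt(2-a) Y_img] -- exactly the
# equivalent unimodal problem -- and split/unweight the H block. Blocks with
# zero weight are excluded from the concatenation and initialized to zero
# (they are refit post hoc by an unweighted least-squares step).
joint_init <- function(Yr, Yi, config) {
  a <- config$alpha
  k <- config$k
  wr <- sqrt(a)
  wi <- sqrt(2 - a)
  have_img <- !is.null(Yi) && ncol(Yi) > 0L
  n <- ncol(Yr)
  f <- if (have_img) ncol(Yi) else 0L
  parts <- list()
  if (wr > 0) parts <- c(parts, list(wr * Yr))
  if (have_img && wi > 0) parts <- c(parts, list(wi * Yi))
  Ycat <- do.call(cbind, parts)
  if (config$init == "nndsvd") {
    ini <- init_nndsvd(Ycat, k)
    W0 <- ini$W0
    H_rna0 <- matrix(0, k, n)
    H_img0 <- matrix(0, k, f)
    off <- 0L
    if (wr > 0) {
      H_rna0 <- ini$H0[, off + seq_len(n), drop = FALSE] / wr
      off <- off + n
    }
    if (have_img && wi > 0)
      H_img0 <- ini$H0[, off + seq_len(f), drop = FALSE] / wi
  } else {
    cmag <- sqrt(mean(Ycat) / k)
    ini <- init_random_halfnormal(nrow(Yr), n, f, k, seed = config$seed,
                                  scale = 1.0, data_magnitude = cmag)
    W0 <- ini$W0
    H_rna0 <- ini$H_rna0
    H_img0 <- ini$H_img0
  }
  list(W0 = W0, H_rna0 = H_rna0, H_img0 = H_img0)
}
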