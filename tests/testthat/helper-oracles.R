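# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force pair enumeration for ARI/FM, an
# exhaustive permutation expectation for AMI, multiplicative-update NMF for
# the solver, and naive loops for binning and correlation.

# ---- partition metrics ----------------------------------------------------

# ARI by explicit enumeration of all unordered item pairs.
oracle_ari <- function(x, y) {
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(diag(n))]
  same_y <- outer(y, y, "==")[upper.tri(diag(n))]
  a <- sum(same_x & same_y)   # together in both
  b <- sum(same_x & !same_y)
  c2 <- sum(!same_x & same_y)
  d <- sum(!same_x & !same_y)
  tot <- a + b + c2 + d
  expected <- (a + b) * (a + c2) / tot
  maxi <- ((a + b) + (a + c2)) / 2
  if (abs(maxi - expected) < 1e-12) return(1.0)
  (a - expected) / (maxi - expected)
}

oracle_fm <- function(x, y) {
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(diag(n))]
  same_y <- outer(y, y, "==")[upper.tri(diag(n))]
  tp <- sum(same_x & same_y)
  px <- sum(same_x); py <- sum(same_y)
  if (px == 0 || py == 0) return(if (px == py) 1.0 else 0.0)
  tp / sqrt(px * py)
}

oracle_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  mi <- 0
  a <- rowSums(tab); b <- colSums(tab)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] / n * log(n * tab[i, j] / (a[i] * b[j]))
  as.numeric(mi)
}

oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

# Exact expected MI under the permutation null: enumerate every permutation
# of y and average the MI. Exponential in n; fine for n <= 6.
oracle_emi_enum <- function(x, y) {
  n <- length(y)
  perms <- all_permutations(n)
  mean(apply(perms, 1L, function(p) oracle_mi(x, y[p])))
}

oracle_ami <- function(x, y) {
  n <- length(x)
  if (length(unique(x)) == 1L && length(unique(y)) == 1L) return(1.0)
  if (length(unique(x)) == n && length(unique(y)) == n) return(1.0)
  hu <- oracle_entropy(x); hv <- oracle_entropy(y)
  mi <- oracle_mi(x, y)
  emi <- oracle_emi_enum(x, y)
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < 1e-12 * max(hu, hv, 1))
    return(if (mi - emi > abs(denom)) 1.0 else 0.0)
  (mi - emi) / denom
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

# All set partitions of n items as label vectors (restricted growth strings).
all_partitions <- function(n) {
  grow <- function(prefix) {
    if (length(prefix) == n) return(list(prefix))
    mx <- max(prefix)
    out <- list()
    for (v in seq_len(mx + 1L)) out <- c(out, grow(c(prefix, v)))
    out
  }
  grow(1L)
}

# ---- solver oracle --------------------------------------------------------

# Plain Lee-Seung multiplicative updates minimizing ||Y - W H||_F^2.
mu_nmf <- function(Y, W, H, n_iter = 2000L, eps = 1e-12) {
  for (it in seq_len(n_iter)) {
    H <- H * (crossprod(W, Y) / (crossprod(W) %*% H + eps))
    W <- W * (Y %*% t(H) / (W %*% tcrossprod(H) + eps))
  }
  list(W = W, H = H, objective = sum((Y - W %*% H)^2))
}

# ---- misc -----------------------------------------------------------------

# Naive per-pixel, per-channel binning.
oracle_hist <- function(block, n_bins, lo = 0, hi = 255) {
  counts <- integer(0)
  width <- (hi - lo) / n_bins
  for (ch in seq_len(dim(block)[3])) {
    cnt <- integer(n_bins)
    for (v in as.numeric(block[, , ch])) {
      b <- if (v >= hi) n_bins else floor((v - lo) / width) + 1
      cnt[b] <- cnt[b] + 1L
    }
    counts <- c(counts, cnt)
  }
  counts
}

oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Small strictly-positive exact low-rank pair used by several tests.
make_exact_lowrank <- function(m, n, f, k, seed) {
  set.seed(seed)
  W <- matrix(abs(rnorm(m * k)) + 0.1, m, k)
  Hr <- matrix(abs(rnorm(k * n)) + 0.1, k, n)
  Hi <- matrix(abs(rnorm(k * f)) + 0.1, k, f)
  list(W = W, Hr = Hr, Hi = Hi, Yr = W %*% Hr, Yi = W %*% Hi)
}
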