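#' Joint factorization objective
#'
#' Evaluates the weighted two-block objective
#' `alpha * ||Y_rna - W H_rna||_F^2 + (2 - alpha) * ||Y_img - W H_img||_F^2`.
#' With `alpha = 2` (or `Y_img = NULL`) the image term is dropped; with
#' `alpha = 0` the expression term is dropped.
#'
#' @param Y_rna m x n non-negative matrix (or a [spot_expression()]).
#' @param Y_img m x f non-negative matrix (or a [spot_image_features()]),
#'   or NULL.
#' @param W m x k matrix of shared spot scores.
#' @param H_rna k x n gene loading matrix.
#' @param H_img k x f image-feature loading matrix (or NULL).
#' @param alpha modality weight in \[0, 2\].
#' @return A single non-negative number.
#' @examples
#' Y <- matrix(c(1, 3, 2, 4), 2, 2)
#' joint_objective(Y, NULL, W = matrix(1, 2, 1), H_rna = matrix(c(1, 2), 1, 2),
#'                 H_img = NULL, alpha = 2)
#' @export
joint_objective <- function(Y_rna, Y_img, W, H_rna, H_img = NULL, alpha = 1.0) {
  Y_rna <- value_matrix(Y_rna)
  Y_img <- if (is.null(Y_img)) NULL else value_matrix(Y_img)
  if (alpha < 0 || alpha > 2) stop("alpha must lie in [0, 2]")
  if (nrow(Y_rna) != nrow(W))
    stop("spot axis mismatch: Y_rna has ", nrow(Y_rna), " rows but W has ",
         nrow(W))
  if (ncol(W) != nrow(H_rna))
    stop("factor axis mismatch: W has ", ncol(W), " columns but H_rna has ",
         nrow(H_rna), " rows")
  if (ncol(Y_rna) != ncol(H_rna))
    stop("gene axis mismatch: Y_rna has ", ncol(Y_rna),
         " columns but H_rna has ", ncol(H_rna))
  obj <- alpha * sum((Y_rna - W %*% H_rna)^2)
  if (!is.null(Y_img)) {
    if (is.null(H_img)) stop("H_img is required when Y_img is given")
    if (nrow(Y_img) != nrow(W))
      stop("spot axis mismatch: Y_img has ", nrow(Y_img), " rows but W has ",
           nrow(W))
    if (ncol(Y_img) != ncol(H_img))
      stop("feature axis mismatch: Y_img has ", ncol(Y_img),
           " columns but H_img has ", ncol(H_img))
    obj <- obj + (2 - alpha) * sum((Y_img - W %*% H_img)^2)
  }
  obj
}

value_matrix <- function(x) {
  if (inherits(x, "spot_expression") || inherits(x, "spot_image_features"))
    return(x$values)
  as.matrix(x)
}

# ---- A-HALS primitives ----------------------------------------------------

# Objective surrogate for the W subproblem given A = sum_b w_b Y_b H_b',
# B = sum_b w_b H_b H_b': f(W) = <W'W, B> - 2 <W, A> (+ data constant).
w_surrogate <- function(W, A, B) sum(W * (W %*% B)) - 2 * sum(W * A)

h_surrogate <- function(H, P, Q) sum(H * (Q %*% H)) - 2 * sum(P * H)

# One cyclic sweep over the columns of W (HALS closed-form column update
# with projection onto the non-negative orthant).
hals_sweep_w <- function(W, A, B) {
  for (j in seq_len(ncol(W))) {
    bjj <- B[j, j]
    if (bjj <= .Machine$double.eps) next
    W[, j] <- pmax(W[, j] + (A[, j] - W %*% B[, j]) / bjj, 0)
  }
  W
}

hals_sweep_h <- function(H, P, Q) {
  for (j in seq_len(nrow(H))) {
    qjj <- Q[j, j]
    if (qjj <= .Machine$double.eps) next
    H[j, ] <- pmax(H[j, ] + (P[j, ] - Q[j, ] %*% H) / qjj, 0)
  }
  H
}

# Accelerated block update: repeat cheap cyclic sweeps while the per-sweep
# decrease of the block objective exceeds `delta` times the first sweep's
# decrease, capped at `cap` sweeps.
accel_update <- function(X, sweep_fun, surrogate_fun, cap, delta) {
  f_prev <- surrogate_fun(X)
  first_dec <- NA_real_
  for (l in seq_len(cap)) {
    X <- sweep_fun(X)
    f_new <- surrogate_fun(X)
    dec <- f_prev - f_new
    f_prev <- f_new
    if (l == 1L) {
      first_dec <- dec
      if (!(first_dec > 0)) break
    } else if (!(dec > delta * first_dec)) break
  }
  X
}

# Inner sweep cap 1 + floor(rho * cost_ratio): ratio of the one-off
# precomputation cost (forming A and B / P and Q) to the per-sweep cost.
inner_cap <- function(rho, dim_big, dim_small, k) {
  1L + as.integer(floor(rho * (dim_big * dim_small + dim_small * k) /
                          (dim_big * k + k * k)))
}

# ---- engine ---------------------------------------------------------------

# blocks: list of list(Y = matrix, w = weight); only blocks with w > 0
# participate in the alternating updates. Runs inside the caller's RNG scope
# (zero-column rescue draws from it).
ahals_engine <- function(blocks, W, Hs, config) {
  m <- nrow(W); k <- ncol(W)
  active <- which(vapply(blocks, function(b) b$w > 0, logical(1)))
  ynorm2 <- vapply(blocks, function(b) sum(b$Y^2), numeric(1))
  ncols <- vapply(blocks, function(b) ncol(b$Y), numeric(1))
  ncat <- sum(ncols[active])
  cap_w <- inner_cap(config$accel_rho, m, ncat, k)
  trace <- numeric(0)
  obj_prev <- Inf
  converged <- FALSE
  for (iter in seq_len(config$max_outer_iter)) {
    # W step on the weighted concatenation
    A <- matrix(0, m, k); B <- matrix(0, k, k)
    for (b in active) {
      A <- A + blocks[[b]]$w * (blocks[[b]]$Y %*% t(Hs[[b]]))
      B <- B + blocks[[b]]$w * tcrossprod(Hs[[b]])
    }
    W <- accel_update(W, function(X) hals_sweep_w(X, A, B),
                      function(X) w_surrogate(X, A, B),
                      cap_w, config$accel_delta)
    resc <- rescue_zero_columns(W, iter)
    W <- resc$W
    # zero the matching H rows so the re-seeded column contributes nothing
    # until the next H step -- keeps the objective trace non-increasing
    if (length(resc$dead))
      for (b in active) Hs[[b]][resc$dead, ] <- 0
    # H steps, one per active block
    Q <- crossprod(W)
    obj <- 0
    for (b in active) {
      P <- crossprod(W, blocks[[b]]$Y)
      cap_h <- inner_cap(config$accel_rho, ncols[b], m, k)
      Hs[[b]] <- accel_update(Hs[[b]],
                              function(X) hals_sweep_h(X, P, Q),
                              function(X) h_surrogate(X, P, Q),
                              cap_h, config$accel_delta)
      obj <- obj + blocks[[b]]$w *
        (ynorm2[b] - 2 * sum(P * Hs[[b]]) + sum(Q * tcrossprod(Hs[[b]])))
    }
    obj <- max(obj, 0)
    trace <- c(trace, obj)
    if (config$verbose)
      message(sprintf("iter %3d  objective %.8g", iter, obj))
    if (is.finite(obj_prev) && obj_prev > 0 &&
        (obj_prev - obj) / obj_prev < config$rel_tol) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  list(W = W, Hs = Hs, trace = trace, converged = converged)
}

# HALS can drive a whole factor column to zero; re-seed such columns from a
# half-normal draw scaled to the mean surviving column norm so the fit keeps
# the requested rank.
rescue_zero_columns <- function(W, iter) {
  cn <- sqrt(colSums(W^2))
  dead <- which(cn < 1e-12)
  if (length(dead) == 0L) return(list(W = W, dead = dead))
  alive <- cn[cn >= 1e-12]
  target <- if (length(alive)) mean(alive) else 1
  for (j in dead) {
    v <- abs(stats::rnorm(nrow(W)))
    W[, j] <- v * (target / sqrt(sum(v^2)))
  }
  warning("re-seeded ", length(dead), " zero factor column(s) of W at outer ",
          "iteration ", iter, call. = FALSE)
  list(W = W, dead = dead)
}

# ---- user-facing fits -----------------------------------------------------

#' Fit the joint non-negative factorization
#'
#' Solves `min_{W, H_rna, H_img >= 0}
#' alpha ||Y_rna - W H_rna||_F^2 + (2 - alpha) ||Y_img - W H_img||_F^2`
#' by accelerated hierarchical alternating least squares: each outer
#' iteration solves the three convex subproblems (W with both loadings
#' fixed, then each loading with the rest fixed) with cyclic closed-form
#' column updates and an inner acceleration loop. Equivalent to unimodal NMF
#' on the column concatenation `[sqrt(alpha) Y_rna | sqrt(2-alpha) Y_img]`.
#'
#' When `modality_rescale` is on (default) each modality is divided by its
#' own Frobenius norm before fitting, so `alpha = 1` weights the modalities
#' equally regardless of raw units; the objective trace is reported in this
#' rescaled space and the scalars are folded back into the returned loadings
#' (so `W %*% H_rna` approximates the original `Y_rna`). After convergence
#' the columns of W are normalized to unit Euclidean norm and the scale is
#' pushed into both loading blocks.
#'
#' A block given zero weight (`alpha = 2` makes the image block inert,
#' `alpha = 0` the expression block) is excluded from the alternating
#' updates entirely; its loadings are fit post hoc by a non-negative
#' least-squares step against the final W and flagged in
#' `model$unweighted_blocks`.
#'
#' @param expr [spot_expression()] or non-negative matrix, m spots x n genes.
#' @param img [spot_image_features()] or non-negative matrix, m x f, or NULL
#'   for a unimodal fit on expression alone.
#' @param config a [fit_config()]; its `k`, `alpha`, `init` and `seed` drive
#'   the fit.
#' @return An object of class `joint_factor_model`: `W` (m x k), `H_rna`
#'   (k x n), `H_img` (k x f), `alpha`, `k`, `objective_trace`, `converged`,
#'   `seed`, `rescale` (the two Frobenius divisors), `unweighted_blocks`.
#' @examples
#' sim <- simulate_joint_data(m = 40, n = 60, f = 12, k = 2, seed = 1)
#' fit <- jnmf_fit(sim$expression, sim$features, fit_config(k = 2, seed = 1))
#' fit$objective_trace[1] >= tail(fit$objective_trace, 1)
#' @export
jnmf_fit <- function(expr, img = NULL, config = fit_config(k = 10)) {
  Yr <- value_matrix(expr)
  Yi <- if (is.null(img)) NULL else value_matrix(img)
  if (inherits(expr, "spot_expression") && inherits(img, "spot_image_features"))
    check_aligned(expr, img)
  if (anyNA(Yr) || min(Yr) < 0)
    stop("expression matrix must be non-negative with no missing values")
  if (!is.null(Yi) && (anyNA(Yi) || min(Yi) < 0))
    stop("image-feature matrix must be non-negative with no missing values")
  if (all(Yr == 0)) stop("expression matrix is identically zero")
  if (!is.null(Yi) && all(Yi == 0)) stop("image-feature matrix is identically zero")
  if (!is.null(Yi) && nrow(Yi) != nrow(Yr))
    stop("expression and image-feature matrices disagree on the number of ",
         "spots (", nrow(Yr), " vs ", nrow(Yi), ")")
  k <- config$k
  if (k > min(dim(Yr)))
    warning("k = ", k, " exceeds min(dim(Y_rna)) = ", min(dim(Yr)),
            "; the factorization is over-parameterized", call. = FALSE)
  s_rna <- sqrt(sum(Yr^2))
  s_img <- if (is.null(Yi)) 1 else sqrt(sum(Yi^2))
  if (config$modality_rescale) {
    Yr <- Yr / s_rna
    if (!is.null(Yi)) Yi <- Yi / s_img
  } else {
    s_rna <- 1; s_img <- 1
  }
  have_img <- !is.null(Yi)
  ini <- joint_init(Yr, Yi, config)
  blocks <- list(rna = list(Y = Yr, w = config$alpha))
  Hs <- list(rna = ini$H_rna0)
  if (have_img) {
    blocks$img <- list(Y = Yi, w = 2 - config$alpha)
    Hs$img <- ini$H_img0
  }
  res <- with_seed(config$seed, ahals_engine(blocks, ini$W0, Hs, config))
  W <- res$W; Hs <- res$Hs
  # post hoc loadings for an unweighted block
  unweighted <- character(0)
  for (b in names(blocks)) {
    if (blocks[[b]]$w > 0) next
    unweighted <- c(unweighted, b)
    Hs[[b]] <- solve_h_given_w(blocks[[b]]$Y, W, config$rel_tol)
  }
  # scale convention: unit-norm W columns, scale pushed into both H blocks
  d <- sqrt(colSums(W^2))
  d[d < 1e-300] <- 1
  W <- sweep(W, 2L, d, "/")
  Hs$rna <- Hs$rna * d
  if (have_img) Hs$img <- Hs$img * d
  # undo modality rescaling in the loadings so W %*% H is on the input scale
  H_rna <- Hs$rna * s_rna
  H_img <- if (have_img) Hs$img * s_img else NULL
  barcodes <- if (inherits(expr, "spot_expression")) expr$barcodes else
    rownames(Yr)
  rownames(W) <- barcodes
  colnames(W) <- paste0("factor", seq_len(k))
  rownames(H_rna) <- colnames(W)
  if (inherits(expr, "spot_expression")) colnames(H_rna) <- expr$gene_ids
  if (have_img) {
    rownames(H_img) <- colnames(W)
    if (inherits(img, "spot_image_features"))
      colnames(H_img) <- img$feature_names
  }
  structure(list(W = W, H_rna = H_rna, H_img = H_img,
                 alpha = config$alpha, k = k,
                 objective_trace = res$trace, converged = res$converged,
                 seed = config$seed,
                 rescale = c(rna = s_rna, img = s_img),
                 unweighted_blocks = unweighted,
                 config = config),
            class = "joint_factor_model")
}

#' Unimodal NMF fit
#'
#' Convenience wrapper: fits a single non-negative matrix with the same
#' A-HALS solver by setting `alpha = 2` and omitting the image block. Used
#' internally by the bi-cross-validation rank selection.
#'
#' @inheritParams jnmf_fit
#' @param Y non-negative matrix.
#' @return A `joint_factor_model` with `H_img = NULL`.
#' @export
nmf_fit <- function(Y, config = fit_config(k = 10)) {
  config$alpha <- 2
  jnmf_fit(Y, img = NULL, config = config)
}

# Non-negative LS fit of H given fixed W: HALS sweeps to tolerance.
solve_h_given_w <- function(Y, W, rel_tol, max_sweeps = 500L) {
  k <- ncol(W)
  Q <- crossprod(W)
  P <- crossprod(W, Y)
  H <- matrix(0, k, ncol(Y))
  f_prev <- Inf
  for (l in seq_len(max_sweeps)) {
    H <- hals_sweep_h(H, P, Q)
    f_new <- h_surrogate(H, P, Q)
    if (is.finite(f_prev) && abs(f_prev - f_new) <=
        rel_tol * max(abs(f_prev), 1e-300)) break
    f_prev <- f_new
  }
  H
}

#' Project new spots onto fitted factors
#'
#' Computes non-negative spot scores `W_new` for new data under the fitted
#' loadings: minimizes the joint objective over W only, holding `H_rna` and
#' `H_img` fixed, using the same HALS W-step run to tolerance. The new
#' matrices must have the model's gene and feature dimensions and are scaled
#' by the model's stored modality divisors before projection.
#'
#' @param model a fitted [jnmf_fit()] model.
#' @param Y_rna_new matrix (or [spot_expression()]) with the model's n genes.
#' @param Y_img_new matrix (or [spot_image_features()]) with the model's f
#'   features, or NULL if the model carries no image block (or `alpha = 2`).
#' @param rel_tol,max_sweeps convergence controls for the W-step.
#' @return Non-negative matrix of spot scores, rows = new spots, columns =
#'   the model's factors.
#' @export
jnmf_transform <- function(model, Y_rna_new, Y_img_new = NULL,
                           rel_tol = 1e-10, max_sweeps = 1000L) {
  stopifnot(inherits(model, "joint_factor_model"))
  Yr <- value_matrix(Y_rna_new)
  if (ncol(Yr) != ncol(model$H_rna))
    stop("gene axis mismatch: new data has ", ncol(Yr),
         " genes but the model was fit with ", ncol(model$H_rna))
  Yi <- NULL
  if (!is.null(Y_img_new)) {
    if (is.null(model$H_img))
      stop("model carries no image loadings; omit Y_img_new")
    Yi <- value_matrix(Y_img_new)
    if (ncol(Yi) != ncol(model$H_img))
      stop("feature axis mismatch: new data has ", ncol(Yi),
           " features but the model was fit with ", ncol(model$H_img))
  }
  a <- model$alpha
  s <- model$rescale
  # back to the solver's rescaled space
  Hr <- model$H_rna / s["rna"]
  Yr <- Yr / s["rna"]
  A <- a * (Yr %*% t(Hr))
  B <- a * tcrossprod(Hr)
  if (!is.null(Yi) && (2 - a) > 0) {
    Hi <- model$H_img / s["img"]
    Yi <- Yi / s["img"]
    A <- A + (2 - a) * (Yi %*% t(Hi))
    B <- B + (2 - a) * tcrossprod(Hi)
  }
  W <- matrix(0, nrow(Yr), model$k)
  f_prev <- Inf
  for (l in seq_len(max_sweeps)) {
    W <- hals_sweep_w(W, A, B)
    f_new <- w_surrogate(W, A, B)
    if (is.finite(f_prev) && abs(f_prev - f_new) <=
        rel_tol * max(abs(f_prev), 1e-300)) break
    f_prev <- f_new
  }
  colnames(W) <- colnames(model$W)
  rownames(W) <- rownames(Yr)
  W
}
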