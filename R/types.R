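#' Spot-level expression matrix
#'
#' Container for a non-negative spots x genes matrix with barcode and gene
#' identifiers. Spots are barcoded capture locations on a spatial
#' transcriptomics array (Visium, Visium HD bins, legacy ST); entries are raw
#' or normalized counts.
#'
#' @param values numeric matrix, m spots x n genes, all entries >= 0.
#' @param barcodes character vector of m unique spot barcodes.
#' @param gene_ids character vector of n unique gene identifiers.
#' @return An object of class `spot_expression` with elements `values`
#'   (dimnames set to barcodes/gene_ids), `barcodes` and `gene_ids`.
#' @examples
#' y <- spot_expression(matrix(1:6, 2, 3), c("b1", "b2"), c("g1", "g2", "g3"))
#' dim(y$values)
#' @export
spot_expression <- function(values, barcodes = rownames(values),
                            gene_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(barcodes)) barcodes <- paste0("spot", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  barcodes <- as.character(barcodes)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least one spot and one gene")
  if (length(barcodes) != nrow(values))
    stop("length of 'barcodes' (", length(barcodes),
         ") does not match number of spots (", nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop("length of 'gene_ids' (", length(gene_ids),
         ") does not match number of genes (", ncol(values), ")")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes are not allowed")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids are not allowed")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (min(values) < 0)
    stop("expression matrix contains negative entries (min = ", min(values), ")")
  dimnames(values) <- list(barcodes, gene_ids)
  structure(list(values = values, barcodes = barcodes, gene_ids = gene_ids),
            class = "spot_expression")
}

#' Spot-level image feature matrix
#'
#' Container for a non-negative spots x features matrix aligned, barcode for
#' barcode, with a [spot_expression()] object. Features are typically
#' multiscale per-channel histogram bin counts from H&E patches
#' (see [build_feature_matrix()]) but any non-negative spot-wise features
#' (e.g. user-supplied CNN embeddings, suitably rectified) are accepted.
#'
#' @param values numeric matrix, m spots x f features, all entries >= 0.
#' @param barcodes character vector of m spot barcodes.
#' @param feature_names character vector of f feature names.
#' @return An object of class `spot_image_features`.
#' @export
spot_image_features <- function(values, barcodes = rownames(values),
                                feature_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(barcodes)) barcodes <- paste0("spot", seq_len(nrow(values)))
  if (is.null(feature_names))
    feature_names <- paste0("feature", seq_len(ncol(values)))
  barcodes <- as.character(barcodes)
  feature_names <- as.character(feature_names)
  if (ncol(values) < 1L) stop("feature matrix must have at least one feature")
  if (length(barcodes) != nrow(values))
    stop("length of 'barcodes' does not match number of spots")
  if (length(feature_names) != ncol(values))
    stop("length of 'feature_names' does not match number of features")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes are not allowed")
  if (anyNA(values)) stop("feature matrix contains missing values")
  if (min(values) < 0)
    stop("feature matrix contains negative entries (min = ", min(values), ")")
  dimnames(values) <- list(barcodes, feature_names)
  structure(list(values = values, barcodes = barcodes,
                 feature_names = feature_names),
            class = "spot_image_features")
}

# Check that expression and image features refer to the same spots in the
# same order; called by every operation that consumes the pair.
check_aligned <- function(expr, img) {
  if (!identical(expr$barcodes, img$barcodes))
    stop("expression and image-feature barcodes differ (or are ordered ",
         "differently); align them with load_user_features() or reorder")
  invisible(TRUE)
}

#' Fit configuration for the joint factorization
#'
#' Bundles solver settings for [jnmf_fit()]. The modality weight `alpha`
#' trades the expression block (weight `alpha`) against the image block
#' (weight `2 - alpha`); `alpha = 1` weights both equally, `alpha = 2`
#' ignores the image block, `alpha = 0` ignores expression.
#'
#' @param alpha modality weight in \[0, 2\]; default 1.0 (equal weighting).
#' @param k number of factors (rank), positive integer.
#' @param init initialization strategy, `"random_halfnormal"` or `"nndsvd"`.
#' @param max_outer_iter maximum outer iterations, default 200.
#' @param rel_tol stop when the relative decrease of the joint objective
#'   between outer iterations falls below this; default 1e-6.
#' @param accel_delta inner acceleration: keep sweeping a block while the
#'   per-sweep objective decrease exceeds this fraction of the first sweep's
#'   decrease; default 0.01.
#' @param accel_rho inner sweep cap multiplier: at most
#'   `1 + floor(accel_rho * cost_ratio)` sweeps per block update; default 0.5.
#' @param seed integer seed driving all solver randomness (required for the
#'   half-normal initializer and the zero-column rescue).
#' @param modality_rescale divide each modality by its own Frobenius norm
#'   before fitting so `alpha = 1` genuinely weights both equally regardless
#'   of raw units; default TRUE. The two scalars are stored on the model and
#'   folded back into the returned loadings.
#' @param verbose print objective values during fitting.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(k, alpha = 1.0, init = c("random_halfnormal", "nndsvd"),
                       max_outer_iter = 200L, rel_tol = 1e-6,
                       accel_delta = 0.01, accel_rho = 0.5, seed = 1L,
                       modality_rescale = TRUE, verbose = FALSE) {
  init <- match.arg(init)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("rank k must be a positive integer")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 2)
    stop("alpha must be a single number in [0, 2]")
  max_outer_iter <- as.integer(max_outer_iter)
  if (max_outer_iter < 1L) stop("max_outer_iter must be >= 1")
  if (!is.numeric(rel_tol) || rel_tol <= 0) stop("rel_tol must be > 0")
  structure(list(k = k, alpha = alpha, init = init,
                 max_outer_iter = max_outer_iter, rel_tol = rel_tol,
                 accel_delta = accel_delta, accel_rho = accel_rho,
                 seed = as.integer(seed), modality_rescale = modality_rescale,
                 verbose = verbose),
            class = "fit_config")
}

#' @export
print.spot_expression <- function(x, ...) {
  cat("spot_expression:", nrow(x$values), "spots x", ncol(x$values), "genes\n")
  invisible(x)
}

#' @export
print.spot_image_features <- function(x, ...) {
  cat("spot_image_features:", nrow(x$values), "spots x", ncol(x$values),
      "features\n")
  invisible(x)
}

#' @export
print.joint_factor_model <- function(x, ...) {
  cat("joint_factor_model: k =", x$k, ", alpha =", x$alpha,
      ",", nrow(x$W), "spots\n")
  cat("  outer iterations:", length(x$objective_trace),
      if (isTRUE(x$converged)) "(converged)" else "(max iterations reached)",
      "\n")
  cat("  final objective:", tail(x$objective_trace, 1L), "\n")
  invisible(x)
}
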