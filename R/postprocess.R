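#' Cluster spots on their factor scores
#'
#' Either k-means on the rows of W (`method = "kmeans"`, honouring
#' `n_clusters` exactly) or graph community detection
#' (`method = "graph"`): a k-nearest-neighbour graph on Euclidean distances
#' between W rows, partitioned by Leiden modularity optimization at the
#' given resolution.
#'
#' @param W spot x factor score matrix (e.g. `model$W`).
#' @param method `"kmeans"` or `"graph"`.
#' @param n_clusters number of clusters for k-means.
#' @param n_neighbors neighbours for the kNN graph (graph mode).
#' @param resolution resolution parameter of the modularity objective;
#'   larger values yield more, smaller communities.
#' @param seed integer seed.
#' @return Integer cluster labels, one per spot, named by `rownames(W)`.
#' @export
cluster_factors <- function(W, method = c("kmeans", "graph"),
                            n_clusters = 6L, n_neighbors = 15L,
                            resolution = 1.0, seed = 1L) {
  method <- match.arg(method)
  W <- as.matrix(W)
  m <- nrow(W)
  if (method == "kmeans") {
    if (n_clusters > m)
      stop("n_clusters = ", n_clusters, " exceeds the number of spots ", m)
    km <- with_seed(as.integer(seed),
                    stats::kmeans(W, centers = n_clusters, nstart = 10L,
                                  iter.max = 100L))
    labels <- km$cluster
  } else {
    g <- knn_graph(W, min(n_neighbors, m - 1L))
    comm <- with_seed(as.integer(seed),
                      igraph::cluster_leiden(
                        g, objective_function = "modularity",
                        resolution = resolution, n_iterations = 5L))
    labels <- igraph::membership(comm)
  }
  labels <- as.integer(labels)
  names(labels) <- rownames(W)
  labels
}

# Undirected kNN graph on Euclidean row distances (small m: dense distances).
knn_graph <- function(W, k) {
  m <- nrow(W)
  D <- as.matrix(stats::dist(W))
  edges <- integer(0)
  for (i in seq_len(m)) {
    nb <- order(D[i, ])[2:(k + 1L)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE),
                                   directed = FALSE)
  igraph::simplify(g)
}

# Contingency counts between two label vectors (NAs dropped pairwise).
#' Cluster x reference contingency table
#'
#' Counts of co-assignment between computed cluster labels and reference
#' annotations; spots lacking either label are dropped. The grand total is
#' the number of doubly-labelled spots.
#'
#' @param labels,reference equal-length label vectors.
#' @return A `table` (clusters in rows, reference in columns).
#' @export
contingency_table <- function(labels, reference) {
  if (length(labels) != length(reference))
    stop("labels and reference must have the same length")
  keep <- !is.na(labels) & !is.na(reference)
  table(cluster = labels[keep], reference = reference[keep])
}

#' Partition agreement scores
#'
#' Adjusted Rand index, adjusted mutual information (permutation-model
#' expectation, arithmetic-mean normalization) and the Fowlkes-Mallows
#' index between computed labels and a reference annotation. Spots with a
#' missing reference are excluded and their count reported via the
#' `n_dropped` attribute. All three scores are invariant to relabelling;
#' two identical trivial partitions score 1 by convention.
#'
#' @param labels,reference equal-length label vectors; `NA`s are dropped
#'   pairwise.
#' @return Named numeric vector `c(ari, ami, fowlkes_mallows)` with
#'   attributes `n_used` and `n_dropped`.
#' @export
clustering_scores <- function(labels, reference) {
  if (length(labels) != length(reference))
    stop("labels and reference must have the same length")
  keep <- !is.na(labels) & !is.na(reference)
  tab <- contingency_table(labels, reference)
  out <- c(ari = ari_from_table(tab), ami = ami_from_table(tab),
           fowlkes_mallows = fm_from_table(tab))
  attr(out, "n_used") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

choose2 <- function(x) x * (x - 1) / 2

ari_from_table <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(a)); sum_b <- sum(choose2(b))
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps * max(1, maxi))
    return(1.0)  # both partitions trivial (all-one-cluster or all-singletons)
  (sum_ij - expected) / (maxi - expected)
}

fm_from_table <- function(tab) {
  a <- rowSums(tab); b <- colSums(tab)
  tp <- sum(choose2(tab))
  pa <- sum(choose2(a)); pb <- sum(choose2(b))
  if (pa == 0 || pb == 0) {
    # no within-cluster pairs on one side: identical trivial partitions -> 1
    return(if (pa == pb) 1.0 else 0.0)
  }
  tp / sqrt(pa * pb)
}

entropy_from_counts <- function(cnt) {
  n <- sum(cnt)
  p <- cnt[cnt > 0] / n
  -sum(p * log(p))
}

mi_from_table <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  nij <- tab[idx]
  sum(nij / n * log(n * nij / (a[idx[, 1]] * b[idx[, 2]])))
}

# Expected mutual information under the permutation (hypergeometric) model
# with the observed marginals; standard lgamma form.
expected_mi <- function(a, b) {
  n <- sum(a)
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      for (nij in lo:hi) {
        lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
          lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
          lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
          lgamma(n - ai - bj + nij + 1)
        emi <- emi + exp(lp) * (nij / n) * log(n * nij / (ai * bj))
      }
    }
  }
  emi
}

ami_from_table <- function(tab) {
  a <- rowSums(tab); b <- colSums(tab)
  # conventions for trivial partitions: identical-shape trivial pairs
  # (both one cluster, or both all-singletons) score 1
  if (length(a) == 1L && length(b) == 1L) return(1.0)
  if (all(a == 1) && all(b == 1)) return(1.0)
  hu <- entropy_from_counts(a); hv <- entropy_from_counts(b)
  mi <- mi_from_table(tab)
  emi <- expected_mi(a, b)
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < 1e-12 * max(hu, hv, 1))
    return(if (mi - emi > abs(denom)) 1.0 else 0.0)
  (mi - emi) / denom
}

#' Top genes of a factor
#'
#' Genes ranked by descending loading in one row of `H_rna`; ties are
#' broken by gene identifier so the ranking is deterministic.
#'
#' @param H_rna k x n loading matrix with gene identifiers as column names.
#' @param factor_index which factor (row), 1-based.
#' @param n_top how many genes to return; truncated with a warning if it
#'   exceeds the number of genes.
#' @return data.frame with columns `gene`, `loading`, `rank`.
#' @export
top_genes <- function(H_rna, factor_index, n_top = 150L) {
  if (factor_index < 1L || factor_index > nrow(H_rna))
    stop("factor_index must be in 1..", nrow(H_rna))
  genes <- colnames(H_rna)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(H_rna)))
  load <- H_rna[factor_index, ]
  if (n_top > length(genes)) {
    warning("n_top = ", n_top, " exceeds the number of genes (",
            length(genes), "); returning all genes")
    n_top <- length(genes)
  }
  ord <- order(-load, genes)
  data.frame(gene = genes[ord][seq_len(n_top)],
             loading = unname(load[ord][seq_len(n_top)]),
             rank = seq_len(n_top))
}

#' Pearson correlation of each factor with a target vector
#'
#' Correlates each column of W with a per-spot target (a gene's expression
#' column, an external score, ...). Constant columns or targets yield 0
#' with a warning rather than `NA`, so pipelines survive dead factors.
#'
#' @param W spot x factor matrix.
#' @param target numeric vector of length `nrow(W)`.
#' @return Named numeric vector of per-factor correlations.
#' @export
factor_correlation <- function(W, target) {
  W <- as.matrix(W)
  if (length(target) != nrow(W))
    stop("target length ", length(target), " does not match number of ",
         "spots ", nrow(W))
  r <- vapply(seq_len(ncol(W)), function(j) {
    if (stats::sd(W[, j]) == 0 || stats::sd(target) == 0) {
      warning("constant factor or target; correlation set to 0",
              call. = FALSE)
      return(0)
    }
    stats::cor(W[, j], target)
  }, numeric(1))
  names(r) <- colnames(W)
  r
}

#' Expression signature score per spot
#'
#' Mean expression of a gene set minus the mean of an expression-matched
#' control set: genes are binned by average expression and, for every set
#' gene, `ctrl_per_gene` control genes are sampled from the same bin.
#' Missing set genes are dropped with a warning.
#'
#' @param expr a [spot_expression()] or matrix with gene column names.
#' @param gene_set character vector of gene identifiers.
#' @param n_background_bins number of average-expression bins, default 25.
#' @param ctrl_per_gene control genes sampled per set gene, default 50.
#' @param seed integer seed for the control sampling.
#' @return Numeric per-spot score vector named by barcode.
#' @export
signature_score <- function(expr, gene_set, n_background_bins = 25L,
                            ctrl_per_gene = 50L, seed = 1L) {
  Y <- value_matrix(expr)
  genes <- colnames(Y)
  if (is.null(genes)) stop("expression matrix must carry gene column names")
  hit <- gene_set %in% genes
  if (!all(hit)) {
    warning(sum(!hit), " gene(s) in the set are absent from the matrix ",
            "and were dropped")
    gene_set <- gene_set[hit]
  }
  if (length(gene_set) == 0L)
    stop("no genes of the set are present in the expression matrix")
  avg <- colMeans(Y)
  nb <- min(n_background_bins, length(unique(avg)))
  bins <- as.integer(cut(rank(avg, ties.method = "first"),
                         breaks = nb, labels = FALSE))
  names(bins) <- genes
  ctrl <- with_seed(as.integer(seed), {
    unlist(lapply(gene_set, function(g) {
      pool <- genes[bins == bins[g]]
      if (length(pool) <= ctrl_per_gene) pool
      else sample(pool, ctrl_per_gene)
    }))
  })
  ctrl <- unique(ctrl)
  score <- rowMeans(Y[, gene_set, drop = FALSE]) -
    rowMeans(Y[, ctrl, drop = FALSE])
  names(score) <- rownames(Y)
  score
}
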