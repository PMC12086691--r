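# Clustering, agreement metrics, contingency tables, gene ranking,
# correlations and signature scores.

test_that("kmeans clustering separates block-structured scores", {
  set.seed(1)
  W <- rbind(matrix(rnorm(20 * 2, mean = 0, sd = 0.05), 20, 2) +
               matrix(rep(c(5, 0), each = 20), 20, 2),
             matrix(rnorm(20 * 2, mean = 0, sd = 0.05), 20, 2) +
               matrix(rep(c(0, 5), each = 20), 20, 2))
  truth <- rep(1:2, each = 20)
  lab <- cluster_factors(W, "kmeans", n_clusters = 2, seed = 4)
  expect_equal(unname(clustering_scores(lab, truth)["ari"]), 1)
  expect_identical(lab, cluster_factors(W, "kmeans", n_clusters = 2,
                                        seed = 4))
  expect_error(cluster_factors(W, "kmeans", n_clusters = 100), "exceeds")
})

test_that("graph clustering responds monotonically to resolution", {
  set.seed(6)
  centers <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6), 4, 2, byrow = TRUE)
  W <- centers[rep(1:4, each = 15), ] + matrix(rnorm(120, sd = 0.3), 60, 2)
  counts <- vapply(c(0.3, 1, 3), function(res) {
    length(unique(cluster_factors(W, "graph", n_neighbors = 8,
                                  resolution = res, seed = 2)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  lab <- cluster_factors(W, "graph", n_neighbors = 8, resolution = 1,
                         seed = 2)
  expect_equal(length(lab), 60L)
})

test_that("agreement scores hit the exact trivial and worked cases", {
  x <- c(1, 1, 2, 2, 3)
  sc <- clustering_scores(x, x)
  expect_equal(unname(sc), c(1, 1, 1), ignore_attr = TRUE)
  # relabelling leaves all metrics unchanged
  y <- c(7, 7, 1, 1, 4)
  expect_equal(unname(clustering_scores(x, y)), c(1, 1, 1), ignore_attr = TRUE)
  # contingency [[10,0],[0,5],[2,3]]: labels/reference constructed to match
  labels <- rep(1:3, c(10, 5, 5))
  reference <- c(rep(1, 10), rep(2, 5), rep(1, 2), rep(2, 3))
  expect_equal(unname(contingency_table(labels, reference)),
               matrix(c(10, 0, 2, 0, 5, 3), 3, 2), ignore_attr = TRUE)
  sc2 <- clustering_scores(labels, reference)
  expect_equal(unname(sc2["ari"]), oracle_ari(labels, reference),
               tolerance = 1e-12)
  expect_equal(unname(sc2["fowlkes_mallows"]), oracle_fm(labels, reference),
               tolerance = 1e-12)
  # identical single-cluster partitions are defined as perfect agreement
  expect_equal(unname(clustering_scores(rep(1, 6), rep(2, 6))), c(1, 1, 1),
               ignore_attr = TRUE)
})

test_that("spots without a reference annotation are dropped and reported", {
  labels <- c(1, 1, 2, 2, 1)
  reference <- c(1, 1, 2, NA, NA)
  sc <- clustering_scores(labels, reference)
  expect_equal(attr(sc, "n_used"), 3L)
  expect_equal(attr(sc, "n_dropped"), 2L)
  expect_equal(unname(sc["ari"]), 1)
  expect_equal(sum(contingency_table(labels, reference)), 3)
})

test_that("metrics match brute-force oracles on random label pairs", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    x <- sample(1:4, n, TRUE)
    y <- sample(1:3, n, TRUE)
    sc <- clustering_scores(x, y)
    expect_equal(unname(sc["ari"]), oracle_ari(x, y), tolerance = 1e-10)
    expect_equal(unname(sc["fowlkes_mallows"]), oracle_fm(x, y),
                 tolerance = 1e-10)
  }
  # AMI against the exhaustive permutation expectation (small n)
  for (rep in 1:6) {
    n <- 6
    x <- sample(1:3, n, TRUE)
    y <- sample(1:2, n, TRUE)
    expect_equal(unname(clustering_scores(x, y)["ami"]), oracle_ami(x, y),
                 tolerance = 1e-10)
  }
})

test_that("contingency tables count co-assignments", {
  expect_equal(unname(diag(contingency_table(c(1, 1, 2), c(1, 1, 2)))),
               c(2, 1))
  tab <- contingency_table(c(1, 2, 3), c(5, 6, 7))
  expect_true(all(tab %in% c(0, 1)) && sum(tab) == 3)
})

test_that("top_genes ranks deterministically with identifier tie-breaks", {
  H <- matrix(c(0, 1, 0, 0,
                0.5, 0.5, 3, 0.1), 2, 4, byrow = TRUE,
              dimnames = list(NULL, c("gB", "gA", "gC", "gD")))
  expect_equal(top_genes(H, 1, 1)$gene, "gA")   # one-hot row
  tg <- top_genes(H, 2, 4)
  expect_equal(tg$gene, c("gC", "gA", "gB", "gD"))  # tie gA/gB by name
  expect_setequal(top_genes(H, 1, 4)$gene, colnames(H))
  expect_warning(top_genes(H, 1, 10), "exceeds")
  expect_error(top_genes(H, 3, 1), "factor_index")
})

test_that("factor correlations match the covariance formula", {
  set.seed(44)
  W <- cbind(a = runif(5), b = runif(5), c = runif(5))
  expect_equal(unname(factor_correlation(W, W[, 2])["b"]), 1)
  expect_equal(unname(factor_correlation(W, max(W[, 2]) - W[, 2])["b"]), -1)
  target <- c(3, 1, 4, 1, 5)
  r <- factor_correlation(W, target)
  for (j in 1:3)
    expect_equal(unname(r[j]), oracle_pearson(W[, j], target),
                 tolerance = 1e-12)
  Wc <- cbind(W, d = rep(2, 5))
  expect_warning(rc <- factor_correlation(Wc, target), "constant")
  expect_equal(unname(rc["d"]), 0)
  expect_error(factor_correlation(W, 1:4), "length")
})

test_that("signature scores behave as mean-minus-matched-background", {
  sim <- simulate_joint_data(m = 40, n = 60, f = 10, k = 2, seed = 14)
  expr <- sim$expression
  # whole-transcriptome set: background equals the set, score ~ 0
  s_all <- signature_score(expr, expr$gene_ids, seed = 2)
  expect_lt(max(abs(s_all)), 1e-8)
  # a uniformly-zero gene set can never beat its background
  Y <- expr$values
  Y[, 1:3] <- 0
  expr0 <- spot_expression(Y, expr$barcodes, expr$gene_ids)
  s0 <- signature_score(expr0, expr$gene_ids[1:3], seed = 2)
  expect_lte(max(s0), 1e-12)
  # tiny worked case: few genes per bin, huge control pool -> deterministic
  # control set, so the oracle is a direct mean-minus-background
  set.seed(3)
  M <- matrix(abs(rnorm(5 * 8)), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:8)))
  sc <- signature_score(M, c("g2", "g5"), n_background_bins = 2,
                        ctrl_per_gene = 100, seed = 9)
  avg <- colMeans(M)
  bins <- as.integer(cut(rank(avg, ties.method = "first"), 2, labels = FALSE))
  pool <- unique(unlist(lapply(c("g2", "g5"), function(g)
    colnames(M)[bins == bins[colnames(M) == g]])))
  oracle <- rowMeans(M[, c("g2", "g5")]) - rowMeans(M[, pool])
  expect_equal(unname(sc), unname(oracle), tolerance = 1e-12)
  expect_warning(signature_score(M, c("g2", "nope"), seed = 1), "dropped")
  expect_error(suppressWarnings(signature_score(M, "nope", seed = 1)),
               "no genes")
})
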