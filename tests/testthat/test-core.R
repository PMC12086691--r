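# Joint objective and the A-HALS solver.

test_that("joint_objective matches hand-computable cases", {
  Yr <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]]
  Yi <- matrix(c(1, 1), 2, 1)
  # zero factors: objective is the total energy
  expect_equal(joint_objective(Yr, Yi, W = matrix(0, 2, 1),
                               H_rna = matrix(0, 1, 2),
                               H_img = matrix(0, 1, 1), alpha = 1),
               sum(Yr^2) + sum(Yi^2))
  # exact factorization: zero
  ex <- make_exact_lowrank(5, 6, 3, 2, seed = 42)
  expect_equal(joint_objective(ex$Yr, ex$Yi, ex$W, ex$Hr, ex$Hi, alpha = 1.3),
               0)
  # worked example, checked against an elementwise summation oracle
  W <- matrix(1, 2, 1); Hr <- matrix(c(1, 2), 1, 2); Hi <- matrix(1, 1, 1)
  oracle <- sum((Yr - W %*% Hr)^2) * 1 + sum((Yi - W %*% Hi)^2) * 1
  expect_equal(oracle, 8)   # residual [[0,0],[2,2]] -> 8, image residual 0
  expect_equal(joint_objective(Yr, Yi, W, Hr, Hi, alpha = 1), oracle)
})

test_that("joint_objective names the mismatching axis", {
  Yr <- matrix(1, 3, 4); Yi <- matrix(1, 3, 2)
  W <- matrix(1, 3, 2); Hr <- matrix(1, 2, 4); Hi <- matrix(1, 2, 2)
  expect_error(joint_objective(Yr, Yi, W[1:2, ], Hr, Hi), "spot axis")
  expect_error(joint_objective(Yr, Yi, W, Hr[, 1:3], Hi), "gene axis")
  expect_error(joint_objective(Yr, Yi, W, Hr, Hi[, 1, drop = FALSE]),
               "feature axis")
})

test_that("noiseless rank-1 inputs are recovered to machine-level error", {
  set.seed(7)
  w <- abs(rnorm(30)) + 0.2
  hr <- abs(rnorm(50)) + 0.2
  hi <- abs(rnorm(8)) + 0.2
  Yr <- w %o% hr; Yi <- w %o% hi
  fit <- jnmf_fit(Yr, Yi, fit_config(k = 1, seed = 1, rel_tol = 1e-14,
                                     max_outer_iter = 500))
  expect_lt(norm(Yr - fit$W %*% fit$H_rna, "F") / norm(Yr, "F"), 1e-6)
  expect_lt(norm(Yi - fit$W %*% fit$H_img, "F") / norm(Yi, "F"), 1e-6)
})

test_that("input validation rejects bad matrices and ranks", {
  Yr <- matrix(1, 4, 5); Yi <- matrix(1, 4, 2)
  expect_error(jnmf_fit(Yr - 2, Yi, fit_config(k = 1)), "non-negative")
  expect_error(jnmf_fit(Yr, Yi - 2, fit_config(k = 1)), "non-negative")
  expect_error(fit_config(k = 0), "positive integer")
  expect_error(jnmf_fit(matrix(0, 4, 5), Yi, fit_config(k = 1)),
               "identically zero")
  expect_warning(jnmf_fit(Yr + matrix(runif(20), 4), Yi,
                          fit_config(k = 5, max_outer_iter = 5)),
                 "over-parameterized")
})

test_that("alpha = 2 reduces exactly to the unimodal fit on expression", {
  sim <- simulate_joint_data(m = 50, n = 70, f = 15, k = 3, seed = 4)
  for (init in c("random_halfnormal", "nndsvd")) {
    cfg <- fit_config(k = 3, alpha = 2, init = init, seed = 9)
    fj <- jnmf_fit(sim$expression, sim$features, cfg)
    fu <- jnmf_fit(sim$expression, NULL, cfg)
    expect_equal(length(fj$objective_trace), length(fu$objective_trace))
    expect_lt(max(abs(fj$objective_trace - fu$objective_trace) /
                    fj$objective_trace[1]), 1e-10)
    expect_lt(max(abs(fj$W - fu$W)), 1e-10)
    expect_lt(max(abs(fj$H_rna - fu$H_rna)), 1e-10)
    expect_identical(fj$unweighted_blocks, "img")
  }
})

test_that("objective trace is non-increasing and factors stay non-negative", {
  for (seed in 1:4) {
    sim <- simulate_joint_data(m = 40, n = 55, f = 12, k = 3,
                               snr_rna = 2, seed = seed)
    fit <- jnmf_fit(sim$expression, sim$features,
                    fit_config(k = 3, alpha = 0.7, seed = seed))
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * tr[1]))
    expect_gte(min(fit$W), 0)
    expect_gte(min(fit$H_rna), 0)
    expect_gte(min(fit$H_img), 0)
  }
})

test_that("swapping the modalities and reflecting alpha gives the same fit", {
  sim <- simulate_joint_data(m = 45, n = 60, f = 25, k = 3, seed = 12)
  A <- sim$expression$values; B <- sim$features$values
  for (a in c(0.6, 1.0, 1.4)) {
    f1 <- jnmf_fit(A, B, fit_config(k = 3, alpha = a, init = "nndsvd"))
    f2 <- jnmf_fit(B, A, fit_config(k = 3, alpha = 2 - a, init = "nndsvd"))
    expect_equal(f1$objective_trace, f2$objective_trace, tolerance = 1e-10)
  }
})

test_that("converged objective matches a multiplicative-update oracle", {
  # the joint problem is unimodal NMF on the weighted concatenation
  set.seed(21)
  sim <- simulate_joint_data(m = 60, n = 120, f = 20, k = 3,
                             snr_rna = 8, snr_img = 8, seed = 21)
  a <- 1.0
  Yr <- sim$expression$values; Yi <- sim$features$values
  cfg <- fit_config(k = 3, alpha = a, seed = 3, modality_rescale = FALSE,
                    max_outer_iter = 400, rel_tol = 1e-9)
  fit <- jnmf_fit(Yr, Yi, cfg)
  obj_fit <- tail(fit$objective_trace, 1)
  Ycat <- cbind(sqrt(a) * Yr, sqrt(2 - a) * Yi)
  ini <- init_nndsvd(Ycat, 3)
  mu <- mu_nmf(Ycat, pmax(ini$W0, 1e-6), pmax(ini$H0, 1e-6), n_iter = 3000L)
  expect_lt(abs(obj_fit - mu$objective) / mu$objective, 0.01)
})

test_that("modality rescaling stores divisors and keeps loadings on the input scale", {
  ex <- make_exact_lowrank(25, 30, 8, 2, seed = 5)
  fit <- jnmf_fit(ex$Yr, ex$Yi, fit_config(k = 2, init = "nndsvd",
                                           rel_tol = 1e-12,
                                           max_outer_iter = 500))
  expect_equal(unname(fit$rescale["rna"]), norm(ex$Yr, "F"))
  # loadings folded back: W %*% H_rna approximates the *raw* input
  expect_lt(norm(ex$Yr - fit$W %*% fit$H_rna, "F") / norm(ex$Yr, "F"), 1e-3)
  # W columns are unit norm
  expect_equal(unname(sqrt(colSums(fit$W^2))), rep(1, 2), tolerance = 1e-8)
})

test_that("transform reproduces training scores and maps zero to zero", {
  sim <- simulate_joint_data(m = 60, n = 80, f = 18, k = 3, snr_rna = 20,
                             snr_img = 20, seed = 6)
  fit <- jnmf_fit(sim$expression, sim$features,
                  fit_config(k = 3, seed = 6, rel_tol = 1e-10,
                             max_outer_iter = 500))
  W_new <- jnmf_transform(fit, sim$expression$values, sim$features$values)
  # fixed-point consistency of the converged W-step
  expect_lt(max(abs(W_new - fit$W)), 1e-4)
  W0 <- jnmf_transform(fit, matrix(0, 3, 80), matrix(0, 3, 18))
  expect_equal(unname(W0), matrix(0, 3, 3))
  # a single new spot copied from training correlates with its training row
  j <- 17L
  W1 <- jnmf_transform(fit, sim$expression$values[j, , drop = FALSE],
                       sim$features$values[j, , drop = FALSE])
  expect_gt(cor(as.numeric(W1), fit$W[j, ]), 0.99)
  expect_error(jnmf_transform(fit, matrix(0, 2, 79)), "gene axis")
})
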