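test_that("propagation cost matches the naive trace and its degenerate cases", {
  set.seed(41)
  W <- rand_rln(15, k = 5)
  Y0 <- matrix(rbinom(15 * 6, 1, 0.4), 15, 6)
  expect_equal(compute_cost(W, Y0), bf_cost(unclass(W), Y0))

  # constant all-ones columns are invisible to a row-stochastic graph
  expect_equal(compute_cost(W, matrix(1, 15, 3)), 0, tolerance = 1e-10)
  expect_equal(compute_cost(W, matrix(0, 15, 3)), 0)
  expect_error(compute_cost(W, matrix(0, 9, 3)), "same drugs")
})

test_that("auto-delta weights follow the closed form and exclude the worst view", {
  sol <- estimate_weights(c(1, 3), alpha = 0.8)
  expect_equal(sol$theta, c(1, 0))

  expect_warning(u <- estimate_weights(c(2, 2, 2)), "equal")
  expect_equal(u$theta, rep(1 / 3, 3))

  set.seed(42)
  for (rep in 1:20) {
    K <- sample(2:10, 1)
    costs <- runif(K, 0, 50)
    alpha <- runif(1, 0.1, 1)
    sol <- estimate_weights(costs, alpha = alpha)
    cmax <- max(costs)
    expect_identical(sol$theta, (cmax - costs) / sum(cmax - costs))
    expect_equal(sol$theta[which.max(costs)], 0)
    expect_equal(sum(sol$theta), 1, tolerance = 1e-10)
    # translation invariance of the auto-delta closed form
    shifted <- estimate_weights(costs + 17.3, alpha = alpha)
    expect_equal(shifted$theta, sol$theta, tolerance = 1e-12)
    # auto-delta cancels alpha
    expect_equal(estimate_weights(costs, alpha = 0.123)$theta, sol$theta)
  }
})

test_that("estimated weights satisfy the KKT system and match a numerical QP", {
  set.seed(43)
  for (rep in 1:30) {
    K <- sample(2:10, 1)
    costs <- runif(K, 0, 20)
    alpha <- runif(1, 0.1, 1)
    delta <- if (rep %% 2) runif(1, 0.05, 10) else "auto"
    sol <- estimate_weights(costs, alpha = alpha, delta = delta)
    d <- sol$delta

    # stationarity / primal / dual feasibility / complementary slackness
    stat <- 2 * d * sol$theta + alpha * costs - sol$lagrange_lambda - sol$eta
    expect_lt(max(abs(stat)), 1e-8)
    expect_lt(abs(sum(sol$theta) - 1), 1e-10)
    expect_gte(min(sol$theta), 0)
    expect_gte(min(sol$eta), -1e-12)
    expect_lt(max(abs(sol$eta * sol$theta)), 1e-8)

    # independent numerical minimizer of delta*||theta||^2 + alpha*C'theta
    qp <- quadprog::solve.QP(2 * d * diag(K) + 1e-12 * diag(K),
                             -alpha * costs,
                             cbind(rep(1, K), diag(K)), c(1, rep(0, K)),
                             meq = 1)
    expect_equal(sol$theta, qp$solution, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("similarity integration is an exact convex combination", {
  set.seed(44)
  W1 <- rand_rln(12, k = 4)
  W2 <- rand_rln(12, k = 6, prob = 0.6)
  expect_equal(integrate_similarities(list(W1, W2), c(1, 0)), W1,
               ignore_attr = TRUE)
  Wm <- integrate_similarities(list(W1, W2), c(0.3, 0.7))
  expect_equal(strip(Wm), 0.3 * strip(W1) + 0.7 * strip(W2))
  expect_equal(rowSums(Wm), rep(1, 12), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(diag(Wm), rep(0, 12), ignore_attr = TRUE)
  expect_error(integrate_similarities(list(W1, W2), c(0.6, 0.6)), "simplex")
})

test_that("multi-view prediction reduces correctly in degenerate setups", {
  b <- small_bundle(n = 25, seed = 13, info = c(0.8, 0.8))
  cfg <- similarity_config("rln", k = 1)
  X_new <- lapply(b$views, function(v) unclass(v)[6, , drop = FALSE])

  # new drug identical to training drug 6 in all views, K = 1: row 6 of Y0
  fit <- lnsm_smi_predict(b, X_new, sim_cfg = cfg, alpha = 0.8)
  expect_equal(as.numeric(fit$scores), as.numeric(b$associations[6, ]),
               tolerance = 1e-10)

  # single view: reduces to W_new %*% Y0
  b1 <- align_bundle(b$views[1], b$associations)
  fit1 <- suppressWarnings(
    lnsm_smi_predict(b1, X_new[1], sim_cfg = similarity_config("rln", k = 5)))
  w <- similarity_to_new(b1$views[[1]], X_new[[1]][1, ],
                         similarity_config("rln", k = 5))
  expect_equal(as.numeric(fit1$scores),
               as.numeric(w %*% unclass(b1$associations)))
  expect_equal(fit1$weights$theta, 1)
})

test_that("the informative view out-weighs the noise view", {
  b <- small_bundle(n = 60, seed = 17, info = c(0.9, 0))
  cfg <- similarity_config("rln", k = 20)
  W <- lapply(b$views, build_similarity_matrix, cfg = cfg)
  costs <- vapply(W, compute_cost, numeric(1), Y0 = unclass(b$associations))
  theta <- estimate_weights(costs)$theta
  expect_gt(theta[1], theta[2])
})
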