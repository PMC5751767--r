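test_that("nearest neighbors match hand computation and brute-force sort", {
  X <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1))
  rownames(X) <- paste0("d", 1:3); colnames(X) <- paste0("f", 1:3)
  nbr <- find_neighbors(X, 1, 1)
  expect_identical(nbr$neighbor_indices, 2L)   # distance 1 beats sqrt(3)
  expect_equal(unname(nbr$distances), 1)
  expect_setequal(find_neighbors(X, 2, 2)$neighbor_indices, c(1L, 3L))

  set.seed(21)
  X <- rand_binary(20, 10)
  for (center in c(1, 7, 20))
    for (k in c(1, 5, 19, 50))  # k > N-1 must cap
      expect_identical(find_neighbors(X, center, k)$neighbor_indices,
                       bf_neighbors(X, center, k))
})

test_that("Gram matrix equals stacked difference outer product", {
  set.seed(22)
  X <- rand_binary(12, 8)
  nbr <- find_neighbors(X, 3, 5)
  G <- compute_gram(X, nbr)
  D <- t(apply(X[nbr$neighbor_indices, ], 1, function(r) X[3, ] - r))
  expect_equal(G, D %*% t(D), ignore_attr = TRUE)
  expect_equal(diag(G), nbr$distances^2, ignore_attr = TRUE)

  # a neighbor identical to the center zeroes its row and column
  X[4, ] <- X[3, ]
  nbr <- find_neighbors(X, 3, 4)
  G <- compute_gram(X, nbr)
  j <- which(nbr$neighbor_indices == 4)
  expect_true(all(G[j, ] == 0) && all(G[, j] == 0))

  # single neighbor at distance d gives the 1x1 matrix [d^2]
  nbr1 <- find_neighbors(X, 1, 1)
  expect_equal(as.numeric(compute_gram(X, nbr1)), unname(nbr1$distances)^2)
})

test_that("reconstruction weights solve the simplex QP", {
  expect_equal(solve_neighbor_weights(matrix(5), 0), 1)   # forced by constraint

  # two identical neighbors share the weight under the strictly convex RLN
  G <- matrix(2, 2, 2)
  expect_equal(solve_neighbor_weights(G, 1), c(0.5, 0.5), tolerance = 1e-8)

  # grid-search oracle at K = 3
  set.seed(23)
  grid <- simplex_grid(3, 0.01)
  for (rep in 1:25) {
    X <- rand_binary(8, 10)
    nbr <- find_neighbors(X, 1, 3)
    G <- compute_gram(X, nbr)
    for (lambda in c(0, 1)) {
      H <- G + diag(lambda, 3)
      w <- tryCatch(solve_neighbor_weights(G, lambda),
                    lnside_singular_gram = function(e) NULL)
      if (is.null(w)) next
      obj <- drop(t(w) %*% H %*% w)
      grid_min <- min(rowSums((grid %*% H) * grid))
      expect_lte(obj, grid_min + 1e-3)
      expect_equal(sum(w), 1, tolerance = 1e-8)
      expect_gte(min(w), 0)
    }
  }
})

test_that("similarity matrix rows agree with an independent interior-point solve", {
  set.seed(24)
  X <- suppressWarnings(feature_matrix(rand_binary(30, 15)))
  cfg <- similarity_config("rln", k = 8)
  W <- build_similarity_matrix(X, cfg)
  expect_equal(rowSums(W), rep(1, 30), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(diag(W), rep(0, 30), ignore_attr = TRUE)
  expect_true(all(W >= 0))
  expect_true(all(rowSums(W > 0) <= 8))

  for (i in sample(30, 5)) {
    nbr <- find_neighbors(X, i, 8)
    H <- 2 * (compute_gram(X, nbr) + diag(8))
    ip <- kernlab::ipop(rep(0, 8), H, matrix(1, 1, 8), 1, rep(0, 8),
                        rep(1, 8), 0, sigf = 9)
    w_oracle <- kernlab::primal(ip)
    expect_equal(W[i, nbr$neighbor_indices], w_oracle,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("two drugs with one neighbor produce the exchange matrix", {
  X <- suppressWarnings(feature_matrix(rbind(c(1, 0), c(0, 1)),
                                       drug_ids = c("a", "b"),
                                       descriptor_ids = c("f1", "f2")))
  W <- build_similarity_matrix(X, similarity_config("rln", k = 1))
  expect_equal(strip(W), matrix(c(0, 1, 1, 0), 2,
               dimnames = list(c("a", "b"), c("a", "b"))))
})

test_that("reconstruction error of binary data is bounded by the dimension p", {
  # the regularization argument: w'Gw <= p on the simplex justifies lambda = 1
  set.seed(25)
  for (rep in 1:20) {
    n <- sample(6:15, 1); p <- sample(4:12, 1)
    X <- rand_binary(n, p)
    nbr <- find_neighbors(X, 1, min(4, n - 1))
    G <- compute_gram(X, nbr)
    w <- solve_neighbor_weights(G, 1)
    expect_lte(drop(t(w) %*% G %*% w), p)
  }
})

test_that("baseline similarities match direct set arithmetic", {
  X <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1),
             d = c(1, 0, 1, 0))
  colnames(X) <- paste0("f", 1:4)
  J <- baseline_similarity(X, "jaccard")
  Cs <- baseline_similarity(X, "cosine")
  Gs <- baseline_similarity(X, "gauss")
  expect_equal(J["a", "b"], 1)          # identical rows
  expect_equal(Cs["a", "b"], 1)
  expect_equal(Gs["a", "b"], 1)
  expect_equal(J["a", "c"], 0)          # disjoint supports
  expect_equal(Cs["a", "c"], 0)
  expect_true(all(diag(J) == 0) && all(diag(Cs) == 0) && all(diag(Gs) == 0))

  set.seed(26)
  Y <- rand_binary(10, 12)
  J <- baseline_similarity(Y, "jaccard")
  Cs <- baseline_similarity(Y, "cosine")
  Gs <- baseline_similarity(Y, "gauss", gamma = 0.05)
  for (pair in list(c(1, 2), c(3, 9), c(5, 10))) {
    x <- Y[pair[1], ]; y <- Y[pair[2], ]
    expect_equal(J[pair[1], pair[2]], sum(x & y) / sum(x | y))
    expect_equal(Cs[pair[1], pair[2]],
                 sum(x * y) / sqrt(sum(x^2) * sum(y^2)))
    expect_equal(Gs[pair[1], pair[2]], exp(-0.05 * sum((x - y)^2)))
  }
})

test_that("out-of-sample weights are simplex-valid and leave-one-out consistent", {
  set.seed(27)
  X <- suppressWarnings(feature_matrix(rand_binary(25, 12)))
  cfg <- similarity_config("rln", k = 6)

  # a copy of training drug j with a single neighbor puts all weight on j
  w <- similarity_to_new(X, X[9, ], similarity_config("rln", k = 1))
  expect_equal(unname(w[9]), 1)

  for (rep in 1:5) {
    x_new <- rbinom(12, 1, 0.5)
    w <- similarity_to_new(X, x_new, cfg)
    expect_equal(sum(w), 1, tolerance = 1e-8)
    expect_gte(min(w), 0)
  }

  # holding out row i and querying it reproduces row i of the full-set matrix
  W_full <- build_similarity_matrix(X, cfg)
  for (i in c(2, 14, 25)) {
    Xtr <- suppressWarnings(feature_matrix(unclass(X)[-i, ]))
    w <- similarity_to_new(Xtr, X[i, ], cfg)
    full_row <- W_full[i, -i]
    expect_equal(unname(w), unname(full_row), tolerance = 1e-8)
  }
})

test_that("duplicated drugs break LN but not RLN", {
  set.seed(28)
  base <- rand_binary(5, 10)
  X <- suppressWarnings(feature_matrix(
    rbind(base, base[1:3, ]),
    drug_ids = sprintf("d%02d", 1:8)))
  expect_error(build_similarity_matrix(X, similarity_config("ln", k = 4)),
               class = "lnside_singular_gram")
  expect_error(build_similarity_matrix(X, similarity_config("ln", k = 4)),
               "RLN")
  W <- build_similarity_matrix(X, similarity_config("rln", k = 4))
  expect_equal(rowSums(W), rep(1, 8), tolerance = 1e-8, ignore_attr = TRUE)
})
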