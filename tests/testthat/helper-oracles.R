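# Independent oracles and small fixture builders. Everything here is
# deliberately naive (loops, enumeration, closed forms) and shares no code
# with the package internals it checks.

# all points of the probability simplex in K dims on a grid of given step
simplex_grid <- function(K, step = 0.01) {
  m <- round(1 / step)
  if (K == 2) {
    i <- 0:m
    return(cbind(i, m - i) / m)
  }
  stopifnot(K == 3)
  pts <- do.call(rbind, lapply(0:m, function(i)
    cbind(i, 0:(m - i), m - i - 0:(m - i))))
  pts / m
}

# exhaustive distance sort for neighbor sets
bf_neighbors <- function(X, center, k) {
  d <- apply(X, 1, function(r) sqrt(sum((r - X[center, ])^2)))
  ord <- order(d, seq_len(nrow(X)))
  setdiff(ord, center)[seq_len(min(k, nrow(X) - 1))]
}

# naive elementwise trace((Y0)'(I - W) Y0) by explicit summation
bf_cost <- function(W, Y0) {
  IW <- diag(nrow(W)) - W
  total <- 0
  for (m in seq_len(ncol(Y0)))
    for (i in seq_len(nrow(W)))
      for (j in seq_len(nrow(W)))
        total <- total + Y0[i, m] * IW[i, j] * Y0[j, m]
  total
}

# --- multi-label metric enumerations (same tie conventions as documented:
# average ranks for coverage, argmax-set for one-error, half-count ties in
# ranking loss, index-broken descending order for average precision) ---

bf_one_error <- function(scores, truth) {
  errs <- c()
  for (i in seq_len(nrow(scores))) {
    y <- truth[i, ]
    if (sum(y) == 0) next
    top <- which(scores[i, ] == max(scores[i, ]))
    errs <- c(errs, as.numeric(!any(y[top] == 1)))
  }
  mean(errs)
}

bf_coverage <- function(scores, truth) {
  covs <- c()
  for (i in seq_len(nrow(scores))) {
    y <- truth[i, ]
    if (sum(y) == 0) next
    s <- scores[i, ]
    ranks <- sapply(seq_along(s), function(j)
      sum(s > s[j]) + (sum(s == s[j]) + 1) / 2)
    covs <- c(covs, max(ranks[y == 1]) - 1)
  }
  mean(covs)
}

bf_ranking_loss <- function(scores, truth) {
  rls <- c()
  for (i in seq_len(nrow(scores))) {
    y <- truth[i, ]
    pos <- which(y == 1); neg <- which(y == 0)
    if (!length(pos) || !length(neg)) next
    bad <- 0
    for (a in pos) for (b in neg) {
      if (scores[i, a] < scores[i, b]) bad <- bad + 1
      if (scores[i, a] == scores[i, b]) bad <- bad + 0.5
    }
    rls <- c(rls, bad / (length(pos) * length(neg)))
  }
  mean(rls)
}

bf_average_precision <- function(scores, truth) {
  aps <- c()
  for (i in seq_len(nrow(scores))) {
    y <- truth[i, ]
    if (sum(y) == 0) next
    ord <- order(-scores[i, ], seq_along(y))
    ysort <- y[ord]
    precs <- sapply(which(ysort == 1), function(r) sum(ysort[1:r]) / r)
    aps <- c(aps, mean(precs))
  }
  mean(aps)
}

bf_hamming <- function(scores, truth, thr = 0.5)
  mean((scores >= thr) != truth)

# Mann-Whitney U statistic AUC
bf_auc_mw <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  u <- 0
  for (a in pos) for (b in neg)
    u <- u + (a > b) + 0.5 * (a == b)
  u / (length(pos) * length(neg))
}

# step-curve average precision, ties broken by original index
bf_aupr_step <- function(scores, truth) {
  ord <- order(-scores, seq_along(scores))
  y <- truth[ord]
  tp <- 0; precs <- c()
  for (r in seq_along(y)) {
    if (y[r] == 1) {
      tp <- tp + 1
      precs <- c(precs, tp / r)
    }
  }
  mean(precs)
}

# drop container class/attributes, keep dim + dimnames
strip <- function(m) {
  m <- unclass(m)
  attr(m, "view_name") <- NULL
  attr(m, "method") <- NULL
  attr(m, "k") <- NULL
  m
}

# random binary matrix with guaranteed valid feature-matrix shape
rand_binary <- function(n, p, prob = 0.4) {
  matrix(rbinom(n * p, 1, prob), n, p,
         dimnames = list(sprintf("d%03d", seq_len(n)),
                         sprintf("f%03d", seq_len(p))))
}

# small RLN similarity from a random binary matrix (helper for propagation
# tests that just need some valid row-stochastic zero-diagonal W)
rand_rln <- function(n, p = 12, k = max(2, n %/% 3), prob = 0.4) {
  X <- suppressWarnings(feature_matrix(rand_binary(n, p, prob)))
  build_similarity_matrix(X, similarity_config("rln", k = k))
}

# symmetric doubly-stochastic zero-diagonal W: mixture of symmetrized
# fixed-point-free permutation matrices
rand_symmetric_w <- function(n, n_perm = 3) {
  W <- matrix(0, n, n)
  wts <- runif(n_perm); wts <- wts / sum(wts)
  for (m in seq_len(n_perm)) {
    repeat {
      perm <- sample(n)
      if (all(perm != seq_len(n))) break
    }
    P <- diag(n)[perm, ]
    W <- W + wts[m] * (P + t(P)) / 2
  }
  W
}

small_bundle <- function(n = 60, seed = 3, info = c(0.9, 0)) {
  generate_dataset(generator_config(
    n_drugs = n, view_informativeness = info, seed = seed))
}
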