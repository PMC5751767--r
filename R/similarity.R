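# Linear neighborhood (LN/RLN) similarity. Each drug is reconstructed as a
# convex combination of its K nearest neighbors in feature space by solving
#
#   min_w  w' (G + lambda I) w   s.t.  sum(w) = 1, w >= 0,
#
# where G[j, k] = (x - x_j) . (x - x_k) is the Gram matrix of difference
# vectors. The optimal weights are the similarities between the drug and its
# neighbors; stacking them row-wise gives a sparse, row-stochastic,
# zero-diagonal similarity matrix W. lambda = 0 is "LN" similarity; the
# ridge-regularized lambda = 1 variant is "RLN". For binary features the
# reconstruction error is bounded by the feature dimension p, and since
# ||w||^2 <= 1 on the simplex, lambda = 1 keeps the error term dominant.

#' Similarity configuration
#'
#' @param method `"rln"` (default) or `"ln"` for the linear neighborhood
#'   similarities, or one of the dense baselines `"jaccard"`, `"cosine"`,
#'   `"gauss"`.
#' @param k neighbor count for LN/RLN; silently capped at N-1 when it
#'   exceeds the number of available drugs.
#' @param lambda ridge weight of the reconstruction program; defaults to 0
#'   for `"ln"` and 1 for `"rln"`.
#' @param gamma Gaussian bandwidth for `method = "gauss"`; defaults to `1/p`.
#' @return a list of class `"similarity_config"`.
#' @export
similarity_config <- function(method = c("rln", "ln", "jaccard", "cosine", "gauss"),
                              k = 400L, lambda = NULL, gamma = NULL) {
  method <- match.arg(method)
  if (is.null(lambda)) lambda <- switch(method, ln = 0, rln = 1, 0)
  if (lambda < 0) stop("lambda must be nonnegative")
  if (k < 1L) stop("k must be at least 1")
  structure(list(method = method, k = as.integer(k), lambda = lambda,
                 gamma = gamma),
            class = "similarity_config")
}

#' Find the K nearest neighbors of one drug
#'
#' Euclidean distance on the raw binary feature vectors, self excluded;
#' ties broken by ascending drug index. `k` is truncated to N-1.
#'
#' @param X feature matrix (drugs x descriptors).
#' @param center_index row index of the query drug (1-based).
#' @param k requested neighbor count.
#' @return list with `center_index`, integer `neighbor_indices`, and their
#'   `distances`.
#' @export
find_neighbors <- function(X, center_index, k) {
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 drugs to define neighbors")
  if (center_index < 1L || center_index > n) stop("center_index out of range")
  k <- min(as.integer(k), n - 1L)
  d2 <- rowSums(sweep(X, 2L, X[center_index, ], `-`)^2)
  d2[center_index] <- Inf
  ord <- order(d2, seq_len(n))[seq_len(k)]
  list(center_index = center_index, neighbor_indices = ord,
       distances = sqrt(d2[ord]))
}

#' Gram matrix of neighbor difference vectors
#'
#' Entry (j, k) is the inner product of the difference vectors from the
#' center drug to neighbors j and k; the diagonal holds squared
#' center-neighbor distances.
#'
#' @param X feature matrix.
#' @param nbr a [find_neighbors()] result.
#' @return symmetric K x K matrix.
#' @export
compute_gram <- function(X, nbr) {
  center <- X[nbr$center_index, ]
  D <- sweep(-X[nbr$neighbor_indices, , drop = FALSE], 2L, -center)
  tcrossprod(D)
}

#' Solve the per-drug reconstruction weights
#'
#' Minimizes `w' (G + lambda I) w` over the probability simplex with a dual
#' active-set quadratic program ([quadprog::solve.QP()]). With `lambda = 0`
#' the Hessian is the raw Gram matrix, which is singular whenever the
#' difference vectors are linearly dependent (duplicate drugs, or more
#' neighbors than descriptors); that case is reported with a diagnostic
#' advising the regularized (RLN, `lambda = 1`) variant, whose Hessian is
#' always positive definite.
#'
#' @param G Gram matrix from [compute_gram()].
#' @param lambda nonnegative ridge weight.
#' @return numeric weight vector on the simplex (sums to 1, entries >= 0).
#' @export
solve_neighbor_weights <- function(G, lambda = 1) {
  G <- as.matrix(G)
  k <- nrow(G)
  if (lambda < 0) stop("lambda must be nonnegative")
  if (k == 1L) return(1)
  H <- 2 * (G + diag(lambda, k))
  Amat <- cbind(rep(1, k), diag(k))
  sol <- tryCatch(
    quadprog::solve.QP(H, rep(0, k), Amat, c(1, rep(0, k)), meq = 1L),
    error = function(e) e)
  if (inherits(sol, "error")) {
    if (lambda == 0)
      stop(singular_gram_condition(conditionMessage(sol)))
    stop("quadratic program failed (lambda = ", lambda, "): ",
         conditionMessage(sol))
  }
  w <- sol$solution
  if (min(w) < -1e-6)
    stop("quadratic program returned weight ", min(w),
         " below the -1e-6 clipping limit")
  w[w < 0] <- 0
  w / sum(w)
}

singular_gram_condition <- function(detail) {
  structure(
    class = c("lnside_singular_gram", "error", "condition"),
    list(message = paste0(
           "LN similarity failed: the Gram matrix of neighbor differences is ",
           "singular (", detail, "). Use the regularized RLN similarity ",
           "(lambda = 1) instead."),
         call = NULL))
}

#' Build the N x N linear neighborhood similarity matrix
#'
#' Row i holds drug i's reconstruction weights scattered to its neighbors'
#' columns; every row sums to 1 and the diagonal is zero.
#'
#' @param X feature matrix.
#' @param cfg a [similarity_config()] with method `"ln"` or `"rln"`.
#' @return N x N matrix of class `"similarity_matrix"` with attributes
#'   `method` and `k`.
#' @export
build_similarity_matrix <- function(X, cfg = similarity_config()) {
  if (!cfg$method %in% c("ln", "rln"))
    stop("build_similarity_matrix needs method 'ln' or 'rln'; see ",
         "baseline_similarity() for ", cfg$method)
  n <- nrow(X)
  k <- min(cfg$k, n - 1L)
  W <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) {
    nbr <- find_neighbors(X, i, k)
    w <- tryCatch(solve_neighbor_weights(compute_gram(X, nbr), cfg$lambda),
                  error = function(e) e)
    if (inherits(w, "lnside_singular_gram"))
      stop(singular_gram_condition(paste0("drug '", rownames(X)[i] %||% i, "'")))
    if (inherits(w, "error"))
      stop("similarity failed for drug '", rownames(X)[i] %||% i, "': ",
           conditionMessage(w))
    W[i, nbr$neighbor_indices] <- w
  }
  structure(W, class = c("similarity_matrix", class(W)),
            method = cfg$method, k = k)
}

#' Dense baseline similarities (Jaccard, cosine, Gaussian)
#'
#' Computed on all drug pairs with no neighbor sparsification and no row
#' normalization; the diagonal is forced to zero. Conventions: Jaccard of
#' two all-zero rows is 0; cosine is 0 when either row has zero norm.
#'
#' @param X feature matrix.
#' @param method `"jaccard"`, `"cosine"`, or `"gauss"`.
#' @param gamma Gaussian bandwidth (`gauss` only); default `1/ncol(X)`.
#' @return N x N `"similarity_matrix"` (not row-stochastic).
#' @export
baseline_similarity <- function(X, method = c("jaccard", "cosine", "gauss"),
                                gamma = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  S <- switch(method,
    jaccard = {
      inter <- tcrossprod(X)
      r <- rowSums(X)
      uni <- outer(r, r, `+`) - inter
      out <- inter / uni
      out[uni == 0] <- 0
      out
    },
    cosine = {
      nrm <- sqrt(rowSums(X^2))
      out <- tcrossprod(X) / outer(nrm, nrm)
      out[outer(nrm, nrm) == 0] <- 0
      out
    },
    gauss = {
      if (is.null(gamma)) gamma <- 1 / ncol(X)
      if (gamma <= 0) stop("gamma must be positive")
      r <- rowSums(X^2)
      d2 <- pmax(outer(r, r, `+`) - 2 * tcrossprod(X), 0)
      exp(-gamma * d2)
    })
  diag(S) <- 0
  dimnames(S) <- list(rownames(X), rownames(X))
  structure(S, class = c("similarity_matrix", class(S)),
            method = method, k = nrow(X) - 1L)
}

#' Out-of-sample similarity vector for a new drug
#'
#' Finds the new drug's nearest neighbors among the training drugs and
#' solves the same reconstruction program with the new drug as center,
#' returning the weights scattered to a length-N vector that sums to 1.
#'
#' @param X_train training feature matrix (N x p).
#' @param x_new binary vector of length p (or a 1 x p matrix).
#' @param cfg a [similarity_config()] with method `"ln"` or `"rln"`.
#' @return numeric length-N vector named by training drug ids.
#' @export
similarity_to_new <- function(X_train, x_new, cfg = similarity_config()) {
  if (!cfg$method %in% c("ln", "rln"))
    stop("out-of-sample similarity requires method 'ln' or 'rln'")
  x_new <- as.numeric(x_new)
  if (length(x_new) != ncol(X_train))
    stop("new drug vector has length ", length(x_new),
         " but the training view has ", ncol(X_train), " descriptors")
  n <- nrow(X_train)
  k <- min(cfg$k, n)
  d2 <- rowSums(sweep(X_train, 2L, x_new, `-`)^2)
  ord <- order(d2, seq_len(n))[seq_len(k)]
  D <- sweep(-X_train[ord, , drop = FALSE], 2L, -x_new)
  w <- solve_neighbor_weights(tcrossprod(D), cfg$lambda)
  out <- numeric(n)
  out[ord] <- w
  names(out) <- rownames(X_train)
  out
}

# Out-of-sample weight vectors for many new drugs at once: rows of the
# returned matrix are similarity_to_new() results.
oos_weight_matrix <- function(X_train, X_new, cfg) {
  W <- matrix(0, nrow(X_new), nrow(X_train),
              dimnames = list(rownames(X_new), rownames(X_train)))
  for (i in seq_len(nrow(X_new)))
    W[i, ] <- similarity_to_new(X_train, X_new[i, ], cfg)
  W
}

# Validates the LN/RLN similarity contract; used before propagation.
assert_row_stochastic <- function(W, tol = 1e-6) {
  if (any(W < -1e-10)) stop("similarity matrix has negative entries")
  if (any(abs(diag(W)) > 1e-12)) stop("similarity matrix has nonzero diagonal")
  dev <- max(abs(rowSums(W) - 1))
  if (dev > tol)
    stop("similarity matrix is not row-stochastic (max row-sum deviation ",
         signif(dev, 3), "); label propagation requires LN/RLN similarity")
  invisible(TRUE)
}
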