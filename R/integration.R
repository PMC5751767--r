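# Similarity matrix integration (LNSM-SMI). Per-view similarity matrices
# W_1..W_K are combined linearly with simplex weights theta. Fixing the
# label matrix at Y0, the weights minimize
#
#   alpha * sum_i theta_i c_i + delta * ||theta||^2,
#   c_i = trace(Y0' (I - W_i) Y0),
#
# over the probability simplex. The minimizer is the Euclidean projection
# of -alpha * C / (2 delta) onto the simplex, so it has a closed form
# obtained by sorting the per-view costs. Choosing
# delta = (alpha / 2) * sum_k (c_max - c_k) makes every view active except
# those attaining the worst cost and collapses the solution to
#
#   theta_i = (c_max - c_i) / sum_k (c_max - c_k),
#
# with Lagrange multiplier lambda = alpha * c_max and eta = 0. Views whose
# similarity graph keeps the observed labels smooth (small c_i) gain large
# weights; the worst view is excluded entirely.

#' Per-view propagation cost
#'
#' `trace(Y0' (I - W) Y0)` computed without forming the full product; small
#' values mean the observed labels vary little across the view's similarity
#' graph, i.e. the view is informative about side effects.
#'
#' @param W similarity matrix for one feature view.
#' @param Y0 binary association matrix aligned with `W`.
#' @return scalar cost.
#' @export
compute_cost <- function(W, Y0) {
  Y0 <- unclass_matrix(Y0)
  if (nrow(W) != ncol(W) || nrow(Y0) != nrow(W))
    stop("cost requires W (N x N) and Y0 (N x M) on the same drugs")
  sum(Y0 * (Y0 - W %*% Y0))
}

#' Estimate simplex weights for similarity matrix integration
#'
#' Solves `min_theta alpha * C' theta + delta * ||theta||^2` over the
#' probability simplex. With `delta = "auto"` the regularizer is set to
#' `(alpha / 2) * sum_k (c_max - c_k)`, which yields the simple closed form
#' `theta_i = (c_max - c_i) / sum_k (c_max - c_k)` (the alpha value then
#' cancels and only needs to be positive). An explicit `delta` is handled by
#' the exact sorted-threshold simplex projection. When all costs are equal
#' (including the single-view case) the objective cannot distinguish views
#' and uniform weights are returned with a warning.
#'
#' @param costs numeric cost vector, one entry per feature view (see
#'   [compute_cost()]); names are carried through as view names.
#' @param alpha absorbing probability weighting the cost term; must be > 0.
#' @param delta `"auto"` or a positive scalar regularization weight.
#' @return a list of class `"integration_solution"` with elements `theta`
#'   (simplex weights), `delta`, `lagrange_lambda`, `eta` (nonnegativity
#'   multipliers), `costs`, and `view_names`.
#' @export
estimate_weights <- function(costs, alpha = 0.8, delta = "auto") {
  if (!length(costs)) stop("need at least one cost")
  if (alpha <= 0) stop("alpha must be positive")
  K <- length(costs)
  nms <- names(costs) %||% paste0("view", seq_len(K))
  costs <- as.numeric(costs)
  cmax <- max(costs)
  spread <- sum(cmax - costs)
  if (spread <= max(1e-12, 1e-12 * abs(cmax)) * K) {
    warning("all per-view costs are (numerically) equal; ",
            "returning uniform weights")
    theta <- rep(1 / K, K)
    d <- if (identical(delta, "auto")) 0 else delta
    sol <- list(theta = theta, delta = d,
                lagrange_lambda = alpha * mean(costs) + 2 * d / K,
                eta = rep(0, K))
  } else if (identical(delta, "auto")) {
    d <- (alpha / 2) * spread
    theta <- (cmax - costs) / spread
    sol <- list(theta = theta, delta = d, lagrange_lambda = alpha * cmax,
                eta = rep(0, K))
  } else {
    if (!is.numeric(delta) || delta <= 0) stop("delta must be positive")
    sol <- project_costs_to_simplex(costs, alpha, delta)
  }
  structure(c(sol, list(costs = costs, view_names = nms)),
            class = "integration_solution")
}

# Exact solution of min alpha*C'theta + delta*theta'theta on the simplex:
# the projection of z = -alpha*C/(2*delta) onto the simplex via the sorted
# cumulative-threshold rule, with KKT multipliers recovered from
# 2*delta*theta + alpha*C - lambda*e - eta = 0.
project_costs_to_simplex <- function(costs, alpha, delta) {
  z <- -alpha * costs / (2 * delta)
  K <- length(z)
  zs <- sort(z, decreasing = TRUE)
  css <- cumsum(zs)
  rho <- max(which(zs - (css - 1) / seq_len(K) > 0))
  tau <- (css[rho] - 1) / rho
  theta <- pmax(z - tau, 0)
  lambda <- -2 * delta * tau
  eta <- 2 * delta * theta + alpha * costs - lambda
  eta[theta > 0] <- 0   # exact complementary slackness
  list(theta = theta, delta = delta, lagrange_lambda = lambda,
       eta = pmax(eta, 0))
}

#' @export
print.integration_solution <- function(x, ...) {
  cat("integration weights (delta =", signif(x$delta, 4), "):\n")
  for (i in seq_along(x$theta))
    cat(sprintf("  %-20s theta = %.4f  (cost %.4g)\n",
                x$view_names[i], x$theta[i], x$costs[i]))
  invisible(x)
}

#' Linearly combine per-view similarity matrices
#'
#' `sum_i theta_i W_i`; a convex combination of row-stochastic zero-diagonal
#' matrices stays row-stochastic with zero diagonal.
#'
#' @param W_list list of aligned similarity matrices.
#' @param theta simplex weight vector (e.g. `estimate_weights(...)$theta`).
#' @return combined `"similarity_matrix"`.
#' @export
integrate_similarities <- function(W_list, theta) {
  if (length(W_list) != length(theta))
    stop("need one weight per similarity matrix")
  if (abs(sum(theta) - 1) > 1e-8 || any(theta < -1e-10))
    stop("theta must lie on the probability simplex")
  dims <- vapply(W_list, dim, integer(2))
  if (any(dims != dims[, 1])) stop("similarity matrices are not aligned")
  W <- Reduce(`+`, Map(function(w, t) t * unclass_matrix(w), W_list, theta))
  dimnames(W) <- dimnames(W_list[[1]])
  structure(W, class = c("similarity_matrix", class(W)),
            method = "integrated", k = attr(W_list[[1]], "k"))
}

#' Predict side effects of new drugs from multiple feature views (LNSM-SMI)
#'
#' Builds one similarity matrix per view on the training drugs, scores each
#' view by its propagation cost, estimates simplex weights, and predicts
#' each new drug as `Y_new = (sum_i theta_i W_new^i) Y0` where `W_new^i` is
#' the view-specific out-of-sample reconstruction weight vector. The raw
#' training labels `Y0` are used by default; `transfer = "propagated"`
#' substitutes the converged label matrix.
#'
#' @param bundle an aligned [align_bundle()] result (training drugs).
#' @param X_new_views list of new-drug feature matrices, one per view, in
#'   the order of `bundle$views`.
#' @param sim_cfg a [similarity_config()] (RLN, 400 neighbors by default).
#' @param alpha absorbing probability used for cost scaling and, when
#'   `transfer = "propagated"`, for propagation.
#' @param delta `"auto"` or explicit regularization for
#'   [estimate_weights()].
#' @param transfer which label matrix `W_new` multiplies.
#' @return list with `scores` (new drugs x side-effect terms) and `weights`
#'   (the `"integration_solution"`).
#' @export
lnsm_smi_predict <- function(bundle, X_new_views,
                             sim_cfg = similarity_config(method = "rln", k = 400L),
                             alpha = 0.8, delta = "auto",
                             transfer = c("raw", "propagated")) {
  transfer <- match.arg(transfer)
  views <- bundle$views
  if (length(X_new_views) != length(views))
    stop("need one new-drug matrix per training view")
  Y0 <- unclass_matrix(bundle$associations)
  W_list <- lapply(views, build_similarity_matrix, cfg = sim_cfg)
  costs <- vapply(W_list, compute_cost, numeric(1), Y0 = Y0)
  weights <- estimate_weights(costs, alpha = alpha, delta = delta)
  Woos <- Map(function(Xtr, Xnew) oos_weight_matrix(Xtr, Xnew, sim_cfg),
              views, X_new_views)
  Wcomb <- Reduce(`+`, Map(`*`, Woos, weights$theta))
  Yt <- if (transfer == "propagated") {
    Wint <- integrate_similarities(W_list, weights$theta)
    propagate(Wint, Y0, propagation_config(alpha = alpha))
  } else Y0
  scores <- Wcomb %*% Yt
  dimnames(scores) <- list(rownames(X_new_views[[1]]), colnames(Y0))
  list(scores = scores, weights = weights)
}
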