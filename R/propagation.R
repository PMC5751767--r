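# Label propagation over the similarity graph (LNSM). Each node absorbs its
# neighbors' labels with probability alpha and retains its initial labels
# with probability 1 - alpha:
#
#   Y^{t+1} = alpha W Y^t + (1 - alpha) Y^0,
#
# which for row-stochastic W converges to the closed form
# Y' = (1 - alpha) (I - alpha W)^{-1} Y^0. Because every update is a convex
# combination of values that start in [0, 1], all propagated scores stay in
# [0, 1].

#' Propagation configuration
#'
#' @param alpha absorbing probability in `[0, 1)`; `alpha = 0` degenerates
#'   to returning the initial labels.
#' @param mode `"closed_form"` (a single linear solve) or `"iterative"`
#'   (fixed-point iteration from `Y0`).
#' @param max_iter,tol iteration controls for `mode = "iterative"`.
#' @return a list of class `"propagation_config"`.
#' @export
propagation_config <- function(alpha = 0.8,
                               mode = c("closed_form", "iterative"),
                               max_iter = 1000L, tol = 1e-9) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  structure(list(alpha = alpha, mode = match.arg(mode),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "propagation_config")
}

#' Propagate side-effect labels over a similarity graph
#'
#' @param W row-stochastic LN/RLN similarity matrix (N x N).
#' @param Y0 initial binary label matrix (N x M), drugs aligned with `W`.
#' @param cfg a [propagation_config()].
#' @return N x M score matrix with entries in `[0, 1]`.
#' @export
propagate <- function(W, Y0, cfg = propagation_config()) {
  Y0 <- unclass_matrix(Y0)
  if (nrow(W) != ncol(W) || nrow(W) != nrow(Y0))
    stop("dimension mismatch: W is ", nrow(W), "x", ncol(W),
         ", Y0 has ", nrow(Y0), " rows")
  assert_row_stochastic(W)
  if (cfg$alpha == 0) return(Y0)
  Y <- if (cfg$mode == "closed_form") {
    (1 - cfg$alpha) * solve(diag(nrow(W)) - cfg$alpha * W, Y0)
  } else {
    Yc <- Y0
    for (it in seq_len(cfg$max_iter)) {
      Yn <- cfg$alpha * (W %*% Yc) + (1 - cfg$alpha) * Y0
      delta <- max(abs(Yn - Yc))
      Yc <- Yn
      if (delta < cfg$tol) break
    }
    Yc
  }
  dimnames(Y) <- dimnames(Y0)
  Y
}

#' Predict side effects of new drugs from one feature view (LNSM)
#'
#' Builds the training similarity graph, propagates the known labels to the
#' converged matrix `Y'`, then scores each new drug as its out-of-sample
#' reconstruction weights times the label matrix:
#' `Y_new = W_new x Y'` (`transfer = "propagated"`, the default) or
#' `Y_new = W_new x Y0` (`transfer = "raw"`).
#'
#' @param X_train training feature matrix.
#' @param Y_train binary association matrix for the training drugs.
#' @param X_new feature matrix of new drugs in the same descriptor space.
#' @param sim_cfg a [similarity_config()]; defaults to RLN with 400
#'   neighbors (capped at N-1).
#' @param prop_cfg a [propagation_config()]; default absorbing probability
#'   0.8.
#' @param transfer whether `W_new` multiplies the propagated labels or the
#'   raw training labels.
#' @return scores matrix (new drugs x side-effect terms) with entries in
#'   `[0, 1]`.
#' @export
lnsm_predict_new <- function(X_train, Y_train, X_new,
                             sim_cfg = similarity_config(method = "rln", k = 400L),
                             prop_cfg = propagation_config(alpha = 0.8),
                             transfer = c("propagated", "raw")) {
  transfer <- match.arg(transfer)
  if (ncol(X_train) != ncol(X_new))
    stop("training and new drugs live in different descriptor spaces")
  W <- build_similarity_matrix(X_train, sim_cfg)
  Yt <- if (transfer == "propagated") propagate(W, Y_train, prop_cfg)
        else unclass_matrix(Y_train)
  Woos <- oos_weight_matrix(X_train, X_new, sim_cfg)
  out <- Woos %*% Yt
  dimnames(out) <- list(rownames(X_new), colnames(Y_train))
  out
}

# strip container classes so arithmetic stays plain-matrix
unclass_matrix <- function(m) {
  m <- as.matrix(m)
  class(m) <- NULL
  attr(m, "view_name") <- NULL
  m
}
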