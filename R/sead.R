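# LNSM-MSE: missing side effects of approved drugs. The drug-side-effect
# bipartite network is an N x M binary association matrix A; each drug's
# association profile A[i, ] serves as its feature vector. Linear
# neighborhood similarity computed on those profiles is fed to label
# propagation, Y = (1 - alpha) (I - alpha W)^{-1} A, and entries at A[i, j]
# = 0 rank candidate missing side effects. Because the propagation retains
# the initial labels with probability 1 - alpha, every known positive keeps
# a score of at least 1 - alpha.

#' Predict missing side effects of approved drugs (LNSM-MSE)
#'
#' @param A binary [association_matrix()] (drugs x side-effect terms).
#' @param sim_cfg a [similarity_config()]; the default is RLN similarity
#'   with 800 neighbors (capped at N-1).
#' @param prop_cfg a [propagation_config()]; default absorbing probability
#'   0.3.
#' @return N x M score matrix in `[0, 1]`; where `A[i, j] == 0` the entry
#'   is the predicted probability that drug i induces side effect j.
#' @export
lnsm_mse_predict <- function(A,
                             sim_cfg = similarity_config(method = "rln", k = 800L),
                             prop_cfg = propagation_config(alpha = 0.3)) {
  if (!sim_cfg$method %in% c("ln", "rln"))
    stop("LNSM-MSE requires LN or RLN similarity")
  Av <- unclass_matrix(A)
  empty <- rowSums(Av) == 0
  if (any(empty))
    warning("drug(s) with an all-zero association profile: ",
            paste(rownames(Av)[empty], collapse = ", "),
            " (their neighborhoods are ill-defined)")
  X <- suppressWarnings(
    feature_matrix(Av, view_name = "association_profile"))
  W <- build_similarity_matrix(X, sim_cfg)
  propagate(W, Av, prop_cfg)
}
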