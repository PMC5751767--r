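# Cross-validation protocols. SEND: drugs are split into equal-sized folds;
# models are fitted on the training drugs only and evaluated on the held-out
# drugs with the multi-label metrics. SEAD: the known positive cells of the
# association matrix are split into folds; held-out positives are zeroed in
# the training copy before BOTH similarity computation and propagation, and
# evaluation pools the held-out positives against all cells that are zero in
# the full matrix (training positives are excluded from the ranked pool:
# they are known, not predictions).

#' Deterministic fold assignment
#'
#' Folds are a pure function of `(seed, sorted unit ids)`: units are sorted,
#' shuffled with a private RNG stream seeded by `seed`, and dealt
#' round-robin, so fold sizes differ by at most one.
#'
#' @param ids character or integer unit identifiers (drugs for SEND,
#'   positive-cell indices for SEAD).
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @param task `"send"` or `"sead"` (bookkeeping only).
#' @return list of class `"fold_spec"` with `assignments` (named integer
#'   vector of fold ids per unit), `n_folds`, `seed`, `task`.
#' @export
make_folds <- function(ids, n_folds = 5L, seed = 1L,
                       task = c("send", "sead")) {
  task <- match.arg(task)
  ids <- sort(as.character(ids))
  if (length(ids) < n_folds)
    stop("cannot make ", n_folds, " folds from ", length(ids), " units")
  shuffled <- with_private_seed(seed, sample(ids))
  fold <- rep(seq_len(n_folds), length.out = length(shuffled))
  assignments <- stats::setNames(fold, shuffled)[ids]
  structure(list(assignments = assignments, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), task = task),
            class = "fold_spec")
}

# Run `expr` under a seeded RNG without disturbing the caller's stream.
with_private_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Five-fold cross-validation for new-drug prediction (SEND)
#'
#' @param bundle an aligned [align_bundle()] result.
#' @param method `"lnsm"` (single view) or `"lnsm_smi"` (all views with
#'   estimated simplex weights).
#' @param view view name or index used when `method = "lnsm"`; defaults to
#'   the first view.
#' @param sim_cfg a [similarity_config()] (RLN, 400 neighbors by default).
#' @param alpha absorbing probability (default 0.8).
#' @param n_folds,seed fold controls (see [make_folds()]).
#' @param threshold Hamming-loss binarization cutoff.
#' @param n_permutations if positive, additionally computes a
#'   permuted-training-label null: per fold and permutation the training
#'   label rows are shuffled (similarities are unchanged) and the pooled
#'   micro-AUPR recorded.
#' @return list with `per_fold` (list of [multilabel_metrics()] reports),
#'   `mean` (metric means across folds), `pooled` (metrics on all test
#'   drugs pooled), `folds`, `theta` (per-fold weight matrix, SMI only),
#'   and `null_aupr` (permutation x statistic, if requested).
#' @export
cross_validate_send <- function(bundle, method = c("lnsm", "lnsm_smi"),
                                view = 1L,
                                sim_cfg = similarity_config(method = "rln", k = 400L),
                                alpha = 0.8, n_folds = 5L, seed = 1L,
                                threshold = 0.5, n_permutations = 0L) {
  method <- match.arg(method)
  prop_cfg <- propagation_config(alpha = alpha)
  Y <- unclass_matrix(bundle$associations)
  drugs <- bundle$drug_ids
  folds <- make_folds(drugs, n_folds, seed, task = "send")
  views <- if (method == "lnsm") bundle$views[view] else bundle$views

  per_fold <- vector("list", n_folds)
  theta <- NULL
  null_aupr <- if (n_permutations > 0)
    matrix(NA_real_, n_permutations, n_folds) else NULL
  pooled_scores <- matrix(NA_real_, length(drugs), ncol(Y),
                          dimnames = list(drugs, colnames(Y)))

  for (f in seq_len(n_folds)) {
    test <- drugs[folds$assignments == f]
    train <- setdiff(drugs, test)
    Ytr <- Y[train, , drop = FALSE]
    Xtr <- lapply(views, function(v) v[train, , drop = FALSE])
    Xte <- lapply(views, function(v) v[test, , drop = FALSE])
    W_list <- lapply(Xtr, build_similarity_matrix, cfg = sim_cfg)
    Woos <- Map(function(a, b) oos_weight_matrix(a, b, sim_cfg), Xtr, Xte)

    if (method == "lnsm") {
      Yp <- propagate(W_list[[1]], Ytr, prop_cfg)
      scores <- Woos[[1]] %*% Yp
      score_fun <- function(Yperm)
        Woos[[1]] %*% propagate(W_list[[1]], Yperm, prop_cfg)
    } else {
      costs <- vapply(W_list, compute_cost, numeric(1), Y0 = Ytr)
      wsol <- suppressWarnings(estimate_weights(costs, alpha = alpha))
      if (is.null(theta))
        theta <- matrix(NA_real_, n_folds, length(views),
                        dimnames = list(NULL, names(views)))
      theta[f, ] <- wsol$theta
      Wcomb <- Reduce(`+`, Map(`*`, Woos, wsol$theta))
      scores <- Wcomb %*% Ytr
      score_fun <- function(Yperm) {
        cp <- vapply(W_list, compute_cost, numeric(1), Y0 = Yperm)
        wp <- suppressWarnings(estimate_weights(cp, alpha = alpha))
        Reduce(`+`, Map(`*`, Woos, wp$theta)) %*% Yperm
      }
    }
    pooled_scores[test, ] <- scores
    per_fold[[f]] <- multilabel_metrics(scores, Y[test, , drop = FALSE],
                                        threshold)
    if (n_permutations > 0) {
      perm_seed <- as.integer((as.double(seed) * 1009 + f) %% 2147483647)
      perms <- with_private_seed(perm_seed, lapply(
        seq_len(n_permutations), function(p) sample(nrow(Ytr))))
      for (p in seq_len(n_permutations)) {
        sp <- score_fun(Ytr[perms[[p]], , drop = FALSE])
        null_aupr[p, f] <- aupr_rank(as.vector(sp),
                                     as.vector(Y[test, , drop = FALSE]))
      }
    }
  }
  out <- list(per_fold = per_fold, mean = mean_metrics(per_fold),
              pooled = multilabel_metrics(pooled_scores, Y, threshold),
              folds = folds, theta = theta)
  if (n_permutations > 0) out$null_aupr <- null_aupr
  out
}

#' Five-fold cross-validation for missing-side-effect recovery (SEAD)
#'
#' @param A binary [association_matrix()].
#' @param sim_cfg a [similarity_config()]; default RLN with 800 neighbors.
#' @param alpha absorbing probability (default 0.3).
#' @param n_folds,seed fold controls over the known positive cells.
#' @param threshold confusion-metric cutoff.
#' @return list with `per_fold` ([binary_metrics()] reports, each extended
#'   with `min_known_positive_score`, the smallest score over the fold's
#'   retained training positives), `mean`, and `folds`.
#' @export
cross_validate_sead <- function(A,
                                sim_cfg = similarity_config(method = "rln", k = 800L),
                                alpha = 0.3, n_folds = 5L, seed = 1L,
                                threshold = 0.5) {
  Av <- unclass_matrix(A)
  prop_cfg <- propagation_config(alpha = alpha)
  pos <- which(Av == 1)
  if (length(pos) < n_folds) stop("too few known positives to fold")
  folds <- make_folds(pos, n_folds, seed, task = "sead")
  assign_of <- folds$assignments[as.character(sort(pos))]
  pos <- sort(pos)

  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    held <- pos[assign_of == f]
    Atr <- Av
    Atr[held] <- 0
    no_train_pos <- rowSums(Atr) == 0
    if (any(no_train_pos))
      warning("fold ", f, " leaves drug(s) without training positives: ",
              paste(rownames(Av)[no_train_pos], collapse = ", "))
    Yhat <- suppressWarnings(
      lnsm_mse_predict(Atr, sim_cfg = sim_cfg, prop_cfg = prop_cfg))
    eval_cells <- c(held, which(Av == 0))
    truth <- c(rep(1, length(held)), rep(0, sum(Av == 0)))
    rep_f <- binary_metrics(Yhat[eval_cells], truth, threshold)
    rep_f$min_known_positive_score <- min(Yhat[Atr == 1])
    per_fold[[f]] <- rep_f
  }
  list(per_fold = per_fold, mean = mean_metrics(per_fold), folds = folds)
}

# element-wise mean of scalar fields across fold reports
mean_metrics <- function(reports) {
  flat <- lapply(reports, function(r)
    unlist(r[vapply(r, function(v) is.numeric(v) && length(v) == 1,
                    logical(1))]))
  out <- as.list(colMeans(do.call(rbind, flat), na.rm = TRUE))
  structure(out, class = "metrics_report")
}
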