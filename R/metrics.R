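# Evaluation metrics. Multi-label rank metrics are computed per drug and
# averaged over the drugs for which they are defined; AUC/AUPR are pooled
# over all prediction cells (micro) with per-drug macro averages reported
# alongside. Tie conventions, stated once and used consistently: label
# ranks use tie-averaged ranks (affects coverage); the top label for
# one-error is the whole argmax set (a tie at the top is an error only if
# no tied label is true); wrongly-ordered pairs in ranking loss count ties
# as 1/2; average precision orders by descending score with ties broken by
# ascending label/cell index.

#' Multi-label metrics for side-effect prediction
#'
#' @param scores real-valued score matrix (drugs x side-effect terms).
#' @param truth binary association matrix of the same shape.
#' @param threshold binarization cutoff for Hamming loss (`score >=
#'   threshold` predicts 1).
#' @return list of class `"metrics_report"`: `auc`, `aupr` (micro-pooled
#'   over all cells), `auc_macro`, `aupr_macro` (per-drug means over drugs
#'   with both classes), `hamming_loss`, `one_error`, `coverage` (on the
#'   un-normalized `0..M-1` scale), `ranking_loss`, `average_precision`,
#'   and `n_evaluated` (drugs contributing to the rank metrics).
#' @export
multilabel_metrics <- function(scores, truth, threshold = 0.5) {
  scores <- unclass_matrix(scores); truth <- unclass_matrix(truth)
  if (!all(dim(scores) == dim(truth)))
    stop("scores and truth must have identical dimensions")
  if (any(!truth %in% c(0, 1))) stop("truth must be binary")
  n <- nrow(scores); M <- ncol(scores)

  one_err <- cov <- rl <- ap <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- scores[i, ]; y <- truth[i, ]
    pos <- which(y == 1); neg <- which(y == 0)
    if (!length(pos)) next
    one_err[i] <- as.numeric(!any(y[s == max(s)] == 1))
    rk <- rank(-s, ties.method = "average")
    cov[i] <- max(rk[pos]) - 1
    if (length(neg)) {
      dif <- outer(s[pos], s[neg], `-`)
      rl[i] <- (sum(dif < 0) + 0.5 * sum(dif == 0)) / (length(pos) * length(neg))
    }
    ord <- order(-s, seq_len(M))
    hits <- cumsum(y[ord] == 1)
    at <- which(y[ord] == 1)
    ap[i] <- mean(hits[at] / at)
  }

  pooled <- binary_metrics(as.vector(scores), as.vector(truth), threshold)
  per_drug <- vapply(seq_len(n), function(i) {
    y <- truth[i, ]
    if (all(y == 0) || all(y == 1)) return(c(NA_real_, NA_real_))
    c(auc_rank(scores[i, ], y), aupr_rank(scores[i, ], y))
  }, numeric(2))

  structure(list(
    auc = pooled$auc, aupr = pooled$aupr,
    auc_macro = mean(per_drug[1, ], na.rm = TRUE),
    aupr_macro = mean(per_drug[2, ], na.rm = TRUE),
    hamming_loss = mean((scores >= threshold) != truth),
    one_error = mean(one_err, na.rm = TRUE),
    coverage = mean(cov, na.rm = TRUE),
    ranking_loss = mean(rl, na.rm = TRUE),
    average_precision = mean(ap, na.rm = TRUE),
    n_evaluated = sum(!is.na(one_err)),
    n_drugs = n, n_labels = M), class = "metrics_report")
}

#' Binary classification metrics on pooled prediction cells
#'
#' Confusion-table metrics at a score threshold plus threshold-free AUC
#' (Mann-Whitney rank statistic with tie-averaging) and AUPR
#' (non-interpolated average precision: the mean of precision at each
#' positive's rank).
#'
#' @param scores numeric score vector.
#' @param truth binary vector of the same length.
#' @param threshold cutoff; `score >= threshold` is called positive.
#' @return list of class `"metrics_report"` with `auc`, `aupr`, `sn`
#'   (= `recall`), `sp`, `precision`, `acc`, `f`, and the confusion counts.
#' @export
binary_metrics <- function(scores, truth, threshold = 0.5) {
  scores <- as.numeric(scores); truth <- as.numeric(truth)
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length")
  if (any(!truth %in% c(0, 1))) stop("truth must be binary")
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC/AUPR are undefined without both positives and negatives")
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f <- if (prec + sn == 0) 0 else 2 * prec * sn / (prec + sn)
  structure(list(
    auc = auc_rank(scores, truth), aupr = aupr_rank(scores, truth),
    sn = sn, recall = sn, sp = sp, precision = prec,
    acc = (tp + tn) / length(truth), f = f,
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_pos = n1, n_neg = n0), class = "metrics_report")
}

# Mann-Whitney AUC with tie-averaged ranks.
auc_rank <- function(scores, truth) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Non-interpolated average precision; ties broken by ascending cell index.
aupr_rank <- function(scores, truth) {
  ord <- order(-scores, seq_along(scores))
  y <- truth[ord]
  hits <- cumsum(y)
  mean((hits / seq_along(y))[y == 1])
}

#' @export
print.metrics_report <- function(x, ...) {
  flat <- x[vapply(x, function(v) is.numeric(v) && length(v) == 1, logical(1))]
  cat(paste0(format(names(flat), width = 18), " ",
             vapply(flat, function(v) formatC(v, digits = 4, format = "f"),
                    character(1)), collapse = "\n"), "\n")
  invisible(x)
}
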