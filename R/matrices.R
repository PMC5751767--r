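# Matrix containers: binary feature views, binary association matrices, and
# the aligned bundle that ties them together. All containers are base
# matrices with mandatory dimnames; the constructors validate invariants and
# tag the matrix with a lightweight S3 class.

#' Construct a binary drug feature matrix
#'
#' A feature view stores one binary descriptor table: rows are drugs,
#' columns are descriptors (substructures, targets, enzymes, ...), and entry
#' (i, j) is 1 when drug i carries descriptor j.
#'
#' @param values numeric matrix with entries in \{0, 1\}.
#' @param drug_ids,descriptor_ids unique row/column identifiers; defaults to
#'   the dimnames of `values`.
#' @param view_name label for the feature view (e.g. `"substructure"`).
#' @return the validated matrix, classed `"feature_matrix"`, with
#'   `attr(, "view_name")` set.
#' @export
feature_matrix <- function(values, drug_ids = rownames(values),
                           descriptor_ids = colnames(values),
                           view_name = "view") {
  values <- as.matrix(values)
  check_ids(drug_ids, nrow(values), "drug")
  check_ids(descriptor_ids, ncol(values), "descriptor")
  if (nrow(values) < 2L)
    stop("a feature matrix needs at least 2 drugs, got ", nrow(values))
  if (ncol(values) < 1L)
    stop("a feature matrix needs at least 1 descriptor")
  check_binary(values, drug_ids, descriptor_ids)
  dimnames(values) <- list(drug_ids, descriptor_ids)
  zero_rows <- rowSums(values) == 0
  if (any(zero_rows))
    warning("all-zero feature rows for drug(s): ",
            paste(drug_ids[zero_rows], collapse = ", "),
            " (their distance to every other drug is degenerate)")
  structure(values, class = c("feature_matrix", class(values)),
            view_name = view_name)
}

#' Construct a binary drug-side-effect association matrix
#'
#' Rows are drugs, columns are side-effect terms; entry (i, j) is 1 when
#' drug i is known to induce side effect j.
#'
#' @param values numeric matrix with entries in \{0, 1\}.
#' @param drug_ids,side_effect_ids unique row/column identifiers; defaults
#'   to the dimnames of `values`.
#' @return the validated matrix, classed `"association_matrix"`.
#' @export
association_matrix <- function(values, drug_ids = rownames(values),
                               side_effect_ids = colnames(values)) {
  values <- as.matrix(values)
  check_ids(drug_ids, nrow(values), "drug")
  check_ids(side_effect_ids, ncol(values), "side-effect")
  check_binary(values, drug_ids, side_effect_ids)
  dimnames(values) <- list(drug_ids, side_effect_ids)
  structure(values, class = c("association_matrix", class(values)))
}

check_ids <- function(ids, n, what) {
  if (is.null(ids))
    stop("missing ", what, " identifiers")
  if (length(ids) != n)
    stop(what, " identifiers do not match matrix dimension")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " identifiers: ", paste(dup, collapse = ", "))
  invisible(TRUE)
}

check_binary <- function(values, row_ids, col_ids) {
  bad <- which(!(values == 0 | values == 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-binary entry at row '", row_ids[bad[1, 1]],
         "', column '", col_ids[bad[1, 2]], "': ",
         values[bad[1, 1], bad[1, 2]])
  }
  invisible(TRUE)
}

#' Align feature views and associations into a dataset bundle
#'
#' Reorders every member matrix to a single canonical drug order
#' (lexicographic by drug identifier) so that row i refers to the same drug
#' everywhere downstream. Aligning an already aligned bundle is a no-op.
#'
#' @param views a list (ideally named) of [feature_matrix()] objects sharing
#'   one drug set, in any row order.
#' @param associations an [association_matrix()] on the same drug set.
#' @return a list of class `"dataset_bundle"` with elements `views`
#'   (named list, rows in lexicographic drug order), `associations`, and
#'   `drug_ids`.
#' @export
align_bundle <- function(views, associations) {
  if (inherits(views, "feature_matrix")) views <- list(views)
  if (!length(views)) stop("at least one feature view is required")
  if (is.null(names(views)) || any(!nzchar(names(views))))
    names(views) <- vapply(seq_along(views), function(i) {
      vn <- attr(views[[i]], "view_name")
      if (is.null(vn)) paste0("view", i) else vn
    }, character(1))
  ref <- sort(rownames(associations))
  all_mats <- c(views, list(associations = associations))
  for (nm in names(all_mats)) {
    ids <- rownames(all_mats[[nm]])
    extra <- setdiff(ids, ref)
    miss <- setdiff(ref, ids)
    if (length(extra) || length(miss))
      stop("drug sets differ in '", nm, "': ",
           if (length(miss)) paste0("missing ", paste(miss, collapse = ", ")),
           if (length(extra) && length(miss)) "; ",
           if (length(extra)) paste0("unexpected ", paste(extra, collapse = ", ")))
  }
  reorder <- function(m) {
    out <- m[ref, , drop = FALSE]
    attributes(out) <- c(attributes(out),
                         attributes(m)[setdiff(names(attributes(m)),
                                               c("dim", "dimnames"))])
    out
  }
  structure(list(views = lapply(views, reorder),
                 associations = reorder(associations),
                 drug_ids = ref),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("dataset_bundle:", length(x$drug_ids), "drugs,",
      ncol(x$associations), "side-effect terms,",
      length(x$views), "feature view(s)\n")
  for (nm in names(x$views))
    cat("  view '", nm, "': ", ncol(x$views[[nm]]), " descriptors\n", sep = "")
  invisible(x)
}
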