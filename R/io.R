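# On-disk format: TSV with one header row and one identifier column. The
# header cell (0,0) is the literal label "id" and is ignored on read. Binary
# matrices use the characters 0/1; score matrices use full-precision decimal
# floats.

#' Read a drug matrix from a TSV file
#'
#' @param path file path to a tab-delimited table whose first row holds
#'   column identifiers and whose first column holds drug identifiers.
#' @param kind `"feature"` for a binary descriptor view, `"association"` for
#'   a binary drug-side-effect table, or `"scores"` for a real-valued score
#'   table.
#' @param view_name view label attached when `kind = "feature"`; defaults to
#'   the file name without extension.
#' @return a [feature_matrix()], [association_matrix()], or plain numeric
#'   matrix (`kind = "scores"`), with row/column order preserved from the
#'   file.
#' @export
read_matrix <- function(path, kind = c("feature", "association", "scores"),
                        view_name = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2L) stop("not a matrix table (needs id column + data): ", path)
  drug_ids <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  col_ids <- colnames(body)
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric entry at row '", drug_ids[bad[1L]], "', column '",
         col_ids[bad[2L]], "' in ", path)
  }
  dimnames(vals) <- list(drug_ids, col_ids)
  switch(kind,
    feature = feature_matrix(vals, view_name = view_name %||%
                               sub("\\.[^.]*$", "", basename(path))),
    association = association_matrix(vals),
    scores = vals)
}

#' Write a drug matrix to a TSV file
#'
#' Binary matrices are written with literal 0/1; real-valued matrices keep
#' 15 significant digits so that a write/read round trip is lossless to
#' better than 1e-12.
#'
#' @param m matrix with complete dimnames.
#' @param path output file path (written atomically: temp file + rename).
#' @export
write_matrix <- function(m, path) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must carry row and column identifiers")
  binary <- all(m == 0 | m == 1)
  body <- if (binary) {
    matrix(as.character(as.integer(m)), nrow = nrow(m))
  } else {
    matrix(formatC(m, digits = 15, format = "g"), nrow = nrow(m))
  }
  df <- data.frame(id = rownames(m), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(m))
  atomic_write(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }, path)
  invisible(path)
}

#' Write a prediction score matrix
#'
#' Refuses non-finite scores; otherwise identical layout to [write_matrix()].
#'
#' @param scores real-valued drugs x side-effect-terms matrix.
#' @param path output file path.
#' @export
write_scores <- function(scores, path) {
  if (any(!is.finite(scores))) {
    bad <- which(!is.finite(scores), arr.ind = TRUE)[1L, ]
    stop("non-finite score at row '", rownames(scores)[bad[1L]],
         "', column '", colnames(scores)[bad[2L]], "'; refusing to write")
  }
  write_matrix(scores, path)
}

# Write via a temp file in the destination directory, then rename, so a
# failed run never leaves a truncated output behind.
atomic_write <- function(writer, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move output into place: ", path)
  invisible(path)
}

#' Read a dataset bundle from a config file
#'
#' The config (JSON or YAML, by file extension) maps view names to feature
#' TSV paths plus one `associations` path:
#' `{"views": {"substructure": "sub.tsv"}, "associations": "assoc.tsv"}`.
#' Relative paths are resolved against the config file's directory.
#'
#' @param path config file path.
#' @return an aligned [align_bundle()] result.
#' @export
read_bundle_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$views) || is.null(cfg$associations))
    stop("config must provide 'views' (name -> path map) and 'associations'")
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  views <- lapply(names(cfg$views), function(nm)
    read_matrix(resolve(cfg$views[[nm]]), "feature", view_name = nm))
  names(views) <- names(cfg$views)
  assoc <- read_matrix(resolve(cfg$associations), "association")
  align_bundle(views, assoc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
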