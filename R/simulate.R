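# Synthetic cluster-structured datasets. Drugs belong to latent clusters;
# each cluster owns a prototype descriptor pattern per view and a block of
# side-effect terms. A view's informativeness sets the fraction of drugs
# whose feature row derives from the cluster prototype (prototype XOR
# Bernoulli flips) rather than pure Bernoulli(0.5) noise, so informativeness
# 1 is fully cluster-determined and 0 is noise. Associations are dense
# inside a drug's own side-effect block and sparse outside, emulating the
# "similar drugs induce similar side effects" structure that the predictors
# assume.

#' Generator configuration
#'
#' Defaults describe the study conditions used throughout the test-bench:
#' 200 drugs in 5 clusters, 50 side-effect terms, and two 100-descriptor
#' views, one strongly informative (0.9) and one pure noise (0.0).
#'
#' @param n_drugs,n_side_effects,n_clusters problem sizes.
#' @param descriptors_per_view integer vector, one entry per view.
#' @param view_informativeness reals in `[0, 1]`, same length; probability
#'   that a drug's row in that view is cluster-derived.
#' @param feature_flip_rate per-bit XOR noise on cluster-derived rows, in
#'   `[0, 0.5)`.
#' @param association_rate_in_cluster,association_rate_background Bernoulli
#'   rates for associations inside/outside a drug's own side-effect block;
#'   the in-cluster rate must exceed the background rate.
#' @param seed integer master seed; per-matrix sub-seeds are derived from it.
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(n_drugs = 200L, n_side_effects = 50L,
                             n_clusters = 5L,
                             descriptors_per_view = c(100L, 100L),
                             view_informativeness = c(0.9, 0),
                             feature_flip_rate = 0.05,
                             association_rate_in_cluster = 0.6,
                             association_rate_background = 0.02,
                             seed = 1L) {
  if (length(descriptors_per_view) != length(view_informativeness))
    stop("descriptors_per_view and view_informativeness must match in length")
  rates <- c(view_informativeness, feature_flip_rate,
             association_rate_in_cluster, association_rate_background)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (feature_flip_rate >= 0.5) stop("feature_flip_rate must be below 0.5")
  if (association_rate_in_cluster <= association_rate_background)
    stop("in-cluster association rate must exceed the background rate")
  structure(list(n_drugs = as.integer(n_drugs),
                 n_side_effects = as.integer(n_side_effects),
                 n_clusters = as.integer(n_clusters),
                 descriptors_per_view = as.integer(descriptors_per_view),
                 view_informativeness = view_informativeness,
                 feature_flip_rate = feature_flip_rate,
                 association_rate_in_cluster = association_rate_in_cluster,
                 association_rate_background = association_rate_background,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a cluster-structured multi-view dataset
#'
#' @param cfg a [generator_config()].
#' @return a `"dataset_bundle"` (see [align_bundle()]) with the additional
#'   element `clusters`: the ground-truth cluster label per drug.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  n <- cfg$n_drugs; M <- cfg$n_side_effects; ncl <- cfg$n_clusters
  drug_ids <- sprintf("drug%04d", seq_len(n))
  se_ids <- sprintf("se%03d", seq_len(M))

  clusters <- with_private_seed(sub_seed(cfg$seed, 0L),
                                sample.int(ncl, n, replace = TRUE))
  names(clusters) <- drug_ids

  views <- lapply(seq_along(cfg$descriptors_per_view), function(v) {
    p <- cfg$descriptors_per_view[v]
    info <- cfg$view_informativeness[v]
    vals <- with_private_seed(sub_seed(cfg$seed, v), {
      proto <- matrix(stats::rbinom(ncl * p, 1L, 0.5), ncl, p)
      from_proto <- stats::runif(n) < info
      t(vapply(seq_len(n), function(i) {
        if (from_proto[i]) {
          flips <- stats::rbinom(p, 1L, cfg$feature_flip_rate)
          as.numeric(xor(proto[clusters[i], ], flips))
        } else stats::rbinom(p, 1L, 0.5)
      }, numeric(p)))
    })
    suppressWarnings(feature_matrix(
      vals, drug_ids = drug_ids,
      descriptor_ids = sprintf("d%04d", seq_len(p)),
      view_name = paste0("view", v)))
  })
  names(views) <- vapply(views, attr, character(1), "view_name")

  blocks <- sort(rep_len(seq_len(ncl), M))   # contiguous near-equal blocks
  A <- with_private_seed(sub_seed(cfg$seed, length(views) + 1L), {
    rate <- matrix(cfg$association_rate_background, n, M)
    for (i in seq_len(n)) rate[i, blocks == clusters[i]] <-
        cfg$association_rate_in_cluster
    matrix(stats::rbinom(n * M, 1L, rate), n, M)
  })
  assoc <- association_matrix(A, drug_ids = drug_ids, side_effect_ids = se_ids)

  bundle <- align_bundle(views, assoc)
  bundle$clusters <- clusters[bundle$drug_ids]
  bundle$side_effect_blocks <- stats::setNames(blocks, se_ids)
  bundle
}

# small deterministic mix keeping sub-seeds positive 32-bit integers
sub_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647L) + 1L
}

#' Write a dataset bundle to a directory of TSV files
#'
#' One file per feature view (`view_<name>.tsv`), `associations.tsv`, the
#' ground-truth `clusters.tsv` when present, and a `bundle.json` config that
#' [read_bundle_config()] accepts.
#'
#' @param bundle a `"dataset_bundle"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  view_files <- stats::setNames(
    paste0("view_", names(bundle$views), ".tsv"), names(bundle$views))
  for (nm in names(bundle$views))
    write_matrix(bundle$views[[nm]], file.path(dir, view_files[[nm]]))
  write_matrix(bundle$associations, file.path(dir, "associations.tsv"))
  if (!is.null(bundle$clusters)) {
    atomic_write(function(tmp) utils::write.table(
      data.frame(id = names(bundle$clusters), cluster = bundle$clusters),
      tmp, sep = "\t", quote = FALSE, row.names = FALSE),
      file.path(dir, "clusters.tsv"))
  }
  jsonlite::write_json(
    list(views = as.list(view_files), associations = "associations.tsv"),
    file.path(dir, "bundle.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
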