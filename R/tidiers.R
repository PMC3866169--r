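#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a K2P distance matrix into a long pair table
#'
#' @param x `k2p_dist` object.
#' @param ... unused.
#' @return tibble with one row per unordered pair: `id_a`, `id_b`,
#'   `n_sites`, `P`, `Q`, `k2p` (NA for saturated or invalid pairs).
#' @export
tidy.k2p_dist <- function(x, ...) {
  up <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    id_a = x$ids[up[, 1]],
    id_b = x$ids[up[, 2]],
    n_sites = x$n_sites[up],
    P = x$P[up],
    Q = x$Q[up],
    k2p = x$d[up]
  )
}

#' @rdname tidy.k2p_dist
#' @return for `glance`: one row with pair counts and distance summaries.
#' @export
glance.k2p_dist <- function(x, ...) {
  v <- x$d[upper.tri(x$d)]
  tibble(
    n_specimens = length(x$ids),
    n_pairs = length(v),
    n_saturated = nrow(x$undefined_pairs),
    n_invalid = nrow(x$invalid_pairs),
    mean_dist = mean(v, na.rm = TRUE),
    min_dist = min(v, na.rm = TRUE),
    max_dist = max(v, na.rm = TRUE)
  )
}

#' Tidy an OTU partition
#'
#' @param x `otu_partition` object.
#' @param ... unused.
#' @return for `tidy`: the specimen-to-cluster assignment tibble; for
#'   `glance`: one row with cluster counts, size summaries and the
#'   clustering parameters.
#' @export
tidy.otu_partition <- function(x, ...) x$assignment

#' @rdname tidy.otu_partition
#' @export
glance.otu_partition <- function(x, ...) {
  sizes <- x$assignment |> count(.data$cluster_id) |> pull(.data$n)
  tibble(
    n_specimens = nrow(x$assignment),
    n_clusters = length(sizes),
    n_singletons = sum(sizes == 1),
    max_cluster_size = max(sizes),
    seed_threshold = x$params$seed_threshold,
    refine_threshold = x$params$refine_threshold,
    mcl_inflation = x$params$mcl_inflation
  )
}

#' Tidy a pipeline run
#'
#' @param x `barcode_run` object.
#' @param ... unused.
#' @return for `tidy`: the per-species concordance classification; for
#'   `glance`: the one-row run summary.
#' @export
tidy.barcode_run <- function(x, ...) x$classified

#' @rdname tidy.barcode_run
#' @export
glance.barcode_run <- function(x, ...) x$summary
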