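#' Per-species barcode-gap table
#'
#' One row per species with the statistics of the barcode gap: mean and
#' maximum intraspecific K2P distance (undefined for singletons), minimum
#' distance to the nearest heterospecific neighbour and which species that
#' is, and the mean pairwise distance to congeners. Saturated (undefined)
#' distances are excluded from every statistic; pair counts are carried so
#' group summaries can reweight exactly.
#'
#' @param dm `k2p_dist` object.
#' @param ds specimen tibble.
#' @return tibble with columns `species`, `genus`, `n_specimens`,
#'   `mean_intra`, `max_intra`, `nn_distance`, `nn_species`,
#'   `mean_congeneric`, `n_intra_pairs`, `n_congeneric_pairs`,
#'   `n_excluded_pairs` (saturated or invalid pairs involving the species).
#' @export
species_gap_table <- function(dm, ds) {
  validate_barcodes(ds)
  sp <- ds$species[match(dm$ids, ds$specimen_id)]
  gn <- ds$genus[match(dm$ids, ds$specimen_id)]
  species <- sort(unique(sp))
  D <- dm$d
  rows <- purrr::map(species, function(s) {
    own <- which(sp == s)
    other <- which(sp != s)
    genus_s <- gn[own[1]]
    cong <- which(sp != s & gn == genus_s)
    intra <- if (length(own) >= 2) {
      sub <- D[own, own, drop = FALSE]
      sub[upper.tri(sub)]
    } else numeric()
    cross <- D[own, other, drop = FALSE]
    cong_d <- as.vector(D[own, cong, drop = FALSE])
    n_excluded <- sum(is.na(intra)) + sum(is.na(cross))
    intra <- intra[!is.na(intra)]
    nn_distance <- NA_real_
    nn_species <- NA_character_
    if (length(other) > 0 && any(!is.na(cross))) {
      w <- which(cross == min(cross, na.rm = TRUE), arr.ind = TRUE)[1, ]
      nn_distance <- min(cross, na.rm = TRUE)
      nn_species <- sp[other[w[2]]]
    }
    tibble(
      species = s,
      genus = genus_s,
      n_specimens = length(own),
      mean_intra = if (length(intra) > 0) mean(intra) else NA_real_,
      max_intra = if (length(intra) > 0) max(intra) else NA_real_,
      nn_distance = nn_distance,
      nn_species = nn_species,
      mean_congeneric = if (any(!is.na(cong_d))) mean(cong_d, na.rm = TRUE)
                        else NA_real_,
      n_intra_pairs = length(intra),
      n_congeneric_pairs = sum(!is.na(cong_d)),
      n_excluded_pairs = n_excluded
    )
  })
  bind_rows(rows)
}

#' Group summary of barcode-gap statistics
#'
#' Condenses per-species gap rows to one row per group (per genus, or the
#' whole table): the unweighted mean over species of mean and maximum
#' intraspecific variation and of the nearest-neighbour divergence, plus the
#' mean congeneric distance over all congeneric pairs in the group
#' (reconstructed from the per-species means via their pair counts; each
#' pair appears in two species rows, which cancels in the weighted mean).
#'
#' @param gap_rows tibble from [species_gap_table()].
#' @param by `"all"` for a single row, `"genus"` for per-genus rows.
#' @return summary tibble with `n_species`, `n_specimens`, `mean_intra`,
#'   `mean_max_intra`, `mean_congeneric`, `mean_nn`.
#' @export
taxon_summary <- function(gap_rows, by = c("all", "genus")) {
  by <- match.arg(by)
  grouped <- if (by == "genus") group_by(gap_rows, .data$genus) else gap_rows
  out <- grouped |>
    summarise(
      n_species = dplyr::n(),
      n_specimens = sum(.data$n_specimens),
      mean_intra = mean(.data$mean_intra, na.rm = TRUE),
      mean_max_intra = mean(.data$max_intra, na.rm = TRUE),
      mean_congeneric = if (sum(.data$n_congeneric_pairs) > 0) {
        sum(.data$mean_congeneric * .data$n_congeneric_pairs, na.rm = TRUE) /
          sum(.data$n_congeneric_pairs)
      } else NA_real_,
      mean_nn = mean(.data$nn_distance, na.rm = TRUE),
      .groups = "drop"
    )
  if (by == "all") out <- mutate(out, taxon = "all", .before = 1)
  out
}

#' Within-cluster distance summary
#'
#' Mean and maximum internal K2P distance for every cluster with two or more
#' members, and the grand means over those clusters — the cluster-side
#' analogue of intraspecific variation.
#'
#' @param dm `k2p_dist` object.
#' @param partition `otu_partition` or assignment tibble.
#' @return list with `clusters` (tibble `cluster_id`, `n_members`,
#'   `mean_intra`, `max_intra`) and `summary` (one row with grand means and
#'   the number of multi-member clusters).
#' @export
intra_cluster_summary <- function(dm, partition) {
  assignment <- partition_assignment(partition)
  clusters <- sort(unique(assignment$cluster_id))
  rows <- purrr::map(clusters, function(cl) {
    ids <- intersect(dm$ids, assignment$specimen_id[assignment$cluster_id == cl])
    if (length(ids) < 2) return(NULL)
    sub <- dm$d[ids, ids, drop = FALSE]
    v <- sub[upper.tri(sub)]
    v <- v[!is.na(v)]
    tibble(cluster_id = cl, n_members = length(ids),
           mean_intra = if (length(v)) mean(v) else NA_real_,
           max_intra = if (length(v)) max(v) else NA_real_)
  })
  per_cluster <- bind_rows(rows)
  summary <- tibble(
    n_multi_clusters = nrow(per_cluster),
    mean_intra = if (nrow(per_cluster)) mean(per_cluster$mean_intra, na.rm = TRUE)
                 else NA_real_,
    mean_max_intra = if (nrow(per_cluster)) mean(per_cluster$max_intra, na.rm = TRUE)
                     else NA_real_
  )
  list(clusters = per_cluster, summary = summary)
}

#' Randomized accumulation curve
#'
#' Richness (of species or clusters) as specimens are added in random order,
#' averaged over seeded shuffles. Each iteration draws its permutation from
#' a stream derived from `seed` and the iteration index, so extending
#' `iterations` never reshuffles earlier iterations.
#'
#' @param ds specimen tibble.
#' @param labels accumulate `"species"` richness or `"cluster"` richness.
#' @param partition required when `labels = "cluster"`.
#' @param iterations number of random orderings (default 100).
#' @param seed integer seed for the shuffles.
#' @return a tibble of class `accum_curve` with `x` (specimens sampled),
#'   `mean_richness`, `sd_richness`, `label`; attribute `iterations`.
#' @export
accumulation_curve <- function(ds, labels = c("species", "cluster"),
                               partition = NULL, iterations = 100L,
                               seed = 1L) {
  labels <- match.arg(labels)
  stopifnot(iterations >= 1)
  lab <- if (labels == "species") {
    ds$species
  } else {
    if (is.null(partition)) abort("partition is required for cluster richness")
    assignment <- partition_assignment(partition)
    assignment$cluster_id[match(ds$specimen_id, assignment$specimen_id)]
  }
  n <- length(lab)
  rich <- matrix(0L, nrow = iterations, ncol = n)
  for (it in seq_len(iterations)) {
    # per-iteration derived stream; independent of the global RNG state
    iter_seed <- (as.integer(seed) + 10007L * it) %% .Machine$integer.max
    ord <- local({
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(iter_seed)
      sample.int(n)
    })
    rich[it, ] <- cumsum(!duplicated(lab[ord]))
  }
  out <- tibble(
    x = seq_len(n),
    mean_richness = colMeans(rich),
    sd_richness = apply(rich, 2, stats::sd),
    label = labels
  )
  class(out) <- c("accum_curve", class(out))
  attr(out, "iterations") <- iterations
  out
}
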