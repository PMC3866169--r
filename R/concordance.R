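#' Bipartite species-to-OTU map
#'
#' Cross-tabulates species labels against cluster assignments: one row per
#' occupied (species, cluster) cell with its specimen count.
#'
#' @param ds specimen tibble.
#' @param partition `otu_partition` from [cluster_otus()], or a tibble with
#'   `specimen_id` and `cluster_id` columns.
#' @return tibble `species`, `cluster_id`, `n`.
#' @export
species_otu_map <- function(ds, partition) {
  assignment <- partition_assignment(partition)
  orphans <- setdiff(assignment$specimen_id, ds$specimen_id)
  if (length(orphans) > 0) {
    abort(paste0("specimens in the cluster assignment but not the dataset: ",
                 paste(head(orphans, 5), collapse = ", ")))
  }
  assignment |>
    inner_join(select(ds, "specimen_id", "species"), by = "specimen_id") |>
    count(.data$species, .data$cluster_id, name = "n") |>
    arrange(.data$species, .data$cluster_id)
}

partition_assignment <- function(partition) {
  if (inherits(partition, "otu_partition")) return(partition$assignment)
  stopifnot(all(c("specimen_id", "cluster_id") %in% names(partition)))
  as_tibble(partition[, c("specimen_id", "cluster_id")])
}

#' Classify species against sequence clusters
#'
#' Applies the category algebra used to confront traditional species with
#' cluster-based delimitation. With `C(s)` the clusters a species occupies,
#' and a cluster called *shared* when it holds two or more species:
#' * `MATCH` — one cluster, exclusive to the species (1:1 correspondence);
#' * `SHARE` — every occupied cluster is shared;
#' * `SPLIT` — two or more clusters, all exclusive;
#' * `MIXTURE` — two or more clusters, at least one shared and one
#'   exclusive (the species both shares and splits).
#'
#' @param map tibble from [species_otu_map()].
#' @return tibble `species`, `n_otus`, `n_shared`, `n_exclusive`,
#'   `category`.
#' @seealso [concordance_summary()] for dataset-level percentages.
#' @export
classify_species <- function(map) {
  if (nrow(map) == 0) abort("empty species-to-OTU map")
  cluster_species <- map |>
    group_by(.data$cluster_id) |>
    summarise(n_species = dplyr::n_distinct(.data$species), .groups = "drop")
  map |>
    left_join(cluster_species, by = "cluster_id") |>
    group_by(.data$species) |>
    summarise(
      n_otus = dplyr::n_distinct(.data$cluster_id),
      n_shared = sum(.data$n_species >= 2),
      n_exclusive = sum(.data$n_species == 1),
      .groups = "drop"
    ) |>
    mutate(category = dplyr::case_when(
      n_otus == 1 & n_exclusive == 1 ~ "MATCH",
      n_shared >= 1 & n_exclusive == 0 ~ "SHARE",
      n_otus >= 2 & n_shared == 0 ~ "SPLIT",
      TRUE ~ "MIXTURE"
    ))
}

#' Dataset-level concordance summary
#'
#' Counts and percentages for the match/share/split/mixture classification.
#' Mixtures both share and split, so the reported share and split
#' percentages each include them and the three percentages can sum to more
#' than 100. Percentages are rounded to the nearest whole percent, halves
#' away from zero.
#'
#' @param classified tibble from [classify_species()].
#' @return one-row tibble with counts (`n_species`, `n_match`,
#'   `n_share_only`, `n_split_only`, `n_mixture`) and percentages
#'   (`match_pct`, `share_pct`, `split_pct`).
#' @export
concordance_summary <- function(classified) {
  n <- nrow(classified)
  n_match <- sum(classified$category == "MATCH")
  n_share_only <- sum(classified$category == "SHARE")
  n_split_only <- sum(classified$category == "SPLIT")
  n_mixture <- sum(classified$category == "MIXTURE")
  tibble(
    n_species = n,
    n_match = n_match,
    n_share_only = n_share_only,
    n_split_only = n_split_only,
    n_mixture = n_mixture,
    match_pct = round_half_up(100 * n_match / n),
    share_pct = round_half_up(100 * (n_share_only + n_mixture) / n),
    split_pct = round_half_up(100 * (n_split_only + n_mixture) / n)
  )
}

#' Detect barcode sharing between co-clustered species
#'
#' For every species pair that co-occupies at least one cluster, reports the
#' minimum interspecific K2P distance, the witnessing specimen pair, and
#' whether the sharing is `identical` (minimum distance exactly zero — the
#' two species hold at least one indistinguishable haplotype) or
#' `diagnosable` (co-clustered but separated by consistent sequence
#' differences).
#'
#' @param dm `k2p_dist` object.
#' @param ds specimen tibble.
#' @param partition `otu_partition` or assignment tibble.
#' @return tibble `species_a`, `species_b` (a < b), `shared_clusters`,
#'   `min_dist`, `specimen_a`, `specimen_b`, `sharing_type`.
#' @export
detect_barcode_sharing <- function(dm, ds, partition) {
  map <- species_otu_map(ds, partition)
  shared <- map |>
    group_by(.data$cluster_id) |>
    filter(dplyr::n_distinct(.data$species) >= 2) |>
    ungroup()
  if (nrow(shared) == 0) {
    return(tibble(species_a = character(), species_b = character(),
                  shared_clusters = character(), min_dist = numeric(),
                  specimen_a = character(), specimen_b = character(),
                  sharing_type = character()))
  }
  pairs <- shared |>
    inner_join(shared, by = "cluster_id", suffix = c("_a", "_b"),
               relationship = "many-to-many") |>
    filter(.data$species_a < .data$species_b) |>
    group_by(.data$species_a, .data$species_b) |>
    summarise(shared_clusters = paste(sort(unique(.data$cluster_id)),
                                      collapse = ","),
              .groups = "drop")
  sp_of <- setNames(ds$species, ds$specimen_id)
  res <- purrr::pmap(pairs, function(species_a, species_b, shared_clusters) {
    ids_a <- dm$ids[sp_of[dm$ids] == species_a]
    ids_b <- dm$ids[sp_of[dm$ids] == species_b]
    sub <- dm$d[ids_a, ids_b, drop = FALSE]
    if (all(is.na(sub))) {
      return(tibble(species_a = species_a, species_b = species_b,
                    shared_clusters = shared_clusters, min_dist = NA_real_,
                    specimen_a = NA_character_, specimen_b = NA_character_,
                    sharing_type = NA_character_))
    }
    w <- which(sub == min(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    md <- min(sub, na.rm = TRUE)
    tibble(species_a = species_a, species_b = species_b,
           shared_clusters = shared_clusters, min_dist = md,
           specimen_a = ids_a[w[1]], specimen_b = ids_b[w[2]],
           sharing_type = ifelse(md == 0, "identical", "diagnosable"))
  })
  bind_rows(res)
}

#' Attach geography to a sharing table
#'
#' Adds the minimum great-circle distance between the two species of each
#' sharing pair (rounded to 10-km classes for reporting) and the sympatry
#' flag (unrounded minimum under 100 km).
#'
#' @param sharing tibble from [detect_barcode_sharing()].
#' @param ds specimen tibble with `lat`/`lon`.
#' @return `sharing` with `min_km`, `km_class`, `sympatric` columns.
#' @export
add_sharing_geography <- function(sharing, ds) {
  if (nrow(sharing) == 0) {
    return(mutate(sharing, min_km = numeric(), km_class = numeric(),
                  sympatric = logical()))
  }
  geo <- purrr::map2(sharing$species_a, sharing$species_b, function(a, b) {
    min_group_distance(ds,
                       ds$specimen_id[ds$species == a],
                       ds$specimen_id[ds$species == b])
  }) |> bind_rows()
  bind_cols(sharing, select(geo, "min_km", "km_class", "sympatric"))
}

#' Diagnosability and range-wide discrimination percentages
#'
#' A species fails barcode diagnosis when it shares an identical haplotype
#' with another species; it fails within its natural range only when that
#' identical partner is also sympatric (minimum distance under 100 km). Both
#' percentages subtract each affected species once — a species in two
#' identical pairs of a triad is not double-counted — and are rounded to the
#' nearest whole percent.
#'
#' @param sharing tibble from [detect_barcode_sharing()], with a `sympatric`
#'   column (see [add_sharing_geography()]) unless no identical pair exists.
#' @param n_species total species in the denominator.
#' @return one-row tibble with `n_species`, `n_identical_pairs`,
#'   `n_identical_sympatric_pairs`, `diagnostic_pct`,
#'   `range_discriminated_pct`.
#' @export
#' @examples
#' # 215 species; 8 identical pairs of which 3 sympatric -> 93% and 97%
diagnosability_summary <- function(sharing, n_species) {
  identical_pairs <- filter(sharing, .data$sharing_type == "identical")
  if (nrow(identical_pairs) > 0 && !"sympatric" %in% names(identical_pairs)) {
    abort("sharing table lacks a sympatric column; see add_sharing_geography()")
  }
  undiag <- unique(c(identical_pairs$species_a, identical_pairs$species_b))
  symp <- if (nrow(identical_pairs) == 0) identical_pairs else
    filter(identical_pairs, .data$sympatric)
  unrange <- unique(c(symp$species_a, symp$species_b))
  tibble(
    n_species = n_species,
    n_identical_pairs = nrow(identical_pairs),
    n_identical_sympatric_pairs = nrow(symp),
    diagnostic_pct = round_half_up(100 * (n_species - length(undiag)) / n_species),
    range_discriminated_pct =
      round_half_up(100 * (n_species - length(unrange)) / n_species)
  )
}

#' Regional re-identification success
#'
#' Restricts the dataset to one region (the region label is authoritative,
#' not the coordinates), keeps the global cluster assignment, rebuilds the
#' species-to-OTU map on the restriction, and reports per-region
#' re-identification success: the percentage of regional species with
#' diagnostic barcodes (no identical haplotype shared with another regional
#' species) and the percentage with an exact regional species-cluster match.
#'
#' @param ds specimen tibble.
#' @param partition global `otu_partition` or assignment tibble.
#' @param dm global `k2p_dist` object.
#' @param regions character vector of region codes; defaults to all regions
#'   present.
#' @return tibble with one row per region: `region`, `n_species`,
#'   `n_specimens`, `diagnostic_pct`, `match_pct`.
#' @export
regional_reidentification <- function(ds, partition, dm, regions = NULL) {
  regions <- regions %||% sort(unique(ds$region))
  assignment <- partition_assignment(partition)
  rows <- purrr::map(regions, function(rg) {
    sub <- filter(ds, .data$region == rg)
    if (nrow(sub) == 0) {
      return(tibble(region = rg, n_species = 0L, n_specimens = 0L,
                    diagnostic_pct = NA_real_, match_pct = NA_real_))
    }
    sub_assign <- filter(assignment, .data$specimen_id %in% sub$specimen_id)
    map <- species_otu_map(sub, sub_assign)
    cls <- classify_species(map)
    sub_dm <- subset_k2p(dm, intersect(dm$ids, sub$specimen_id))
    sharing <- detect_barcode_sharing(sub_dm, sub, sub_assign)
    undiag <- sharing |>
      filter(.data$sharing_type == "identical")
    undiag_species <- unique(c(undiag$species_a, undiag$species_b))
    n_sp <- nrow(cls)
    tibble(
      region = rg,
      n_species = n_sp,
      n_specimens = nrow(sub),
      diagnostic_pct =
        round_half_up(100 * (n_sp - length(undiag_species)) / n_sp),
      match_pct = round_half_up(100 * sum(cls$category == "MATCH") / n_sp)
    )
  })
  bind_rows(rows)
}
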