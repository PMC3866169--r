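#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km. Vectorized; any
#' missing coordinate yields `NA`.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (WGS84).
#' @return kilometres.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 1)  # ~111.19 km along the equator
haversine_km <- function(lat1, lon1, lat2, lon2) {
  ok <- !(is.na(lat1) | is.na(lon1) | is.na(lat2) | is.na(lon2))
  out <- rep(NA_real_, max(length(lat1), length(lat2)))
  if (any(ok)) {
    out[ok] <- geosphere::distHaversine(
      cbind(rep_len(lon1, length(out))[ok], rep_len(lat1, length(out))[ok]),
      cbind(rep_len(lon2, length(out))[ok], rep_len(lat2, length(out))[ok]),
      r = 6371
    )
  }
  out
}

#' Minimum geographic distance between two specimen groups
#'
#' The minimum great-circle distance over all cross pairs with defined
#' coordinates. Sympatry is decided on the unrounded minimum (strictly under
#' 100 km); for reporting, the distance is also rounded to the nearest 10-km
#' class (halves away from zero).
#'
#' @param ds specimen tibble with `lat`/`lon`.
#' @param ids_a,ids_b non-empty specimen id sets.
#' @param sympatry_km sympatry cutoff in km (default 100, strict `<`).
#' @return one-row tibble: `min_km` (unrounded), `km_class` (10-km class),
#'   `sympatric`, `specimen_a`, `specimen_b` (the witnessing pair),
#'   `n_pairs_compared`. All-NA when no coordinate-bearing cross pair
#'   exists.
#' @export
min_group_distance <- function(ds, ids_a, ids_b, sympatry_km = 100) {
  stopifnot(length(ids_a) > 0, length(ids_b) > 0)
  a <- ds[match(ids_a, ds$specimen_id), ]
  b <- ds[match(ids_b, ds$specimen_id), ]
  a <- a[!is.na(a$lat) & !is.na(a$lon), ]
  b <- b[!is.na(b$lat) & !is.na(b$lon), ]
  if (nrow(a) == 0 || nrow(b) == 0) {
    warn("no coordinate-bearing cross pair; geographic minimum undefined")
    return(tibble(min_km = NA_real_, km_class = NA_real_, sympatric = NA,
                  specimen_a = NA_character_, specimen_b = NA_character_,
                  n_pairs_compared = 0L))
  }
  grid <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  km <- haversine_km(a$lat[grid$i], a$lon[grid$i], b$lat[grid$j], b$lon[grid$j])
  w <- which.min(km)
  tibble(
    min_km = km[w],
    km_class = round_half_up(km[w] / 10) * 10,
    sympatric = km[w] < sympatry_km,
    specimen_a = a$specimen_id[grid$i[w]],
    specimen_b = b$specimen_id[grid$j[w]],
    n_pairs_compared = length(km)
  )
}

#' Geographic and genetic table of within-species cluster splits
#'
#' For every species assigned to two or more clusters, every unordered
#' cluster-pair combination yields one row with the minimum pairwise K2P
#' distance between the two clusters, the
#' minimum geographic distance (with 10-km class and sympatry flag), the
#' cluster sizes and a singleton flag. A species in `k` clusters contributes
#' `choose(k, 2)` rows.
#'
#' @param ds specimen tibble.
#' @param partition `otu_partition` or assignment tibble.
#' @param dm `k2p_dist` object.
#' @param sympatry_km sympatry cutoff in km (default 100).
#' @return tibble `species`, `cluster_a`, `cluster_b`, `n_a`, `n_b`,
#'   `has_singleton`, `min_k2p`, `min_km`, `km_class`, `sympatric`.
#' @export
split_pair_table <- function(ds, partition, dm, sympatry_km = 100) {
  assignment <- partition_assignment(partition)
  map <- species_otu_map(ds, assignment)
  split_species <- map |>
    group_by(.data$species) |>
    filter(dplyr::n_distinct(.data$cluster_id) >= 2) |>
    ungroup()
  if (nrow(split_species) == 0) {
    return(tibble(species = character(), cluster_a = character(),
                  cluster_b = character(), n_a = integer(), n_b = integer(),
                  has_singleton = logical(), min_k2p = numeric(),
                  min_km = numeric(), km_class = numeric(),
                  sympatric = logical()))
  }
  cl_of <- setNames(assignment$cluster_id, assignment$specimen_id)
  rows <- split_species |>
    group_by(.data$species) |>
    dplyr::group_map(function(cells, key) {
      sp <- key$species
      ids_sp <- ds$specimen_id[ds$species == sp]
      combos <- combn(sort(cells$cluster_id), 2)
      purrr::map(seq_len(ncol(combos)), function(k) {
        ca <- combos[1, k]; cb <- combos[2, k]
        ids_a <- ids_sp[cl_of[ids_sp] == ca]
        ids_b <- ids_sp[cl_of[ids_sp] == cb]
        sub <- dm$d[intersect(dm$ids, ids_a), intersect(dm$ids, ids_b),
                    drop = FALSE]
        geo <- min_group_distance(ds, ids_a, ids_b, sympatry_km = sympatry_km)
        tibble(
          species = sp, cluster_a = ca, cluster_b = cb,
          n_a = length(ids_a), n_b = length(ids_b),
          has_singleton = length(ids_a) == 1 || length(ids_b) == 1,
          min_k2p = if (any(!is.na(sub))) min(sub, na.rm = TRUE) else NA_real_,
          min_km = geo$min_km, km_class = geo$km_class,
          sympatric = geo$sympatric
        )
      }) |> bind_rows()
    }) |> bind_rows()
  arrange(rows, .data$species, .data$cluster_a, .data$cluster_b)
}
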