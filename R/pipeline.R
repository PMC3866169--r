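#' Run the full barcode concordance pipeline
#'
#' Orchestrates the whole analysis chain on one specimen table: length
#' filtering, K2P distances (pairwise deletion), refined single-linkage OTU
#' delimitation, species-to-cluster concordance, barcode sharing and
#' diagnosability, barcode-gap statistics, within-cluster variation, split
#' geography, regional re-identification and randomized accumulation
#' curves. All stochastic stages are driven by `seed`, so a re-run with the
#' same inputs reproduces every output byte for byte.
#'
#' @param ds specimen tibble (see [read_barcodes()] / [sim_barcodes()]).
#' @param out_dir optional directory; when given, every table is written as
#'   TSV/JSON (and the tree as Newick) into it.
#' @param seed_threshold,refine_threshold,inflation,expansion clustering
#'   parameters, see [cluster_otus()].
#' @param min_sites barcode length filter, see [filter_barcode_compliant()].
#' @param curve_iterations randomized accumulation iterations.
#' @param seed integer seed for the accumulation shuffles.
#' @param regions regions for the re-identification report (default: all).
#' @param tree build a neighbour-joining tree (off by default; quadratic
#'   memory and cubic time in the number of specimens).
#' @return an object of class `barcode_run`: a list with `data`, `dm`,
#'   `partition`, `map`, `classified`, `concordance`, `sharing`,
#'   `diagnosability`, `gap`, `taxon`, `taxon_by_genus`, `intra_cluster`,
#'   `splits`, `regional`, `curves`, `tree` (or `NULL`), `summary` (one-row
#'   tibble) and `provenance`.
#' @export
run_pipeline <- function(ds, out_dir = NULL, seed_threshold = 0.022,
                         refine_threshold = 0.04, inflation = 2,
                         expansion = 2L, min_sites = 500L,
                         curve_iterations = 100L, seed = 1L,
                         regions = NULL, tree = FALSE) {
  validate_barcodes(ds)
  if (!is.null(regions)) {
    unknown <- setdiff(regions, unique(ds$region))
    if (length(unknown) > 0) {
      abort(paste0("unknown region(s): ", paste(unknown, collapse = ", ")))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  n_input <- nrow(ds)
  filtered <- stage("filter", suppressMessages(
    filter_barcode_compliant(ds, min_sites = min_sites)))
  dm <- stage("distances", k2p_matrix(filtered))
  partition <- stage("clustering", cluster_otus(
    dm, seed_threshold = seed_threshold, refine_threshold = refine_threshold,
    inflation = inflation, expansion = expansion))
  map <- stage("concordance", species_otu_map(filtered, partition))
  classified <- stage("concordance", classify_species(map))
  conc <- concordance_summary(classified)
  sharing <- stage("sharing", detect_barcode_sharing(dm, filtered, partition) |>
                     add_sharing_geography(filtered))
  diag <- diagnosability_summary(sharing, n_species = conc$n_species)
  gap <- stage("gap", species_gap_table(dm, filtered))
  tax <- taxon_summary(gap, by = "all")
  tax_genus <- taxon_summary(gap, by = "genus")
  intra_cl <- stage("gap", intra_cluster_summary(dm, partition))
  splits <- stage("geography", split_pair_table(filtered, partition, dm))
  regional <- stage("regional", regional_reidentification(
    filtered, partition, dm, regions = regions))
  curves <- stage("accumulation", bind_rows(
    accumulation_curve(filtered, "species", iterations = curve_iterations,
                       seed = seed),
    accumulation_curve(filtered, "cluster", partition = partition,
                       iterations = curve_iterations, seed = seed)))
  nj <- if (tree) stage("tree", nj_tree(dm)) else NULL

  sp <- filtered$species[match(dm$ids, filtered$specimen_id)]
  inter <- dm$d[upper.tri(dm$d)][outer(sp, sp, "!=")[upper.tri(dm$d)]]
  n_clusters <- dplyr::n_distinct(partition$assignment$cluster_id)
  summary <- tibble(
    n_records_input = n_input,
    n_dropped_short = n_input - nrow(filtered),
    n_specimens = nrow(filtered),
    n_species = conc$n_species,
    n_clusters = n_clusters,
    cluster_species_discrepancy_pct =
      round_half_up(100 * (n_clusters - conc$n_species) / n_clusters),
    match_pct = conc$match_pct,
    share_pct = conc$share_pct,
    split_pct = conc$split_pct,
    n_mixture = conc$n_mixture,
    diagnostic_pct = diag$diagnostic_pct,
    range_discriminated_pct = diag$range_discriminated_pct,
    n_identical_pairs = diag$n_identical_pairs,
    n_identical_sympatric_pairs = diag$n_identical_sympatric_pairs,
    mean_interspecific = mean(inter, na.rm = TRUE),
    mean_intra = tax$mean_intra,
    mean_max_intra = tax$mean_max_intra,
    mean_congeneric = tax$mean_congeneric,
    mean_nn = tax$mean_nn,
    mean_intra_cluster = intra_cl$summary$mean_intra,
    mean_max_intra_cluster = intra_cl$summary$mean_max_intra,
    n_multi_member_clusters = intra_cl$summary$n_multi_clusters,
    n_split_combinations = nrow(splits),
    allopatric_split_pct = if (nrow(splits) > 0)
      round_half_up(100 * mean(!splits$sympatric, na.rm = TRUE))
      else NA_real_,
    n_saturated_pairs = nrow(dm$undefined_pairs),
    mean_specimens_per_species = nrow(filtered) / conc$n_species
  )
  provenance <- list(
    params = list(seed_threshold = seed_threshold,
                  refine_threshold = refine_threshold,
                  inflation = inflation, expansion = expansion,
                  min_sites = min_sites,
                  curve_iterations = curve_iterations, seed = seed),
    input_hash = rlang::hash(ds[order(ds$specimen_id), ]),
    n_records_input = n_input
  )
  run <- structure(list(
    data = filtered, dm = dm, partition = partition, map = map,
    classified = classified, concordance = conc, sharing = sharing,
    diagnosability = diag, gap = gap, taxon = tax,
    taxon_by_genus = tax_genus, intra_cluster = intra_cl, splits = splits,
    regional = regional, curves = curves, tree = nj, summary = summary,
    provenance = provenance
  ), class = "barcode_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(dataset_manifest(run$data), p("manifest.tsv"))
  write_distance_matrix(run$dm, p("distance_matrix.tsv"))
  readr::write_tsv(run$partition$assignment, p("clusters.tsv"))
  readr::write_tsv(run$classified, p("concordance.tsv"))
  readr::write_tsv(run$concordance, p("concordance_summary.tsv"))
  readr::write_tsv(run$sharing, p("sharing_pairs.tsv"))
  readr::write_tsv(run$gap, p("gap_table.tsv"))
  readr::write_tsv(bind_rows(run$taxon |> rename(genus = "taxon"),
                             run$taxon_by_genus), p("taxon_summary.tsv"))
  readr::write_tsv(run$intra_cluster$clusters, p("intra_cluster.tsv"))
  readr::write_tsv(run$splits, p("split_pairs.tsv"))
  readr::write_tsv(run$regional, p("regional_reidentification.tsv"))
  readr::write_tsv(run$curves, p("accumulation_curves.tsv"))
  if (!is.null(run$tree)) ape::write.tree(run$tree, p("nj_tree.nwk"))
  jsonlite::write_json(c(as.list(run$summary), run$provenance),
                       p("summary.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.barcode_run <- function(x, ...) {
  s <- x$summary
  cat("Barcode concordance run\n")
  cat(sprintf("  %d specimens (%d dropped as short), %d species, %d clusters\n",
              s$n_specimens, s$n_dropped_short, s$n_species, s$n_clusters))
  cat(sprintf("  match %d%% | share %d%% | split %d%% (mixtures: %d)\n",
              s$match_pct, s$share_pct, s$split_pct, s$n_mixture))
  cat(sprintf("  diagnostic barcodes %d%%, within natural range %d%%\n",
              s$diagnostic_pct, s$range_discriminated_pct))
  cat(sprintf(paste0("  mean K2P: intra %.2f%%, congeneric %.2f%%, ",
                     "nearest neighbour %.2f%%\n"),
              100 * s$mean_intra, 100 * s$mean_congeneric, 100 * s$mean_nn))
  invisible(x)
}
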