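test_that("gap rows handle singletons and two-specimen species", {
  base <- strrep("ACGT", 130)
  ds <- toy_ds(
    c(a1 = base, a2 = flip_sites(base, 2), b1 = flip_sites(base, 30)),
    species = c("X a", "X a", "X b")
  )
  dm <- k2p_matrix(ds)
  gap <- species_gap_table(dm, ds)
  a <- gap[gap$species == "X a", ]
  expect_equal(a$n_specimens, 2)
  expect_equal(a$mean_intra, a$max_intra)
  expect_equal(a$mean_intra, dm$d["a1", "a2"])
  expect_equal(a$nn_species, "X b")
  b <- gap[gap$species == "X b", ]
  expect_true(is.na(b$mean_intra) && is.na(b$max_intra))
  expect_equal(b$nn_distance, min(dm$d["b1", c("a1", "a2")]))
})

test_that("gap rows equal brute-force enumeration on random fixtures", {
  sim <- sim_barcodes(scenario_spec(n_species = 8, n_genera = 3,
                                    mean_specimens = 3), seed = 6)
  ds <- sim$data
  dm <- k2p_matrix(ds)
  gap <- species_gap_table(dm, ds)
  want <- brute_gap(dm$d, ds$species, ds$genus)
  expect_equal(gap$mean_intra, want$mean_intra, tolerance = 1e-12)
  expect_equal(gap$max_intra, want$max_intra, tolerance = 1e-12)
  expect_equal(gap$nn_distance, want$nn_distance, tolerance = 1e-12)
  expect_equal(gap$mean_congeneric, want$mean_congeneric, tolerance = 1e-12)
})

test_that("group summaries reweight per-species congeneric means exactly", {
  sim <- sim_barcodes(scenario_spec(n_species = 6, n_genera = 2,
                                    mean_specimens = 4), seed = 8)
  ds <- sim$data
  dm <- k2p_matrix(ds)
  gap <- species_gap_table(dm, ds)
  ts <- taxon_summary(gap, by = "all")
  # oracle: mean over all congeneric pairs, enumerated directly
  sp <- ds$species; gn <- ds$genus
  vals <- c()
  for (i in seq_len(nrow(ds) - 1)) for (j in (i + 1):nrow(ds)) {
    if (sp[i] != sp[j] && gn[i] == gn[j]) vals <- c(vals, dm$d[i, j])
  }
  expect_equal(ts$mean_congeneric, mean(vals), tolerance = 1e-12)
  expect_equal(ts$mean_intra, mean(gap$mean_intra, na.rm = TRUE))
  expect_equal(ts$mean_nn, mean(gap$nn_distance))
  by_genus <- taxon_summary(gap, by = "genus")
  expect_equal(nrow(by_genus), 2)
  expect_equal(sum(by_genus$n_species), nrow(gap))
  # single-species group: congeneric mean undefined
  solo <- taxon_summary(gap[1, ], by = "genus")
  expect_true(is.na(solo$mean_congeneric) || gap$n_congeneric_pairs[1] > 0)
})

test_that("within-cluster summaries cover degenerate and refining cases", {
  base <- strrep("ACGT", 130)
  ds <- toy_ds(
    c(a1 = base, a2 = flip_sites(base, 2), a3 = flip_sites(base, 4),
      b1 = flip_sites(base, 40)),
    species = c("X a", "X a", "X a", "X b")
  )
  dm <- k2p_matrix(ds)
  ca <- tibble::tibble(specimen_id = c("a1", "a2", "a3", "b1"),
                       cluster_id = c("OTU.1", "OTU.1", "OTU.1", "OTU.2"))
  res <- intra_cluster_summary(dm, ca)
  expect_equal(nrow(res$clusters), 1)  # only the 3-member cluster
  v <- c(dm$d["a1", "a2"], dm$d["a1", "a3"], dm$d["a2", "a3"])
  expect_equal(res$clusters$mean_intra, mean(v))
  expect_equal(res$clusters$max_intra, max(v))
  # all-singleton partition: nothing to summarise
  singl <- intra_cluster_summary(dm, tibble::tibble(
    specimen_id = ds$specimen_id, cluster_id = paste0("OTU.", 1:4)))
  expect_equal(singl$summary$n_multi_clusters, 0)
  # clusters refine species: cluster-level max cannot exceed species-level max
  gap <- species_gap_table(dm, ds)
  expect_lte(res$clusters$max_intra, max(gap$max_intra, na.rm = TRUE))
})

test_that("accumulation curves are monotone, bounded and deterministic", {
  sim <- sim_barcodes(scenario_spec(n_species = 6, mean_specimens = 3),
                      seed = 10)
  curve <- accumulation_curve(sim$data, iterations = 20, seed = 5)
  expect_true(all(diff(curve$mean_richness) >= 0))
  expect_equal(curve$mean_richness[nrow(curve)],
               length(unique(sim$data$species)))
  expect_true(all(curve$mean_richness <= length(unique(sim$data$species))))
  again <- accumulation_curve(sim$data, iterations = 20, seed = 5)
  expect_identical(curve, again)
  # growing the iteration count preserves earlier iterations' contribution:
  # iteration streams are derived, so the first-iteration curve is stable
  one <- accumulation_curve(sim$data, iterations = 1, seed = 5)
  expect_equal(one$mean_richness[1] %in% c(1), TRUE)
})

test_that("accumulation means match the closed-form expectation", {
  # under uniform random ordering, E[richness after x draws] has a
  # hypergeometric closed form: S - sum_s C(N - n_s, x) / C(N, x)
  sim <- sim_barcodes(scenario_spec(n_species = 5, mean_specimens = 4),
                      seed = 12)
  ds <- sim$data[1:20, ]
  counts <- table(ds$species)
  N <- sum(counts)
  expected <- vapply(seq_len(N), function(x) {
    sum(1 - exp(lchoose(N - counts, x) - lchoose(N, x)))
  }, numeric(1))
  curve <- accumulation_curve(ds, iterations = 2000, seed = 3)
  se <- curve$sd_richness / sqrt(2000)
  dev <- abs(curve$mean_richness - expected)
  expect_true(all(dev <= pmax(3 * se, 1e-9)))
})

test_that("cluster-labelled curves end at the cluster richness", {
  sim <- sim_barcodes(scenario_spec(
    n_species = 4, scenarios = list(list(type = "SPLIT_ALLOPATRIC"))),
    seed = 14)
  dm <- k2p_matrix(sim$data)
  part <- cluster_otus(dm)
  curve <- accumulation_curve(sim$data, "cluster", partition = part,
                              iterations = 10, seed = 2)
  expect_equal(curve$mean_richness[nrow(curve)],
               dplyr::n_distinct(part$assignment$cluster_id))
})
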