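assignment_of <- function(...) {
  # specimen -> cluster pairs as alternating arguments
  v <- c(...)
  tibble::tibble(specimen_id = names(v), cluster_id = unname(v))
}

ds_of <- function(sp) {
  toy_ds(setNames(rep(strrep("ACGT", 130), length(sp)), names(sp)),
         species = unname(sp))
}

test_that("the species-to-OTU map counts cells and rejects orphans", {
  ds <- ds_of(c(a1 = "X a", a2 = "X a", b1 = "X b"))
  ca <- assignment_of(a1 = "OTU.0001", a2 = "OTU.0002", b1 = "OTU.0002")
  map <- species_otu_map(ds, ca)
  expect_equal(nrow(map), 3)
  expect_equal(sum(map$n), 3)
  expect_equal(map$n[map$species == "X a" & map$cluster_id == "OTU.0001"], 1)
  expect_error(
    species_otu_map(ds[1:2, ], ca),
    "not the dataset")
})

test_that("category algebra covers match, share, split and mixture", {
  # A alone in X -> MATCH
  m1 <- tibble::tibble(species = "A", cluster_id = "X", n = 2)
  expect_equal(classify_species(m1)$category, "MATCH")
  # A and B share X -> both SHARE
  m2 <- tibble::tibble(species = c("A", "B"), cluster_id = "X", n = 1)
  expect_equal(classify_species(m2)$category, c("SHARE", "SHARE"))
  # A split over exclusive X and Y -> SPLIT
  m3 <- tibble::tibble(species = c("A", "A"), cluster_id = c("X", "Y"), n = 1)
  expect_equal(classify_species(m3)$category, "SPLIT")
  # A in shared X and exclusive Y -> MIXTURE; B stays SHARE
  m4 <- tibble::tibble(species = c("A", "A", "B"),
                       cluster_id = c("X", "Y", "X"), n = 1)
  cls <- classify_species(m4)
  expect_equal(cls$category[cls$species == "A"], "MIXTURE")
  expect_equal(cls$category[cls$species == "B"], "SHARE")
})

test_that("summary percentages double-count mixtures and reconcile", {
  cls <- tibble::tibble(
    species = letters[1:10],
    category = c(rep("MATCH", 6), "SHARE", "SHARE", "SPLIT", "MIXTURE")
  )
  s <- concordance_summary(cls)
  expect_equal(s$n_match + s$n_share_only + s$n_split_only + s$n_mixture,
               s$n_species)
  expect_equal(s$match_pct, 60)
  expect_equal(s$share_pct, 30)  # 2 share + 1 mixture
  expect_equal(s$split_pct, 20)  # 1 split + 1 mixture
})

test_that("planted scenario categories are recovered from the truth map", {
  scenarios <- c(
    rep(list(list(type = "SHARE_IDENTICAL")), 2),
    rep(list(list(type = "SPLIT_ALLOPATRIC")), 2),
    list(list(type = "MIXTURE"))
  )
  sim <- sim_barcodes(scenario_spec(n_species = 18, scenarios = scenarios),
                      seed = 2)
  truth_assign <- sim$truth$specimens |>
    dplyr::rename(cluster_id = planted_cluster)
  cls <- classify_species(species_otu_map(sim$data, truth_assign))
  want <- sim$truth$species
  got <- cls$category[match(want$species, cls$species)]
  expect_equal(got, want$category)
  s <- concordance_summary(cls)
  expect_equal(s$n_match, 10)
  expect_equal(s$n_share_only, 5)   # 4 identical sharers + mixture partner
  expect_equal(s$n_split_only, 2)
  expect_equal(s$n_mixture, 1)
})

test_that("sharing is identical at zero distance and diagnosable otherwise", {
  base <- strrep("ACGT", 130)
  ds <- toy_ds(c(a1 = base, a2 = base, b1 = base, c1 = flip_sites(base, 2),
                 d1 = flip_sites(base, 40)),
               species = c("X a", "X a", "X b", "X c", "X d"))
  ca <- assignment_of(a1 = "OTU.1", a2 = "OTU.1", b1 = "OTU.1",
                      c1 = "OTU.1", d1 = "OTU.2")
  dm <- k2p_matrix(ds)
  sharing <- detect_barcode_sharing(dm, ds, ca)
  expect_equal(nrow(sharing), 3)  # pairs among {a,b,c}; d is alone
  ab <- sharing[sharing$species_a == "X a" & sharing$species_b == "X b", ]
  expect_equal(ab$sharing_type, "identical")
  expect_equal(ab$min_dist, 0)
  ac <- sharing[sharing$species_a == "X a" & sharing$species_b == "X c", ]
  expect_equal(ac$sharing_type, "diagnosable")
  expect_gt(ac$min_dist, 0)
  expect_false("X d" %in% c(sharing$species_a, sharing$species_b))
})

test_that("diagnosability arithmetic matches the worked examples", {
  mk_sharing <- function(n_pairs, n_symp) {
    tibble::tibble(
      species_a = sprintf("sp%02da", seq_len(n_pairs)),
      species_b = sprintf("sp%02db", seq_len(n_pairs)),
      sharing_type = "identical",
      sympatric = seq_len(n_pairs) <= n_symp
    )
  }
  # 215 species, 8 identical pairs, 3 of them sympatric -> 93% and 97%
  s <- diagnosability_summary(mk_sharing(8, 3), n_species = 215)
  expect_equal(s$diagnostic_pct, 93)
  expect_equal(s$range_discriminated_pct, 97)
  # no identical pairs -> 100/100
  empty <- tibble::tibble(species_a = character(), species_b = character(),
                          sharing_type = character(), sympatric = logical())
  s2 <- diagnosability_summary(empty, n_species = 50)
  expect_equal(c(s2$diagnostic_pct, s2$range_discriminated_pct), c(100, 100))
  # 10 species, 1 sympatric identical pair -> 80/80
  s3 <- diagnosability_summary(mk_sharing(1, 1), n_species = 10)
  expect_equal(c(s3$diagnostic_pct, s3$range_discriminated_pct), c(80, 80))
})

test_that("a species in a triad is subtracted once, not per pair", {
  triad <- tibble::tibble(
    species_a = c("X a", "X a", "X b"),
    species_b = c("X b", "X c", "X c"),
    sharing_type = "identical",
    sympatric = TRUE
  )
  s <- diagnosability_summary(triad, n_species = 10)
  # 3 distinct species affected, not 6
  expect_equal(s$diagnostic_pct, 70)
})

test_that("regional restriction recomputes success with regional species", {
  base <- strrep("ACGT", 130)
  ds <- toy_ds(
    c(a1 = base, a2 = flip_sites(base, 1), b1 = base,
      c1 = flip_sites(base, 30), d1 = flip_sites(base, 60)),
    species = c("X a", "X a", "X b", "X c", "X d"),
    region = c("FI", "FI", "FI", "Sic", "Sic")
  )
  ca <- assignment_of(a1 = "OTU.1", a2 = "OTU.1", b1 = "OTU.1",
                      c1 = "OTU.2", d1 = "OTU.3")
  dm <- k2p_matrix(ds)
  rep <- regional_reidentification(ds, ca, dm)
  fi <- rep[rep$region == "FI", ]
  # a and b share an identical haplotype in FI: neither diagnostic, no match
  expect_equal(fi$n_species, 2)
  expect_equal(fi$diagnostic_pct, 0)
  expect_equal(fi$match_pct, 0)
  sic <- rep[rep$region == "Sic", ]
  # c and d each alone in their cluster: a perfect regional record
  expect_equal(c(sic$diagnostic_pct, sic$match_pct), c(100, 100))
  # absent region: empty report row
  none <- regional_reidentification(ds, ca, dm, regions = "XX")
  expect_equal(none$n_species, 0)
  expect_true(is.na(none$diagnostic_pct))
})

test_that("regional success rises when subsetting removes sharing partners", {
  # continental dataset: two species share an identical haplotype, but only
  # one of them occurs on the island
  base <- strrep("ACGT", 130)
  ds <- toy_ds(
    c(a1 = base, a2 = base, b1 = base, b2 = flip_sites(base, 1)),
    species = c("X a", "X a", "X b", "X b"),
    region = c("IT", "IT", "IT", "Sar")
  )
  ca <- assignment_of(a1 = "OTU.1", a2 = "OTU.1", b1 = "OTU.1", b2 = "OTU.1")
  dm <- k2p_matrix(ds)
  continental <- diagnosability_summary(
    add_sharing_geography(detect_barcode_sharing(dm, ds, ca), ds),
    n_species = 2)
  regional <- regional_reidentification(ds, ca, dm, regions = "Sar")
  expect_equal(continental$diagnostic_pct, 0)
  expect_equal(regional$diagnostic_pct, 100)
})
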