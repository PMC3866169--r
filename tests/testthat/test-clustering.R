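sym <- function(ids, ...) {
  # build a symmetric distance matrix from i-j-d triples
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  trip <- list(...)
  for (t in trip) {
    d[t[[1]], t[[2]]] <- d[t[[2]], t[[1]]] <- t[[3]]
  }
  d
}

test_that("single-linkage seeds are the thresholded connected components", {
  d <- sym(c("A", "B", "C"), list("A", "B", 0.010),
           list("A", "C", 0.050), list("B", "C", 0.050))
  cl <- seed_clusters(fake_dm(d), threshold = 0.022)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_false(cl$cluster[3] == cl$cluster[1])

  # all pairs above threshold: all singletons
  d2 <- sym(c("A", "B", "C"), list("A", "B", 0.05), list("A", "C", 0.05),
            list("B", "C", 0.05))
  expect_equal(dplyr::n_distinct(seed_clusters(fake_dm(d2), 0.022)$cluster), 3)

  # chaining: A-C exceeds the threshold but joins through B
  d3 <- sym(c("A", "B", "C"), list("A", "B", 0.02), list("B", "C", 0.02),
            list("A", "C", 0.04))
  expect_equal(dplyr::n_distinct(seed_clusters(fake_dm(d3), 0.022)$cluster), 1)
})

test_that("seed clusters equal brute-force components on random graphs", {
  set.seed(23)
  for (k in 1:5) {
    n <- 50
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.06)
    d <- d + t(d)
    # sprinkle undefined pairs, which must act as non-edges
    idx <- which(upper.tri(d))[sample(n * (n - 1) / 2, 20)]
    d[idx] <- NA
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
    got <- seed_clusters(fake_dm(d), 0.022)$cluster
    want <- brute_components(d, 0.022)
    expect_equal(mclust::adjustedRandIndex(got, want), 1)
  }
})

test_that("MCL splits two cliques joined by a weak bridge", {
  ids <- paste0("s", 1:6)
  d <- matrix(0.06, 6, 6, dimnames = list(ids, ids))
  diag(d) <- 0
  d[1:3, 1:3] <- 0.005; d[4:6, 4:6] <- 0.005; diag(d) <- 0
  d["s3", "s4"] <- d["s4", "s3"] <- 0.035
  W <- 1 - d / 0.04
  W[W < 0] <- 0
  diag(W) <- 1
  res <- mcl(W, inflation = 2, expansion = 2)
  expect_true(res$converged)
  expect_equal(res$membership[1:3], rep(res$membership[1], 3))
  expect_equal(res$membership[4:6], rep(res$membership[4], 3))
  expect_false(res$membership[1] == res$membership[4])
  # the same split falls out of refine_clusters on a manual seed
  seed <- tibble::tibble(specimen_id = ids, cluster = 1L)
  ref <- refine_clusters(seed, fake_dm(d), refine_threshold = 0.04)
  expect_equal(dplyr::n_distinct(ref$cluster), 2)
})

test_that("MCL keeps transition matrices column-stochastic throughout", {
  set.seed(11)
  for (k in 1:5) {
    n <- sample(4:12, 1)
    W <- matrix(runif(n * n), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- 1
    res <- mcl(W, inflation = 2, expansion = 2)
    expect_true(all(res$colsum_dev < 1e-9))
  }
})

test_that("singletons and tight seed clusters pass through refinement", {
  ids <- c("a", "b", "c")
  d <- sym(ids, list("a", "b", 0.005), list("a", "c", 0.005),
           list("b", "c", 0.005))
  seed <- tibble::tibble(specimen_id = ids, cluster = c(1L, 1L, 1L))
  ref <- refine_clusters(seed, fake_dm(d), refine_threshold = 0.04)
  expect_equal(dplyr::n_distinct(ref$cluster), 1)
  one <- refine_clusters(tibble::tibble(specimen_id = "a", cluster = 1L),
                         subset_k2p(fake_dm(d), "a"))
  expect_equal(nrow(one), 1)
})

test_that("refinement never crosses seed-cluster boundaries", {
  sim <- sim_mixed_survey(seed = 4)
  dm <- k2p_matrix(sim$data)
  seed <- seed_clusters(dm)
  refined <- refine_clusters(seed, dm)
  joined <- dplyr::left_join(seed, refined, by = "specimen_id",
                             suffix = c("_seed", "_ref"))
  spans <- joined |>
    dplyr::distinct(.data$cluster_seed, .data$cluster_ref) |>
    dplyr::count(.data$cluster_ref)
  expect_true(all(spans$n == 1))
})

test_that("OTU ids follow the smallest-member ordering and are stable", {
  memb <- tibble::tibble(specimen_id = c("B", "A", "C"),
                         cluster = c(1L, 1L, 2L))
  ids <- assign_otu_ids(memb)
  expect_equal(ids$cluster_id[ids$specimen_id %in% c("A", "B")],
               rep("OTU.0001", 2))
  expect_equal(ids$cluster_id[ids$specimen_id == "C"], "OTU.0002")
  # permuting input rows (and cluster integer labels) changes nothing
  memb2 <- tibble::tibble(specimen_id = c("C", "A", "B"),
                          cluster = c(9L, 4L, 4L))
  ids2 <- assign_otu_ids(memb2)
  expect_equal(dplyr::arrange(ids, specimen_id),
               dplyr::arrange(ids2, specimen_id))
  expect_equal(nrow(assign_otu_ids(tibble::tibble(specimen_id = character(),
                                                  cluster = integer()))), 0)
})

test_that("the full clustering is deterministic across record order", {
  sim <- sim_barcodes(scenario_spec(n_species = 8), seed = 21)
  dm1 <- k2p_matrix(sim$data)
  set.seed(3)
  perm <- sample(nrow(sim$data))
  dm2 <- k2p_matrix(sim$data[perm, ])
  a1 <- dplyr::arrange(cluster_otus(dm1)$assignment, specimen_id)
  a2 <- dplyr::arrange(cluster_otus(dm2)$assignment, specimen_id)
  expect_equal(a1, a2)
})

test_that("neighbour joining solves the three-point configuration", {
  d <- sym(c("A", "B", "C"), list("A", "B", 0.2), list("A", "C", 0.3),
           list("B", "C", 0.4))
  tr <- nj_tree(fake_dm(d))
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(0.05, 0.15, 0.25))
})

test_that("neighbour joining recovers an additive four-taxon tree", {
  # tree ((A:0.1,B:0.2):0.05,C:0.15,D:0.3)
  ids <- c("A", "B", "C", "D")
  d <- sym(ids, list("A", "B", 0.3), list("A", "C", 0.3), list("A", "D", 0.45),
           list("B", "C", 0.4), list("B", "D", 0.55), list("C", "D", 0.45))
  tr <- nj_tree(fake_dm(d))
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[ids, ids], d,
               tolerance = 1e-10)
  ref <- ape::nj(as.dist(d))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("equidistant taxa yield equal path lengths and NA distances error", {
  ids <- c("A", "B", "C", "D")
  d <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(d) <- 0
  tr <- nj_tree(fake_dm(d))
  coph <- as.matrix(ape::cophenetic.phylo(tr))[ids, ids]
  expect_equal(unname(coph[upper.tri(coph)]), rep(0.5, 6), tolerance = 1e-10)

  d_na <- d; d_na["A", "B"] <- d_na["B", "A"] <- NA
  expect_error(nj_tree(fake_dm(d_na)), "undefined")
})
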