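#' Single-linkage seed clusters
#'
#' Stage one of refined single-linkage OTU delimitation: specimens are the
#' nodes of a graph with an edge wherever the pairwise distance is defined
#' and at most `threshold`; seed clusters are the connected components.
#' Transitivity is intentional — a chain of close pairs joins specimens whose
#' direct distance exceeds the threshold.
#'
#' @param dm `k2p_dist` object from [k2p_matrix()].
#' @param threshold maximum within-edge distance, as a fraction (default
#'   0.022, the published operating point of the BIN clustering algorithm).
#' @return tibble with columns `specimen_id` and integer `cluster`.
#' @export
seed_clusters <- function(dm, threshold = 0.022) {
  stopifnot(inherits(dm, "k2p_dist"), threshold > 0)
  n <- length(dm$ids)
  if (n == 0) {
    return(tibble(specimen_id = character(), cluster = integer()))
  }
  adj <- !is.na(dm$d) & dm$d <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  tibble(specimen_id = dm$ids, cluster = as.integer(memb))
}

#' Markov clustering of a similarity matrix
#'
#' Plain MCL: the column-normalized similarity matrix is alternately expanded
#' (matrix power) and inflated (element-wise power followed by column
#' renormalization) until the transition matrix reaches a fixed point. The
#' final clusters are the connected components of the symmetrized support of
#' the converged matrix.
#'
#' @param W square non-negative similarity matrix; self-loops should be on
#'   the diagonal.
#' @param inflation inflation exponent (> 1).
#' @param expansion integer matrix-power for expansion.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the max absolute change.
#' @return list with integer `membership`, `iterations`, `converged`, and
#'   `colsum_dev`, the per-iteration maximum deviation of column sums from 1
#'   (a stochasticity audit trail).
#' @export
mcl <- function(W, inflation = 2, expansion = 2L, max_iter = 100L,
                tol = 1e-6) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), inflation > 1, expansion >= 1)
  n <- nrow(W)
  if (n == 1L) {
    return(list(membership = 1L, iterations = 0L, converged = TRUE,
                colsum_dev = numeric()))
  }
  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(W)
  dev <- numeric()
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Mexp <- M
    if (expansion > 1) {
      for (k in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    }
    Mnew <- normalize(Mexp^inflation)
    dev <- c(dev, max(abs(colSums(Mnew) - 1)))
    if (max(abs(Mnew - M)) < tol) {
      M <- Mnew
      converged <- TRUE
      break
    }
    M <- Mnew
  }
  support <- (M > 1e-5) | t(M > 1e-5)
  diag(support) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected")
  list(membership = as.integer(igraph::components(g)$membership),
       iterations = iter, converged = converged, colsum_dev = dev)
}

#' Markov-clustering refinement of seed clusters
#'
#' Stage two of refined single-linkage: each seed cluster whose internal
#' diameter (maximum pairwise distance) exceeds `refine_threshold` is
#' re-examined by MCL on the similarity graph with weights
#' `1 - d / refine_threshold` (clipped at zero, unit self-loops). Tight seed
#' clusters pass through untouched, and refined clusters never span seed
#' boundaries. Non-convergent refinements keep the seed cluster intact with
#' a warning.
#'
#' @param seed tibble from [seed_clusters()].
#' @param dm `k2p_dist` object.
#' @param refine_threshold diameter trigger and weight scale (default 0.04,
#'   matching the divergence conventionally treated as a deep split).
#' @param inflation,expansion,max_iter,tol MCL controls, see [mcl()].
#' @param trace if `TRUE`, keep per-seed-cluster MCL diagnostics.
#' @return tibble `specimen_id`, `cluster` (integers, renumbered), with an
#'   attribute `mcl_log` when `trace = TRUE`.
#' @export
refine_clusters <- function(seed, dm, refine_threshold = 0.04, inflation = 2,
                            expansion = 2L, max_iter = 100L, tol = 1e-6,
                            trace = FALSE) {
  stopifnot(inherits(dm, "k2p_dist"))
  out <- seed
  out$cluster_refined <- NA_integer_
  log <- list()
  next_id <- 0L
  for (cl in sort(unique(seed$cluster))) {
    ids <- seed$specimen_id[seed$cluster == cl]
    sub <- dm$d[ids, ids, drop = FALSE]
    internal <- sub[upper.tri(sub)]
    needs_refine <- length(ids) > 1 &&
      any(!is.na(internal) & internal > refine_threshold)
    if (!needs_refine) {
      next_id <- next_id + 1L
      out$cluster_refined[match(ids, out$specimen_id)] <- next_id
      next
    }
    W <- 1 - sub / refine_threshold
    W[is.na(W) | W < 0] <- 0
    diag(W) <- 1
    res <- mcl(W, inflation = inflation, expansion = expansion,
               max_iter = max_iter, tol = tol)
    if (!res$converged) {
      warn(paste0("MCL did not converge for seed cluster ", cl,
                  "; keeping it intact"))
      next_id <- next_id + 1L
      out$cluster_refined[match(ids, out$specimen_id)] <- next_id
    } else {
      out$cluster_refined[match(ids, out$specimen_id)] <-
        next_id + res$membership
      next_id <- next_id + max(res$membership)
    }
    if (trace) log[[as.character(cl)]] <- res
  }
  res <- tibble(specimen_id = out$specimen_id,
                cluster = out$cluster_refined)
  if (trace) attr(res, "mcl_log") <- log
  res
}

#' Assign stable OTU identifiers
#'
#' Clusters receive identifiers `OTU.0001`, `OTU.0002`, ... allocated in the
#' order of each cluster's lexicographically smallest member id, so the
#' labelling is invariant to record order and re-runs.
#'
#' @param membership tibble with `specimen_id` and `cluster` columns.
#' @return tibble `specimen_id`, `cluster_id`.
#' @export
assign_otu_ids <- function(membership) {
  if (nrow(membership) == 0) {
    return(tibble(specimen_id = character(), cluster_id = character()))
  }
  anchors <- membership |>
    group_by(.data$cluster) |>
    summarise(anchor = min(.data$specimen_id), .groups = "drop") |>
    arrange(.data$anchor) |>
    mutate(cluster_id = sprintf("OTU.%04d", row_number()))
  membership |>
    left_join(select(anchors, "cluster", "cluster_id"), by = "cluster") |>
    select("specimen_id", "cluster_id")
}

#' Delimit OTUs by refined single-linkage
#'
#' The full two-stage procedure used by the BIN system: single-linkage seed
#' clusters at `seed_threshold`, Markov-clustering refinement of seed
#' clusters wider than `refine_threshold`, and stable OTU identifiers.
#'
#' @inheritParams seed_clusters
#' @inheritParams refine_clusters
#' @param seed_threshold single-linkage edge threshold (default 0.022).
#' @return an object of class `otu_partition`: list with `assignment`
#'   (tibble `specimen_id`, `cluster_id`), `seed` (stage-one tibble),
#'   `params`, and `mcl_log` (when `trace = TRUE`). `tidy()` returns the
#'   assignment, `glance()` one summary row.
#' @export
#' @examples
#' ds <- sim_barcodes(scenario_spec(n_species = 5), seed = 1)$data
#' dm <- k2p_matrix(ds)
#' part <- cluster_otus(dm)
#' glance(part)
cluster_otus <- function(dm, seed_threshold = 0.022, refine_threshold = 0.04,
                         inflation = 2, expansion = 2L, max_iter = 100L,
                         tol = 1e-6, trace = FALSE) {
  seed <- seed_clusters(dm, threshold = seed_threshold)
  refined <- refine_clusters(seed, dm, refine_threshold = refine_threshold,
                             inflation = inflation, expansion = expansion,
                             max_iter = max_iter, tol = tol, trace = trace)
  assignment <- assign_otu_ids(refined)
  structure(list(
    assignment = assignment,
    seed = seed,
    params = list(seed_threshold = seed_threshold,
                  refine_threshold = refine_threshold,
                  mcl_inflation = inflation, mcl_expansion = expansion,
                  max_iter = max_iter, tol = tol),
    mcl_log = attr(refined, "mcl_log")
  ), class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  k <- dplyr::n_distinct(x$assignment$cluster_id)
  cat("OTU partition:", nrow(x$assignment), "specimens in", k, "clusters\n")
  cat(sprintf("  seed threshold %.3f, refine threshold %.3f, inflation %.1f\n",
              x$params$seed_threshold, x$params$refine_threshold,
              x$params$mcl_inflation))
  invisible(x)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with two determinism conventions: ties
#' in the Q-criterion are broken towards the lexicographically smallest label
#' pair, and negative branch lengths are clamped to zero with the excess
#' moved to the sister branch (preserving the path length through the new
#' node). All pairwise distances must be defined.
#'
#' @param dm `k2p_dist` object with at least three specimens.
#' @return an `ape` `phylo` tree (unrooted, with branch lengths).
#' @export
nj_tree <- function(dm) {
  stopifnot(inherits(dm, "k2p_dist"))
  D <- dm$d
  if (nrow(D) < 3) abort("neighbour joining needs at least 3 taxa")
  if (anyNA(D) || nrow(dm$invalid_pairs) > 0) {
    abort(paste0("undefined distances present; exclude the affected records ",
                 "before building a tree"))
  }
  labels <- dm$ids
  frag <- labels                      # newick fragment per active node
  anchor <- labels                    # smallest original label in the clade
  active <- seq_along(labels)
  while (length(active) > 3) {
    n <- length(active)
    Dsub <- D[active, active, drop = FALSE]
    r <- rowSums(Dsub)
    Qm <- (n - 2) * Dsub - outer(r, r, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(anchor[active[ij[1]]], anchor[active[ij[2]]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- active[pick[1]]
    j <- active[pick[2]]
    dij <- D[i, j]
    vi <- dij / 2 + (r[pick[1]] - r[pick[2]]) / (2 * (n - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    dk <- (D[i, active] + D[j, active] - dij) / 2
    D[i, active] <- dk
    D[active, i] <- dk
    D[i, i] <- 0
    frag[i] <- new_frag
    anchor[i] <- min(anchor[i], anchor[j])
    active <- setdiff(active, j)
  }
  a <- active[1]; b <- active[2]; c <- active[3]
  va <- (D[a, b] + D[a, c] - D[b, c]) / 2
  vb <- (D[a, b] + D[b, c] - D[a, c]) / 2
  vc <- (D[a, c] + D[b, c] - D[a, b]) / 2
  va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    frag[a], va, frag[b], vb, frag[c], vc)
  ape::read.tree(text = newick)
}
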