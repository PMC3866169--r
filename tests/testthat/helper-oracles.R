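# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (per-site loops, union-find) so they cannot share a bug
# with the vectorized implementations they check.

# per-site K2P counter: loops over positions and classifies each explicitly
brute_k2p <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  n <- 0L; ts <- 0L; tv <- 0L
  purines <- c("A", "G")
  for (i in seq_along(ca)) {
    x <- ca[i]; y <- cb[i]
    if (!(x %in% c("A", "C", "G", "T")) || !(y %in% c("A", "C", "G", "T"))) next
    n <- n + 1L
    if (x == y) next
    if ((x %in% purines) == (y %in% purines)) ts <- ts + 1L else tv <- tv + 1L
  }
  if (n == 0L) return(list(n = 0L, P = NA, Q = NA, d = NA))
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1 * sqrt(w2))
  list(n = n, P = P, Q = Q, d = d)
}

# connected components of the thresholded distance graph via union-find
brute_components <- function(d, threshold) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.na(d[i, j]) && d[i, j] <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# per-species gap statistics by explicit loops
brute_gap <- function(D, species, genus) {
  out <- list()
  for (s in sort(unique(species))) {
    own <- which(species == s)
    other <- which(species != s)
    g <- genus[own[1]]
    intra <- c()
    if (length(own) >= 2) {
      for (i in seq_along(own)) for (j in seq_along(own)) {
        if (i < j) intra <- c(intra, D[own[i], own[j]])
      }
    }
    intra <- intra[!is.na(intra)]
    nn <- Inf; nn_sp <- NA
    cong <- c()
    for (i in own) for (j in other) {
      v <- D[i, j]
      if (!is.na(v) && v < nn) { nn <- v; nn_sp <- species[j] }
      if (genus[j] == g && !is.na(v)) cong <- c(cong, v)
    }
    out[[s]] <- data.frame(
      species = s,
      mean_intra = if (length(intra)) mean(intra) else NA,
      max_intra = if (length(intra)) max(intra) else NA,
      nn_distance = if (is.finite(nn)) nn else NA,
      nn_species = nn_sp,
      mean_congeneric = if (length(cong)) mean(cong) else NA
    )
  }
  do.call(rbind, out)
}

# wrap a plain distance matrix as a k2p_dist so clustering/NJ can be tested
# on hand-built fixtures
fake_dm <- function(d, ids = NULL) {
  ids <- ids %||% rownames(d) %||% paste0("s", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  n <- nrow(d)
  structure(list(
    ids = ids, d = d,
    n_sites = matrix(658L, n, n, dimnames = list(ids, ids)),
    P = d / 2, Q = d / 2,
    undefined_pairs = tibble::tibble(id_a = character(), id_b = character()),
    invalid_pairs = tibble::tibble(id_a = character(), id_b = character())
  ), class = "k2p_dist")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# minimal specimen table from named sequences
toy_ds <- function(seqs, species = names(seqs), genus = "GenusA",
                   region = "IT", lat = 42, lon = 13) {
  tibble::tibble(
    specimen_id = names(seqs),
    species = species,
    genus = genus,
    subfamily = "Subfam1",
    region = region,
    lat = lat,
    lon = lon,
    sequence = unname(seqs)
  )
}

# random ACGT string
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# mutate a sequence string at k chosen positions (first k sites), cycling
# each base to a fixed partner
flip_sites <- function(s, k, map = c(A = "G", C = "T", G = "A", T = "C")) {
  ch <- strsplit(s, "")[[1]]
  ch[seq_len(k)] <- map[ch[seq_len(k)]]
  paste(ch, collapse = "")
}
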