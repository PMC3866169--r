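#' Kimura 2-parameter comparison of one sequence pair
#'
#' Classifies aligned sites under pairwise deletion: positions where either
#' sequence has a gap or an ambiguity code are excluded, transitions
#' (A<->G, C<->T) and transversions (all other differences) are counted over
#' the remaining `n_sites`, and the K2P distance
#' \deqn{d = -\tfrac{1}{2}\ln\left[(1-2P-Q)\sqrt{1-2Q}\right]}
#' is evaluated, where `P` and `Q` are the transition and transversion
#' proportions. When no comparable site exists the comparison is invalid;
#' when the logarithm's argument is non-positive the pair is saturated and
#' the distance undefined.
#'
#' @param seq_a,seq_b aligned nucleotide strings of equal length.
#' @return one-row tibble with `n_sites`, `P`, `Q`, `p_dist` (= P + Q),
#'   `k2p` (NA when undefined), `valid` (any comparable site) and
#'   `saturated`.
#' @export
#' @examples
#' k2p_pair("ACGT", "ACGA")  # one transversion over four sites
k2p_pair <- function(seq_a, seq_b) {
  a <- encode_seq(seq_a)
  b <- encode_seq(seq_b)
  if (length(a) != length(b)) {
    abort("sequences must have equal aligned length")
  }
  ok <- a > 0L & b > 0L
  n <- sum(ok)
  if (n == 0L) {
    return(tibble(n_sites = 0L, P = NA_real_, Q = NA_real_,
                  p_dist = NA_real_, k2p = NA_real_,
                  valid = FALSE, saturated = FALSE))
  }
  da <- a[ok]
  db <- b[ok]
  diff <- da != db
  # transitions stay within the purine {A,G} or pyrimidine {C,T} class
  purine_a <- da == 1L | da == 3L
  purine_b <- db == 1L | db == 3L
  ts <- sum(diff & (purine_a == purine_b))
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- w1 <= 0 || w2 <= 0
  d <- if (saturated) NA_real_ else -0.5 * log(w1 * sqrt(w2))
  tibble(n_sites = n, P = P, Q = Q, p_dist = P + Q, k2p = d,
         valid = TRUE, saturated = saturated)
}

#' All-pairs Kimura 2-parameter distance matrix
#'
#' Computes K2P distances with pairwise deletion between every unordered pair
#' of records. Site-class counts are obtained through cross-products of
#' one-hot base indicators, so the full matrix is computed in a handful of
#' BLAS calls rather than per-pair loops.
#'
#' @param ds specimen tibble (normally already filtered with
#'   [filter_barcode_compliant()]).
#' @return an object of class `k2p_dist`: a list with `ids`, distance matrix
#'   `d` (NA where undefined), compared-site matrix `n_sites`, `P` and `Q`
#'   matrices, and `undefined_pairs` / `invalid_pairs` tibbles. Use
#'   [tidy.k2p_dist()] for a long pair table and `as.matrix()`/`as.dist()`
#'   for interoperability.
#' @export
k2p_matrix <- function(ds) {
  validate_barcodes(ds)
  ids <- ds$specimen_id
  n <- length(ids)
  empty <- function() {
    structure(list(
      ids = ids,
      d = matrix(0, n, n, dimnames = list(ids, ids)),
      n_sites = matrix(0L, n, n, dimnames = list(ids, ids)),
      P = matrix(0, n, n, dimnames = list(ids, ids)),
      Q = matrix(0, n, n, dimnames = list(ids, ids)),
      undefined_pairs = tibble(id_a = character(), id_b = character()),
      invalid_pairs = tibble(id_a = character(), id_b = character())
    ), class = "k2p_dist")
  }
  if (n < 2) {
    warn("fewer than 2 records: returning an empty distance matrix")
    return(empty())
  }
  L <- nchar(ds$sequence)
  if (length(unique(L)) != 1) {
    abort("sequences must share one aligned length; see read_barcodes()")
  }
  M <- matrix(unlist(strsplit(toupper(ds$sequence), "", fixed = TRUE)),
              nrow = n, byrow = TRUE)
  XA <- (M == "A") * 1
  XC <- (M == "C") * 1
  XG <- (M == "G") * 1
  XT <- (M == "T") * 1
  V <- XA + XC + XG + XT
  N <- tcrossprod(V)                       # comparable sites per pair
  S <- tcrossprod(XA) + tcrossprod(XC) + tcrossprod(XG) + tcrossprod(XT)
  TS <- tcrossprod(XA, XG) + tcrossprod(XG, XA) +
    tcrossprod(XC, XT) + tcrossprod(XT, XC)
  TV <- N - S - TS
  P <- ifelse(N > 0, TS / N, NA_real_)
  Q <- ifelse(N > 0, TV / N, NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- ifelse(!is.na(w1) & w1 > 0 & w2 > 0, -0.5 * log(w1 * sqrt(w2)), NA_real_)
  diag(d) <- 0
  dimnames(d) <- dimnames(N) <- dimnames(P) <- dimnames(Q) <- list(ids, ids)

  up <- which(upper.tri(N), arr.ind = TRUE)
  invalid <- up[N[up] == 0, , drop = FALSE]
  undef <- up[N[up] > 0 & is.na(d[up]), , drop = FALSE]
  structure(list(
    ids = ids,
    d = d,
    n_sites = matrix(as.integer(N), n, n, dimnames = list(ids, ids)),
    P = P, Q = Q,
    undefined_pairs = tibble(id_a = ids[undef[, 1]], id_b = ids[undef[, 2]]),
    invalid_pairs = tibble(id_a = ids[invalid[, 1]], id_b = ids[invalid[, 2]])
  ), class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  n <- length(x$ids)
  cat("K2P distance matrix:", n, "specimens,",
      n * (n - 1) / 2, "pairs\n")
  if (nrow(x$undefined_pairs) > 0) {
    cat("  saturated (undefined) pairs:", nrow(x$undefined_pairs), "\n")
  }
  if (nrow(x$invalid_pairs) > 0) {
    cat("  invalid pairs (no comparable site):", nrow(x$invalid_pairs), "\n")
  }
  finite <- x$d[upper.tri(x$d)]
  finite <- finite[!is.na(finite)]
  if (length(finite) > 0) {
    cat(sprintf("  distances: mean %.4f, range [%.4f, %.4f]\n",
                mean(finite), min(finite), max(finite)))
  }
  invisible(x)
}

#' @export
as.matrix.k2p_dist <- function(x, ...) x$d

#' @export
as.dist.k2p_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Subset a distance matrix to a set of specimens
#'
#' @param dm `k2p_dist` object.
#' @param ids specimen ids to keep (order preserved as given).
#' @return a `k2p_dist` restricted to `ids`.
#' @export
subset_k2p <- function(dm, ids) {
  stopifnot(inherits(dm, "k2p_dist"))
  missing_ids <- setdiff(ids, dm$ids)
  if (length(missing_ids) > 0) {
    abort(paste0("ids not in distance matrix: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  keep_pair <- function(tb) filter(tb, .data$id_a %in% ids & .data$id_b %in% ids)
  structure(list(
    ids = ids,
    d = dm$d[ids, ids, drop = FALSE],
    n_sites = dm$n_sites[ids, ids, drop = FALSE],
    P = dm$P[ids, ids, drop = FALSE],
    Q = dm$Q[ids, ids, drop = FALSE],
    undefined_pairs = keep_pair(dm$undefined_pairs),
    invalid_pairs = keep_pair(dm$invalid_pairs)
  ), class = "k2p_dist")
}

#' Write a distance matrix to disk
#'
#' @param dm `k2p_dist` object.
#' @param path output file.
#' @param format `"tsv"` for a square labelled matrix, `"phylip"` for the
#'   PHYLIP distance format used by neighbour-joining tools.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(dm$d)
    df <- cbind(specimen_id = rownames(df), df)
    readr::write_tsv(as_tibble(df), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(dm$ids)), con)
    for (i in seq_along(dm$ids)) {
      writeLines(paste0(formatC(dm$ids[i], width = -10),
                        paste(sprintf("%.6f", dm$d[i, ]), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
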