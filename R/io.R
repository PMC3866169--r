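#' Read a barcode dataset from FASTA plus a specimen metadata table
#'
#' Assembles the analysis table from two files: a FASTA of (aligned or
#' alignable) COI barcode sequences whose headers are specimen identifiers,
#' and a tab-separated metadata table with columns `specimen_id`, `species`,
#' `genus`, `subfamily`, `region`, `lat`, `lon`. Records present in only one
#' of the two files are dropped with a message. Sequences are upper-cased and
#' right-padded with `-` to a common alignment length (COI barcodes are
#' length-conserved, so no alignment is attempted).
#'
#' @param fasta_path path to a FASTA file; headers must be specimen ids.
#' @param metadata_path path to a tab-separated metadata file with a header.
#' @return A tibble with one row per specimen and columns
#'   `specimen_id`, `species`, `genus`, `subfamily`, `region`, `lat`, `lon`,
#'   `sequence`, `n_acgt` (count of unambiguous nucleotides) and
#'   `barcode_compliant` (`n_acgt > 500`).
#' @seealso [write_barcodes()], [filter_barcode_compliant()]
#' @export
read_barcodes <- function(fasta_path, metadata_path) {
  seqs <- ape::read.FASTA(fasta_path)
  seq_chr <- toupper(vapply(as.character(seqs), paste, "", collapse = ""))
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate specimen_id in FASTA: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            specimen_id = readr::col_character(),
                            species = readr::col_character(),
                            genus = readr::col_character(),
                            subfamily = readr::col_character(),
                            region = readr::col_character(),
                            lat = readr::col_character(),
                            lon = readr::col_character()
                          ))
  if (anyDuplicated(meta$specimen_id)) {
    abort(paste0("duplicate specimen_id in metadata: ",
                 paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
                       collapse = ", ")))
  }
  # unparseable coordinates become missing, with a warning
  parse_coord <- function(x, what, lim) {
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & nzchar(x) & is.na(v)
    out_of_range <- !is.na(v) & abs(v) > lim
    if (any(bad | out_of_range)) {
      warn(paste0(sum(bad | out_of_range), " unparseable or out-of-range ",
                  what, " value(s) set to missing"))
      v[out_of_range] <- NA_real_
    }
    v
  }
  meta$lat <- parse_coord(meta$lat, "latitude", 90)
  meta$lon <- parse_coord(meta$lon, "longitude", 180)

  orphan_fasta <- setdiff(ids, meta$specimen_id)
  orphan_meta <- setdiff(meta$specimen_id, ids)
  if (length(orphan_fasta) > 0) {
    inform(paste0("dropping ", length(orphan_fasta),
                  " FASTA record(s) without metadata: ",
                  paste(head(orphan_fasta, 5), collapse = ", ")))
  }
  if (length(orphan_meta) > 0) {
    inform(paste0("dropping ", length(orphan_meta),
                  " metadata row(s) without a sequence: ",
                  paste(head(orphan_meta, 5), collapse = ", ")))
  }
  keep_ids <- ids[ids %in% meta$specimen_id]
  ds <- meta |>
    filter(.data$specimen_id %in% keep_ids) |>
    mutate(sequence = unname(seq_chr[match(.data$specimen_id, ids)]))
  # pad to a common alignment length
  len <- nchar(ds$sequence)
  aln <- max(len)
  short <- len < aln
  ds$sequence[short] <- paste0(
    ds$sequence[short],
    vapply(aln - len[short], function(k) strrep("-", k), "")
  )
  ds <- ds |>
    mutate(
      n_acgt = n_unambiguous(.data$sequence),
      barcode_compliant = .data$n_acgt > 500L
    )
  validate_barcodes(ds)
  as_tibble(ds)
}

#' Write a barcode dataset to FASTA plus a metadata table
#'
#' Inverse of [read_barcodes()]: `read_barcodes()` on the written files
#' reproduces the dataset exactly (sequences, taxonomy and coordinates).
#'
#' @param ds specimen tibble as returned by [read_barcodes()] or
#'   [sim_barcodes()].
#' @param fasta_path,metadata_path output paths.
#' @return `ds`, invisibly.
#' @export
write_barcodes <- function(ds, fasta_path, metadata_path) {
  validate_barcodes(ds)
  lines <- character(2L * nrow(ds))
  lines[c(TRUE, FALSE)] <- paste0(">", ds$specimen_id)
  lines[c(FALSE, TRUE)] <- ds$sequence
  writeLines(lines, fasta_path)
  ds |>
    select(dplyr::all_of(c("specimen_id", "species", "genus", "subfamily",
                           "region", "lat", "lon"))) |>
    readr::write_tsv(metadata_path)
  invisible(ds)
}

#' Restrict a dataset to barcode-compliant records
#'
#' Retains exactly the records with more than 500 unambiguous (A/C/G/T)
#' nucleotides, the conventional length requirement for full barcode status.
#' Ambiguity codes and alignment gaps do not count towards length. The
#' operation is idempotent and preserves record order.
#'
#' @param ds specimen tibble.
#' @param min_sites minimum number of unambiguous sites; a record is kept
#'   when its count is strictly greater than this (default 500).
#' @return filtered tibble.
#' @export
filter_barcode_compliant <- function(ds, min_sites = 500L) {
  validate_barcodes(ds)
  n <- n_unambiguous(ds$sequence)
  dropped <- sum(n <= min_sites)
  if (dropped > 0) {
    inform(paste0("dropped ", dropped, " record(s) with <= ", min_sites,
                  " unambiguous nucleotides"))
  }
  ds[n > min_sites, , drop = FALSE]
}

#' Dataset manifest
#'
#' Summary counts for a specimen table: record, species, genus and region
#' totals, alignment length, and how many records meet the barcode length
#' requirement.
#'
#' @param ds specimen tibble.
#' @return one-row tibble.
#' @export
dataset_manifest <- function(ds) {
  validate_barcodes(ds)
  tibble(
    n_records = nrow(ds),
    n_species = dplyr::n_distinct(ds$species),
    n_genera = dplyr::n_distinct(ds$genus),
    n_regions = dplyr::n_distinct(ds$region),
    alignment_length = max(nchar(ds$sequence)),
    n_barcode_compliant = sum(n_unambiguous(ds$sequence) > 500L),
    n_missing_coords = sum(is.na(ds$lat) | is.na(ds$lon))
  )
}
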