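#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows bind_cols distinct n row_number
#'   across rename relocate pull count
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_dbl map_int map2 pmap imap keep
#' @importFrom stats as.dist rexp runif setNames uniroot rlnorm
#' @importFrom utils combn head
NULL

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages here follow the
#' convention of rounding halves away from zero (so 92.5 -> 93).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(92.5)   # 93
#' round_half_up(0.5)    # 1
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# nucleotide integer coding: A=1, C=2, G=3, T=4, everything else 0 (treated as
# missing under pairwise deletion)
.base_levels <- c("A", "C", "G", "T")

encode_seq <- function(s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  out <- match(chars, .base_levels)
  out[is.na(out)] <- 0L
  out
}

decode_seq <- function(code) {
  paste(ifelse(code == 0L, "N", .base_levels[pmax(code, 1L)]), collapse = "")
}

# count unambiguous (A/C/G/T) positions in a sequence string
n_unambiguous <- function(s) {
  vapply(
    strsplit(toupper(s), "", fixed = TRUE),
    function(ch) sum(ch %in% .base_levels),
    integer(1)
  )
}

.iupac_chars <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")

# required columns for a barcode specimen table
.ds_cols <- c("specimen_id", "species", "genus", "subfamily", "region",
              "lat", "lon", "sequence")

validate_barcodes <- function(ds, call = rlang::caller_env()) {
  missing_cols <- setdiff(.ds_cols, names(ds))
  if (length(missing_cols) > 0) {
    abort(paste0("specimen table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  if (anyDuplicated(ds$specimen_id)) {
    dup <- unique(ds$specimen_id[duplicated(ds$specimen_id)])
    abort(paste0("duplicate specimen_id: ", paste(head(dup, 5), collapse = ", ")),
          call = call)
  }
  if (any(!nzchar(ds$sequence))) {
    abort("empty sequence(s) present", call = call)
  }
  bad <- !grepl(paste0("^[", paste(c(.iupac_chars, tolower(.iupac_chars)),
                                   collapse = ""), "]+$"), ds$sequence)
  if (any(bad)) {
    abort(paste0("sequence with non-IUPAC characters for specimen ",
                 ds$specimen_id[which(bad)[1]]), call = call)
  }
  g <- dplyr::distinct(ds, .data$species, .data$genus)
  if (anyDuplicated(g$species)) {
    abort("inconsistent species -> genus mapping", call = call)
  }
  invisible(ds)
}
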