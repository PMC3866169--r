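#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_abline geom_hline
#'   geom_vline geom_histogram geom_ribbon labs scale_x_continuous
#'   scale_y_continuous autoplot theme_minimal
NULL

#' Barcode-gap scatter
#'
#' Maximum intraspecific variation against nearest-neighbour divergence, one
#' point per species; points above the identity line have a barcode gap.
#' Singletons (no intraspecific distance) are drawn at zero.
#'
#' @param gap_rows tibble from [species_gap_table()].
#' @return a ggplot object.
#' @export
plot_barcode_gap <- function(gap_rows) {
  df <- mutate(gap_rows,
               max_intra = dplyr::coalesce(.data$max_intra, 0),
               singleton = .data$n_specimens == 1)
  ggplot(df, aes(x = 100 * .data$max_intra, y = 100 * .data$nn_distance,
                 shape = .data$singleton)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    geom_point(alpha = 0.8) +
    labs(x = "maximum intraspecific K2P distance (%)",
         y = "nearest-neighbour K2P distance (%)",
         shape = "singleton") +
    theme_minimal()
}

#' Records-per-species histogram
#'
#' @param ds specimen tibble.
#' @return a ggplot object.
#' @export
plot_records_per_species <- function(ds) {
  counts <- count(ds, .data$species)
  ggplot(counts, aes(x = .data$n)) +
    geom_histogram(binwidth = 1, fill = "steelblue", colour = "white") +
    labs(x = "DNA barcodes per species", y = "species") +
    theme_minimal()
}

#' Split geography scatter
#'
#' Genetic divergence between the clusters of split species against the
#' shortest geographic distance between their members; the vertical line is
#' the sympatry cutoff.
#'
#' @param splits tibble from [split_pair_table()].
#' @param sympatry_km cutoff drawn as a reference line.
#' @return a ggplot object.
#' @export
plot_split_geography <- function(splits, sympatry_km = 100) {
  ggplot(splits, aes(x = .data$min_km, y = 100 * .data$min_k2p,
                     colour = .data$sympatric,
                     shape = .data$has_singleton)) +
    geom_vline(xintercept = sympatry_km, linetype = "dashed",
               colour = "grey50") +
    geom_point(size = 2, alpha = 0.8) +
    labs(x = "shortest distance between cluster members (km)",
         y = "minimum pairwise K2P distance (%)",
         colour = "sympatric", shape = "singleton cluster") +
    theme_minimal()
}

#' @export
autoplot.accum_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$mean_richness,
                     colour = .data$label, fill = .data$label)) +
    geom_ribbon(aes(ymin = .data$mean_richness - .data$sd_richness,
                    ymax = .data$mean_richness + .data$sd_richness),
                alpha = 0.2, colour = NA) +
    geom_line() +
    labs(x = "specimens sampled", y = "richness", colour = NULL,
         fill = NULL) +
    theme_minimal()
}

#' @export
plot.accum_curve <- function(x, ...) print(autoplot(x, ...))
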