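#' @import ggplot2
NULL

#' Plot a per-position variability profile
#'
#' Bar chart of the number of unique amino acids per alignment position.
#'
#' @param profile Output of [variability_profile()].
#' @return A ggplot object.
#' @export
plot_variability <- function(profile) {
  ggplot(profile, aes(x = .data$position, y = .data$n_residues)) +
    geom_col(width = 1, fill = "grey25") +
    labs(x = "alignment position (aa)", y = "unique amino acids") +
    theme_classic()
}

#' Plot per-exon synonymous/non-synonymous mutation density
#'
#' @param density Output of [exon_mutation_density()].
#' @return A ggplot object.
#' @export
plot_mutation_density <- function(density) {
  long <- density |>
    select("exon", "region", "S_density", "NS_density") |>
    tidyr::pivot_longer(c("S_density", "NS_density"),
                        names_to = "class", values_to = "density") |>
    mutate(class = ifelse(.data$class == "S_density", "S", "NS"))
  ggplot(long, aes(x = factor(.data$exon), y = .data$density,
                   fill = .data$class)) +
    geom_col(position = "dodge") +
    labs(x = "exon", y = "mutations / exon length (bp)", fill = NULL) +
    theme_classic()
}

#' Plot a shared splice-event catalog as stacked per-exon bars
#'
#' @param catalog Output of [filter_shared_events()].
#' @return A ggplot object.
#' @export
plot_shared_events <- function(catalog) {
  ggplot(shared_event_counts(catalog),
         aes(x = factor(.data$exon), y = .data$n_events,
             fill = .data$kind)) +
    geom_col() +
    labs(x = "exon", y = "alternative splicing events", fill = NULL) +
    theme_classic()
}

#' Plot a residue frequency table as stacked bars
#'
#' @param freqs Output of [residue_frequency_table()].
#' @return A ggplot object.
#' @export
plot_residue_frequencies <- function(freqs) {
  ggplot(freqs, aes(x = factor(.data$position), y = .data$frequency,
                    fill = .data$residue)) +
    geom_col() +
    labs(x = "alignment position", y = "frequency", fill = "residue") +
    theme_classic()
}

#' @export
autoplot.lilr_dist <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$item1, y = .data$item2,
                 fill = .data$distance)) +
    geom_tile() +
    labs(x = NULL, y = NULL, fill = object$method) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
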