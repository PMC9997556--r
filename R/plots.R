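#' Plot a gene category summary
#'
#' Bar chart of gene counts per effect category, colored by the
#' conserved / altered-benign / deleterious grouping used in triage.
#'
#' @param x A `category_summary` ([summarize_genes()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.category_summary <- function(x, ...) {
  d <- tidy(x)
  d$group <- ifelse(d$conserved, "conserved",
                    ifelse(d$deleterious, "deleterious", "altered (benign)"))
  d$category <- factor(d$category, levels = EFFECT_CATEGORIES)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "genes", fill = NULL,
                  title = sprintf("%d genes: %d%% conserved, %d deleterious",
                                  x$total, x$conserved_pct, x$deleterious_total)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.category_summary
#' @export
plot_category_summary <- function(x, ...) autoplot.category_summary(x, ...)

#' Plot donor-sequence provenance per sequence
#'
#' Stacked bars of sample-derived versus donor-filled bases per sequence
#' (the `total` row is dropped), annotated with the source ratio.
#'
#' @param provenance A provenance tibble ([provenance_report()]).
#' @return A ggplot object.
#' @export
plot_provenance <- function(provenance) {
  d <- filter(provenance, .data$seq_name != "total")
  long <- tidyr::pivot_longer(
    mutate(d, sample_bp = .data$total_bp - .data$donor_bp),
    c("sample_bp", "donor_bp"), names_to = "source", values_to = "bp"
  )
  long$source <- ifelse(long$source == "donor_bp", "donor (lowercase)", "sample")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$seq_name, y = .data$bp,
                                     fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      data = d,
      ggplot2::aes(x = .data$seq_name, y = .data$total_bp,
                   label = sprintf("%.4f", .data$ratio)),
      inherit.aes = FALSE, vjust = -0.3, size = 3
    ) +
    ggplot2::scale_fill_brewer(palette = "Paired") +
    ggplot2::labs(x = NULL, y = "bases", fill = NULL,
                  title = "Source of assembled sequence") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
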