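#' Plot per-column mutation counts of a hotspot scan
#'
#' Lollipop plot of mutation counts along the alignment columns of the
#' most mutated families, coloured by Bonferroni significance, one facet
#' per (family, dataset).
#'
#' @param object A `hotspot_scan`.
#' @param dataset Dataset run to show (`"genome"`, `"TS"` or `"OG"`).
#' @param mclass Mutation class to show.
#' @param max_families Show at most this many families (by top count).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hotspot_scan
#' @export
autoplot.hotspot_scan <- function(object, dataset = "genome",
                                  mclass = "missense",
                                  max_families = 6, ...) {
  d <- filter(object$results, .data$dataset == !!dataset,
              .data$mclass == !!mclass)
  top <- d %>%
    group_by(.data$family_id) %>%
    summarise(kk = max(.data$k), .groups = "drop") %>%
    arrange(dplyr::desc(.data$kk)) %>%
    head(max_families) %>%
    pull("family_id")
  d <- filter(d, .data$family_id %in% top)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$msa_column, y = .data$k)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$msa_column,
                                       yend = 0)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 2) +
    ggplot2::facet_wrap(~family_id, scales = "free_x") +
    ggplot2::labs(x = "alignment column", y = "mutation count",
                  colour = "significant",
                  title = paste0(mclass, " hotspots, ", dataset,
                                 " run")) +
    ggplot2::theme_minimal()
}

#' Plot domain enrichment results
#'
#' Observed/background rate ratio against the corrected p-value, one
#' panel per mutation class, enriched families highlighted.
#'
#' @param object A `domain_enrichment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot domain_enrichment
#' @export
autoplot.domain_enrichment <- function(object, ...) {
  d <- filter(as_tibble(object), .data$observed > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rate_ratio,
                                  y = -log10(pmax(.data$p_corrected,
                                                  1e-300)))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$enriched)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~mclass) +
    ggplot2::labs(x = "rate ratio (family / background)",
                  y = "-log10 corrected p",
                  colour = "enriched") +
    ggplot2::theme_minimal()
}

#' Bar chart of hotspot-overlap regions
#'
#' The seven exclusive intersection regions of the tumour-suppressor,
#' oncogene and whole-genome hotspot sets (a Venn diagram in bar form).
#'
#' @param object A `hotspot_overlap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hotspot_overlap
#' @export
autoplot.hotspot_overlap <- function(object, ...) {
  d <- as_tibble(select(unclass_overlap(object), "region", "count"))
  d$region <- factor(d$region, levels = d$region)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "hotspot count",
                  title = paste0("hotspot overlap (",
                                 attr(object, "level"), " level, ",
                                 attr(object, "mclass"), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

unclass_overlap <- function(x) {
  class(x) <- setdiff(class(x), "hotspot_overlap")
  x
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
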