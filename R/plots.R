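#' Sequence-versus-structure preference scatter
#'
#' One point per experiment: mean top-10 Z of sequence 7-mers against mean
#' top-10 Z of structure 11-mers. Structure-specific binders sit above the
#' diagonal, sequence-specific binders below.
#'
#' @param profiles A tibble with columns `experiment`, `seq_top10_z`,
#'   `struct_top10_z` (e.g. row-bound [preference_profile()] outputs).
#' @return A ggplot object.
#' @export
plot_preference <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$seq_top10_z,
                                         y = .data$struct_top10_z)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    {if ("experiment" %in% names(profiles))
      ggplot2::geom_text(ggplot2::aes(label = .data$experiment),
                         vjust = -0.8, size = 3)} +
    ggplot2::labs(x = "sequence preference (top-10 7-mer Z)",
                  y = "structure preference (top-10 11-mer Z)") +
    ggplot2::theme_minimal()
}

#' Structure k-mer enrichment against pool occurrence
#'
#' Scatter of per-11-mer enrichment versus overall pool occurrence,
#' colored by hairpin loop-size class, with the top `highlight` enriched
#' k-mers emphasized -- the tri-loop specificity view.
#'
#' @param tbl Output of [enrichment_vs_occurrence()].
#' @param highlight How many top-enriched k-mers to emphasize (default 30).
#' @return A ggplot object.
#' @export
plot_enrichment_vs_occurrence <- function(tbl, highlight = 30) {
  tbl <- tbl %>% dplyr::mutate(top = dplyr::row_number(dplyr::desc(.data$enrichment)) <= highlight)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$occurrence, y = .data$enrichment,
                                    colour = .data$loop_class)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = dplyr::filter(tbl, .data$top), colour = "red",
                        size = 1.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "occurrence in pool", y = "log2 enrichment",
                  colour = "loop size",
                  subtitle = sprintf("top %d enriched 11-mers in red", highlight)) +
    ggplot2::theme_minimal()
}

#' Heat-map view of a fitted stem-loop binding model
#'
#' Pattern score per (closing pair, pairing bin) row and loop-triplet
#' column; missing (support < 20) patterns are blank.
#'
#' @param model An `"lre_model"` from [fit_lre_model()].
#' @return A ggplot object.
#' @export
plot_lre_model <- function(model) {
  dat <- model %>%
    dplyr::mutate(rowlab = paste0(.data$pair, " bin", .data$bin))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$triplet, y = .data$rowlab,
                                    fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  na.value = "grey92") +
    ggplot2::labs(x = "loop triplet (I II III)", y = "closing pair x pairing bin",
                  fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 5))
}
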