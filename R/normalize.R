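#' Build an input reference from a compendium of arrays
#'
#' The RNAcompete setup hybridizes a different experiment in each channel,
#' so no within-array input exists; the input reference is the per-oligo
#' median intensity across a compendium of experiments.
#'
#' @param compendium A tibble with an `oligo_id` column and one numeric
#'   column per sample.
#' @return A tibble with columns `oligo_id`, `reference`.
#' @export
build_input_reference <- function(compendium) {
  samples <- setdiff(names(compendium), "oligo_id")
  if (length(samples) == 0) stop("compendium has no sample columns")
  m <- as.matrix(compendium[, samples])
  tibble(oligo_id = compendium$oligo_id,
         reference = apply(m, 1, median))
}

#' Remove oligos with low median intensity
#'
#' Drops oligos whose median log2 intensity across samples is strictly
#' below `threshold_log2` (default 6) -- the reliability filter applied
#' before any enrichment computation. Intensities are passed in linear
#' scale unless `log2_scale = TRUE`.
#'
#' @param intensities A tibble with `oligo_id` plus numeric sample columns.
#' @param threshold_log2 Log2-space cutoff; strictly-below is removed.
#' @param log2_scale Set `TRUE` if the columns are already log2.
#' @return A list with elements `table` (kept rows) and `removed`
#'   (character vector of removed oligo ids).
#' @export
filter_low_median <- function(intensities, threshold_log2 = 6, log2_scale = FALSE) {
  samples <- setdiff(names(intensities), "oligo_id")
  m <- as.matrix(intensities[, samples])
  if (!log2_scale) m <- log2(m)
  med <- apply(m, 1, median)
  drop <- med < threshold_log2
  list(table = intensities[!drop, , drop = FALSE],
       removed = intensities$oligo_id[drop])
}

#' Quantile-normalize intensity columns
#'
#' Forces every sample column onto the same distribution by replacing each
#' rank with the cross-sample mean at that rank (ties get the mean of their
#' ranks' values). After normalization the sorted values of every column
#' are identical.
#'
#' @param x A tibble with `oligo_id` plus at least two numeric columns.
#' @return A tibble of the same shape.
#' @export
quantile_normalize <- function(x) {
  samples <- setdiff(names(x), "oligo_id")
  stopifnot(length(samples) >= 2)
  m <- limma::normalizeQuantiles(as.matrix(x[, samples]), ties = TRUE)
  out <- x
  out[, samples] <- as_tibble(as.data.frame(m))
  out
}

#' Flag and remove unreliable probes in a two-channel experiment
#'
#' Removes (a) low-efficiency probes -- input intensity strictly below
#' `input_cutoff_log2`, whose pulldown signal cannot reflect the intended
#' target -- and (b) a depleted subpopulation with both input and pulldown
#' strictly below their cutoffs (an RBP is unlikely to specifically deplete
#' a small subset of RNAs). Cutoffs are log2-space; cutoffs of 0 remove
#' nothing when intensities are >= 1.
#'
#' @param channels A tibble with columns `oligo_id`, `input`, `pulldown`
#'   (linear scale).
#' @param input_cutoff_log2 Low-efficiency input cutoff (log2).
#' @param depleted_cutoff_log2 Cutoff pair applied to input AND pulldown for
#'   the depleted subpopulation (log2).
#' @return A list with `table` (kept rows), `removed_low_efficiency`,
#'   `removed_depleted` (character id vectors).
#' @export
artifact_filter <- function(channels, input_cutoff_log2 = 6,
                            depleted_cutoff_log2 = 6) {
  li <- log2(channels$input)
  lp <- log2(channels$pulldown)
  low_eff <- li < input_cutoff_log2
  depleted <- li < depleted_cutoff_log2 & lp < depleted_cutoff_log2
  drop <- low_eff | depleted
  list(table = channels[!drop, , drop = FALSE],
       removed_low_efficiency = channels$oligo_id[low_eff],
       removed_depleted = channels$oligo_id[depleted])
}

#' Loess-residual binding enrichment
#'
#' Fits a degree-1 loess of log2 pulldown on log2 input and reports, per
#' oligo, the vertical distance to the fit. Any smooth intensity-dependent
#' trend (including a constant offset) is absorbed by the fit; the residual
#' is the oligo's log2 binding enrichment.
#'
#' @param channels A tibble with columns `oligo_id`, `input`, `pulldown`,
#'   already on log2 scale.
#' @param span Loess span (default 0.3).
#' @param degree Local polynomial degree (default 1).
#' @return A tibble with columns `oligo_id`, `enrichment`.
#' @export
loess_enrichment <- function(channels, span = 0.3, degree = 1) {
  if (nrow(channels) < 50) stop("need >= 50 oligos for a loess fit")
  fit <- loess(pulldown ~ input, data = channels, span = span, degree = degree,
               family = "gaussian",
               control = stats::loess.control(surface = "interpolate"))
  tibble(oligo_id = channels$oligo_id,
         enrichment = channels$pulldown - fitted(fit))
}

#' Full two-channel preprocessing pipeline
#'
#' Chains the preprocessing in assay order: low-median filter, artifact
#' filters, quantile normalization of the two channels, then loess residual
#' enrichment on log2 scale.
#'
#' @param channels A tibble with `oligo_id`, `input`, `pulldown` (linear).
#' @param median_threshold_log2,input_cutoff_log2,depleted_cutoff_log2
#'   Filter cutoffs (log2 space).
#' @param span Loess span.
#' @return A list with `enrichment` (tibble `oligo_id`, `enrichment`) and
#'   `removed` (named list of removed-id vectors per filter).
#' @export
normalize_two_channel <- function(channels, median_threshold_log2 = 6,
                                  input_cutoff_log2 = 6,
                                  depleted_cutoff_log2 = 6, span = 0.3) {
  f1 <- filter_low_median(channels[, c("oligo_id", "input", "pulldown")],
                          threshold_log2 = median_threshold_log2)
  f2 <- artifact_filter(f1$table, input_cutoff_log2, depleted_cutoff_log2)
  qn <- quantile_normalize(f2$table[, c("oligo_id", "input", "pulldown")] %>%
                             dplyr::mutate(input = log2(.data$input),
                                           pulldown = log2(.data$pulldown)))
  list(
    enrichment = loess_enrichment(qn, span = span),
    removed = list(low_median = f1$removed,
                   low_efficiency = f2$removed_low_efficiency,
                   depleted = f2$removed_depleted)
  )
}
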