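#' Scan one transcript for predicted stem-loop binding sites
#'
#' Computes the sliding-window distance-4 pairing profile over the full
#' spliced sequence (structure does not respect annotation boundaries),
#' looks up every canonical-flank position in the selected pattern table,
#' and emits sites whose pattern score reaches at least the "minimal"
#' strength threshold (0.225). Each site is assigned to 5'UTR, CDS or 3'UTR
#' by the transcript coordinate of loop position II (the loop center).
#'
#' @param transcript_id Transcript identifier.
#' @param seq The spliced transcript sequence.
#' @param regions A tibble with columns `transcript_id`, `region`, `start`,
#'   `end` (1-based inclusive transcript coordinates).
#' @param patterns A selected pattern table (see
#'   [select_binding_patterns()]) with columns `pair`, `triplet`, `bin`,
#'   `score`.
#' @param window,span,step Windowed-folding parameters, see
#'   [windowed_distance4_profile()].
#' @return A tibble with columns `transcript_id`, `pos` (stem position -1),
#'   `region`, `pair`, `triplet`, `bin`, `pattern`, `score`, `strength`.
#' @export
scan_transcript <- function(transcript_id, seq, regions, patterns,
                            window = 70L, span = window, step = 1L) {
  empty <- tibble(transcript_id = character(0), pos = integer(0),
                  region = character(0), pair = character(0),
                  triplet = character(0), bin = integer(0),
                  pattern = character(0), score = numeric(0),
                  strength = factor(character(0),
                                    levels = c("minimal", "weak", "medium", "strong"),
                                    ordered = TRUE))
  if (nchar(seq) < 5) return(empty)
  profile <- windowed_distance4_profile(seq, window = window, span = span, step = step)
  occ <- find_pattern_occurrences(seq, profile)
  if (nrow(occ) == 0) return(empty)
  reg <- regions[regions$transcript_id == transcript_id, , drop = FALSE]
  hits <- occ %>%
    dplyr::inner_join(patterns[, c("pair", "triplet", "bin", "score")],
                      by = c("pair", "triplet", "bin")) %>%
    dplyr::mutate(strength = strength_bin(.data$score)) %>%
    dplyr::filter(.data$strength != "none")
  if (nrow(hits) == 0) return(empty)
  loop_center <- hits$pos + 2L # loop position II
  region <- rep(NA_character_, nrow(hits))
  for (r in seq_len(nrow(reg))) {
    inside <- loop_center >= reg$start[r] & loop_center <= reg$end[r]
    region[inside] <- reg$region[r]
  }
  hits %>%
    dplyr::mutate(transcript_id = transcript_id, region = region,
                  strength = factor(as.character(.data$strength),
                                    levels = c("minimal", "weak", "medium", "strong"),
                                    ordered = TRUE)) %>%
    dplyr::select("transcript_id", "pos", "region", "pair", "triplet",
                  "bin", "pattern", "score", "strength") %>%
    dplyr::arrange(.data$pos)
}

#' Scan a set of transcripts for predicted sites
#'
#' Applies [scan_transcript()] across a transcript table.
#'
#' @param transcripts A tibble with columns `id`, `seq` (or a
#'   `"synthetic_transcriptome"`; its regions are then used by default).
#' @param regions Region annotation tibble (see [read_region_gff3()]).
#' @param patterns Selected pattern table.
#' @inheritParams scan_transcript
#' @return A tibble of predicted sites across all transcripts.
#' @export
scan_transcriptome <- function(transcripts, regions = NULL, patterns,
                               window = 70L, span = window, step = 1L) {
  if (inherits(transcripts, "synthetic_transcriptome")) {
    if (is.null(regions)) regions <- transcripts$regions
    transcripts <- transcripts$transcripts
  }
  purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
    scan_transcript(transcripts$id[i], transcripts$seq[i], regions, patterns,
                    window = window, span = span, step = step)
  })
}

#' Per-transcript site counts over region x strength
#'
#' The 12-column feature matrix used as regression predictors: counts of
#' predicted sites per (region, strength) combination, with all-zero rows
#' for transcripts without sites.
#'
#' @param sites A site tibble from [scan_transcriptome()].
#' @param transcript_ids Character vector of all transcripts to report
#'   (rows), including those without sites.
#' @return A tibble with `transcript_id` plus 12 integer columns named
#'   `<region>_<strength>` (regions 5UTR, CDS, 3UTR; strengths minimal,
#'   weak, medium, strong).
#' @export
site_feature_matrix <- function(sites, transcript_ids) {
  if (nrow(sites) > 0 && !all(sites$transcript_id %in% transcript_ids)) {
    stop("sites reference transcripts missing from `transcript_ids`")
  }
  regions <- c("5UTR", "CDS", "3UTR")
  strengths <- c("minimal", "weak", "medium", "strong")
  cols <- as.vector(t(outer(regions, strengths, paste, sep = "_")))
  grid <- tidyr::crossing(transcript_id = transcript_ids,
                          feature = factor(cols, levels = cols))
  counts <- if (nrow(sites) == 0) {
    tibble(transcript_id = character(0), feature = character(0), n = integer(0))
  } else {
    sites %>%
      dplyr::mutate(feature = paste(.data$region, as.character(.data$strength),
                                    sep = "_")) %>%
      dplyr::count(.data$transcript_id, .data$feature)
  }
  grid %>%
    dplyr::left_join(counts, by = c("transcript_id", "feature")) %>%
    dplyr::mutate(n = as.integer(dplyr::coalesce(.data$n, 0L))) %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "n") %>%
    dplyr::arrange(match(.data$transcript_id, transcript_ids))
}
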