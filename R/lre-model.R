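#' Building blocks of the stem-loop pattern space
#'
#' The model describes a tri-loop hairpin by three features: the closing
#' base pair at stem position 1 (positions -1/+1, six canonical pairs), the
#' loop triplet (positions I, II, III; 64 combinations), and the binned
#' pairing probability of the -1/+1 pair (seven log2 bins).
#'
#' @return `lre_closing_pairs()`: the six canonical pairs; `lre_loop_triplets()`:
#'   the 64 loop triplets.
#' @export
lre_closing_pairs <- function() c("AU", "UA", "GC", "CG", "GU", "UG")

#' @rdname lre_closing_pairs
#' @export
lre_loop_triplets <- function() {
  b <- c("A", "C", "G", "U")
  grid <- expand.grid(III = b, II = b, I = b, stringsAsFactors = FALSE)
  paste0(grid$I, grid$II, grid$III)
}

#' Enumerate all 2688 stem-loop binding patterns
#'
#' The full pattern space: 6 closing pairs x 64 loop triplets x 7 pairing
#' bins = 2688 patterns (dropping the pairing bin gives the 384
#' sequence-only variants).
#'
#' @return A tibble with columns `pair`, `triplet`, `bin` and a `pattern`
#'   key `"<pair>:<triplet>:<bin>"`, 2688 rows.
#' @export
enumerate_patterns <- function() {
  tidyr::crossing(pair = lre_closing_pairs(), triplet = lre_loop_triplets(),
                  bin = 1:7) %>%
    dplyr::mutate(pattern = paste(.data$pair, .data$triplet, .data$bin, sep = ":")) %>%
    dplyr::arrange(.data$pair, .data$triplet, .data$bin)
}

#' Bin a pairing probability on the log2 scale
#'
#' Adds a pseudo-count of 1e-4, takes log2, and places the value into seven
#' equal-width bins spanning `[log2(1e-4), 0]`. Bin 1 holds unpaired
#' (p = 0), bin 7 near-certain pairing (p = 1); the map is monotone in p.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param pseudo Pseudo-count added before the log (default 1e-4).
#' @param n_bins Number of bins (default 7).
#' @return Integer vector of bins in `1..n_bins`.
#' @export
pairing_bin <- function(p, pseudo = 1e-4, n_bins = 7) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities must lie in [0, 1]")
  lo <- log2(pseudo)
  width <- (0 - lo) / n_bins
  bin <- floor((log2(p + pseudo) - lo) / width) + 1
  as.integer(pmin(pmax(bin, 1), n_bins))
}

#' Locate stem-loop pattern occurrences along a sequence
#'
#' At every position `i` whose bases `(i, i + 4)` form a canonical pair,
#' the sequence presents the pattern (pair = bases at `i`/`i + 4`, triplet
#' = bases `i+1..i+3`, bin = [pairing_bin()] of the distance-4 pairing
#' probability at `i`). Non-canonical flanks yield no occurrence.
#'
#' @param seq A single RNA sequence.
#' @param profile Distance-4 pairing profile aligned to `seq` (length
#'   `nchar(seq) - 4`), from [distance4_profile()] or
#'   [windowed_distance4_profile()].
#' @return A tibble with columns `pos` (1-based position of stem position
#'   -1), `pair`, `triplet`, `bin`, `pattern`.
#' @export
find_pattern_occurrences <- function(seq, profile) {
  seq <- sanitize_rna(seq)
  n <- nchar(seq)
  if (n < 5) {
    return(tibble(pos = integer(0), pair = character(0), triplet = character(0),
                  bin = integer(0), pattern = character(0)))
  }
  stopifnot(length(profile) == n - 4)
  i <- seq_len(n - 4)
  pair <- paste0(substring(seq, i, i), substring(seq, i + 4, i + 4))
  keep <- pair %in% lre_closing_pairs()
  i <- i[keep]
  if (length(i) == 0) {
    return(tibble(pos = integer(0), pair = character(0), triplet = character(0),
                  bin = integer(0), pattern = character(0)))
  }
  tibble(
    pos = i,
    pair = pair[keep],
    triplet = substring(seq, i + 1, i + 3),
    bin = pairing_bin(profile[i])
  ) %>%
    dplyr::mutate(pattern = paste(.data$pair, .data$triplet, .data$bin, sep = ":"))
}

#' Clip small enrichments to zero
#'
#' Sets every enrichment strictly inside `(low, high)` to zero and leaves
#' the rest unchanged. The pool is dominated by RNAs with small
#' enrichments, so any pool-wide sequence bias (the AAA/CCC artifact) would
#' otherwise dominate per-pattern means; discarding the interval suppresses
#' it while keeping the extent of strong binding.
#'
#' @param values Numeric vector of enrichments.
#' @param low,high Interval bounds (default -2 and 2); boundary values are
#'   kept.
#' @return Numeric vector of the same length.
#' @export
clip_enrichments <- function(values, low = -2, high = 2) {
  stopifnot(all(is.finite(values)))
  values[values > low & values < high] <- 0
  values
}

#' Fit the stem-loop binding model from a pool and its enrichments
#'
#' Scores each of the 2688 patterns as the mean (clipped) binding
#' enrichment of all oligos containing at least one occurrence of that
#' pattern (each oligo counted once per pattern, however often the pattern
#' occurs in it). Patterns supported by fewer than `min_support` oligos get
#' a missing score.
#'
#' @param pool A pool tibble with columns `id`, `seq`.
#' @param enrichments A tibble with columns `id`, `enrichment` (log2).
#' @param clip Clip enrichments with [clip_enrichments()] first (default
#'   TRUE, the bias-suppressing model fit).
#' @param min_support Minimum oligo count per pattern (default 20).
#' @param engine Folding engine for the distance-4 profiles.
#' @return A tibble of class `"lre_model"` with columns `pair`, `triplet`,
#'   `bin`, `pattern`, `score`, `support`; always exactly 2688 rows.
#' @export
fit_lre_model <- function(pool, enrichments, clip = TRUE, min_support = 20,
                          engine = "builtin") {
  if (nrow(pool) == 0) stop("empty pool")
  stopifnot(all(c("id", "seq") %in% names(pool)),
            all(c("id", "enrichment") %in% names(enrichments)))
  e <- enrichments$enrichment[match(pool$id, enrichments$id)]
  if (anyNA(e)) stop("every pool oligo needs an enrichment value")
  if (clip) e <- clip_enrichments(e)
  profiles <- distance4_profiles(pool$seq)
  # one vectorized pass over all (oligo, position) windows
  lens <- nchar(pool$seq)
  n_win <- pmax(lens - 4L, 0L)
  oligo <- rep.int(seq_len(nrow(pool)), n_win)
  pos <- sequence(n_win)
  s_rep <- pool$seq[oligo]
  pair <- paste0(substring(s_rep, pos, pos), substring(s_rep, pos + 4, pos + 4))
  p4 <- unlist(profiles, use.names = FALSE)
  keep <- pair %in% lre_closing_pairs()
  occs <- tibble(
    oligo = oligo[keep],
    pattern = paste(pair[keep],
                    substring(s_rep[keep], pos[keep] + 1, pos[keep] + 3),
                    pairing_bin(p4[keep]), sep = ":")
  ) %>%
    dplyr::distinct() # each oligo counted once per pattern
  per_pattern <- occs %>%
    dplyr::group_by(.data$pattern) %>%
    dplyr::summarise(score = mean(e[.data$oligo]), support = dplyr::n(),
                     .groups = "drop")
  out <- enumerate_patterns() %>%
    dplyr::left_join(per_pattern, by = "pattern") %>%
    dplyr::mutate(support = dplyr::coalesce(.data$support, 0L),
                  score = ifelse(.data$support < min_support, NA_real_, .data$score))
  class(out) <- c("lre_model", class(out))
  out
}

#' Select the convincing binding patterns from a fitted model
#'
#' Keeps U-A closing-pair patterns with pairing bin >= `ua_min_bin` and
#' score >= `min_score`, and C-G patterns with pairing bin exactly
#' `cg_bin` (the top bin) and score >= `min_score`; every other closing
#' pair contributes no binding and is excluded.
#'
#' @param model A fitted `"lre_model"` (see [fit_lre_model()]).
#' @param min_score Minimum pattern score (default 0.1).
#' @param ua_min_bin Minimum pairing bin for U-A patterns (default 4).
#' @param cg_bin Required pairing bin for C-G patterns (default 7).
#' @return A tibble of retained patterns with their scores.
#' @export
select_binding_patterns <- function(model, min_score = 0.1, ua_min_bin = 4,
                                    cg_bin = 7) {
  model %>%
    dplyr::filter(!is.na(.data$score), .data$score >= min_score,
                  (.data$pair == "UA" & .data$bin >= ua_min_bin) |
                    (.data$pair == "CG" & .data$bin == cg_bin)) %>%
    as_tibble()
}

#' Grade a binding score into a strength bin
#'
#' Twofold threshold steps 0.225 / 0.45 / 0.9 / 1.8 split scores into
#' `none < minimal < weak < medium < strong`; intervals are left-closed
#' (a score of exactly 1.8 is strong). The "minimal" group serves as a
#' close-to-no-binding control downstream.
#'
#' @param score Numeric vector of pattern scores.
#' @param thresholds The four increasing thresholds.
#' @return An ordered factor with levels none, minimal, weak, medium, strong.
#' @export
strength_bin <- function(score, thresholds = c(0.225, 0.45, 0.9, 1.8)) {
  stopifnot(length(thresholds) == 4, !is.unsorted(thresholds))
  cut(score, breaks = c(-Inf, thresholds, Inf), right = FALSE,
      labels = c("none", "minimal", "weak", "medium", "strong"),
      ordered_result = TRUE)
}

#' @export
print.lre_model <- function(x, ...) {
  cat("Stem-loop binding model: 2688 patterns (6 pairs x 64 triplets x 7 bins)\n")
  cat(sprintf("  scored: %d; missing (support < 20): %d\n",
              sum(!is.na(x$score)), sum(is.na(x$score))))
  top <- x %>% dplyr::filter(!is.na(.data$score)) %>%
    dplyr::arrange(dplyr::desc(.data$score)) %>% head(5)
  if (nrow(top)) {
    cat("  top patterns:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %-12s score %.3f (support %d)\n",
                  top$pattern[i], top$score[i], top$support[i]))
    }
  }
  invisible(x)
}
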