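#' Select the bound fraction of a pool
#'
#' The foreground of every enrichment computation: the top 2% of oligos by
#' binding score. The fraction is sized with a ceiling and ties spanning
#' the cutoff are broken lexicographically by oligo id, so the result is
#' deterministic and has exactly `ceiling(n * top_fraction)` members.
#'
#' @param scores A tibble with columns `id`, `score`.
#' @param top_fraction Fraction of the pool to keep (default 0.02).
#' @return Character vector of oligo ids.
#' @export
bound_fraction <- function(scores, top_fraction = 0.02) {
  stopifnot(all(c("id", "score") %in% names(scores)))
  n <- nrow(scores)
  if (n < 50) stop("need >= 50 oligos to define a bound fraction")
  k <- ceiling(n * top_fraction)
  ord <- order(-scores$score, scores$id)
  scores$id[ord[seq_len(k)]]
}

#' K-mer enrichment of a bound fraction over a size-matched background
#'
#' For each k-mer: `enrichment = log2(fg + pseudo) - log2(all * top_fraction
#' + pseudo)`, where `fg` is its count in the bound fraction and `all` its
#' count in the whole pool (scaled down by the bound-fraction size to give a
#' size-matched background). The pseudo-count (default 8) guards against
#' high enrichments from low counts. Enrichments are standardized to
#' Z-scores (sample standard deviation, n - 1) over the table; a
#' zero-variance table gets all-zero Z.
#'
#' @param fg_counts,all_counts Count tibbles from [count_kmers()] over the
#'   same alphabet.
#' @param top_fraction Bound-fraction size used for background scaling.
#' @param pseudo Pseudo-count (default 8).
#' @param universe Optional character vector fixing the k-mer universe the
#'   enrichments are standardized over (k-mers absent from both tables get
#'   zero counts, hence zero enrichment). Default: the union of k-mers
#'   observed in either table. The two channels of a preference profile are
#'   only comparable when their universes have comparable size, which is
#'   why the dot-bracket window length 11 was chosen against the 16,384
#'   sequence 7-mers; [preference_profile()] therefore standardizes
#'   structure enrichments over all embeddable 11-mers.
#' @return A tibble with columns `kmer`, `fg_count`, `bg_count`,
#'   `enrichment`, `z`, sorted by decreasing enrichment.
#' @export
kmer_enrichment <- function(fg_counts, all_counts, top_fraction = 0.02, pseudo = 8,
                            universe = NULL) {
  if (nrow(all_counts) == 0) stop("empty background count table")
  tbl <- dplyr::full_join(
    dplyr::rename(fg_counts, fg_count = "count"),
    dplyr::rename(all_counts, all_count = "count"),
    by = "kmer"
  )
  if (!is.null(universe)) {
    tbl <- dplyr::full_join(tbl, tibble(kmer = universe), by = "kmer")
  }
  tbl <- tbl %>%
    dplyr::mutate(
      fg_count = dplyr::coalesce(.data$fg_count, 0L),
      all_count = dplyr::coalesce(.data$all_count, 0L),
      bg_count = .data$all_count * top_fraction,
      enrichment = log2(.data$fg_count + pseudo) - log2(.data$bg_count + pseudo)
    )
  s <- sd(tbl$enrichment)
  tbl$z <- if (is.na(s) || s == 0) 0 else (tbl$enrichment - mean(tbl$enrichment)) / s
  tbl %>%
    dplyr::select("kmer", "fg_count", "bg_count", "enrichment", "z") %>%
    dplyr::arrange(dplyr::desc(.data$enrichment), .data$kmer)
}

#' Mean Z-score of the top k-mers
#'
#' Summarizes an enrichment table into one specificity number: the mean of
#' the `top` largest Z-scores. An RBP highly specific for a small set of
#' k-mers produces a large value; a diffuse binder does not.
#'
#' @param table A tibble from [kmer_enrichment()].
#' @param top How many top Z values to average (default 10).
#' @return A single number.
#' @export
top_k_mean_z <- function(table, top = 10) {
  stopifnot(nrow(table) >= top)
  mean(sort(table$z, decreasing = TRUE)[seq_len(top)])
}

#' Sequence-versus-structure binding preference of an experiment
#'
#' The per-experiment preference metric: 7-mer enrichment over the RNA
#' sequences quantifies sequence specificity, and 11-mer enrichment over
#' the dot-bracket strings of the folded pool quantifies structure
#' specificity; both are summarized as the mean Z of the top 10 k-mers
#' through the same bound-fraction pipeline.
#'
#' @param pool A pool tibble with columns `id`, `seq`.
#' @param scores A tibble with columns `id`, `score`.
#' @param seq_k,struct_k K-mer lengths (defaults 7 and 11).
#' @param top_fraction,pseudo,top Pipeline parameters, see
#'   [kmer_enrichment()] and [top_k_mean_z()].
#' @param engine Folding engine for [fold_mfe()].
#' @return A one-row tibble with columns `seq_top10_z`, `struct_top10_z`;
#'   the per-k-mer tables are attached as attributes `seq_table` and
#'   `struct_table`.
#' @export
preference_profile <- function(pool, scores, seq_k = 7, struct_k = 11,
                               top_fraction = 0.02, pseudo = 8, top = 10,
                               engine = "builtin") {
  bound <- bound_fraction(scores, top_fraction)
  structs <- fold_mfe(pool$seq, engine = engine)
  in_bound <- pool$id %in% bound
  seq_universe <- if (seq_k <= 8) {
    sort(Biostrings::mkAllStrings(c("A", "C", "G", "U"), seq_k))
  }
  struct_universe <- if (struct_k <= 12) enumerate_embeddable(struct_k)
  seq_tbl <- kmer_enrichment(count_kmers(pool$seq[in_bound], seq_k),
                             count_kmers(pool$seq, seq_k),
                             top_fraction, pseudo, universe = seq_universe)
  struct_tbl <- kmer_enrichment(count_kmers(structs[in_bound], struct_k),
                                count_kmers(structs, struct_k),
                                top_fraction, pseudo, universe = struct_universe)
  out <- tibble(seq_top10_z = top_k_mean_z(seq_tbl, top),
                struct_top10_z = top_k_mean_z(struct_tbl, top))
  attr(out, "seq_table") <- seq_tbl
  attr(out, "struct_table") <- struct_tbl
  out
}

#' Structure 11-mer enrichment versus pool occurrence
#'
#' For every structure k-mer observed in the folded pool, tabulates its
#' overall occurrence, its enrichment in the bound fraction, and its
#' hairpin-loop-size class (3/4/5/6/other) -- the tri-loop specificity
#' analysis.
#'
#' @inheritParams preference_profile
#' @param k Structure k-mer length (default 11).
#' @return A tibble with columns `kmer`, `occurrence`, `enrichment`, `z`,
#'   `loop_class`, sorted by decreasing enrichment.
#' @export
enrichment_vs_occurrence <- function(pool, scores, k = 11, top_fraction = 0.02,
                                     pseudo = 8, engine = "builtin") {
  bound <- bound_fraction(scores, top_fraction)
  structs <- fold_mfe(pool$seq, engine = engine)
  in_bound <- pool$id %in% bound
  all_counts <- count_kmers(structs, k)
  tbl <- kmer_enrichment(count_kmers(structs[in_bound], k), all_counts,
                         top_fraction, pseudo)
  tbl %>%
    dplyr::left_join(dplyr::rename(all_counts, occurrence = "count"), by = "kmer") %>%
    dplyr::mutate(occurrence = dplyr::coalesce(.data$occurrence, 0L),
                  loop_class = loop_size_class(.data$kmer)) %>%
    dplyr::select("kmer", "occurrence", "enrichment", "z", "loop_class")
}
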