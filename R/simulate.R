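#' Configuration for the synthetic RNAcompete-style generators
#'
#' Bundles every knob of the seeded generators that emulate the in vitro
#' selection assay: a pool of 30-41-nt RNA oligos, a binder that recognizes
#' either a planted stem-loop pattern table (structure kind, LIN41-like), a
#' planted single-stranded 6-mer motif (sequence kind, Brat-like
#' 5'-UUGUUG-3'), or nothing (null kind), and a two-channel array readout
#' with lognormal intensities and a configurable fraction of low-efficiency
#' probe artifacts.
#'
#' @param seed Integer seed; every generator call is a pure function of
#'   (config, seed).
#' @param n_oligos Number of oligos in the pool.
#' @param length_range Integer pair, oligo lengths drawn uniformly from this
#'   range (default 30-41 nt, the assay's pool geometry).
#' @param binder_kind `"structure"`, `"sequence"` or `"null"`.
#' @param pattern_weights Named numeric vector mapping stem-loop patterns
#'   (`"<pair>:<triplet>"`, e.g. `"UA:CCA"`) to binding effects in log2
#'   units; used by the structure binder. Default: [default_pattern_weights()].
#' @param ssrna_motif RNA string recognized by the sequence binder
#'   (default `"UUGUUG"`).
#' @param motif_effect Binding effect (log2) of one ssRNA motif occurrence.
#' @param noise_sd Gaussian noise on binding scores / multiplicative
#'   (log2-scale) noise on the pulldown channel.
#' @param planted_fraction Fraction of oligos carrying a planted element
#'   (each oligo independently with this probability).
#' @param artifact_fraction Fraction of probes turned into low-efficiency
#'   artifacts in the two-channel simulation.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L,
                             n_oligos = 1000L,
                             length_range = c(30L, 41L),
                             binder_kind = c("structure", "sequence", "null"),
                             pattern_weights = default_pattern_weights(),
                             ssrna_motif = "UUGUUG",
                             motif_effect = 3,
                             noise_sd = 0.25,
                             planted_fraction = 0.05,
                             artifact_fraction = 0.05) {
  binder_kind <- match.arg(binder_kind)
  length_range <- as.integer(length_range)
  stopifnot(
    length(length_range) == 2,
    length_range[1] >= 10, length_range[2] <= 200,
    length_range[1] <= length_range[2],
    planted_fraction >= 0, planted_fraction <= 1,
    artifact_fraction >= 0, artifact_fraction <= 1,
    noise_sd >= 0, n_oligos >= 1
  )
  ssrna_motif <- sanitize_rna(ssrna_motif)
  structure(
    list(seed = as.integer(seed), n_oligos = as.integer(n_oligos),
         length_range = length_range, binder_kind = binder_kind,
         pattern_weights = pattern_weights, ssrna_motif = ssrna_motif,
         motif_effect = motif_effect, noise_sd = noise_sd,
         planted_fraction = planted_fraction,
         artifact_fraction = artifact_fraction),
    class = "generator_config"
  )
}

#' Default stem-loop pattern weights for the structure binder
#'
#' A LIN41-like specificity over all 64 loop triplets under a U-A closing
#' pair: graded weights in which a purine at loop position III contributes
#' most, a pyrimidine at position I and A/C at position II contribute less,
#' on a common baseline -- so about half the triplets show appreciable
#' binding (0.8 to 3.2 log2 units) rather than an all-or-nothing split.
#'
#' @return Named numeric vector keyed `"UA:<triplet>"`.
#' @export
default_pattern_weights <- function() {
  triplets <- lre_loop_triplets()
  w <- ifelse(substr(triplets, 3, 3) %in% c("A", "G"), 3, 0.5)
  setNames(w, paste0("UA:", triplets))
}

.random_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.wc_complement <- function(x) chartr("ACGU", "UGCA", x)

# designed stem-loop element. The closing pair and loop triplet come from the
# pattern key "<pair>:<tri>"; the stem grows outward from the loop the way
# natural stems vary: three perfect Watson-Crick pairs next to the closing
# pair (so the -1/+1 pairing probability stays high), then 1-3 further pairs
# each of which is either stacked directly or preceded by a small bulge or
# internal loop at a random position -- a continuum of geometries rather than
# a fixed menu, so no single stem fingerprint is shared across elements. The
# element is wrapped in a non-pairable flanking base pair so surrounding
# sequence cannot coaxially extend the designed helix.
.design_hairpin <- function(pattern) {
  parts <- strsplit(pattern, ":", fixed = TRUE)[[1]]
  pair <- parts[1]; triplet <- parts[2]
  draw_pair <- function(biased = TRUE) {
    p <- if (biased) c(0.15, 0.35, 0.35, 0.15) else rep(0.25, 4)
    b <- sample(c("A", "C", "G", "U"), 1, prob = p)
    c(b, .wc_complement(b))
  }
  # inner helix: base adjacent to the closing pair uniform, rest GC-biased
  # (the designed fold must dominate the ensemble)
  inner <- c(list(draw_pair(biased = FALSE)), replicate(2, draw_pair(), simplify = FALSE))
  left <- paste(vapply(rev(inner), `[`, character(1), 1), collapse = "")
  right <- paste(vapply(inner, `[`, character(1), 2), collapse = "")
  extra <- sample(2:4, 1)
  budget <- 8L # unpaired nt available for interruptions (elements must fit a 30-mer)
  for (k in seq_len(extra)) {
    ev <- if (budget >= 2L) {
      sample(c("stack", "bulge5", "bulge3", "iloop"), 1,
             prob = c(0.55, 0.14, 0.14, 0.17))
    } else "stack"
    if (ev == "bulge5") {
      nb <- min(sample(1:3, 1), budget)
      left <- paste0(paste(sample(c("A", "C", "G", "U"), nb, TRUE), collapse = ""),
                     left)
      budget <- budget - nb
    } else if (ev == "bulge3") {
      nb <- min(sample(1:3, 1), budget)
      right <- paste0(right,
                      paste(sample(c("A", "C", "G", "U"), nb, TRUE), collapse = ""))
      budget <- budget - nb
    } else if (ev == "iloop") { # A/C only, cannot pair across the helix
      n5 <- min(sample(1:2, 1), budget - 1L); n3 <- min(sample(1:2, 1), budget - n5)
      left <- paste0(paste(sample(c("A", "C"), n5, TRUE), collapse = ""), left)
      right <- paste0(right, paste(sample(c("A", "C"), n3, TRUE), collapse = ""))
      budget <- budget - n5 - n3
    }
    bp <- draw_pair()
    left <- paste0(bp[1], left)
    right <- paste0(right, bp[2])
  }
  flank <- sample(c("A", "C"), 2, replace = TRUE) # A/C cannot pair
  paste0(flank[1], left, substr(pair, 1, 1), triplet, substr(pair, 2, 2),
         right, flank[2])
}

.embed <- function(seq, insert) {
  L <- nchar(seq); li <- nchar(insert)
  if (li > L) stop("element longer than oligo")
  at <- sample.int(L - li + 1, 1)
  paste0(substr(seq, 1, at - 1), insert, substr(seq, at + li, L))
}

#' Generate a synthetic oligo pool
#'
#' Draws `n_oligos` random RNA sequences with lengths uniform over
#' `length_range`; a `planted_fraction` of them (Bernoulli per oligo) carry
#' an embedded element. For the structure binder the element is a designed
#' tri-loop stem-loop whose closing pair and loop come from a pattern drawn
#' uniformly from `pattern_weights` and whose stem geometry varies
#' continuously (3 perfect pairs at the loop, then 2-4 further pairs with
#' random bulges/internal loops); for the sequence binder it is
#' `ssrna_motif`. Reproducible for a fixed seed.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `id`, `seq`, `planted` (pattern key, motif,
#'   or `NA`), `planted_effect`.
#' @export
generate_oligo_pool <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    n <- config$n_oligos
    lens <- sample(seq(config$length_range[1], config$length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, .random_seq, character(1))
    planted <- rep(NA_character_, n)
    effect <- numeric(n)
    hit <- runif(n) < config$planted_fraction
    if (config$binder_kind == "structure" && any(hit)) {
      keys <- sample(names(config$pattern_weights), sum(hit), replace = TRUE)
      seqs[hit] <- mapply(function(s, key) .embed(s, .design_hairpin(key)),
                          seqs[hit], keys)
      planted[hit] <- keys
      effect[hit] <- unname(config$pattern_weights[keys])
    } else if (config$binder_kind == "sequence" && any(hit)) {
      seqs[hit] <- vapply(seqs[hit], .embed, character(1), insert = config$ssrna_motif)
      planted[hit] <- config$ssrna_motif
      effect[hit] <- config$motif_effect
    }
    tibble(
      id = sprintf("oligo_%06d", seq_len(n)),
      seq = seqs, planted = planted, planted_effect = effect
    )
  })
}

#' Simulate binding scores for a pool
#'
#' Score = the strongest planted effect present in the oligo plus Gaussian
#' noise. For the structure binder the effect is the `pattern_weights`
#' entry of the oligo's planted pattern (0 for unplanted oligos); for the
#' sequence binder every oligo containing the motif -- planted or by
#' chance -- gets `motif_effect`; the null binder contributes 0.
#'
#' @param pool A pool from [generate_oligo_pool()].
#' @param config The matching [generator_config()].
#' @return A tibble with columns `id`, `score`.
#' @export
simulate_binding_scores <- function(pool, config) {
  stopifnot(inherits(config, "generator_config"), all(c("id", "seq") %in% names(pool)))
  effect <- switch(config$binder_kind,
    structure = pool$planted_effect,
    sequence = config$motif_effect *
      (stringr::str_count(pool$seq, stringr::fixed(config$ssrna_motif)) > 0),
    null = rep(0, nrow(pool))
  )
  withr::with_seed(config$seed + 1L, {
    tibble(id = pool$id, score = effect + rnorm(nrow(pool), 0, config$noise_sd))
  })
}

#' Simulate a two-channel array readout
#'
#' Input-channel intensities are lognormal (log2 mean 10, sd 1.5); the
#' pulldown channel is `input * 2^score` with multiplicative log2-scale
#' Gaussian noise. An `artifact_fraction` of probes are low-efficiency:
#' their input intensity is forced below the median-6 (log2) cutoff and
#' their pulldown is uncorrelated with the binding score. Intensities are
#' linear scale, as raw array exports are.
#'
#' @param pool A pool from [generate_oligo_pool()].
#' @param scores Scores from [simulate_binding_scores()].
#' @param config The matching [generator_config()].
#' @return A tibble with columns `id`, `input`, `pulldown`, `artifact`.
#' @export
simulate_two_channel <- function(pool, scores, config) {
  stopifnot(nrow(pool) == nrow(scores))
  s <- scores$score[match(pool$id, scores$id)]
  withr::with_seed(config$seed + 2L, {
    n <- nrow(pool)
    log2_input <- rnorm(n, 10, 1.5)
    log2_pull <- log2_input + s + rnorm(n, 0, config$noise_sd)
    artifact <- runif(n) < config$artifact_fraction
    if (any(artifact)) {
      log2_input[artifact] <- rnorm(sum(artifact), 4.5, 0.5)
      log2_pull[artifact] <- rnorm(sum(artifact), 4.5, 0.5)
    }
    tibble(id = pool$id, input = 2^log2_input, pulldown = 2^log2_pull,
           artifact = artifact)
  })
}

#' Generate a synthetic transcriptome with planted LREs
#'
#' Builds `n_transcripts` transcripts segmented 5'UTR -> CDS -> 3'UTR, with
#' stem-loop response elements planted at requested positions. The
#' background alphabet defaults to `{A, C}`, which admits no canonical base
#' pair, so a planted hairpin (perfect 6-bp stem + closing pair + tri-loop,
#' 17 nt) is the only stable fold and any reasonable folding engine pairs
#' its -1/+1 flanks.
#'
#' @param n_transcripts Number of transcripts.
#' @param region_lengths Named integer vector `c(utr5 = , cds = , utr3 = )`.
#' @param sites `NULL`, or a tibble with columns `transcript` (integer index
#'   in `1..n_transcripts`), `region` (`"5UTR"`, `"CDS"`, `"3UTR"`) and
#'   `pattern` (`"<pair>:<triplet>"`); one planted site per row.
#' @param seed Integer seed.
#' @param background Background alphabet: `"AC"` (default, unstructured) or
#'   `"ACGU"`.
#' @return A list of class `"synthetic_transcriptome"` with elements
#'   `transcripts` (tibble `id`, `seq`), `regions` (tibble `transcript_id`,
#'   `region`, `start`, `end`), and `truth` (tibble `transcript_id`, `pos`
#'   = coordinate of stem position -1, `region`, `pattern`).
#' @export
generate_transcriptome <- function(n_transcripts,
                                   region_lengths = c(utr5 = 100L, cds = 300L, utr3 = 200L),
                                   sites = NULL, seed = 1L,
                                   background = c("AC", "ACGU")) {
  background <- match.arg(background)
  alphabet <- strsplit(background, "")[[1]]
  region_lengths <- as.integer(region_lengths)
  stopifnot(length(region_lengths) == 3, all(region_lengths >= 0))
  total <- sum(region_lengths)
  reg_names <- c("5UTR", "CDS", "3UTR")
  reg_start <- cumsum(c(1L, region_lengths[-3]))
  reg_end <- cumsum(region_lengths)
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("tx_%04d", seq_len(n_transcripts))
    seqs <- vapply(rep(total, n_transcripts), .random_seq, character(1),
                   alphabet = alphabet)
    truth <- tibble(transcript_id = character(0), pos = integer(0),
                    region = character(0), pattern = character(0))
    if (!is.null(sites) && nrow(sites) > 0) {
      stopifnot(all(c("transcript", "region", "pattern") %in% names(sites)),
                all(sites$transcript %in% seq_len(n_transcripts)),
                all(sites$region %in% reg_names))
      hp_len <- 17L # 6-bp stem + closing pair + tri-loop
      rows <- vector("list", nrow(sites))
      for (r in seq_len(nrow(sites))) {
        ti <- sites$transcript[r]
        ri <- match(sites$region[r], reg_names)
        if (region_lengths[ri] < hp_len) {
          stop("planted site does not fit in region ", sites$region[r])
        }
        hp <- .design_transcript_hairpin(sites$pattern[r])
        at <- reg_start[ri] + sample.int(region_lengths[ri] - hp_len + 1L, 1) - 1L
        s <- seqs[ti]
        seqs[ti] <- paste0(substr(s, 1, at - 1), hp, substr(s, at + hp_len, total))
        rows[[r]] <- tibble(transcript_id = ids[ti],
                            pos = at + 6L, # stem position -1 of the tri-loop
                            region = sites$region[r],
                            pattern = sites$pattern[r])
      }
      truth <- dplyr::bind_rows(rows) %>%
        dplyr::arrange(.data$transcript_id, .data$pos)
    }
    regions <- tidyr::crossing(transcript_id = ids, ri = 1:3) %>%
      dplyr::mutate(region = reg_names[.data$ri],
                    start = reg_start[.data$ri], end = reg_end[.data$ri]) %>%
      dplyr::filter(.data$end >= .data$start) %>%
      dplyr::select(-"ri") %>%
      dplyr::arrange(.data$transcript_id, .data$start)
    structure(list(transcripts = tibble(id = ids, seq = seqs),
                   regions = regions, truth = truth),
              class = "synthetic_transcriptome")
  })
}

# 6-bp GC-rich perfect stem so the planted hairpin dominates the ensemble
.design_transcript_hairpin <- function(pattern) {
  parts <- strsplit(pattern, ":", fixed = TRUE)[[1]]
  pair <- parts[1]; triplet <- parts[2]
  stem5 <- sample(c("G", "C", "G", "C", "A", "U"), 6, replace = TRUE)
  stem3 <- rev(vapply(stem5, .wc_complement, character(1)))
  paste0(paste(stem5, collapse = ""), substr(pair, 1, 1), triplet,
         substr(pair, 2, 2), paste(stem3, collapse = ""))
}

#' Write a synthetic transcriptome to disk
#'
#' Emits FASTA (transcript sequences), GFF3 (region features, 1-based
#' inclusive) and a truth TSV of planted sites into `dir`.
#'
#' @param tx A `"synthetic_transcriptome"` from [generate_transcriptome()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_transcriptome <- function(tx, dir) {
  stopifnot(inherits(tx, "synthetic_transcriptome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "transcripts.fa"),
             gff3 = file.path(dir, "regions.gff3"),
             truth = file.path(dir, "planted_sites.tsv"))
  write_rna_fasta(tx$transcripts, paths["fasta"])
  write_region_gff3(tx$regions, paths["gff3"])
  readr::write_tsv(tx$truth, paths["truth"])
  invisible(paths)
}

#' Simulate per-gene RIP enrichments from a site feature matrix
#'
#' Enrichment = intercept + features %*% coefficients + Gaussian noise; the
#' linear response the downstream regression assumes.
#'
#' @param features A tibble with a `transcript_id` column and numeric
#'   feature columns (see [site_feature_matrix()]).
#' @param coefficients Named numeric vector; names must match the feature
#'   columns exactly.
#' @param intercept Intercept (log2 enrichment units).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return A tibble with columns `transcript_id`, `enrichment`.
#' @export
simulate_rip <- function(features, coefficients, intercept = 0,
                         noise_sd = 0.5, seed = 1L) {
  fcols <- setdiff(names(features), "transcript_id")
  if (!setequal(names(coefficients), fcols)) {
    stop("coefficient names do not match feature columns")
  }
  x <- as.matrix(features[, names(coefficients)])
  withr::with_seed(as.integer(seed), {
    tibble(
      transcript_id = features$transcript_id,
      enrichment = as.numeric(intercept + x %*% coefficients +
                                rnorm(nrow(x), 0, noise_sd))
    )
  })
}
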