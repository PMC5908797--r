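test_that("generator config validates its invariants", {
  expect_error(generator_config(length_range = c(5, 41)))
  expect_error(generator_config(length_range = c(41, 30)))
  expect_error(generator_config(planted_fraction = 1.2))
  expect_error(generator_config(noise_sd = -1))
  expect_error(generator_config(ssrna_motif = "UUXGUG"), "invalid symbols")
})

test_that("oligo pools have the configured geometry and are reproducible", {
  cfg <- generator_config(seed = 1, n_oligos = 100)
  pool <- generate_oligo_pool(cfg)
  expect_equal(nrow(pool), 100)
  expect_true(all(nchar(pool$seq) >= 30 & nchar(pool$seq) <= 41))
  expect_false(any(grepl("[^ACGU]", pool$seq)))
  pool2 <- generate_oligo_pool(cfg)
  expect_identical(pool, pool2)
  # byte-identical FASTA on rerun
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_rna_fasta(pool, f1); write_rna_fasta(generate_oligo_pool(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planting rate follows the configured fraction", {
  cfg <- generator_config(seed = 42, n_oligos = 100, planted_fraction = 0.2,
                          binder_kind = "structure")
  pool <- generate_oligo_pool(cfg)
  n_planted <- sum(!is.na(pool$planted))
  # Bernoulli(0.2) per oligo: 99.9% interval at n = 100
  expect_gte(n_planted, 8)
  expect_lte(n_planted, 34)
  # every planted element carries a U-A closing pair at stem position 1
  expect_true(all(startsWith(na.omit(pool$planted), "UA:")))
  keys <- na.omit(pool$planted)
  loops <- substr(keys, 4, 6)
  expect_true(all(mapply(grepl, paste0("U", loops, "A"), pool$seq[!is.na(pool$planted)],
                         fixed = TRUE)))
})

test_that("binding scores reflect planted effects", {
  cfg0 <- generator_config(seed = 2, n_oligos = 60, binder_kind = "null", noise_sd = 0)
  pool0 <- generate_oligo_pool(cfg0)
  expect_true(all(simulate_binding_scores(pool0, cfg0)$score == 0))

  w <- c("UA:CCA" = 3)
  cfg1 <- generator_config(seed = 3, n_oligos = 60, binder_kind = "structure",
                           pattern_weights = w, planted_fraction = 1, noise_sd = 0)
  pool1 <- generate_oligo_pool(cfg1)
  expect_true(all(simulate_binding_scores(pool1, cfg1)$score == 3))

  # law of large numbers: planted minus unplanted mean ~ mean planted weight
  cfg2 <- generator_config(seed = 4, n_oligos = 10000, binder_kind = "structure",
                           planted_fraction = 0.3, noise_sd = 0.25)
  pool2 <- generate_oligo_pool(cfg2)
  sc2 <- simulate_binding_scores(pool2, cfg2)
  planted <- !is.na(pool2$planted)
  gap <- mean(sc2$score[planted]) - mean(sc2$score[!planted])
  expect_equal(gap, mean(pool2$planted_effect[planted]), tolerance = 0.05)
})

test_that("two-channel simulation obeys its contract", {
  cfg <- generator_config(seed = 5, n_oligos = 200, binder_kind = "null",
                          noise_sd = 0, artifact_fraction = 0)
  pool <- generate_oligo_pool(cfg)
  sc <- simulate_binding_scores(pool, cfg)
  tc <- simulate_two_channel(pool, sc, cfg)
  expect_equal(tc$pulldown, tc$input, tolerance = 1e-12)

  cfg2 <- generator_config(seed = 6, n_oligos = 1000, binder_kind = "null",
                           artifact_fraction = 0.1)
  pool2 <- generate_oligo_pool(cfg2)
  sc2 <- simulate_binding_scores(pool2, cfg2)
  tc2 <- simulate_two_channel(pool2, sc2, cfg2)
  n_art <- sum(tc2$artifact)
  expect_gt(n_art, 60); expect_lt(n_art, 140)
  expect_true(all(log2(tc2$input[tc2$artifact]) < 6.5))
  expect_identical(tc2, simulate_two_channel(pool2, sc2, cfg2))
})

test_that("synthetic transcriptomes segment and plant correctly", {
  sites <- tibble::tibble(transcript = 1, region = "3UTR", pattern = "UA:GCA")
  tx <- generate_transcriptome(1, c(utr5 = 60, cds = 120, utr3 = 100),
                               sites = sites, seed = 9)
  expect_equal(nrow(tx$truth), 1)
  expect_equal(tx$truth$region, "3UTR")
  expect_equal(nchar(tx$transcripts$seq), 280)
  # segmentation covers the transcript exactly once, in order
  reg <- tx$regions
  expect_equal(reg$region, c("5UTR", "CDS", "3UTR"))
  expect_equal(reg$start, c(1, 61, 181))
  expect_equal(reg$end, c(60, 180, 280))
  # the planted -1/+1 and loop bases are where the truth table says
  p <- tx$truth$pos
  expect_equal(substr(tx$transcripts$seq, p, p + 4), "UGCAA")

  # sites that cannot fit are rejected
  expect_error(
    generate_transcriptome(1, c(utr5 = 10, cds = 50, utr3 = 5),
                           sites = tibble::tibble(transcript = 1, region = "3UTR",
                                                  pattern = "UA:AAA"),
                           seed = 1),
    "does not fit")

  # 50 transcripts x 3 sites, reproducible
  sites3 <- tidyr::crossing(transcript = 1:50, region = c("5UTR", "CDS", "3UTR")) %>%
    dplyr::mutate(pattern = "UA:CAA")
  tx3 <- generate_transcriptome(50, sites = sites3, seed = 10)
  expect_equal(nrow(tx3$truth), 150)
  tx3b <- generate_transcriptome(50, sites = sites3, seed = 10)
  expect_identical(tx3$transcripts, tx3b$transcripts)
  expect_identical(tx3$truth, tx3b$truth)
})

test_that("generated files round-trip through the package readers", {
  sites <- tibble::tibble(transcript = c(1, 2), region = c("CDS", "3UTR"),
                          pattern = c("UA:AAA", "UA:GGA"))
  tx <- generate_transcriptome(2, sites = sites, seed = 12)
  dir <- tempfile(); paths <- write_transcriptome(tx, dir)
  fa <- read_rna_fasta(paths[["fasta"]])
  expect_equal(fa$id, tx$transcripts$id)
  expect_equal(fa$seq, tx$transcripts$seq)
  gff <- read_region_gff3(paths[["gff3"]])
  expect_equal(as.data.frame(gff), as.data.frame(tx$regions))
  truth <- read_table_tsv(paths[["truth"]])
  expect_equal(as.data.frame(truth), as.data.frame(tx$truth))
})

test_that("simulate_rip is linear in the features", {
  feats <- tibble::tibble(transcript_id = c("a", "b", "c"),
                          x = c(0, 1, 3), y = c(2, 0, 1))
  r0 <- simulate_rip(feats, c(x = 0, y = 0), intercept = 1.5, noise_sd = 0, seed = 1)
  expect_true(all(r0$enrichment == 1.5))
  r1 <- simulate_rip(feats, c(x = 2, y = 0), intercept = 0, noise_sd = 0, seed = 1)
  expect_equal(diff(r1$enrichment), 2 * diff(feats$x))
  expect_error(simulate_rip(feats, c(x = 1)), "do not match")
})
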