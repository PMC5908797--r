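test_that("pattern space enumerates 6 x 64 x 7 = 2688", {
  pats <- enumerate_patterns()
  expect_equal(nrow(pats), 2688)
  expect_length(unique(pats$pattern), 2688)
  expect_length(lre_closing_pairs(), 6)
  expect_length(lre_loop_triplets(), 64)
  expect_equal(nrow(dplyr::distinct(pats, pair, triplet)), 384)
  expect_setequal(unique(pats$bin), 1:7)
})

test_that("pairing bins span the log2 scale monotonically", {
  expect_equal(pairing_bin(0), 1L)
  expect_equal(pairing_bin(1), 7L)
  p <- sort(runif(200))
  b <- pairing_bin(p)
  expect_true(all(diff(b) >= 0))
  expect_true(all(b >= 1 & b <= 7))
  expect_error(pairing_bin(1.2), "\\[0, 1\\]")
  expect_error(pairing_bin(-0.1), "\\[0, 1\\]")
})

test_that("pattern occurrences require canonical -1/+1 flanks", {
  seq <- "GGAGUCCAACUCC"
  prof <- distance4_profile(pair_probabilities(seq))
  occ <- find_pattern_occurrences(seq, prof)
  hit <- occ[occ$pos == 5, ]
  expect_equal(hit$pair, "UA")
  expect_equal(hit$triplet, "CCA")
  expect_gte(hit$bin, 6)
  expect_equal(nrow(find_pattern_occurrences("AAAAAAAAA", rep(0, 5))), 0)
  expect_lte(nrow(occ), nchar(seq) - 4)
})

test_that("clipping zeroes the open interval and keeps boundaries", {
  expect_equal(clip_enrichments(1.5), 0)
  expect_equal(clip_enrichments(-3), -3)
  expect_equal(clip_enrichments(2), 2)
  expect_equal(clip_enrichments(-2), -2)
  v <- c(-3, -2, -1.99, 0, 1.99, 2, 3)
  expect_equal(clip_enrichments(clip_enrichments(v)), clip_enrichments(v)) # idempotent
  expect_equal(clip_enrichments(-v), -clip_enrichments(v))                 # odd
  expect_error(clip_enrichments(NA_real_))
})

test_that("model fitting recovers constructed pattern scores exactly", {
  # 25 copies each of pure elements for three patterns; enrichment is a
  # deterministic function of the pattern
  f <- c("UA:AAA" = 3, "UA:CCG" = 2.5, "CG:GAA" = -2.5)
  mk <- function(key) {
    parts <- strsplit(key, ":")[[1]]
    perfect_hairpin_fixture(triplet = parts[2], pair = parts[1])
  }
  pool <- tibble::tibble(
    id = sprintf("o%03d", 1:75),
    seq = rep(vapply(names(f), mk, character(1)), each = 25)
  )
  enr <- tibble::tibble(id = pool$id, enrichment = rep(unname(f), each = 25))
  mod <- fit_lre_model(pool, enr)
  expect_equal(nrow(mod), 2688)
  for (key in names(f)) {
    parts <- strsplit(key, ":")[[1]]
    got <- mod[mod$pair == parts[1] & mod$triplet == parts[2] & mod$bin == 7, ]
    expect_equal(got$score, unname(clip_enrichments(f[key])), label = key)
    expect_gte(got$support, 25)
  }
  # support below 20 -> missing score
  pool19 <- pool[1:19, ]
  mod19 <- fit_lre_model(pool19, enr[1:19, ])
  got19 <- mod19[mod19$pair == "UA" & mod19$triplet == "AAA" & mod19$bin == 7, ]
  expect_equal(got19$support, 19)
  expect_true(is.na(got19$score))
})

test_that("model fitting is order-invariant and bias-suppressing", {
  cfg <- generator_config(seed = 71, n_oligos = 1500, binder_kind = "null",
                          noise_sd = 0.25)
  pool <- generate_oligo_pool(cfg)
  enr <- dplyr::rename(simulate_binding_scores(pool, cfg), enrichment = "score")
  mod <- fit_lre_model(pool, enr)
  perm <- withr::with_seed(2, sample(nrow(pool)))
  mod_perm <- fit_lre_model(pool[perm, ], enr[perm, ])
  expect_equal(as.data.frame(mod), as.data.frame(mod_perm))
  # a pool-wide +0.5 bias (AAA/CCC-style artifact) is clipped away
  mod_bias <- fit_lre_model(pool, dplyr::mutate(enr, enrichment = enrichment + 0.5))
  expect_equal(mod_bias$score, mod$score)
})

test_that("pattern selection follows the closing-pair rules", {
  mod <- enumerate_patterns()
  mod$score <- NA_real_
  mod$support <- 0L
  set_score <- function(m, pair, triplet, bin, s) {
    i <- m$pair == pair & m$triplet == triplet & m$bin == bin
    m$score[i] <- s; m$support[i] <- 50L; m
  }
  mod <- set_score(mod, "UA", "AAA", 5, 0.3)   # retained
  mod <- set_score(mod, "UA", "CCC", 3, 0.5)   # bin too low
  mod <- set_score(mod, "UA", "GGG", 7, 0.05)  # score too low
  mod <- set_score(mod, "CG", "AAA", 7, 0.5)   # retained
  mod <- set_score(mod, "CG", "GAA", 6, 0.5)   # bin must be 7
  mod <- set_score(mod, "GC", "AAA", 7, 2.0)   # other pairs excluded
  class(mod) <- c("lre_model", class(mod))
  sel <- select_binding_patterns(mod)
  expect_setequal(paste(sel$pair, sel$triplet, sel$bin), c("UA AAA 5", "CG AAA 7"))
})

test_that("strength bins use left-closed twofold thresholds", {
  s <- strength_bin(c(0.2, 0.225, 0.3, 0.45, 1.0, 1.8, 5))
  expect_equal(as.character(s),
               c("none", "minimal", "minimal", "weak", "medium", "strong", "strong"))
  expect_true(is.ordered(s))
})
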