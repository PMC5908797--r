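# a selected-pattern table with known scores per loop triplet, spanning all
# four strengths, over UA bins 4-7
demo_patterns <- function() {
  enumerate_patterns() %>%
    dplyr::filter(.data$pair == "UA", .data$bin >= 4,
                  .data$triplet %in% c("AAA", "CAA", "GGA", "UUA")) %>%
    dplyr::mutate(score = c(AAA = 2.0, CAA = 1.0, GGA = 0.5, UUA = 0.3)[.data$triplet])
}

test_that("planted sites are recovered with exact position, region and strength", {
  sites <- tidyr::crossing(transcript = 1:6, region = c("5UTR", "CDS", "3UTR")) %>%
    dplyr::mutate(pattern = paste0("UA:", rep(c("AAA", "CAA", "GGA"), 6)))
  tx <- generate_transcriptome(6, c(utr5 = 80, cds = 200, utr3 = 120),
                               sites = sites, seed = 91)
  found <- scan_transcriptome(tx, patterns = demo_patterns())
  joined <- dplyr::inner_join(tx$truth, found, by = c("transcript_id", "pos"))
  expect_equal(nrow(joined), nrow(tx$truth)) # 100% recall
  expect_equal(joined$region.x, joined$region.y)
  truth_strength <- c(AAA = "strong", CAA = "medium", GGA = "weak")
  expect_equal(as.character(joined$strength),
               unname(truth_strength[sub("UA:", "", joined$pattern.x)]))
  # no site at non-canonical flanks, none below the minimal threshold
  flank <- substr(found$pattern, 1, 2)
  expect_true(all(flank %in% c("AU", "UA", "GC", "CG", "GU", "UG")))
  expect_true(all(found$score >= 0.225))
})

test_that("unstructured transcripts yield no sites", {
  expect_equal(nrow(scan_transcript("t1", strrep("A", 200),
                                    tibble::tibble(transcript_id = "t1",
                                                   region = "CDS", start = 1, end = 200),
                                    demo_patterns())), 0)
  expect_equal(nrow(scan_transcript("t1", "ACG",
                                    tibble::tibble(transcript_id = "t1", region = "CDS",
                                                   start = 1, end = 3),
                                    demo_patterns())), 0)
})

test_that("sites spanning a region boundary are assigned by the loop center", {
  # place the element so that stem position -1 is the last CDS base:
  # loop position II (pos + 2) then lies in the 3'UTR
  hp <- perfect_hairpin_fixture("AAA") # closing U at local position 15
  bg <- strrep("AC", 60)
  seq <- paste0(substr(bg, 1, 40), hp, substr(bg, 1, 60))
  pos <- 40 + 15 # transcript coordinate of stem position -1
  regions <- tibble::tibble(transcript_id = "t1", region = c("5UTR", "CDS", "3UTR"),
                            start = c(1, 21, pos + 2), end = c(20, pos + 1, nchar(seq)))
  found <- scan_transcript("t1", seq, regions, demo_patterns())
  site <- found[found$pos == pos, ]
  expect_equal(nrow(site), 1)
  expect_equal(site$region, "3UTR")
})

test_that("site feature matrices count by region and strength", {
  sites <- tibble::tibble(
    transcript_id = c("t1", "t1", "t2"),
    pos = c(10L, 50L, 30L), region = c("3UTR", "CDS", "3UTR"),
    pair = "UA", triplet = "AAA", bin = 7L, pattern = "UA:AAA:7",
    score = c(2, 0.3, 0.5),
    strength = factor(c("strong", "minimal", "weak"),
                      levels = c("minimal", "weak", "medium", "strong"),
                      ordered = TRUE)
  )
  fm <- site_feature_matrix(sites, c("t1", "t2", "t3"))
  expect_equal(dim(fm), c(3, 13))
  expect_equal(fm$`3UTR_strong`, c(1L, 0L, 0L))
  expect_equal(fm$CDS_minimal, c(1L, 0L, 0L))
  expect_equal(fm$`3UTR_weak`, c(0L, 1L, 0L))
  expect_true(all(fm[fm$transcript_id == "t3", -1] == 0))
  # conservation: column sums equal per-category site counts
  expect_equal(sum(fm[, -1]), nrow(sites))
  expect_error(site_feature_matrix(sites, c("t1")), "missing from")
})

test_that("scan results export valid BED6", {
  sites <- tibble::tibble(transcript_id = "t1", pos = 10L, region = "3UTR",
                          pair = "UA", triplet = "AAA", bin = 7L,
                          pattern = "UA:AAA:7", score = 0.9,
                          strength = factor("medium"))
  path <- tempfile(fileext = ".bed")
  write_sites_bed(sites, path)
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         show_col_types = FALSE)
  expect_equal(bed$start, 9)  # 0-based half-open, covering -1 .. +1
  expect_equal(bed$end, 14)
  expect_equal(bed$score, as.integer(round(1000 * 0.9 / 1.8)))
  expect_equal(bed$strand, "+")
})
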