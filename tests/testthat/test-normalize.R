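test_that("input reference is the per-oligo median", {
  tbl <- tibble::tibble(oligo_id = c("a", "b"), s1 = c(3, 2), s2 = c(5, 4), s3 = c(7, 100))
  expect_equal(build_input_reference(tbl)$reference, c(5, 4))
  one <- tibble::tibble(oligo_id = "a", s1 = 9)
  expect_equal(build_input_reference(one)$reference, 9)
  even <- tibble::tibble(oligo_id = "a", s1 = 2, s2 = 4)
  expect_equal(build_input_reference(even)$reference, 3) # mean of middle pair
  expect_error(build_input_reference(tibble::tibble(oligo_id = "a")), "no sample")
})

test_that("low-median filter applies a strict log2 cutoff", {
  tbl <- tibble::tibble(oligo_id = c("lo", "edge", "hi"),
                        s1 = 2^c(5.9, 6.0, 9))
  f <- filter_low_median(tbl)
  expect_equal(f$removed, "lo")          # 5.9 < 6 removed
  expect_true("edge" %in% f$table$oligo_id) # exactly 6 kept
  cfg <- generator_config(seed = 31, n_oligos = 2000, binder_kind = "null",
                          artifact_fraction = 0.1)
  pool <- generate_oligo_pool(cfg)
  tc <- simulate_two_channel(pool, simulate_binding_scores(pool, cfg), cfg)
  f2 <- filter_low_median(dplyr::rename(tc[, 1:3], oligo_id = "id"))
  expect_equal(length(f2$removed) / 2000, 0.1, tolerance = 0.25)
})

test_that("quantile normalization equalizes column distributions", {
  x <- tibble::tibble(oligo_id = c("a", "b", "c"),
                      s1 = c(1, 2, 3), s2 = c(8, 4, 6))
  qn <- quantile_normalize(x)
  expect_equal(qn$s1, c(2.5, 4, 5.5))
  expect_equal(qn$s2, c(5.5, 2.5, 4))
  expect_identical(quantile_normalize(qn), qn) # idempotent
  same <- tibble::tibble(oligo_id = c("a", "b"), s1 = c(1, 5), s2 = c(1, 5))
  expect_equal(quantile_normalize(same), same)
  withr::with_seed(8, {
    big <- tibble::tibble(oligo_id = sprintf("o%03d", 1:200),
                          s1 = rlnorm(200), s2 = rlnorm(200, 1), s3 = rlnorm(200, 2))
  })
  qb <- quantile_normalize(big)
  expect_equal(sort(qb$s1), sort(qb$s2))
  expect_equal(sort(qb$s1), sort(qb$s3))
  # matches an independently written rank-mean construction (tie-free input)
  expect_equal(as.matrix(qb[, 2:4]), rank_mean_qn(as.matrix(big[, 2:4])),
               ignore_attr = TRUE)
})

test_that("artifact filter flags low-efficiency and depleted probes", {
  cfg <- generator_config(seed = 33, n_oligos = 2000, binder_kind = "structure",
                          planted_fraction = 0.05, artifact_fraction = 0.08)
  pool <- generate_oligo_pool(cfg)
  sc <- simulate_binding_scores(pool, cfg)
  tc <- dplyr::rename(simulate_two_channel(pool, sc, cfg), oligo_id = "id")
  f <- artifact_filter(tc)
  # all synthetic low-efficiency probes are flagged at the default cutoffs
  expect_true(all(tc$oligo_id[tc$artifact] %in% f$removed_low_efficiency))
  # flagged sets never intersect intact planted high-binders
  strong <- tc$oligo_id[!is.na(pool$planted) & pool$planted_effect == 3 & !tc$artifact]
  expect_length(intersect(c(f$removed_low_efficiency, f$removed_depleted), strong), 0)
  # cutoffs of zero remove nothing
  f0 <- artifact_filter(tc, input_cutoff_log2 = 0, depleted_cutoff_log2 = 0)
  expect_length(f0$removed_low_efficiency, 0)
  expect_equal(nrow(f0$table), nrow(tc))
})

test_that("loess residuals recover offsets and planted enrichments", {
  withr::with_seed(44, {
    x <- rnorm(500, 10, 1.5)
  })
  flat <- tibble::tibble(oligo_id = sprintf("o%04d", 1:500), input = x, pulldown = x)
  expect_lt(max(abs(loess_enrichment(flat)$enrichment)), 1e-6)
  off <- dplyr::mutate(flat, pulldown = input + 1)
  expect_lt(max(abs(loess_enrichment(off)$enrichment)), 1e-6)
  expect_error(loess_enrichment(flat[1:20, ]), ">= 50")

  # 5% of oligos at +3 log2 over a smooth trend
  withr::with_seed(45, {
    n <- 4000
    input <- rnorm(n, 10, 1.5)
    trend <- input + 0.1 * (input - 10)^2 / 5
    hot <- seq_len(n) <= n * 0.05
    pulldown <- trend + 3 * hot + rnorm(n, 0, 0.3)
  })
  ch <- tibble::tibble(oligo_id = sprintf("o%05d", 1:n), input = input,
                       pulldown = pulldown)
  enr <- loess_enrichment(ch)
  m <- mean(enr$enrichment[hot])
  expect_gte(m, 2.5); expect_lte(m, 3.1)
  # residual mean ~ 0 overall
  expect_lt(abs(mean(enr$enrichment)), 0.1)
})

test_that("the full two-channel pipeline recovers planted enrichment", {
  cfg <- generator_config(seed = 46, n_oligos = 4000, binder_kind = "structure",
                          planted_fraction = 0.05, noise_sd = 0.25,
                          artifact_fraction = 0.05)
  pool <- generate_oligo_pool(cfg)
  sc <- simulate_binding_scores(pool, cfg)
  tc <- dplyr::rename(simulate_two_channel(pool, sc, cfg), oligo_id = "id")
  out <- normalize_two_channel(tc)
  strong <- pool$id[pool$planted_effect == 3 & !tc$artifact]
  got <- out$enrichment$enrichment[out$enrichment$oligo_id %in% strong]
  expect_equal(mean(got), 3, tolerance = 0.15)
  # filters report exactly what they removed
  expect_true(all(lengths(out$removed) >= 0))
  expect_false(any(out$enrichment$oligo_id %in% unlist(out$removed)))
})
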