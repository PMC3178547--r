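test_that("allelic states classify against the sample ploidy", {
  expect_equal(classify_allelic_event(2, 0, 2.8), "NEAR_CN_LOH")
  expect_equal(classify_allelic_event(3, 0, 2.8), "NEAR_CN_LOH")
  expect_equal(classify_allelic_event(2, 0, 2.0), "NEAR_CN_LOH")
  expect_equal(classify_allelic_event(3, 0, 2.0), "GAIN_LOH")
  expect_equal(classify_allelic_event(1, 0, 2.0), "LOSS_LOH")
  expect_equal(classify_allelic_event(0, 0, 2.0), "LOSS_LOH")
  expect_equal(classify_allelic_event(3, 1, 4.0), "ALLELIC_IMBALANCE")
  expect_equal(classify_allelic_event(4, 1, 4.0), "ALLELIC_IMBALANCE")
  expect_equal(classify_allelic_event(2, 2, 4.0), "BALANCED")
  expect_equal(classify_allelic_event(2, 1, 2.0), "BALANCED")
  expect_equal(classify_allelic_event(1, 1, 2.0), "BALANCED")
})

test_that("every minor-zero state of total >= 1 falls in exactly one LOH class", {
  for (p in c(2, 2.8, 3.4, 4)) {
    for (a in 1:6) {
      cat_ <- classify_allelic_event(a, 0, p)
      expect_true(cat_ %in% c("NEAR_CN_LOH", "GAIN_LOH", "LOSS_LOH"))
    }
  }
})

test_that("extent classification honours the end tolerance and precedence", {
  expect_equal(classify_extent(1, 1000, 1000), "WHOLE_CHROMOSOME")
  expect_equal(classify_extent(4, 997, 1000, tol_markers = 5),
               "WHOLE_CHROMOSOME")
  expect_equal(classify_extent(1, 400, 1000), "TELOMERIC")
  expect_equal(classify_extent(600, 1000, 1000), "TELOMERIC")
  expect_equal(classify_extent(200, 800, 1000), "INTERSTITIAL")
  expect_equal(classify_extent(7, 400, 1000, tol_markers = 5),
               "INTERSTITIAL")
})

make_fit <- function(states, rho = 0, c_tilde = 2, ...) {
  seg <- segments_from_states(states, rho = rho, c_tilde = c_tilde, ...)
  fit_sample(seg)
}

test_that("calls carry categories, extents and honour the size threshold", {
  states <- data.frame(major = c(1, 2, 1, 1), minor = c(1, 0, 1, 0))
  seg <- segments_from_states(states, rho = 0, c_tilde = 2,
                              chrom = c("chr1", "chr2", "chr3", "chr4"))
  # make the (1,0) call 1.2 Mb: below the 1.5 Mb reporting threshold
  seg$end[4] <- seg$start[4] + 1.2e6 - 1
  fit <- fit_sample(seg)
  calls <- call_loh(fit)
  expect_setequal(calls$category[calls$chrom == "chr2"], "NEAR_CN_LOH")
  expect_equal(calls$extent[calls$chrom == "chr2"], "WHOLE_CHROMOSOME")
  s <- sample_event_summary(calls, fit)
  expect_equal(s$n_near_cnloh, 1)
  expect_equal(s$n_whole_chromosome, 1)
  # the 1.2 Mb loss is dropped from aberration counting by size
  s2 <- sample_event_summary(calls, fit, min_event_size_bp = 1e6)
  expect_equal(s2$n_aberrant, 2)
  expect_equal(s$n_aberrant, 1)
})

test_that("sub-threshold near-CN-LOH events are not counted", {
  states <- data.frame(major = c(1, 2), minor = c(1, 0))
  seg <- segments_from_states(states, rho = 0, c_tilde = 2,
                              chrom = c("chr1", "chr2"))
  seg$end[2] <- seg$start[2] + 1.2e6 - 1     # 1.2 Mb (2,0)
  fit <- fit_sample(seg)
  s <- sample_event_summary(call_loh(fit), fit)
  expect_equal(s$n_near_cnloh, 0)
})

test_that("profile flags identify flat, MYCN-only and CN-LOH-only samples", {
  flat <- make_fit(data.frame(major = c(1, 1, 1), minor = c(1, 1, 1)))
  s <- sample_event_summary(call_loh(flat), flat)
  expect_true(s$flat_profile)
  expect_equal(s$n_near_cnloh, 0)

  # single MYCN amplicon, rest balanced
  states <- data.frame(major = c(1, 22, 1), minor = c(1, 1, 1))
  seg <- segments_from_states(states, rho = 0, c_tilde = 2,
                              chrom = c("chr1", "chr2", "chr3"))
  seg$start[2] <- 14.5e6; seg$end[2] <- 16.5e6
  fit <- fit_sample(seg)
  s <- sample_event_summary(call_loh(fit), fit)
  expect_true(s$mycn_amp_only)
  expect_false(s$flat_profile)

  cn <- make_fit(data.frame(major = c(1, 2, 2), minor = c(1, 0, 0)),
                 chrom = c("chr1", "chr2", "chr3"))
  s <- sample_event_summary(call_loh(cn), cn)
  expect_true(s$cnloh_only)
  expect_equal(s$n_near_cnloh, 2)
})

test_that("X-chromosome events never enter the counts", {
  states <- data.frame(major = c(1, 2, 2), minor = c(1, 0, 0))
  seg <- segments_from_states(states, rho = 0, c_tilde = 2,
                              chrom = c("chr1", "chr2", "chrX"))
  fit <- fit_sample(seg)
  s <- sample_event_summary(call_loh(fit), fit)
  expect_equal(s$n_near_cnloh, 1)
})

test_that("extent counts partition the near-CN-LOH total", {
  set.seed(17)
  map <- make_marker_map(spacing_bp = 1.2e6)
  for (i in 1:4) {
    tp <- simulate_truth_profile("flat_diploid", 3, c(0.4, 0.4, 0.2), map,
                                 rho = 0.3)
    tab <- simulate_snp_table(tp, map, noise_sd = 0)
    res <- analyze_sample(tab, min_markers = 10)
    s <- res$summary
    expect_equal(s$n_near_cnloh,
                 s$n_interstitial + s$n_telomeric + s$n_whole_chromosome)
  }
})

test_that("profile comparison labels shared, unique and partial events", {
  mk <- function(states, chrom) {
    seg <- segments_from_states(states, rho = 0, c_tilde = 2, chrom = chrom)
    fit_sample(seg)
  }
  base <- data.frame(major = c(1, 2, 3), minor = c(1, 0, 1))
  f1 <- mk(base, c("chr1", "chr2", "chr3"))
  f2 <- mk(base, c("chr1", "chr2", "chr3"))
  f3 <- mk(base, c("chr1", "chr2", "chr3"))
  f1$sample_id <- "A"; f2$sample_id <- "B"; f3$sample_id <- "C"
  cmp <- compare_profiles(list(f1, f2, f3))
  expect_true(all(cmp$sharing == "shared_by_all"))

  # same arm, different copy number -> partial (distinct events)
  alt <- data.frame(major = c(1, 3, 3), minor = c(1, 0, 1))
  f2b <- mk(alt, c("chr1", "chr2", "chr3"))
  f2b$sample_id <- "B"
  cmp2 <- compare_profiles(list(f1, f2b))
  chr2 <- cmp2[cmp2$chrom == "chr2", ]
  expect_true(all(chr2$sharing == "unique"))
  expect_true(all(chr2$partial_with != ""))

  # overlap 0.4 with threshold 0.5 -> unique to each sample
  s1 <- segments_from_states(data.frame(major = c(2, 1), minor = c(0, 1)),
                             rho = 0, c_tilde = 2,
                             chrom = c("chr1", "chr1"))
  s1$start <- c(1, 40e6 + 1); s1$end <- c(40e6, 100e6)
  s1$idx_first <- c(1L, 4001L); s1$idx_last <- c(4000L, 10000L)
  attr(s1, "marker_extent") <- data.frame(chrom = "chr1", n_markers = 10000L,
                                          first_pos = 1, last_pos = 100e6)
  g1 <- fit_sample(s1)
  s2 <- s1; s2$mean_t <- rev(s1$mean_t)
  s2$mean_strong <- rev(s1$mean_strong)
  s2$hom_only <- rev(s1$hom_only)
  s2$n_het <- rev(s1$n_het)
  s2$start <- c(1, 24e6 + 1); s2$end <- c(24e6, 100e6)
  s2$idx_first <- c(1L, 2401L); s2$idx_last <- c(2400L, 10000L)
  g2 <- fit_sample(s2)   # (1,1) then (2,0): overlap of the two (2,0) runs
  g1$sample_id <- "A"; g2$sample_id <- "B"
  cmp3 <- compare_profiles(list(g1, g2), reciprocal_overlap = 0.5)
  loh <- cmp3[cmp3$major == 2 & cmp3$minor == 0, ]
  # overlap = 16 Mb; 16/40 = 0.4 and 16/76 = 0.21, both below 0.5
  expect_true(all(loh$sharing == "unique"))

  expect_error(compare_profiles(list(f1)), "two")
  tiny <- mk(base, c("chr1", "chr2", "chr3"))
  attr(tiny$segments, "marker_extent")$n_markers[1] <- 99L
  expect_error(compare_profiles(list(f1, tiny)), "marker map")
})
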