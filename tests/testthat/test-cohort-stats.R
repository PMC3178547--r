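mk_summary <- function(id, n = 0, ni = 0, nt = 0, nw = 0,
                       flat = FALSE, mycn = FALSE, cn = FALSE) {
  data.frame(sample_id = id, n_near_cnloh = n, n_interstitial = ni,
             n_telomeric = nt, n_whole_chromosome = nw,
             n_aberrant = n + 1L, flat_profile = flat, mycn_amp_only = mycn,
             cnloh_only = cn, stringsAsFactors = FALSE)
}

mk_meta <- function(ids, group, related = NA_character_,
                    outcome = NA_character_) {
  data.frame(sample_id = ids, group = group, related_group = related,
             outcome = outcome, stage = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("exclusions keep the designated parent and log every removal", {
  sm <- do.call(rbind, lapply(c("P", "S1", "S2", "T1"), mk_summary, n = 1))
  meta <- mk_meta(c("P", "S1", "S2", "T1"), "cell_line",
                  related = c("P", "P", "P", NA))
  ex <- apply_exclusions(sm, meta)
  expect_setequal(ex$included$sample_id, c("P", "T1"))
  expect_setequal(ex$exclusions$sample_id, c("S1", "S2"))
  expect_true(all(ex$exclusions$reason == "related_subclone"))

  # every removal appears exactly once
  expect_equal(anyDuplicated(ex$exclusions$sample_id), 0)

  # no designated parent -> error
  meta_bad <- mk_meta(c("S1", "S2"), "cell_line", related = "P")
  expect_error(apply_exclusions(sm[2:3, ], meta_bad), "parent")
})

test_that("stroma-filter flags exclude tumour and cell-line samples only", {
  sm <- rbind(mk_summary("T1", n = 2),
              mk_summary("T2", flat = TRUE),
              mk_summary("T3", mycn = TRUE),
              mk_summary("T4", n = 1, cn = TRUE),
              mk_summary("C1", flat = TRUE),
              mk_summary("C2", n = 1, cn = TRUE))
  meta <- mk_meta(sm$sample_id,
                  c("tumor", "tumor", "tumor", "tumor",
                    "control", "control"))
  ex <- apply_exclusions(sm, meta)
  expect_setequal(ex$included$sample_id, c("T1", "C1", "C2"))
  expect_setequal(ex$exclusions$reason,
                  c("flat_profile", "mycn_amp_only", "cnloh_only"))

  # no flags, no relatives: identity
  sm2 <- rbind(mk_summary("T1", 1), mk_summary("T2"))
  ex2 <- apply_exclusions(sm2, mk_meta(c("T1", "T2"), "tumor"))
  expect_equal(nrow(ex2$exclusions), 0)
  expect_equal(nrow(ex2$included), 2)
})

test_that("Fisher prevalence matches enumeration and known values", {
  expect_equal(round(fisher_prevalence(47, 134, 7, 8), 3), 0.005)
  expect_equal(fisher_prevalence(3, 10, 3, 10), 1)
  # symmetry in group order
  expect_equal(fisher_prevalence(5, 12, 2, 9),
               fisher_prevalence(2, 9, 5, 12))
  # label swap leaves the two-sided p unchanged
  expect_equal(fisher_prevalence(5, 12, 2, 9),
               fisher_prevalence(12 - 5, 12, 9 - 2, 9))
  # exhaustive fixed-margin enumeration oracle on all small tables
  for (n_a in c(3, 5, 8)) for (n_b in c(4, 6)) {
    for (k_a in 0:n_a) for (k_b in 0:n_b) {
      expect_equal(fisher_prevalence(k_a, n_a, k_b, n_b),
                   fisher_oracle(k_a, n_a, k_b, n_b), tolerance = 1e-9)
    }
  }
  expect_error(fisher_prevalence(1, 0, 1, 5), "positive")
  expect_error(fisher_prevalence(6, 5, 1, 5), "counts")
})

test_that("Mann-Whitney agrees with full permutation enumeration", {
  id <- mw_burden(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$p, 1)
  expect_equal(id$U, 4.5)                    # n1*n2/2 with ties

  sep <- mw_burden(c(1, 2, 3), c(7, 8, 9))
  expect_equal(sep$p, 0.1)                   # 2/20, complete separation
  expect_equal(sep$method, "exact")

  set.seed(4)
  for (i in 1:12) {
    a <- rpois(sample(3:7, 1), 1.2)
    b <- rpois(sample(3:7, 1), 2.0)
    expect_equal(mw_burden(a, b)$p, mw_oracle(a, b), tolerance = 1e-9,
                 info = paste("case", i))
  }
})

test_that("the tie-corrected approximation tracks the exact distribution", {
  set.seed(9)
  for (i in 1:8) {
    # lightly tied data: approximation within 0.01 of the permutation p
    a <- round(rnorm(12, 10, 3), 1); b <- round(rnorm(13, 12, 3), 1)
    expect_lt(abs(mw_burden(a, b, exact_limit = 0)$p -
                    mw_burden(a, b, exact_limit = 400)$p), 0.01)
    # heavily tied counts (half the values identical): the standard
    # approximation can deviate a few percent, which is why group pairs
    # this small always take the exact branch in practice; it must still
    # be identical to the reference continuity- and tie-corrected formula
    ca <- rpois(12, 1); cb <- rpois(13, 1.8)
    approx <- mw_burden(ca, cb, exact_limit = 0)$p
    expect_lt(abs(approx - mw_burden(ca, cb, exact_limit = 400)$p), 0.04)
    expect_equal(approx, suppressWarnings(wilcox.test(ca, cb)$p.value),
                 tolerance = 1e-12)
  }
  # large groups switch to the normal branch
  expect_equal(mw_burden(rpois(40, 1), rpois(40, 1))$method, "normal")
})

test_that("burden descriptives use linear-interpolation quantiles", {
  expect_equal(describe_burden(c(0, 0, 0)),
               c(median = 0, mean = 0, p25 = 0, p75 = 0))
  expect_equal(describe_burden(c(0, 1, 2, 3)),
               c(median = 1.5, mean = 1.5, p25 = 0.75, p75 = 2.25))
  expect_equal(describe_burden(5), c(median = 5, mean = 5, p25 = 5, p75 = 5))
  expect_error(describe_burden(numeric(0)), "non-empty")
})

test_that("subtype spectra are proportions over near-CN-LOH calls", {
  calls <- data.frame(
    sample_id = "s", chrom = c("chr1", "chr2", "chr3", "chrX", "chr4"),
    size_bp = c(5e6, 5e6, 5e6, 5e6, 1e6),
    category = c("NEAR_CN_LOH", "NEAR_CN_LOH", "GAIN_LOH", "NEAR_CN_LOH",
                 "NEAR_CN_LOH"),
    extent = c("INTERSTITIAL", "INTERSTITIAL", "TELOMERIC", "TELOMERIC",
               "INTERSTITIAL"),
    stringsAsFactors = FALSE)
  sp <- subtype_spectrum(calls)
  # X and sub-threshold and non-near calls are excluded: 2 interstitial
  expect_equal(unname(sp["INTERSTITIAL"]), 1)
  expect_equal(sum(sp), 1)

  empty <- subtype_spectrum(calls[0, ])
  expect_equal(length(empty), 0)
  expect_match(attr(empty, "note"), "no events")

  # binomial sampling check against a configured mixture
  set.seed(12)
  mix <- c(0.5, 0.35, 0.15)
  n <- 400
  ext <- sample(c("INTERSTITIAL", "TELOMERIC", "WHOLE_CHROMOSOME"), n,
                replace = TRUE, prob = mix)
  big <- data.frame(sample_id = "s", chrom = "chr1", size_bp = 5e6,
                    category = "NEAR_CN_LOH", extent = ext)
  sp <- subtype_spectrum(big)
  for (k in 1:3)
    expect_lt(abs(sp[[k]] - mix[k]), 3 * sqrt(mix[k] * (1 - mix[k]) / n))
})

test_that("outcome comparison behaves for null, strong and degenerate cases", {
  sm <- do.call(rbind, lapply(sprintf("T%02d", 1:40), mk_summary))
  sm$n_near_cnloh <- rep(c(1, 1), each = 20)
  sm$n_interstitial <- sm$n_near_cnloh
  sm$outcome <- rep(c("DOD", "NED"), each = 20)
  ob <- outcome_burden(sm)
  expect_true(all(ob$p[ob$comparison %in% c("overall", "interstitial")] == 1))

  set.seed(6)
  sm$n_near_cnloh <- c(rpois(20, 3), rpois(20, 0.05))
  ob2 <- outcome_burden(sm)
  expect_lt(ob2$p[ob2$comparison == "overall"], 0.01)

  sm$outcome <- "unknown"
  expect_error(outcome_burden(sm), "outcome")
})

test_that("cohort statistics assemble prevalence, tests and spectra", {
  set.seed(30)
  ids_t <- sprintf("T%03d", 1:40)
  ids_c <- sprintf("C%02d", 1:6)
  ids_h <- sprintf("H%02d", 1:10)
  sm <- do.call(rbind, c(
    lapply(seq_along(ids_t), function(i)
      mk_summary(ids_t[i], n = rpois(1, 0.9))),
    lapply(seq_along(ids_c), function(i)
      mk_summary(ids_c[i], n = 1 + rpois(1, 1.4))),
    lapply(seq_along(ids_h), function(i)
      mk_summary(ids_h[i], n = 0))))
  sm$n_interstitial <- sm$n_near_cnloh
  meta <- mk_meta(c(ids_t, ids_c, ids_h),
                  rep(c("tumor", "cell_line", "control"),
                      c(length(ids_t), length(ids_c), length(ids_h))),
                  outcome = c(sample(c("DOD", "NED"), length(ids_t), TRUE),
                              rep(NA, length(ids_c) + length(ids_h))))
  calls <- data.frame(sample_id = rep(sm$sample_id, sm$n_near_cnloh),
                      chrom = "chr1", size_bp = 5e6,
                      category = "NEAR_CN_LOH", extent = "INTERSTITIAL",
                      stringsAsFactors = FALSE)
  res <- cohort_stats(sm, calls, meta)
  expect_s3_class(res, "cohort_result")
  expect_equal(sum(res$n), nrow(sm))
  pv <- res$prevalence
  expect_true(all(pv$fraction >= 0 & pv$fraction <= 1))
  expect_equal(pv$affected[pv$group == "cell_line"], 6)
  expect_equal(nrow(res$fisher), 3)
  expect_equal(nrow(res$mann_whitney), 3)
  expect_equal(unname(res$spectrum$tumor["INTERSTITIAL"]), 1)
  expect_false(is.null(res$outcome))
  expect_output(print(res), "Fisher")
})

test_that("simulated printed-scale prevalences give Fisher p near 0.005", {
  set.seed(77)
  ps <- replicate(25, {
    k1 <- rbinom(1, 134, 0.35)
    k2 <- rbinom(1, 8, 7 / 8)
    fisher_prevalence(k1, 134, k2, 8)
  })
  expect_gt(median(ps), 0.001)
  expect_lt(median(ps), 0.02)
})
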