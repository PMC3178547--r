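test_that("marker maps place floor(length/spacing) markers per chromosome", {
  lens <- data.frame(chrom = "chr1", length_bp = 247e6)
  map <- make_marker_map(lens, spacing_bp = 12000)
  expect_equal(nrow(map), 20583)           # floor(247e6 / 12e3)
  expect_true(all(diff(map$pos) == 12000))
  expect_true(all(map$pos >= 1 & map$pos <= 247e6))

  # summation oracle over a multi-chromosome table
  lens <- tiny_lengths(5, 60e6); lens$length_bp <- c(60e6, 41e6, 33.3e6, 7e6, 1.9e6)
  map <- make_marker_map(lens, spacing_bp = 1.7e6)
  expect_equal(nrow(map), sum(floor(lens$length_bp / 1.7e6)))
})

test_that("degenerate spacing warns and errors are raised", {
  lens <- data.frame(chrom = c("chr1", "chr2"), length_bp = c(50e6, 1e6))
  expect_warning(map <- make_marker_map(lens, spacing_bp = 2e6), "chr2")
  expect_false("chr2" %in% map$chrom)
  expect_error(make_marker_map(lens, spacing_bp = 0), "positive")
})

test_that("truth profiles respect their background contracts", {
  map <- tiny_map(4)
  set.seed(1)
  flat <- simulate_truth_profile("flat_diploid", 0, c(1, 0, 0), map)
  expect_true(all(flat$segments$major == 1 & flat$segments$minor == 1))

  # degenerate mixture: every injected event is interstitial
  set.seed(2)
  tp <- simulate_truth_profile("flat_diploid", 3, c(1, 0, 0), map)
  expect_true(nrow(tp$events) > 0)
  expect_true(all(tp$events$extent == "INTERSTITIAL"))

  # near-triploid: whole-chromosome totals in 2..5, no interior breakpoints
  map23 <- make_marker_map(spacing_bp = 2.5e6)
  for (s in 1:5) {
    set.seed(s)
    nt <- simulate_truth_profile("numerical_near_triploid", 2, c(0, 0, 1),
                                 map23, rho = 0.3)
    per_chr <- table(nt$segments$chrom)
    expect_true(all(per_chr == 1))         # zero intra-chromosome breakpoints
    tot <- nt$segments$major + nt$segments$minor
    expect_true(all(tot %in% 2:5))
  }

  expect_error(simulate_truth_profile("weird", 1, c(1, 0, 0), map))
  expect_error(simulate_truth_profile("control", 1, c(1, 0, 0), map,
                                      rho = 0.2), "rho")
})

test_that("truth segments tile each chromosome exactly", {
  map <- make_marker_map(spacing_bp = 2.5e6)
  for (type in c("mycn_segmental", "del11q_segmental", "control")) {
    set.seed(7)
    tp <- simulate_truth_profile(type, 2, c(0.4, 0.3, 0.3), map)
    idx <- nearloh:::match_segments(map, tp$segments)  # errors if not tiling
    expect_equal(length(idx), nrow(map))
    for (ch in unique(tp$segments$chrom)) {
      s <- tp$segments[tp$segments$chrom == ch, ]
      s <- s[order(s$start), ]
      expect_equal(s$start[1], 1)
      if (nrow(s) > 1)
        expect_equal(s$start[-1], s$end[-nrow(s)] + 1)
    }
  }
})

test_that("noise-free signals follow the mixture model", {
  map <- tiny_map(1, 30e6, spacing = 100e3)
  tp <- simulate_truth_profile("flat_diploid", 0, c(1, 0, 0), map,
                               rho = 0)
  set.seed(3)
  tab <- simulate_snp_table(tp, map, germline_het_prob = 0.5, noise_sd = 0)
  expect_true(all(tab$total_ratio == 1))
  het <- tab$call == "AB"
  expect_true(all(tab$baf[het] == 0.5))
  expect_true(all(tab$baf[!het] %in% c(0, 1)))

  # (2,0) at rho 0.3: t stays 1, mirrored fraction 0.85
  tp$segments$major <- 2; tp$segments$minor <- 0
  tp$rho <- 0.3
  set.seed(4)
  tab <- simulate_snp_table(tp, map, germline_het_prob = 0.5, noise_sd = 0)
  expect_equal(unique(tab$total_ratio), 1)
  het <- tab$call == "AB"
  expect_true(any(het))
  expect_equal(unique(pmax(tab$baf[het], 1 - tab$baf[het])), 0.85)

  # rho -> 1 limit: indistinguishable from balanced diploid
  tp$rho <- 0.999
  set.seed(5)
  tab <- simulate_snp_table(tp, map, germline_het_prob = 0.5, noise_sd = 0)
  expect_true(all(abs(tab$total_ratio - 1) < 1e-2))
  expect_true(all(abs(tab$baf[tab$call == "AB"] - 0.5) < 1e-2))
})

test_that("contamination mirrors decrease monotonically from 1 to 0.5", {
  rhos <- seq(0, 0.99, by = 0.01)
  m <- expected_signals(2, 0, rhos[1], 2)$mirrored
  vals <- vapply(rhos, function(r) expected_signals(2, 0, r, 2)$mirrored,
                 numeric(1))
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0.5))
})

test_that("IBD runs never yield het calls; contaminated somatic LOH does", {
  map <- tiny_map(1, 30e6, spacing = 50e3)
  base <- simulate_truth_profile("flat_diploid", 0, c(1, 0, 0), map)
  ibd <- base$segments
  ibd$major <- 2; ibd$minor <- 0; ibd$origin <- "germlineIBD"
  for (rho in c(0, 0.3, 0.6)) {
    tp <- base; tp$segments <- ibd; tp$rho <- rho
    set.seed(10 + round(100 * rho))
    tab <- simulate_snp_table(tp, map, noise_sd = 0)
    expect_false(any(tab$call == "AB"), info = paste("rho =", rho))
  }
  som <- ibd; som$origin <- "somatic"
  for (rho in c(0.2, 0.4, 0.6)) {
    tp <- base; tp$segments <- som; tp$rho <- rho
    set.seed(20 + round(100 * rho))
    tab <- simulate_snp_table(tp, map, noise_sd = 0)
    expect_true(any(tab$call == "AB"), info = paste("rho =", rho))
  }
})

test_that("cohort simulation is reproducible and correctly sized", {
  cfg <- cohort_config(n_tumors = 5, n_cell_lines = 2, n_controls = 3,
                       marker_spacing_bp = 2.5e6, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$snp_tables, b$snp_tables)
  expect_identical(a$truth_events, b$truth_events)
  expect_equal(length(a$snp_tables), 10)
  expect_equal(nrow(a$metadata), 10)
  expect_setequal(unique(a$metadata$group), c("tumor", "cell_line", "control"))

  d1 <- tempfile(); dir.create(d1)
  write_cohort(a, d1)
  expect_error(write_cohort(a, d1), "overwrite")
  expect_silent(write_cohort(a, d1, overwrite = TRUE))
  rt <- read_snp_table(file.path(d1, "NB001.snp.tsv"))
  expect_equal(rt$total_ratio, a$snp_tables$NB001$total_ratio)
  expect_equal(attr(rt, "sample_id"), "NB001")
  unlink(d1, recursive = TRUE)
})

test_that("realized event counts match the Poisson means", {
  cfg <- cohort_config(n_tumors = 134, n_cell_lines = 8, n_controls = 30,
                       marker_spacing_bp = 5e6, seed = 99)
  co <- simulate_cohort(cfg)
  expect_equal(length(co$snp_tables), 172)
  rates <- c(tumor = 0.89, cell_line = 2.4, control = 0.10)
  for (g in names(rates)) {
    ids <- co$metadata$sample_id[co$metadata$group == g]
    counts <- co$truth_params$n_events[match(ids, co$truth_params$sample_id)]
    se <- sqrt(rates[[g]] / length(ids))
    expect_lt(abs(mean(counts) - rates[[g]]), 3 * se + 1e-9)
  }
})

test_that("related subclones share the parent profile plus private events", {
  cfg <- cohort_config(n_tumors = 2, n_cell_lines = 3, n_controls = 2,
                       marker_spacing_bp = 2.5e6, n_related_subclones = 2,
                       seed = 7)
  co <- simulate_cohort(cfg)
  expect_equal(length(co$snp_tables), 9)
  subs <- co$metadata$sample_id[!is.na(co$metadata$related_group) &
                                  co$metadata$sample_id != "CL01"]
  expect_equal(length(subs), 2)
  for (s in subs) {
    tr_sub <- co$truth[[s]]$events
    tr_par <- co$truth[["CL01"]]$events
    expect_gt(nrow(tr_sub), nrow(tr_par))   # private events added
  }
})
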