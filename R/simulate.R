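#' Configuration for a synthetic SNP-array cohort
#'
#' The defaults emulate the study conditions this package targets: 134
#' primary neuroblastoma tumours, 8 independent cell lines and 30 healthy
#' blood-donor controls, with mean near-CN-LOH event counts of 0.89, 2.4 and
#' 0.10 events per sample respectively, and extent-subtype mixtures of
#' (interstitial, telomeric, whole-chromosome) = (0.50, 0.15, 0.35) for
#' tumours, (0.05, 0.74, 0.21) for cell lines and (1, 0, 0) for controls
#' (controls carry only germline identical-by-descent runs, which present
#' as interstitial copy-neutral LOH).
#'
#' @param n_tumors,n_cell_lines,n_controls group sizes.
#' @param event_rate named numeric: mean near-CN-LOH events per sample for
#'   `tumor`, `cell_line`, `control` (Poisson means).
#' @param subtype_mix named list of length-3 probability vectors
#'   (interstitial, telomeric, whole_chromosome) per group; each must sum
#'   to 1 within 1e-9.
#' @param tumor_profile_mix probabilities over tumour background profiles
#'   `numerical_near_triploid`, `mycn_segmental`, `del11q_segmental`,
#'   `flat_diploid`.
#' @param tumor_rho_range range of stromal contamination for tumours
#'   (uniform draw); cell lines and controls have rho = 0.
#' @param noise_sd additive Gaussian SD on both the total ratio and the
#'   B-allele fraction.
#' @param marker_spacing_bp marker spacing for [make_marker_map()].
#' @param germline_het_prob probability that a marker is germline
#'   heterozygous (outside identical-by-descent runs).
#' @param n_related_subclones extra cell-line samples appended as subclones
#'   of the first cell line (sharing its `related_group`), used to exercise
#'   relatedness exclusions and profile comparison.
#' @param seed integer seed; a fixed seed makes [simulate_cohort()] output
#'   byte-identical.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumors = 134L, n_cell_lines = 8L, n_controls = 30L,
                          event_rate = c(tumor = 0.89, cell_line = 2.4,
                                         control = 0.10),
                          subtype_mix = list(
                            tumor = c(0.50, 0.15, 0.35),
                            cell_line = c(0.05, 0.74, 0.21),
                            control = c(1, 0, 0)),
                          tumor_profile_mix = c(numerical_near_triploid = 0.35,
                                                mycn_segmental = 0.20,
                                                del11q_segmental = 0.25,
                                                flat_diploid = 0.20),
                          tumor_rho_range = c(0.2, 0.55),
                          noise_sd = 0.05,
                          marker_spacing_bp = 12000,
                          germline_het_prob = 0.3,
                          n_related_subclones = 0L,
                          seed = 1L) {
  cfg <- list(n_tumors = as.integer(n_tumors),
              n_cell_lines = as.integer(n_cell_lines),
              n_controls = as.integer(n_controls),
              event_rate = event_rate, subtype_mix = subtype_mix,
              tumor_profile_mix = tumor_profile_mix,
              tumor_rho_range = tumor_rho_range, noise_sd = noise_sd,
              marker_spacing_bp = marker_spacing_bp,
              germline_het_prob = germline_het_prob,
              n_related_subclones = as.integer(n_related_subclones),
              seed = as.integer(seed))
  for (g in c("tumor", "cell_line", "control")) {
    mix <- cfg$subtype_mix[[g]]
    if (length(mix) != 3L || any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
      stop("subtype_mix$", g, " must be 3 non-negative probabilities summing to 1")
    if (is.na(cfg$event_rate[[g]]) || cfg$event_rate[[g]] < 0)
      stop("event_rate$", g, " must be >= 0")
  }
  if (abs(sum(tumor_profile_mix) - 1) > 1e-9 || any(tumor_profile_mix < 0))
    stop("'tumor_profile_mix' must sum to 1")
  if (cfg$noise_sd < 0) stop("'noise_sd' must be >= 0")
  class(cfg) <- "cohort_config"
  cfg
}

profile_types <- function() {
  c("flat_diploid", "numerical_near_triploid", "mycn_segmental",
    "del11q_segmental", "control")
}

extent_levels <- function() c("INTERSTITIAL", "TELOMERIC", "WHOLE_CHROMOSOME")

# Overlay an interval with a new state on a tiled per-chromosome segment set.
overlay_interval <- function(segs, chrom, start, end, major, minor, origin) {
  keep <- segs[segs$chrom != chrom, ]
  cs <- segs[segs$chrom == chrom, ]
  out <- list()
  for (i in seq_len(nrow(cs))) {
    s <- cs[i, ]
    if (s$end < start || s$start > end) { out[[length(out) + 1L]] <- s; next }
    if (s$start < start) {
      left <- s; left$end <- start - 1
      out[[length(out) + 1L]] <- left
    }
    if (s$end > end) {
      right <- s; right$start <- end + 1
      out[[length(out) + 1L]] <- right
    }
  }
  out[[length(out) + 1L]] <- data.frame(
    chrom = chrom, start = start, end = end, major = major, minor = minor,
    origin = origin, stringsAsFactors = FALSE)
  res <- rbind(keep, do.call(rbind, out))
  res <- res[order(match(res$chrom, unique(segs$chrom)), res$start), ]
  rownames(res) <- NULL
  res
}

#' Simulate the true allelic-state profile of one sample
#'
#' Draws a background karyotype according to `profile_type`, then injects
#' `Poisson(event_rate)` near-CN-LOH events whose extents follow
#' `subtype_mix` (interstitial: interior 2-10 Mb; telomeric: 5-30 Mb from a
#' chromosome end; whole-chromosome).  At most one event is placed per
#' chromosome, on autosomes free of other simulated features, so that one
#' biological event always corresponds to one maximal constant-state run.
#'
#' Background profiles:
#' \describe{
#'   \item{flat_diploid}{all chromosomes (1,1).}
#'   \item{numerical_near_triploid}{whole-chromosome totals drawn from
#'     2-5 with no intra-chromosome breakpoints; injected LOH events are
#'     therefore realised as whole-chromosome (2,0)/(3,0) states.}
#'   \item{mycn_segmental}{diploid background plus one high-level amplicon
#'     (total copies >= 20) at the designated 2p locus.}
#'   \item{del11q_segmental}{diploid background plus a telomeric 11q
#'     hemizygous deletion (1,0) and a telomeric 17q gain (2,1).}
#'   \item{control}{diploid; events are germline identical-by-descent runs
#'     (origin `germlineIBD`, state (2,0)); requires `rho = 0`.}
#' }
#'
#' @param profile_type one of [profile_types()].
#' @param event_rate mean number of injected near-CN-LOH events.
#' @param subtype_mix length-3 probabilities over
#'   (interstitial, telomeric, whole_chromosome).
#' @param marker_map a [make_marker_map()] map (defines chromosome set).
#' @param sample_id sample identifier.
#' @param rho stromal contamination fraction in `[0, 1)`.
#' @return list of class `truth_profile` with `sample_id`, `profile_type`,
#'   `rho`, `segments` (tiling data.frame: chrom, start, end, major, minor,
#'   origin) and `events` (injected near-CN-LOH events with extent labels).
#' @export
simulate_truth_profile <- function(profile_type, event_rate, subtype_mix,
                                   marker_map, sample_id = "S1", rho = 0) {
  profile_type <- match.arg(profile_type, profile_types())
  if (length(subtype_mix) != 3L || abs(sum(subtype_mix) - 1) > 1e-9 ||
      any(subtype_mix < 0))
    stop("'subtype_mix' must be 3 non-negative probabilities summing to 1")
  if (profile_type == "control" && rho != 0)
    stop("control profiles must have rho = 0")
  lens <- attr(marker_map, "chrom_lengths")
  if (is.null(lens)) stop("'marker_map' lacks its chromosome-length table")
  chroms <- lens$chrom
  len_of <- stats::setNames(lens$length_bp, chroms)

  base_state <- function(total) {
    switch(as.character(total),
           "2" = c(1, 1),
           "3" = c(2, 1),
           "4" = if (stats::runif(1) < 0.7) c(2, 2) else c(3, 1),
           "5" = c(3, 2))
  }

  segs <- data.frame(chrom = chroms, start = 1, end = lens$length_bp,
                     major = 1, minor = 1, origin = "somatic",
                     stringsAsFactors = FALSE)
  busy <- character(0)  # chromosomes unavailable for event placement

  if (profile_type == "numerical_near_triploid") {
    for (ch in chroms) {
      tot <- if (ch == "chrX") 2 else
        sample(2:5, 1, prob = c(0.25, 0.45, 0.20, 0.10))
      st <- base_state(tot)
      segs[segs$chrom == ch, c("major", "minor")] <- st
    }
  } else if (profile_type == "mycn_segmental") {
    loc <- mycn_region()
    segs <- overlay_interval(segs, loc$chrom, loc$start_bp, loc$end_bp,
                             major = 22, minor = 1, origin = "somatic")
    busy <- c(busy, loc$chrom)
  } else if (profile_type == "del11q_segmental") {
    segs <- overlay_interval(segs, "chr11", 70e6, len_of[["chr11"]],
                             major = 1, minor = 0, origin = "somatic")
    segs <- overlay_interval(segs, "chr17", 40e6, len_of[["chr17"]],
                             major = 2, minor = 1, origin = "somatic")
    busy <- c(busy, "chr11", "chr17")
  }

  n_events <- stats::rpois(1, event_rate)
  origin <- if (profile_type == "control") "germlineIBD" else "somatic"
  free <- setdiff(intersect(autosomes(), chroms), busy)
  n_events <- min(n_events, length(free))
  events <- list()
  if (n_events > 0) {
    ev_chroms <- sample(free, n_events, prob = len_of[free])
    for (ch in ev_chroms) {
      len <- len_of[[ch]]
      if (profile_type == "numerical_near_triploid") {
        extent <- "WHOLE_CHROMOSOME"
      } else {
        extent <- extent_levels()[
          sample.int(3L, 1L, prob = subtype_mix)]
      }
      if (extent == "WHOLE_CHROMOSOME") {
        start <- 1; end <- len
        tot <- if (profile_type == "numerical_near_triploid")
          sample(2:3, 1) else 2
      } else if (extent == "TELOMERIC") {
        size <- stats::runif(1, 5e6, min(30e6, len / 2))
        if (stats::runif(1) < 0.5) { start <- 1; end <- round(size) }
        else { start <- len - round(size) + 1; end <- len }
        tot <- 2
      } else {  # INTERSTITIAL
        size <- round(stats::runif(1, 2e6, 10e6))
        start <- round(stats::runif(1, 2e6, len - size - 2e6))
        end <- start + size - 1
        tot <- 2
      }
      segs <- overlay_interval(segs, ch, start, end, major = tot, minor = 0,
                               origin = origin)
      events[[length(events) + 1L]] <- data.frame(
        chrom = ch, start = start, end = end, major = tot, minor = 0,
        extent = extent, origin = origin, size_bp = end - start + 1,
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               major = numeric(0), minor = numeric(0), extent = character(0),
               origin = character(0), size_bp = numeric(0))
  structure(list(sample_id = sample_id, profile_type = profile_type,
                 rho = rho, segments = segs, events = events),
            class = "truth_profile")
}

# Marker-weighted median total copy number of a truth profile: the total
# copy state that normalises to t = 1 in the simulated signals.
truth_c_tilde <- function(truth, marker_map) {
  idx <- match_segments(marker_map, truth$segments)
  tot <- truth$segments$major[idx] + truth$segments$minor[idx]
  stats::median(tot)
}

# For each marker, the row index of the truth segment covering it.
match_segments <- function(marker_map, segments) {
  idx <- rep(NA_integer_, nrow(marker_map))
  for (ch in unique(marker_map$chrom)) {
    m <- marker_map$chrom == ch
    cs <- which(segments$chrom == ch)
    if (!length(cs)) stop("truth segments missing chromosome ", ch)
    o <- cs[order(segments$start[cs])]
    # tiling check
    if (segments$start[o[1]] != 1 ||
        any(segments$start[o[-1]] != segments$end[o[-length(o)]] + 1))
      stop("truth segments do not tile chromosome ", ch)
    j <- findInterval(marker_map$pos[m], segments$start[o])
    if (any(j < 1) || any(marker_map$pos[m] > segments$end[o[length(o)]]))
      stop("truth segments do not cover all markers on ", ch)
    idx[m] <- o[j]
  }
  idx
}

#' Simulate the observed per-SNP table of one sample
#'
#' Each marker receives a germline genotype (heterozygous with probability
#' `germline_het_prob`, except inside germline identical-by-descent runs,
#' which are forced homozygous).  Observed signals follow the tumour-normal
#' mixture model of [expected_signals()] with the sample's contamination
#' `rho` and a normalisation ploidy equal to the marker-weighted median
#' total copy number, plus additive Gaussian noise.  The tumour genotype
#' call is derived from the observed B-allele fraction by thresholding:
#' `AB` when it falls inside `het_call_range`, else `AA`/`BB`.  The default
#' window (0.1-0.9) reproduces the "false heterozygous" calls that
#' contaminating normal cells regenerate inside somatic LOH regions (a
#' (2,0) region at contamination rho has B-allele fraction rho/2 at
#' germline-het markers, which re-enters the window once rho reaches 0.2),
#' while germline-homozygous markers stay at 0/1 and are never called
#' heterozygous in the noise-free limit.
#'
#' @param truth a `truth_profile` from [simulate_truth_profile()].
#' @param marker_map a [make_marker_map()] map.
#' @param germline_het_prob germline heterozygosity rate, in (0, 1).
#' @param noise_sd additive Gaussian SD (>= 0) applied to both signals;
#'   fractions are truncated to `[0, 1]`, ratios to `>= 0`.
#' @param het_call_range length-2 window of observed fractions called `AB`.
#' @return A `snp_table`: data.frame `chrom, pos, total_ratio, baf, call`
#'   with attribute `sample_id`.
#' @export
simulate_snp_table <- function(truth, marker_map,
                               germline_het_prob = 0.3, noise_sd = 0.05,
                               het_call_range = c(0.1, 0.9)) {
  stopifnot(noise_sd >= 0, germline_het_prob > 0, germline_het_prob < 1)
  rho <- truth$rho
  idx <- match_segments(marker_map, truth$segments)
  seg <- truth$segments[idx, ]
  n <- nrow(marker_map)
  ibd <- seg$origin == "germlineIBD"
  het <- stats::runif(n) < germline_het_prob
  het[ibd] <- FALSE

  c_tilde <- truth_c_tilde(truth, marker_map)
  c_norm <- 2 * rho + (1 - rho) * c_tilde
  c_tot <- 2 * rho + (1 - rho) * (seg$major + seg$minor)

  # For germline hets, the B allele is the major or the minor haplotype
  # with equal probability; for homozygotes the B allele is absent/fixed.
  b_is_major <- stats::runif(n) < 0.5
  c_b <- ifelse(het,
                rho + (1 - rho) * ifelse(b_is_major, seg$major, seg$minor),
                ifelse(b_is_major, c_tot, 0))
  baf <- ifelse(c_tot > 0, c_b / c_tot, 0.5)
  t <- c_tot / c_norm
  if (noise_sd > 0) {
    t <- t + stats::rnorm(n, 0, noise_sd)
    baf <- baf + stats::rnorm(n, 0, noise_sd)
  }
  t <- pmax(t, 0)
  baf <- pmin(pmax(baf, 0), 1)
  call <- ifelse(baf >= het_call_range[1] & baf <= het_call_range[2], "AB",
                 ifelse(baf < het_call_range[1], "AA", "BB"))
  out <- data.frame(chrom = marker_map$chrom, pos = marker_map$pos,
                    total_ratio = t, baf = baf, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- truth$sample_id
  class(out) <- c("snp_table", "data.frame")
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates tumour, cell-line and control samples according to a
#' [cohort_config()], fully reproducibly from its seed.  Cell-line
#' subclones (if requested) share their parent's truth profile plus one or
#' two private events.
#'
#' @param config a [cohort_config()].
#' @return list of class `cohort` with elements `snp_tables` (named list),
#'   `metadata` (sample_id, group, related_group, outcome, stage),
#'   `truth` (named list of `truth_profile`s), `truth_events` (one row per
#'   injected event), `truth_params` (per-sample rho / profile type) and
#'   `marker_map`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  map <- make_marker_map(spacing_bp = config$marker_spacing_bp)

  ids <- c(sprintf("NB%03d", seq_len(config$n_tumors)),
           sprintf("CL%02d", seq_len(config$n_cell_lines)),
           sprintf("HC%02d", seq_len(config$n_controls)))
  groups <- rep(c("tumor", "cell_line", "control"),
                c(config$n_tumors, config$n_cell_lines, config$n_controls))

  truths <- vector("list", length(ids))
  names(truths) <- ids
  meta <- data.frame(sample_id = ids, group = groups,
                     related_group = NA_character_,
                     outcome = NA_character_, stage = NA_character_,
                     stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    g <- groups[i]
    if (g == "tumor") {
      type <- names(config$tumor_profile_mix)[
        sample.int(length(config$tumor_profile_mix), 1,
                   prob = config$tumor_profile_mix)]
      rho <- stats::runif(1, config$tumor_rho_range[1],
                          config$tumor_rho_range[2])
      meta$outcome[i] <- sample(c("DOD", "NED", "unknown"), 1,
                                prob = c(0.25, 0.60, 0.15))
      meta$stage[i] <- sample(c("L", "M", "MS", "unknown"), 1,
                              prob = c(66, 51, 4, 13) / 134)
    } else if (g == "cell_line") {
      type <- "del11q_segmental"; rho <- 0
    } else {
      type <- "control"; rho <- 0
    }
    truths[[i]] <- simulate_truth_profile(
      type, config$event_rate[[g]], config$subtype_mix[[g]], map,
      sample_id = ids[i], rho = rho)
  }

  if (config$n_related_subclones > 0) {
    parent_id <- sprintf("CL%02d", 1L)
    meta$related_group[meta$sample_id == parent_id] <- parent_id
    for (k in seq_len(config$n_related_subclones)) {
      sid <- sprintf("%s_SC%d", parent_id, k)
      sub <- truths[[parent_id]]
      sub$sample_id <- sid
      # one or two private events on chromosomes untouched in the parent
      aberrant <- unique(sub$segments$chrom[
        sub$segments$major != 1 | sub$segments$minor != 1])
      free <- setdiff(autosomes(), aberrant)
      for (ch in sample(free, sample(1:2, 1))) {
        len <- attr(map, "chrom_lengths")
        len <- len$length_bp[len$chrom == ch]
        size <- round(stats::runif(1, 5e6, min(30e6, len / 2)))
        sub$segments <- overlay_interval(sub$segments, ch, len - size + 1,
                                         len, major = 2, minor = 0,
                                         origin = "somatic")
        sub$events <- rbind(sub$events, data.frame(
          chrom = ch, start = len - size + 1, end = len, major = 2,
          minor = 0, extent = "TELOMERIC", origin = "somatic",
          size_bp = size))
      }
      truths[[sid]] <- sub
      meta <- rbind(meta, data.frame(sample_id = sid, group = "cell_line",
                                     related_group = parent_id,
                                     outcome = NA_character_,
                                     stage = NA_character_))
    }
  }

  snp <- lapply(truths, simulate_snp_table, marker_map = map,
                germline_het_prob = config$germline_het_prob,
                noise_sd = config$noise_sd)

  ev <- lapply(names(truths), function(id) {
    e <- truths[[id]]$events
    if (nrow(e)) cbind(sample_id = id, e) else NULL
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev))
    ev <- data.frame(sample_id = character(0), chrom = character(0),
                     start = numeric(0), end = numeric(0), major = numeric(0),
                     minor = numeric(0), extent = character(0),
                     origin = character(0), size_bp = numeric(0))
  params <- data.frame(
    sample_id = names(truths),
    profile_type = vapply(truths, `[[`, "", "profile_type"),
    rho = vapply(truths, `[[`, 0, "rho"),
    n_events = vapply(truths, function(x) nrow(x$events), 0L),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(snp_tables = snp, metadata = meta, truth = truths,
                 truth_events = ev, truth_params = params, marker_map = map),
            class = "cohort")
}

#' Write a simulated cohort to tab-delimited files
#'
#' Writes one `<sample_id>.snp.tsv` per sample plus `metadata.tsv`,
#' `truth_segments.tsv` and `truth_events.tsv` into `dir`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param overwrite error on existing files unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(paste0(names(cohort$snp_tables), ".snp.tsv"),
             "metadata.tsv", "truth_segments.tsv", "truth_events.tsv")
  existing <- files[file.exists(file.path(dir, files))]
  if (length(existing) && !overwrite)
    stop("output files already exist (", existing[1],
         ", ...); use overwrite = TRUE")
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(cohort$snp_tables)) {
    tab <- cohort$snp_tables[[id]]
    tsv(tab, paste0(id, ".snp.tsv"))
  }
  tsv(cohort$metadata, "metadata.tsv")
  segs <- do.call(rbind, lapply(names(cohort$truth), function(id)
    cbind(sample_id = id, cohort$truth[[id]]$segments)))
  tsv(segs, "truth_segments.tsv")
  tsv(cohort$truth_events, "truth_events.tsv")
  invisible(dir)
}

#' Read a per-SNP table written by [write_cohort()]
#'
#' @param path file with header `chrom pos total_ratio baf call`.
#' @param sample_id sample identifier; defaults to the file name stem.
#' @return a `snp_table`.
#' @export
read_snp_table <- function(path, sample_id = NULL) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "total_ratio", "baf", "call")
  if (!all(need %in% names(x)))
    stop("snp table must have columns: ", paste(need, collapse = ", "))
  if (is.null(sample_id))
    sample_id <- sub("\\.snp\\.tsv$", "", basename(path))
  attr(x, "sample_id") <- sample_id
  class(x) <- c("snp_table", "data.frame")
  x
}
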