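loh_categories <- function() {
  c("NEAR_CN_LOH", "GAIN_LOH", "LOSS_LOH", "ALLELIC_IMBALANCE", "BALANCED")
}

#' Classify an allelic state relative to the sample's ploidy
#'
#' "Near copy-neutral LOH" is LOH at least partially compensated by the
#' remaining allele, judged against the sample's overall ploidy `P =
#' round(sample_ploidy)`: with one allele lost (`minor = 0`), a total of
#' 2..P is near-CN-LOH (in a near-triploid sample both 2+0 and 3+0
#' qualify), a total above P is gain-LOH and a total below 2 is a classical
#' hemizygous (or homozygous) loss.  States retaining both alleles are
#' allelic imbalance when they differ from the most balanced split of the
#' same total (e.g. 3+1 vs 2+2), otherwise balanced.
#'
#' Vectorised over `major`/`minor`.
#'
#' @param major,minor integer allele copies.
#' @param sample_ploidy overall sample ploidy (> 0), e.g.
#'   `fit$overall_ploidy`.
#' @return character vector over [loh_categories()].
#' @export
#' @examples
#' classify_allelic_event(2, 0, 2.8)   # NEAR_CN_LOH
#' classify_allelic_event(3, 0, 2.0)   # GAIN_LOH
classify_allelic_event <- function(major, minor, sample_ploidy) {
  stopifnot(sample_ploidy > 0)
  p <- round(sample_ploidy)
  total <- major + minor
  bal <- balanced_state(total)
  ifelse(minor == 0 & total >= 2 & total <= p, "NEAR_CN_LOH",
  ifelse(minor == 0 & total > p, "GAIN_LOH",
  ifelse(total < 2, "LOSS_LOH",
  ifelse(minor >= 1 & major != minor &
           !(major == bal$major & minor == bal$minor),
         "ALLELIC_IMBALANCE", "BALANCED"))))
}

#' Classify the chromosomal extent of a call
#'
#' A call reaching both the first and last marker of its chromosome
#' (within `tol_markers` markers) is a whole-chromosome event; reaching
#' exactly one end makes it telomeric; neither, interstitial.
#' Whole-chromosome takes precedence over telomeric.
#'
#' @param idx_first,idx_last marker-index range of the call within its
#'   chromosome (1-based).
#' @param n_chrom_markers total markers on the chromosome.
#' @param tol_markers slack in markers when judging "reaches the end".
#' @return one of `"WHOLE_CHROMOSOME"`, `"TELOMERIC"`, `"INTERSTITIAL"`
#'   (vectorised).
#' @export
classify_extent <- function(idx_first, idx_last, n_chrom_markers,
                            tol_markers = 5L) {
  at_start <- idx_first <= 1L + tol_markers
  at_end <- idx_last >= n_chrom_markers - tol_markers
  ifelse(at_start & at_end, "WHOLE_CHROMOSOME",
         ifelse(at_start | at_end, "TELOMERIC", "INTERSTITIAL"))
}

#' Call and classify allelic events from a fitted sample
#'
#' Merges adjacent same-state segments, classifies every non-balanced,
#' non-amplified segment into the allelic-event taxonomy and assigns extent
#' subtypes.  All calls are returned regardless of size; downstream
#' summaries apply the reporting threshold.
#'
#' @param fit a `sample_fit`.
#' @param tol_markers see [classify_extent()].
#' @return A `loh_calls` data.frame: `sample_id, chrom, start, end,
#'   size_bp, major, minor, category, extent, n_markers, amplified`.
#' @export
call_loh <- function(fit, tol_markers = 5L) {
  seg <- merge_adjacent(fit$segments)
  ext <- attr(seg, "marker_extent")
  n_chr <- stats::setNames(ext$n_markers, ext$chrom)
  seg$category <- classify_allelic_event(seg$major, seg$minor,
                                         fit$overall_ploidy)
  seg$extent <- classify_extent(seg$idx_first, seg$idx_last,
                                n_chr[seg$chrom], tol_markers)
  calls <- seg[seg$category != "BALANCED" & !seg$amplified, , drop = FALSE]
  out <- data.frame(sample_id = rep(fit$sample_id %||% NA_character_,
                                    nrow(calls)),
                    chrom = calls$chrom, start = calls$start,
                    end = calls$end, size_bp = calls$end - calls$start + 1,
                    major = calls$major, minor = calls$minor,
                    category = calls$category, extent = calls$extent,
                    n_markers = calls$n_markers,
                    amplified = calls$amplified,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "merged_segments") <- seg
  class(out) <- c("loh_calls", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample event summary and stroma-filter flags
#'
#' Counts autosomal near-CN-LOH events of at least `min_event_size_bp`
#' (default 1.5 Mb, the reporting threshold used throughout) by extent
#' subtype, and derives the profile flags used by the cohort exclusion
#' rules: `flat_profile` (no aberrant segment at all), `mycn_amp_only`
#' (the only aberration is an amplification at the designated 2p locus)
#' and `cnloh_only` (every aberration is near-CN-LOH).  An aberrant
#' segment is one whose state differs from the sample's modal balanced
#' state (or is amplified) and that reaches the reporting size.
#'
#' @param calls a `loh_calls` from [call_loh()].
#' @param fit the matching `sample_fit`.
#' @param min_event_size_bp reporting threshold (default 1.5e6).
#' @return one-row data.frame: `sample_id, n_near_cnloh, n_interstitial,
#'   n_telomeric, n_whole_chromosome, n_aberrant, flat_profile,
#'   mycn_amp_only, cnloh_only`.
#' @export
sample_event_summary <- function(calls, fit, min_event_size_bp = 1.5e6) {
  seg <- attr(calls, "merged_segments")
  if (is.null(seg)) stop("'calls' must come from call_loh()")
  core <- seg[!seg$amplified, , drop = FALSE]
  modal_total <- weighted_mode(core$total, core$n_markers)
  base <- balanced_state(modal_total)
  size <- seg$end - seg$start + 1
  aberrant <- size >= min_event_size_bp &
    (seg$amplified | seg$major != base$major | seg$minor != base$minor)
  ab <- seg[aberrant, , drop = FALSE]

  keep <- calls$size_bp >= min_event_size_bp &
    calls$category == "NEAR_CN_LOH" & is_autosome(calls$chrom)
  ev <- calls[keep, , drop = FALSE]
  n_ext <- table(factor(ev$extent, levels = extent_levels()))

  loc <- mycn_region()
  is_mycn_amp <- ab$amplified & ab$chrom == loc$chrom &
    ab$start <= loc$end_bp & ab$end >= loc$start_bp
  ab_cat <- classify_allelic_event(ab$major, ab$minor, fit$overall_ploidy)
  ab_reported <- (ab$end - ab$start + 1) >= min_event_size_bp
  data.frame(
    sample_id = fit$sample_id %||% NA_character_,
    n_near_cnloh = nrow(ev),
    n_interstitial = as.integer(n_ext[["INTERSTITIAL"]]),
    n_telomeric = as.integer(n_ext[["TELOMERIC"]]),
    n_whole_chromosome = as.integer(n_ext[["WHOLE_CHROMOSOME"]]),
    n_aberrant = nrow(ab),
    flat_profile = nrow(ab) == 0L,
    mycn_amp_only = nrow(ab) > 0L && all(is_mycn_amp),
    cnloh_only = nrow(ab) > 0L &&
      all(ab_cat == "NEAR_CN_LOH" & !ab$amplified),
    stringsAsFactors = FALSE
  )
}

#' Compare aberration profiles between related samples
#'
#' Labels every reported aberration of every sample as shared by all
#' samples, shared by a subset, or unique, the way one compares a parental
#' cell line with its subclones.  Two aberrations match when they lie on
#' the same chromosome with reciprocal overlap of at least
#' `reciprocal_overlap` *and* identical `(major, minor)` states; events
#' that overlap but fail either condition are flagged as partial -
#' similar-looking lesions with different breakpoints or copy numbers
#' that likely arose as distinct events.
#'
#' @param fits list of two or more `sample_fit`s on the same marker map.
#' @param reciprocal_overlap minimum reciprocal overlap fraction
#'   (default 0.5).
#' @param min_event_size_bp aberration reporting threshold (default 1.5 Mb).
#' @param tol_markers extent tolerance passed to [call_loh()].
#' @return data.frame with one row per (sample, aberration):
#'   `sample_id, chrom, start, end, major, minor, category, n_sharing,
#'   sharing` (`shared_by_all` / `shared_by_subset` / `unique`) and
#'   `partial_with` (comma-separated samples with overlapping but
#'   non-matching events).
#' @export
compare_profiles <- function(fits, reciprocal_overlap = 0.5,
                             min_event_size_bp = 1.5e6, tol_markers = 5L) {
  if (length(fits) < 2L) stop("need at least two sample fits")
  sigs <- vapply(fits, function(f)
    map_signature(attr(f$segments, "marker_extent")), "")
  if (length(unique(sigs)) != 1L)
    stop("samples are not on the same marker map")
  abs_of <- function(fit) {
    seg <- attr(call_loh(fit, tol_markers), "merged_segments")
    core <- seg[!seg$amplified, , drop = FALSE]
    base <- balanced_state(weighted_mode(core$total, core$n_markers))
    keep <- (seg$end - seg$start + 1) >= min_event_size_bp &
      (seg$amplified | seg$major != base$major | seg$minor != base$minor)
    a <- seg[keep, , drop = FALSE]
    a$category <- classify_allelic_event(a$major, a$minor,
                                         fit$overall_ploidy)
    a
  }
  ab <- lapply(fits, abs_of)
  ids <- vapply(fits, function(f) f$sample_id %||% "?", "")
  n <- length(fits)
  rows <- list()
  for (i in seq_len(n)) {
    a <- ab[[i]]
    for (r in seq_len(nrow(a))) {
      x <- a[r, ]
      matched <- character(0); partial <- character(0)
      for (j in setdiff(seq_len(n), i)) {
        b <- ab[[j]]
        ov <- pmin(b$end, x$end) - pmax(b$start, x$start) + 1
        cand <- b$chrom == x$chrom & ov > 0
        if (!any(cand)) next
        frac_ok <- cand &
          ov / (x$end - x$start + 1) >= reciprocal_overlap &
          ov / (b$end - b$start + 1) >= reciprocal_overlap
        full <- frac_ok & b$major == x$major & b$minor == x$minor
        if (any(full)) matched <- c(matched, ids[j])
        else partial <- c(partial, ids[j])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[i], chrom = x$chrom, start = x$start, end = x$end,
        major = x$major, minor = x$minor, category = x$category,
        n_sharing = length(matched) + 1L,
        sharing = if (length(matched) == n - 1L) "shared_by_all"
                  else if (length(matched) > 0L) "shared_by_subset"
                  else "unique",
        partial_with = paste(partial, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), major = numeric(0),
               minor = numeric(0), category = character(0),
               n_sharing = integer(0), sharing = character(0),
               partial_with = character(0))
  rownames(out) <- NULL
  out
}

#' Export calls as TSV
#'
#' @param calls a `loh_calls` data.frame (or several rbind-ed together).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- as.data.frame(calls)
  out$size_mb <- round(out$size_bp / 1e6, 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
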