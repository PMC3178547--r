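#' Select the best-matched reference samples for normalisation
#'
#' Ranks candidate (control) samples by the standard deviation of
#' `log2(sample / candidate)` total ratios over autosomal markers and
#' returns the `k` candidates with the lowest SD (ties broken by candidate
#' id).  The ranking is invariant to a global multiplicative rescaling of
#' the sample, so mismatched overall intensity does not bias the choice.
#'
#' @param sample_table a `snp_table`.
#' @param candidates named list of `snp_table`s on the same marker map.
#' @param k number of references to keep (default 6).
#' @return list with `selected` (character ids, best first) and `sd_table`
#'   (data.frame `candidate`, `sd`, sorted).
#' @export
select_references <- function(sample_table, candidates, k = 6L) {
  if (k < 1L) stop("'k' must be >= 1")
  if (length(candidates) < k)
    stop("need at least k = ", k, " candidates, got ", length(candidates))
  if (is.null(names(candidates)))
    names(candidates) <- paste0("ref", seq_along(candidates))
  auto <- is_autosome(sample_table$chrom)
  s <- pmax(sample_table$total_ratio[auto], 1e-6)
  sds <- vapply(candidates, function(cand) {
    check_same_markers(sample_table, cand)
    r <- pmax(cand$total_ratio[auto], 1e-6)
    stats::sd(log2(s / r))
  }, numeric(1))
  ord <- order(sds, names(candidates))
  list(selected = names(candidates)[ord][seq_len(k)],
       sd_table = data.frame(candidate = names(candidates)[ord],
                             sd = sds[ord], row.names = NULL))
}

check_same_markers <- function(a, b) {
  if (nrow(a) != nrow(b) || !all(a$chrom == b$chrom) || !all(a$pos == b$pos))
    stop("samples are not on the same marker map")
  invisible(TRUE)
}

#' Normalised total-ratio track
#'
#' Divides the sample's total ratio by the marker-wise mean of the
#' reference pool, then rescales so the autosomal median equals 1.  Markers
#' where the reference pool has no signal are dropped with a warning.
#' With `references = NULL` only the median rescaling is applied.
#'
#' @param sample_table a `snp_table`.
#' @param references list of reference `snp_table`s (the selected subset),
#'   or `NULL`.
#' @return data.frame `chrom, pos, t` (possibly fewer rows than the input).
#' @export
normalized_total_ratio <- function(sample_table, references = NULL) {
  t <- sample_table$total_ratio
  keep <- rep(TRUE, length(t))
  if (!is.null(references) && length(references)) {
    for (r in references) check_same_markers(sample_table, r)
    pool <- rowMeans(do.call(cbind, lapply(references, `[[`, "total_ratio")))
    bad <- pool <= 0
    if (any(bad)) {
      warning(sum(bad), " marker(s) dropped: zero reference signal")
      keep <- !bad
    }
    t <- t[keep] / pool[keep]
  }
  auto <- is_autosome(sample_table$chrom[keep])
  med <- stats::median(t[auto])
  if (!is.finite(med) || med <= 0) stop("degenerate total-ratio track")
  data.frame(chrom = sample_table$chrom[keep], pos = sample_table$pos[keep],
             t = t / med, stringsAsFactors = FALSE)
}

#' Mirrored allele-fraction tracks
#'
#' Heterozygous-informative markers are those called `AB`; for each, the
#' strongest-allele fraction is `max(baf, 1 - baf)` and the weakest is its
#' complement, so the tracks are invariant under `baf -> 1 - baf`.
#' Homozygous and no-call markers are excluded from the mirrored tracks
#' (`het = FALSE`) but retained for the total-ratio track.
#'
#' @param sample_table a `snp_table`.
#' @return data.frame `chrom, pos, strong, weak, het`; `strong`/`weak` are
#'   `NA` at non-informative markers.  Attribute `n_het` gives the number
#'   of informative markers (0 flags a fully homozygous sample).
#' @export
allele_fraction_tracks <- function(sample_table) {
  het <- sample_table$call == "AB"
  strong <- ifelse(het, pmax(sample_table$baf, 1 - sample_table$baf), NA_real_)
  out <- data.frame(chrom = sample_table$chrom, pos = sample_table$pos,
                    strong = strong, weak = 1 - strong, het = het,
                    stringsAsFactors = FALSE)
  attr(out, "n_het") <- sum(het)
  out
}

#' Assemble the per-marker analysis tracks for one sample
#'
#' Combines [normalized_total_ratio()] and [allele_fraction_tracks()] into
#' the joint `(t, strong, het)` representation used by segmentation and
#' state fitting.
#'
#' @param sample_table a `snp_table`.
#' @param references optional list of reference `snp_table`s; when given
#'   together with `candidates = TRUE` semantics see [select_references()].
#' @param k number of references used when `references` is a candidate
#'   pool larger than `k` (the best `k` by matched SD are used).
#' @return An `allele_tracks` data.frame `chrom, pos, t, strong, weak, het`
#'   with attributes `sample_id` and `het_rate`.
#' @export
build_tracks <- function(sample_table, references = NULL, k = 6L) {
  refs <- references
  if (!is.null(refs) && length(refs) > k) {
    sel <- select_references(sample_table, refs, k = k)
    refs <- refs[sel$selected]
  }
  tt <- normalized_total_ratio(sample_table, refs)
  af <- allele_fraction_tracks(sample_table)
  if (nrow(tt) == nrow(af)) {       # no markers dropped: already aligned
    m <- cbind(tt, af[, c("strong", "weak", "het")])
  } else {
    m <- merge(tt, af, by = c("chrom", "pos"), sort = FALSE)
    m <- m[order(match(m$chrom, unique(sample_table$chrom)), m$pos), ]
  }
  rownames(m) <- NULL
  attr(m, "sample_id") <- attr(sample_table, "sample_id")
  attr(m, "het_rate") <- mean(m$het)
  class(m) <- c("allele_tracks", "data.frame")
  m
}
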