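# Change-point search on the joint per-marker signal.
#
# Three channels enter the least-squares cost: the normalised total ratio
# (all markers), the mirrored strongest-allele fraction (het-informative
# markers only) and the het-call indicator.  The third channel is what
# makes copy-neutral LOH visible in uncontaminated samples: a (2,0) run in
# a pure diploid sample leaves the total ratio flat and carries no AB
# calls, so the only segmentation signal is the collapse of het density.
# Channels are standardised by robust noise-variance estimates so a single
# penalty applies to their summed cost reduction.

channel_cost_funs <- function(x) {
  # NA-aware prefix sums; returns cost(i, j) = within-segment SS and
  # sums(i, j) = c(n, sum), both vectorised over i and j.
  ok <- !is.na(x)
  cx <- c(0, cumsum(ifelse(ok, x, 0)))
  cx2 <- c(0, cumsum(ifelse(ok, x^2, 0)))
  cn <- c(0, cumsum(ok))
  list(
    cost = function(i, j) {
      s <- cx[j + 1] - cx[i]
      s2 <- cx2[j + 1] - cx2[i]
      n <- cn[j + 1] - cn[i]
      pmax(s2 - s^2 / pmax(n, 1), 0)
    },
    sums = function(i, j) {
      c(n = cn[j + 1] - cn[i], s = cx[j + 1] - cx[i])
    })
}

diff_var <- function(x, floor_var = 1e-6) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(floor_var)
  max((stats::mad(diff(x)) / sqrt(2))^2, floor_var)
}

# Change-point search on one chromosome.  Candidate breakpoints come from
# two generators: greedy least-squares binary segmentation (strong, wide
# shifts) and a multi-scale block scan that carves interior windows out of
# the whole series with a two-breakpoint gain (greedy binary splits dilute
# the contrast of a short interior run over its long flanks, so events
# visible only through modest per-marker contrast - e.g. the collapse of
# het density in an uncontaminated CN-LOH run - would otherwise be
# missed).  The candidate union is then refined by local re-optimisation
# and backward-pruned against the penalty, so only breakpoints that pay
# for themselves in the final model survive.
binseg_chrom <- function(t, strong, het, penalty, min_markers = 25L) {
  n <- length(t)
  w <- c(t = 1 / diff_var(t),
         s = 1 / diff_var(strong),
         h = 1 / max(mean(het) * (1 - mean(het)), 0.04))
  ch_t <- channel_cost_funs(t)
  ch_s <- channel_cost_funs(strong)
  ch_h <- channel_cost_funs(as.numeric(het))
  cost_t <- ch_t$cost; cost_s <- ch_s$cost; cost_h <- ch_h$cost
  seg_cost <- function(i, j)
    w[["t"]] * cost_t(i, j) + w[["s"]] * cost_s(i, j) + w[["h"]] * cost_h(i, j)
  # between-range mean-shift gain of two disjoint ranges (the boundary
  # strength between two segments with anything in between excluded)
  gap_gain <- function(i1, j1, i2, j2) {
    g <- 0
    for (cc in list(c(w[["t"]], 1), c(w[["s"]], 2), c(w[["h"]], 3))) {
      f <- switch(cc[2], ch_t$sums, ch_s$sums, ch_h$sums)
      a <- f(i1, j1); b <- f(i2, j2)
      if (a[["n"]] > 0 && b[["n"]] > 0) {
        d <- a[["s"]] / a[["n"]] - b[["s"]] / b[["n"]]
        g <- g + cc[1] * a[["n"]] * b[["n"]] / (a[["n"]] + b[["n"]]) * d^2
      }
    }
    g
  }

  # greedy binary segmentation
  best_split <- function(i, j) {
    if (j - i + 1 < 4) return(NULL)
    ks <- (i + 1):(j - 2)               # >= 2 markers on each side
    gain <- seg_cost(i, j) - (seg_cost(i, ks) + seg_cost(ks + 1, j))
    k <- ks[which.max(gain)]
    if (max(gain) > penalty) k else NULL
  }
  bps <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    k <- best_split(ij[1], ij[2])
    if (!is.null(k)) {
      bps <- c(bps, k)
      stack <- c(stack, list(c(ij[1], k)), list(c(as.integer(k + 1), ij[2])))
    }
  }

  # Multi-scale interior-block scan (two breakpoints at once), run within
  # each greedy segment so the statistic is local: against the whole
  # series, any window carved out of a region flanking a large step shows
  # a spurious gain.
  bounds <- c(0L, sort(unique(bps)), n)
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b] + 1L; hi <- bounds[b + 1L]
    len <- hi - lo + 1L
    size <- max(4L, min_markers)
    while (3L * size <= len) {
      step <- max(1L, size %/% 4L)
      i <- seq(lo + 1L, hi - size, by = step)
      j <- i + size - 1L
      gain <- seg_cost(lo, hi) - seg_cost(lo, i - 1L) - seg_cost(i, j) -
        seg_cost(pmin(j + 1L, hi), hi)
      hit <- which(gain > 2 * penalty)
      bps <- c(bps, i[hit] - 1L, j[hit])
      size <- 2L * size
    }
  }
  breaks <- sort(unique(bps))
  breaks <- refine_breaks(breaks, n, seg_cost)
  breaks <- prune_breaks(breaks, n, seg_cost, penalty)
  list(breaks = breaks, seg_cost = seg_cost, gap_gain = gap_gain)
}

# Re-optimise each breakpoint between its neighbours (one sweep).
refine_breaks <- function(breaks, n, seg_cost) {
  if (!length(breaks)) return(breaks)
  bounds <- c(0L, breaks, n)
  for (m in seq_along(breaks)) {
    lo <- bounds[m] + 1L; hi <- bounds[m + 2L]
    if (hi - lo + 1 < 4) next
    ks <- (lo + 1L):(hi - 2L)
    gain <- seg_cost(lo, hi) - (seg_cost(lo, ks) + seg_cost(ks + 1L, hi))
    bounds[m + 1L] <- ks[which.max(gain)]
  }
  sort(unique(bounds[-c(1L, length(bounds))]))
}

# Backward elimination: repeatedly drop the breakpoint whose removal
# increases the model cost least, while that increase is below the
# penalty.
prune_breaks <- function(breaks, n, seg_cost, penalty) {
  repeat {
    if (!length(breaks)) return(breaks)
    bounds <- c(0L, breaks, n)
    inc <- vapply(seq_along(breaks), function(m) {
      lo <- bounds[m] + 1L; b <- bounds[m + 1L]; hi <- bounds[m + 2L]
      seg_cost(lo, hi) - seg_cost(lo, b) - seg_cost(b + 1L, hi)
    }, numeric(1))
    worst <- which.min(inc)
    if (inc[worst] >= penalty) return(breaks)
    breaks <- breaks[-worst]
  }
}

# Remove segments shorter than min_markers.  A short interior segment is
# dissolved: when its two neighbours do not differ between themselves
# (two-range mean-shift gain, short run excluded, below the penalty) all
# three merge into one - a brief excursion leaves no breakpoint at all;
# when the neighbours genuinely differ, the short run is absorbed into the
# side it separates less strongly from.
prune_short <- function(breaks, n, min_markers, seg_cost, gap_gain,
                        penalty) {
  repeat {
    bounds <- c(0L, breaks, n)
    sizes <- diff(bounds)
    if (length(sizes) == 1L) return(integer(0))
    short <- which(sizes < min_markers)
    if (!length(short)) return(breaks)
    s <- short[which.min(sizes[short])]
    lo <- bounds[s] + 1L; hi <- bounds[s + 1L]
    if (s == 1L) {                       # leading segment: absorb right
      breaks <- setdiff(breaks, hi)
    } else if (s == length(sizes)) {     # trailing segment: absorb left
      breaks <- setdiff(breaks, lo - 1L)
    } else {
      l0 <- bounds[s - 1L] + 1L; r1 <- bounds[s + 2L]
      if (gap_gain(l0, lo - 1L, hi + 1L, r1) > penalty) {
        gl <- gap_gain(l0, lo - 1L, lo, hi)
        gr <- gap_gain(lo, hi, hi + 1L, r1)
        breaks <- setdiff(breaks, if (gl >= gr) hi else lo - 1L)
      } else {
        breaks <- setdiff(breaks, c(lo - 1L, hi))
      }
    }
  }
}

#' Segment a sample into runs of constant signal
#'
#' Partitions each chromosome into intervals of constant joint signal by
#' least-squares binary segmentation with a penalty on each added
#' change-point, then dissolves segments shorter than `min_markers` (short
#' excursions vanish entirely; genuine boundaries flanked by a short run
#' are retained).  Chromosomes with fewer than `min_markers` markers come
#' back as a single flagged segment.
#'
#' @param tracks an `allele_tracks` object from [build_tracks()].
#' @param min_markers minimum markers per returned segment (default 25).
#' @param penalty cost-reduction threshold per change-point, in
#'   noise-standardised units; default `4 * log(n)` per chromosome
#'   (an information-criterion style term over the three channels).
#' @return A `segments` data.frame: `chrom, start, end, idx_first,
#'   idx_last, n_markers, n_het, mean_t, mean_strong, hom_only, low_markers`
#'   with `start`/`end` the first/last marker positions (1-based,
#'   inclusive).  `mean_strong` is 1.0 with `hom_only = TRUE` when a
#'   segment carries no informative het markers, so LOH in uncontaminated
#'   samples remains representable.  Attributes: `sample_id`,
#'   `marker_extent`, `het_rate`.
#' @export
segment_sample <- function(tracks, min_markers = 25L, penalty = NULL) {
  if (min_markers < 2L) stop("'min_markers' must be >= 2")
  ext <- marker_extent(tracks)
  out <- list()
  for (ch in unique(tracks$chrom)) {
    m <- tracks[tracks$chrom == ch, ]
    n <- nrow(m)
    if (n < min_markers) {
      out[[ch]] <- summarize_runs(m, ch, integer(0), low = TRUE)
      next
    }
    pen <- if (is.null(penalty)) 4 * log(n) else penalty
    bs <- binseg_chrom(m$t, m$strong, m$het, pen, min_markers)
    breaks <- prune_short(bs$breaks, n, min_markers, bs$seg_cost,
                          bs$gap_gain, pen)
    out[[ch]] <- summarize_runs(m, ch, breaks, low = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "sample_id") <- attr(tracks, "sample_id")
  attr(res, "marker_extent") <- ext
  attr(res, "het_rate") <- attr(tracks, "het_rate")
  # Marker-level noise SD of the mirrored fraction, used by the state fit
  # to correct for folding; 0 when noise-free.  The raw difference-based
  # estimate is attenuated where the track is folded around 0.5 (the SD of
  # a folded normal is sqrt(1 - 2/pi) of the unfolded one), so it is
  # rescaled by the estimated folded/unfolded mix.
  s <- tracks$strong[tracks$het]
  sd_raw <- if (length(s) > 3) stats::mad(diff(s)) / sqrt(2) else 0
  w_folded <- if (length(s)) mean(s < 0.6) else 0
  attr(res, "strong_sd") <-
    sd_raw / (sqrt(1 - 2 / pi) * w_folded + (1 - w_folded))
  class(res) <- c("segments", "data.frame")
  res
}

summarize_runs <- function(m, ch, breaks, low) {
  n <- nrow(m)
  bounds <- c(0L, breaks, n)
  do.call(rbind, lapply(seq_len(length(bounds) - 1L), function(i) {
    lo <- bounds[i] + 1L; hi <- bounds[i + 1L]
    s <- m[lo:hi, ]
    nh <- sum(s$het)
    # hom_only is rate-based: an essentially AB-free run is treated as
    # carrying no retained second allele even if a handful of markers leak
    # across an imprecise boundary or the genotyping noise floor
    data.frame(chrom = ch, start = s$pos[1], end = s$pos[nrow(s)],
               idx_first = lo, idx_last = hi, n_markers = hi - lo + 1L,
               n_het = nh,
               mean_t = mean(s$t),
               mean_strong = if (nh > 0) mean(s$strong[s$het]) else 1.0,
               hom_only = nh / (hi - lo + 1L) < 0.05, low_markers = low,
               stringsAsFactors = FALSE)
  }))
}

#' Merge adjacent segments with identical fitted states
#'
#' After state assignment, adjacent segments on the same chromosome that
#' carry the same `(major, minor)` state are merged so that one biological
#' event is counted once.  Summaries are recomputed as marker-weighted
#' means; the mirrored-fraction mean is weighted by het markers.
#'
#' @param segments a `segments` data.frame carrying `major` and `minor`
#'   columns (see [fit_sample()]).
#' @return the merged `segments` data.frame (same attributes).
#' @export
merge_adjacent <- function(segments) {
  if (!all(c("major", "minor") %in% names(segments)))
    stop("'segments' must carry fitted 'major'/'minor' states")
  key <- paste(segments$chrom, segments$major, segments$minor,
               if ("amplified" %in% names(segments)) segments$amplified else 0)
  new_run <- c(TRUE, key[-1] != key[-length(key)])
  run <- cumsum(new_run)
  merged <- do.call(rbind, lapply(split(segments, run), function(s) {
    w <- s$n_markers; wh <- s$n_het
    out <- s[1, , drop = FALSE]
    out$end <- s$end[nrow(s)]
    out$idx_last <- s$idx_last[nrow(s)]
    out$n_markers <- sum(w)
    out$n_het <- sum(wh)
    out$mean_t <- sum(s$mean_t * w) / sum(w)
    out$mean_strong <- if (sum(wh) > 0)
      sum(s$mean_strong[wh > 0] * wh[wh > 0]) / sum(wh) else 1.0
    out$hom_only <- sum(wh) / sum(w) < 0.05
    if ("residual" %in% names(s)) out$residual <- sum(s$residual)
    out
  }))
  rownames(merged) <- NULL
  for (a in c("sample_id", "marker_extent", "het_rate", "strong_sd"))
    attr(merged, a) <- attr(segments, a)
  class(merged) <- class(segments)
  merged
}

#' Export segments as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open.  Extra columns carry the fitted state when present.
#'
#' @param segments a `segments` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  name <- if (all(c("major", "minor") %in% names(segments)))
    paste0(segments$major, "+", segments$minor) else "."
  bed <- data.frame(chrom = segments$chrom,
                    start = format(segments$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(segments$end, scientific = FALSE,
                                 trim = TRUE),
                    name = name, score = segments$n_markers)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
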