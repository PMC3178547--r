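# Shared fixtures.  Tiny marker maps keep runtimes down; tests that need
# array-like density build their own.

tiny_lengths <- function(n_chrom = 3, length_bp = 60e6) {
  data.frame(chrom = paste0("chr", seq_len(n_chrom)),
             length_bp = rep(length_bp, n_chrom))
}

tiny_map <- function(n_chrom = 3, length_bp = 60e6, spacing = 250e3) {
  make_marker_map(tiny_lengths(n_chrom, length_bp), spacing_bp = spacing)
}

# Build an allele_tracks object directly from per-marker vectors, skipping
# the snp_table layer, for segmentation unit tests.
tracks_from_vectors <- function(t, strong = NULL, chrom = "chr1",
                                spacing = 1e4) {
  n <- length(t)
  het <- !is.null(strong) & if (is.null(strong)) rep(FALSE, n) else !is.na(strong)
  if (is.null(strong)) strong <- rep(NA_real_, n)
  out <- data.frame(chrom = chrom, pos = spacing / 2 + (0:(n - 1)) * spacing,
                    t = t, strong = strong, weak = 1 - strong, het = het,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- "test"
  attr(out, "het_rate") <- mean(het)
  class(out) <- c("allele_tracks", "data.frame")
  out
}

# Minimal segments row(s) for state-fit tests (marker summaries given
# directly).
segments_from_states <- function(states, rho, c_tilde, n_markers = 500,
                                 het_rate = 0.3, chrom = NULL) {
  ex <- expected_signals(states$major, states$minor, rho, c_tilde)
  k <- nrow(states)
  if (is.null(chrom)) chrom <- paste0("chr", seq_len(k))
  hom <- ex$mirrored > 0.999 | states$major + states$minor == 0
  seg <- data.frame(chrom = chrom, start = 1,
                    end = n_markers * 1e4,
                    idx_first = 1L, idx_last = as.integer(n_markers),
                    n_markers = as.integer(n_markers),
                    n_het = as.integer(ifelse(hom, 0, n_markers * het_rate)),
                    mean_t = ex$t,
                    mean_strong = ifelse(hom, 1.0, ex$mirrored),
                    hom_only = hom, low_markers = FALSE,
                    stringsAsFactors = FALSE)
  attr(seg, "sample_id") <- "synthetic"
  attr(seg, "marker_extent") <- data.frame(
    chrom = chrom, n_markers = as.integer(n_markers),
    first_pos = 1, last_pos = n_markers * 1e4)
  attr(seg, "het_rate") <- het_rate
  attr(seg, "strong_sd") <- 0
  class(seg) <- c("segments", "data.frame")
  seg
}
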