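#' Approximate autosome + X chromosome lengths
#'
#' Returns a constant table of approximate chromosome lengths (22 autosomes
#' plus X) from the genome-build era of the early Affymetrix mapping arrays.
#' Only the relative geometry of the chromosomes matters for the analyses in
#' this package; the values are rounded to 0.1 Mb.
#'
#' @return A data.frame with columns `chrom` (character, "chr1".."chr22",
#'   "chrX") and `length_bp` (integer basepairs).
#' @export
#' @examples
#' head(chrom_lengths())
chrom_lengths <- function() {
  data.frame(
    chrom = paste0("chr", c(1:22, "X")),
    length_bp = c(
      247200000, 242800000, 199500000, 191300000, 180900000, 170900000,
      158800000, 146300000, 140300000, 135400000, 134500000, 132300000,
      114100000, 106400000, 100300000,  88800000,  78800000,  76100000,
       63800000,  62400000,  46900000,  49700000, 154900000
    ),
    stringsAsFactors = FALSE
  )
}

autosomes <- function() paste0("chr", 1:22)

is_autosome <- function(chrom) chrom %in% autosomes()

#' Build an evenly spaced SNP marker map
#'
#' Places markers at regular intervals along each chromosome, emulating the
#' density of a genotyping array.  Markers sit at `spacing/2`, `3*spacing/2`,
#' ... so that each chromosome carries `floor(length_bp / spacing)` markers.
#' The default spacing of 12 kb gives roughly 260k genome-wide markers,
#' comparable to a 250K mapping array; 24 kb approximates a 50K + 250K mix.
#'
#' @param chrom_lengths data.frame with columns `chrom`, `length_bp`
#'   (default [chrom_lengths()]).
#' @param spacing_bp marker spacing in basepairs (> 0).
#' @return A `marker_map`: data.frame with columns `chrom`, `pos` (1-based,
#'   strictly increasing within chromosome), carrying the length table as
#'   attribute `chrom_lengths`.
#' @export
#' @examples
#' map <- make_marker_map(spacing_bp = 1e6)
#' table(map$chrom)[["chr21"]]
make_marker_map <- function(chrom_lengths = nearloh::chrom_lengths(),
                            spacing_bp = 12000) {
  if (!is.numeric(spacing_bp) || length(spacing_bp) != 1L || spacing_bp <= 0)
    stop("'spacing_bp' must be a single positive number")
  if (nrow(chrom_lengths) == 0L)
    stop("'chrom_lengths' must be non-empty")
  pieces <- lapply(seq_len(nrow(chrom_lengths)), function(i) {
    len <- chrom_lengths$length_bp[i]
    n <- floor(len / spacing_bp)
    if (n == 0L) {
      warning("spacing larger than chromosome ", chrom_lengths$chrom[i],
              ": 0 markers placed")
      return(NULL)
    }
    data.frame(chrom = chrom_lengths$chrom[i],
               pos = as.numeric(spacing_bp / 2 + (seq_len(n) - 1) * spacing_bp),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, pieces)
  rownames(map) <- NULL
  attr(map, "chrom_lengths") <- chrom_lengths
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Per-chromosome marker extent
#'
#' @param map a `marker_map`.
#' @return data.frame with `chrom`, `n_markers`, `first_pos`, `last_pos`.
#' @export
marker_extent <- function(map) {
  sp <- split(map$pos, factor(map$chrom, levels = unique(map$chrom)))
  data.frame(
    chrom = names(sp),
    n_markers = vapply(sp, length, integer(1)),
    first_pos = vapply(sp, min, numeric(1)),
    last_pos = vapply(sp, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Signature used to check that two samples were profiled on the same map.
map_signature <- function(extent) {
  paste(extent$chrom, extent$n_markers, extent$first_pos, extent$last_pos,
        collapse = ";")
}

#' Designated MYCN amplicon locus
#'
#' The 2p locus used by the synthetic generator for high-level amplification
#' and by the event summary to recognise "MYCN amplification only" profiles.
#'
#' @return list with `chrom`, `start_bp`, `end_bp`.
#' @export
mycn_region <- function() list(chrom = "chr2", start_bp = 14.5e6, end_bp = 16.5e6)
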