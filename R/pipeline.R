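#' Analyse one sample end to end
#'
#' Convenience wrapper chaining [build_tracks()], [segment_sample()],
#' [fit_sample()], [call_loh()] and [sample_event_summary()].
#'
#' @param snp_table a `snp_table`.
#' @param references optional list of reference `snp_table`s (a candidate
#'   pool; the best `k` by matched SD are used).
#' @param k references kept from the pool.
#' @param min_markers,penalty segmentation controls ([segment_sample()]).
#' @param grid,max_copies,lambda fit controls ([fit_sample()]).
#' @param min_event_size_bp reporting threshold.
#' @param tol_markers extent tolerance.
#' @param anchors optional per-chromosome copy-number anchors.
#' @return list `tracks, segments, fit, calls, summary`.
#' @export
analyze_sample <- function(snp_table, references = NULL, k = 6L,
                           min_markers = 25L, penalty = NULL,
                           grid = fit_grid(), max_copies = 12L,
                           lambda = 0.01, min_event_size_bp = 1.5e6,
                           tol_markers = 5L, anchors = NULL) {
  tracks <- build_tracks(snp_table, references, k = k)
  segments <- segment_sample(tracks, min_markers = min_markers,
                             penalty = penalty)
  fit <- fit_sample(segments, grid = grid, max_copies = max_copies,
                    lambda = lambda, anchors = anchors)
  calls <- call_loh(fit, tol_markers = tol_markers)
  summary <- sample_event_summary(calls, fit, min_event_size_bp)
  list(tracks = tracks, segments = segments, fit = fit, calls = calls,
       summary = summary)
}

#' Analyse a whole cohort end to end
#'
#' Runs [analyze_sample()] on every sample of a (simulated or read-in)
#' cohort, using the control samples as the reference pool for
#' normalisation when `use_references = TRUE`, then computes the group
#' statistics with [cohort_stats()].
#'
#' @param cohort a `cohort` (as from [simulate_cohort()]), or a list with
#'   `snp_tables` and `metadata`.
#' @param use_references normalise each non-control sample against its
#'   best-matched controls (default FALSE: the per-sample median rescaling
#'   alone, appropriate when ratios are already reference-normalised).
#' @param progress print one line per sample.
#' @param ... passed to [analyze_sample()].
#' @return list of class `cohort_analysis`: `per_sample` (named list of
#'   [analyze_sample()] results), `summaries`, `calls`, `stats`.
#' @export
analyze_cohort <- function(cohort, use_references = FALSE,
                           progress = FALSE, ...) {
  meta <- cohort$metadata
  controls <- meta$sample_id[meta$group == "control"]
  per_sample <- list()
  for (id in names(cohort$snp_tables)) {
    refs <- NULL
    if (use_references && !(id %in% controls) && length(controls) >= 1)
      refs <- cohort$snp_tables[controls]
    if (progress) message("analysing ", id)
    per_sample[[id]] <- analyze_sample(cohort$snp_tables[[id]],
                                       references = refs, ...)
  }
  summaries <- do.call(rbind, lapply(per_sample, `[[`, "summary"))
  rownames(summaries) <- NULL
  calls <- do.call(rbind, lapply(per_sample, function(x)
    as.data.frame(x$calls)))
  rownames(calls) <- NULL
  stats <- cohort_stats(summaries, calls, meta)
  structure(list(per_sample = per_sample, summaries = summaries,
                 calls = calls, stats = stats),
            class = "cohort_analysis")
}

#' Write a cohort result as JSON and TSV tables
#'
#' @param result a `cohort_result` from [cohort_stats()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  js <- list(n = as.list(result$n),
             prevalence = result$prevalence,
             burden = result$burden,
             fisher = result$fisher,
             mann_whitney = result$mann_whitney,
             spectrum = lapply(result$spectrum, function(s)
               if (length(s)) as.list(s) else list()),
             outcome = result$outcome,
             exclusions = result$exclusions)
  jsonlite::write_json(js, file.path(dir, "cohort_result.json"),
                       auto_unbox = TRUE, digits = NA)
  tsv <- function(x, f) if (!is.null(x) && nrow(x)) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(result$prevalence, "prevalence.tsv")
  tsv(result$burden, "burden.tsv")
  tsv(result$fisher, "fisher.tsv")
  tsv(result$mann_whitney, "mann_whitney.tsv")
  tsv(result$exclusions, "exclusions.tsv")
  invisible(dir)
}
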