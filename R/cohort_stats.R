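#' Apply the cohort inclusion/exclusion rules
#'
#' Removes, with a logged reason for every removal: (i) within each
#' related-sample group, every sample except the designated parent (the
#' sample whose id equals the `related_group` label - the convention the
#' generator and metadata format use); (ii) tumour and cell-line samples
#' whose profiles indicate heavy stromal contamination - flat profiles,
#' MYCN-amplification-only profiles and CN-LOH-only profiles.  Healthy
#' controls are flat by construction and are exempt from the profile
#' flags.  X-chromosome calls never enter the event counts (the summaries
#' are autosome-only), so no per-call filtering is needed here.
#'
#' @param summaries data.frame of per-sample rows from
#'   [sample_event_summary()].
#' @param metadata data.frame with `sample_id, group, related_group`
#'   (and optionally `outcome`, `stage`).
#' @return list with `included` (metadata rows kept, joined with the
#'   summaries) and `exclusions` (data.frame `sample_id, reason`).
#' @export
apply_exclusions <- function(summaries, metadata) {
  stopifnot(all(c("sample_id", "group") %in% names(metadata)))
  m <- merge(metadata, summaries, by = "sample_id", all.x = TRUE,
             sort = FALSE)
  excl <- list()
  drop <- function(ids, reason) {
    for (id in ids)
      excl[[length(excl) + 1L]] <<- data.frame(sample_id = id,
                                               reason = reason,
                                               stringsAsFactors = FALSE)
  }
  if ("related_group" %in% names(m)) {
    for (rg in unique(stats::na.omit(m$related_group))) {
      members <- m$sample_id[!is.na(m$related_group) & m$related_group == rg]
      if (!rg %in% members)
        stop("related group '", rg, "' has no designated parent sample")
      drop(setdiff(members, rg), "related_subclone")
    }
  }
  flaggable <- m$group %in% c("tumor", "cell_line")
  for (flag in c("flat_profile", "mycn_amp_only", "cnloh_only")) {
    if (!flag %in% names(m)) next
    hit <- flaggable & !is.na(m[[flag]]) & m[[flag]]
    already <- m$sample_id %in% vapply(excl, `[[`, "", "sample_id")
    drop(m$sample_id[hit & !already], flag)
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(sample_id = character(0), reason = character(0))
  list(included = m[!m$sample_id %in% exclusions$sample_id, , drop = FALSE],
       exclusions = exclusions)
}

#' Two-sided Fisher exact test on event prevalence
#'
#' Compares the proportion of samples with at least one near-CN-LOH event
#' between two groups.  The two-sided p-value sums the probabilities of
#' all 2x2 tables with the same margins whose hypergeometric probability
#' does not exceed that of the observed table (the convention of
#' [stats::fisher.test()], which performs the computation).
#'
#' @param k_a,n_a affected count and group size of group A.
#' @param k_b,n_b same for group B.
#' @return the two-sided p-value.
#' @export
#' @examples
#' fisher_prevalence(47, 134, 7, 8)   # ~0.005
fisher_prevalence <- function(k_a, n_a, k_b, n_b) {
  if (n_a <= 0 || n_b <= 0) stop("group sizes must be positive")
  if (k_a < 0 || k_a > n_a || k_b < 0 || k_b > n_b)
    stop("counts must satisfy 0 <= k <= n")
  stats::fisher.test(matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), 2))$p.value
}

#' Mann-Whitney U test on event burden
#'
#' Two-sided rank-sum comparison of per-sample event counts.  Ties are
#' handled by midranks in both branches.  When `nA * nB <= exact_limit`
#' the exact permutation distribution of the rank sum is computed by
#' dynamic programming over the (doubled, hence integer) midranks, so the
#' exact p-value is correct in the presence of ties; otherwise the
#' tie-corrected normal approximation is used.
#'
#' @param counts_a,counts_b numeric vectors of per-sample event counts.
#' @param exact_limit product-of-sizes threshold for the exact branch
#'   (default 400).
#' @return list `U`, `p`, `method` ("exact" or "normal").
#' @export
mw_burden <- function(counts_a, counts_b, exact_limit = 400) {
  n1 <- length(counts_a); n2 <- length(counts_b)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(counts_a, counts_b))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 * n2 <= exact_limit) {
    p <- mw_exact_p(r, n1)
    list(U = u, p = p, method = "exact")
  } else {
    ties <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = u, p = 1, method = "normal"))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)   # continuity-corrected
    list(U = u, p = min(1, 2 * stats::pnorm(-max(z, 0))), method = "normal")
  }
}

# Exact two-sided rank-sum p-value under the permutation null, by dynamic
# programming over subset rank sums (doubled midranks are integers).
mw_exact_p <- function(r, n1) {
  n <- length(r)
  ri <- as.integer(round(2 * r))
  w_obs <- sum(ri[seq_len(n1)])
  smax <- sum(sort(ri, decreasing = TRUE)[seq_len(n1)])
  ways <- matrix(0, n1 + 1L, smax + 1L)
  ways[1L, 1L] <- 1
  for (x in ri) {
    kmax <- n1
    for (k in kmax:1) {
      idx <- seq_len(smax + 1L - x)
      ways[k + 1L, idx + x] <- ways[k + 1L, idx + x] + ways[k, idx]
    }
  }
  dist <- ways[n1 + 1L, ]
  mu <- n1 * sum(ri) / n
  dev <- abs(w_obs - mu)
  s <- 0:smax
  sum(dist[abs(s - mu) >= dev - 1e-9]) / sum(dist)
}

#' Burden descriptives
#'
#' Median, mean and 25th/75th percentiles of per-sample event counts,
#' with quantiles by linear interpolation between order statistics
#' (quantile type 7).
#'
#' @param counts non-empty numeric vector.
#' @return named numeric `median, mean, p25, p75`.
#' @export
#' @examples
#' describe_burden(c(0, 1, 2, 3))   # median 1.5, p25 0.75, p75 2.25
describe_burden <- function(counts) {
  if (length(counts) == 0) stop("'counts' must be non-empty")
  q <- stats::quantile(counts, c(0.25, 0.75), type = 7, names = FALSE)
  c(median = stats::median(counts), mean = mean(counts),
    p25 = q[1], p75 = q[2])
}

#' Extent-subtype spectrum of near-CN-LOH events
#'
#' Fractions of events per extent subtype (interstitial, telomeric,
#' whole-chromosome) among the supplied near-CN-LOH calls.
#'
#' @param calls a `loh_calls`-style data.frame (rows are used as-is if a
#'   `category` column is absent; otherwise only `NEAR_CN_LOH` autosomal
#'   rows count).
#' @param min_event_size_bp reporting threshold.
#' @return named numeric of fractions summing to 1, or an empty numeric
#'   (with attribute `note`) when the group has no events.
#' @export
subtype_spectrum <- function(calls, min_event_size_bp = 1.5e6) {
  x <- calls
  if ("category" %in% names(x))
    x <- x[x$category == "NEAR_CN_LOH" & is_autosome(x$chrom) &
             x$size_bp >= min_event_size_bp, , drop = FALSE]
  if (nrow(x) == 0) {
    out <- numeric(0)
    attr(out, "note") <- "no events; spectrum undefined"
    return(out)
  }
  tab <- table(factor(x$extent, levels = extent_levels()))
  prop <- as.numeric(tab) / sum(tab)
  stats::setNames(prop, extent_levels())
}

#' Event burden versus clinical outcome
#'
#' Compares near-CN-LOH burden between patients dead of disease (`DOD`)
#' and those with no evidence of disease (`NED`), overall and per extent
#' subtype.  Samples with any other outcome label are excluded (the binary
#' definition requires five-year follow-up).
#'
#' @param summaries per-sample summary rows joined with metadata (must
#'   carry `outcome`, `n_near_cnloh` and the per-extent counts).
#' @return data.frame `comparison, n_dod, n_ned, p` with one row for the
#'   overall burden and one per extent subtype; `p` is `NA` (with the
#'   reason in `note`) when either outcome group is empty.
#' @export
outcome_burden <- function(summaries) {
  ok <- !is.na(summaries$outcome) & summaries$outcome %in% c("DOD", "NED")
  s <- summaries[ok, , drop = FALSE]
  if (nrow(s) == 0) stop("no samples with a DOD/NED outcome")
  cols <- c(overall = "n_near_cnloh", interstitial = "n_interstitial",
            telomeric = "n_telomeric", whole_chromosome = "n_whole_chromosome")
  dod <- s$outcome == "DOD"
  rows <- lapply(names(cols), function(nm) {
    a <- s[[cols[[nm]]]][dod]; b <- s[[cols[[nm]]]][!dod]
    if (length(a) == 0 || length(b) == 0)
      data.frame(comparison = nm, n_dod = length(a), n_ned = length(b),
                 p = NA_real_, note = "a group is empty",
                 stringsAsFactors = FALSE)
    else
      data.frame(comparison = nm, n_dod = length(a), n_ned = length(b),
                 p = mw_burden(a, b)$p, note = "",
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-level cohort statistics
#'
#' Applies the exclusion rules, then computes per-group prevalence (count
#' and fraction of samples with at least one near-CN-LOH event), burden
#' descriptives, pairwise Fisher exact and Mann-Whitney tests, per-group
#' extent spectra, and the outcome comparison within tumours.
#'
#' @param summaries per-sample rows from [sample_event_summary()].
#' @param calls combined `loh_calls` rows for all samples.
#' @param metadata cohort metadata (`sample_id, group, related_group,
#'   outcome, stage`).
#' @param min_event_size_bp reporting threshold for spectra.
#' @return list of class `cohort_result`: `n`, `prevalence`, `burden`,
#'   `fisher`, `mann_whitney`, `spectrum`, `outcome`, `exclusions`,
#'   `included`.
#' @export
cohort_stats <- function(summaries, calls, metadata,
                         min_event_size_bp = 1.5e6) {
  ex <- apply_exclusions(summaries, metadata)
  inc <- ex$included
  groups <- intersect(c("tumor", "cell_line", "control"), unique(inc$group))
  by_group <- split(inc, factor(inc$group, levels = groups))

  prevalence <- do.call(rbind, lapply(groups, function(g) {
    s <- by_group[[g]]
    data.frame(group = g, n = nrow(s),
               affected = sum(s$n_near_cnloh >= 1),
               fraction = mean(s$n_near_cnloh >= 1),
               stringsAsFactors = FALSE)
  }))
  burden <- do.call(rbind, lapply(groups, function(g) {
    d <- describe_burden(by_group[[g]]$n_near_cnloh)
    data.frame(group = g, t(d), stringsAsFactors = FALSE)
  }))

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  fisher <- do.call(rbind, lapply(pairs, function(pr) {
    a <- by_group[[pr[1]]]; b <- by_group[[pr[2]]]
    data.frame(group_a = pr[1], group_b = pr[2],
               p = fisher_prevalence(sum(a$n_near_cnloh >= 1), nrow(a),
                                     sum(b$n_near_cnloh >= 1), nrow(b)),
               stringsAsFactors = FALSE)
  }))
  mann_whitney <- do.call(rbind, lapply(pairs, function(pr) {
    mw <- mw_burden(by_group[[pr[1]]]$n_near_cnloh,
                    by_group[[pr[2]]]$n_near_cnloh)
    data.frame(group_a = pr[1], group_b = pr[2], U = mw$U, p = mw$p,
               method = mw$method, stringsAsFactors = FALSE)
  }))

  spectrum <- lapply(stats::setNames(groups, groups), function(g) {
    ids <- by_group[[g]]$sample_id
    subtype_spectrum(calls[calls$sample_id %in% ids, , drop = FALSE],
                     min_event_size_bp)
  })
  tum <- inc[inc$group == "tumor", , drop = FALSE]
  outcome <- if (nrow(tum) && any(tum$outcome %in% c("DOD", "NED"),
                                  na.rm = TRUE))
    outcome_burden(tum) else NULL

  structure(list(n = stats::setNames(vapply(by_group, nrow, 0L), groups),
                 prevalence = prevalence, burden = burden, fisher = fisher,
                 mann_whitney = mann_whitney, spectrum = spectrum,
                 outcome = outcome, exclusions = ex$exclusions,
                 included = inc),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Cohort result\n")
  for (i in seq_len(nrow(x$prevalence))) {
    pv <- x$prevalence[i, ]
    cat(sprintf("  %-10s n = %3d, prevalence %d/%d (%.0f%%)\n", pv$group,
                pv$n, pv$affected, pv$n, 100 * pv$fraction))
  }
  for (i in seq_len(nrow(x$fisher)))
    cat(sprintf("  Fisher %s vs %s: p = %.4g\n", x$fisher$group_a[i],
                x$fisher$group_b[i], x$fisher$p[i]))
  for (i in seq_len(nrow(x$mann_whitney)))
    cat(sprintf("  Mann-Whitney %s vs %s: p = %.4g (%s)\n",
                x$mann_whitney$group_a[i], x$mann_whitney$group_b[i],
                x$mann_whitney$p[i], x$mann_whitney$method[i]))
  if (nrow(x$exclusions))
    cat("  excluded:", nrow(x$exclusions), "sample(s)\n")
  invisible(x)
}
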