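#' Grid for the contamination / normalisation-ploidy search
#'
#' @param rho contamination grid (default 0 to 0.9 by 0.02).
#' @param c_tilde normalisation-ploidy grid (default 1.5 to 5 by 0.05).
#' @return list with `rho` and `c_tilde` vectors.
#' @export
fit_grid <- function(rho = seq(0, 0.9, by = 0.02),
                     c_tilde = seq(1.5, 5, by = 0.05)) {
  stopifnot(all(rho >= 0), all(rho < 1), all(c_tilde > 0))
  list(rho = sort(rho), c_tilde = sort(c_tilde))
}

#' Fit the best integer allelic state to one segment
#'
#' Minimises the marker-weighted squared error between the observed
#' `(mean_t, mean_strong)` summary and [expected_signals()] over all states
#' `(a, b)` with `b <= a <= max_copies`.  The total-ratio term is weighted
#' by the segment's marker count and the mirrored-fraction term by its
#' het-informative marker count, so segments without allele information are
#' fitted on the total ratio alone.  Fully homozygous segments are
#' additionally restricted to `minor = 0` states: a segment large enough to
#' be called that carries not a single AB genotype cannot hold a retained
#' second allele.  Ties break toward the smaller total, then the larger
#' minor allele count.
#'
#' @param mean_t,mean_strong observed segment summaries.
#' @param n_markers,n_het marker / het-marker counts (weights).
#' @param rho,c_tilde mixture parameters.
#' @param max_copies cap on the major allele count (default 12).
#' @param hom_only logical: no informative het markers in the segment.
#' @param strong_sd marker-level noise SD of the mirrored fraction, used
#'   to correct the expected fraction for folding around 0.5 (0 = no
#'   correction).
#' @return list `major, minor, total, residual, amplified`; `amplified` is
#'   set when the observed ratio implies a total beyond `max_copies`
#'   (high-level amplicon), in which case the state is capped.
#' @export
fit_segment_state <- function(mean_t, mean_strong, n_markers, n_het,
                              rho, c_tilde, max_copies = 12L,
                              hom_only = n_het == 0, strong_sd = 0) {
  if (max_copies < 1L) stop("'max_copies' must be >= 1")
  st <- enumerate_states(max_copies)
  if (hom_only) st <- st[st$minor == 0, ]
  ex <- expected_signals(st$major, st$minor, rho, c_tilde)
  res <- n_markers * (mean_t - ex$t)^2
  if (!hom_only && n_het > 0)
    res <- res + n_het *
      (mean_strong - mirrored_expectation(ex$mirrored, strong_sd))^2
  i <- which.min(res)
  c_norm <- 2 * rho + (1 - rho) * c_tilde
  implied_total <- (mean_t * c_norm - 2 * rho) / (1 - rho)
  list(major = st$major[i], minor = st$minor[i], total = st$total[i],
       residual = res[i], amplified = implied_total > max_copies + 0.5)
}

# Vectorised grid engine.  For every (rho, c_tilde) combination, assigns
# each segment its least-squares state and accumulates the marker-weighted
# objective plus a complexity penalty per distinct state used.  Returns
# matrices of the objective, the mean fitted ploidy and the number of
# distinct states per grid point, plus an anchor-feasibility mask.
# The (0,0) state is disallowed for segments covering more than half a
# chromosome: focal homozygous deletions are real, whole-chromosome
# nullisomy is not, and admitting it opens an exact down-shifted
# contamination alias of every fully balanced profile.
grid_objective <- function(segments, grid, states, lambda, anchors = NULL,
                           strong_sd = 0) {
  fit_idx <- !segments$amp_candidate
  seg <- segments[fit_idx, , drop = FALSE]
  nseg <- nrow(seg)
  if (nseg == 0L) stop("no segments usable for the grid fit")
  ns <- nrow(states)
  nct <- length(grid$c_tilde)
  O <- matrix(NA_real_, length(grid$rho), nct)
  P <- matrix(NA_real_, length(grid$rho), nct)
  K <- matrix(NA_integer_, length(grid$rho), nct)
  feasible <- matrix(TRUE, length(grid$rho), nct)
  hom_mask <- matrix(0, nseg, ns)
  hom_mask[seg$hom_only, states$minor > 0] <- Inf
  big <- (seg$end - seg$start + 1) > 10e6 |
    (!is.null(seg$chrom_frac) & seg$chrom_frac > 0.5)
  hom_mask[big, states$total == 0] <- Inf
  frac_w <- ifelse(seg$hom_only, 0, seg$n_het)
  CT <- matrix(NA_real_, length(grid$rho), nct)
  for (ri in seq_along(grid$rho)) {
    rho <- grid$rho[ri]
    c_tot <- 2 * rho + (1 - rho) * states$total
    c_str <- rho + (1 - rho) * states$major
    frac <- ifelse(c_tot > 0, c_str / c_tot, 1)
    frac <- mirrored_expectation(frac, strong_sd)
    fres <- frac_w * outer(seg$mean_strong, frac, `-`)^2 + hom_mask
    c_norm <- 2 * rho + (1 - rho) * grid$c_tilde
    t_exp <- outer(c_tot, 1 / c_norm)                      # ns x nct
    # residual array: seg x ns x nct
    R <- array(rep(as.vector(t_exp), each = nseg), c(nseg, ns, nct))
    R <- seg$n_markers * (seg$mean_t - R)^2 + as.vector(fres)
    Rm <- matrix(aperm(R, c(2, 1, 3)), nrow = ns)          # ns x (nseg*nct)
    arg <- max.col(-t(Rm), ties.method = "first")
    amat <- matrix(arg, nseg, nct)
    # Given each column's state assignment, the normalisation ploidy that
    # minimises the total-ratio residual has a weighted-least-squares
    # closed form; using it makes the scale direction of the grid
    # continuous, so discretisation noise cannot favour one solution
    # family over another.
    totals <- matrix(states$total[amat], nseg, nct)
    ctot_fit <- 2 * rho + (1 - rho) * totals
    num <- colSums(seg$n_markers * seg$mean_t * ctot_fit)
    den <- colSums(seg$n_markers * ctot_fit^2)
    inv_norm <- ifelse(den > 0, num / den, NA_real_)
    c_norm_opt <- 1 / pmax(inv_norm, 1e-9)
    ct_opt <- pmin(pmax((c_norm_opt - 2 * rho) / (1 - rho),
                        min(grid$c_tilde)), max(grid$c_tilde))
    c_norm_cl <- 2 * rho + (1 - rho) * ct_opt
    res_t <- colSums(seg$n_markers *
                       (seg$mean_t - t(t(ctot_fit) / c_norm_cl))^2)
    res_f <- colSums(matrix(fres[cbind(rep(seq_len(nseg), nct),
                                       as.vector(amat))], nseg, nct))
    O[ri, ] <- res_t + res_f
    CT[ri, ] <- ct_opt
    K[ri, ] <- apply(amat, 2, function(a) length(unique(a)))
    P[ri, ] <- colSums(totals * seg$n_markers) / sum(seg$n_markers)
    if (!is.null(anchors)) {
      for (ch in names(anchors)) {
        rows <- seg$chrom == ch
        if (!any(rows)) stop("anchor names chromosome ", ch,
                             " absent from the fitted segments")
        ok <- vapply(seq_len(nct), function(j) {
          weighted_mode(totals[rows, j], seg$n_markers[rows]) ==
            anchors[[ch]]
        }, logical(1))
        feasible[ri, ] <- feasible[ri, ] & ok
      }
    }
  }
  list(objective = O + lambda * K, ploidy = P, c_tilde_opt = CT,
       feasible = feasible)
}

weighted_mode <- function(x, w) {
  tw <- tapply(w, x, sum)
  as.numeric(names(tw)[which.max(tw)])
}

# Evaluate a forced state assignment at (rho, c_tilde); used for the
# genome-doubling check.
eval_assignment <- function(seg, major, minor, rho, c_tilde, lambda,
                            strong_sd = 0) {
  ex <- expected_signals(major, minor, rho, c_tilde)
  frac_w <- ifelse(seg$hom_only, 0, seg$n_het)
  res <- seg$n_markers * (seg$mean_t - ex$t)^2 +
    frac_w * (seg$mean_strong - mirrored_expectation(ex$mirrored,
                                                     strong_sd))^2
  sum(res) + lambda * nrow(unique(cbind(major, minor)))
}

#' Fit contamination, ploidy and per-segment allelic states for one sample
#'
#' Runs a grid search over the contamination fraction `rho` and the
#' normalisation ploidy `c_tilde`, assigning every segment its
#' least-squares integer state at each grid point; the objective is the
#' marker-weighted residual sum plus `lambda` per distinct state used
#' (discouraging spurious high-copy solutions).  Ties prefer the
#' lower-ploidy, lower-contamination grid point.  Segments whose mean
#' ratio pre-screens as a high-level amplicon (`mean_t > amp_t_min`) are
#' excluded from the objective - a MYCN-class amplicon would otherwise
#' drag the ploidy estimate - and are state-fitted afterwards with the
#' amplification flag.
#'
#' A genome-doubling check follows: if halving all totals (at `c_tilde/2`)
#' scores within `rel_tol` of the optimum the halved solution is preferred;
#' if doubling scores within `rel_tol` the fit is ambiguous.  Either way
#' `ambiguous = TRUE` and the alternative solution is reported rather than
#' silently resolved, mirroring how such cases need an external anchor
#' (e.g. FISH) to settle.
#'
#' @param segments a `segments` data.frame (from [segment_sample()]).
#' @param grid a [fit_grid()].
#' @param max_copies cap on the major allele count.
#' @param lambda complexity penalty per distinct state (marker-weighted
#'   squared-error units).
#' @param rel_tol relative objective tolerance below which two solutions
#'   are treated as indistinguishable (near-tie candidate set, ambiguity
#'   flagging).
#' @param double_rel_tol more generous relative tolerance for preferring
#'   the halved (lower-ploidy) solution of an exact doubling alias; see
#'   Details.
#' @param amp_t_min normalised-ratio threshold above which a segment is
#'   treated as an amplicon candidate.
#' @param anchors optional named list/vector `chrom -> integer total copies`
#'   restricting the grid to solutions whose fitted per-chromosome total
#'   matches (see [apply_anchor()]).
#' @return A `sample_fit` list: `rho`, `c_tilde`, `segments` (with
#'   `major, minor, total, residual, amplified`), `per_chromosome`
#'   (marker-weighted modal totals), `overall_ploidy` (marker-weighted mean
#'   autosomal total, amplicons excluded), `ambiguous`, `alternative`,
#'   `objective`, `n_distinct_states`.
#' @export
fit_sample <- function(segments, grid = fit_grid(), max_copies = 12L,
                       lambda = 0.01, rel_tol = 0.02, double_rel_tol = 0.25,
                       amp_t_min = 3.5, anchors = NULL) {
  if (is.null(segments) || nrow(segments) == 0L) stop("no segments to fit")
  states <- enumerate_states(max_copies)
  strong_sd <- attr(segments, "strong_sd") %||% 0
  seg <- segments
  seg$amp_candidate <- seg$mean_t > amp_t_min
  seg$weight_scale <- 1
  ext <- attr(segments, "marker_extent")
  if (!is.null(ext)) {
    n_chr <- stats::setNames(ext$n_markers, ext$chrom)
    seg$chrom_frac <- seg$n_markers / n_chr[seg$chrom]
  }
  go <- grid_objective(seg, grid, states, lambda, anchors,
                       strong_sd = strong_sd)
  O <- go$objective
  O[!go$feasible] <- Inf
  if (!any(is.finite(O))) {
    bad <- names(anchors)[1]
    stop("no (rho, c_tilde) grid point satisfies anchor ", bad, " = ",
         anchors[[bad]])
  }
  # Contamination by diploid normal cells makes some profiles
  # observationally near-equivalent under state shifts and rescalings.
  # Among grid points whose objective is within rel_tol of the optimum,
  # report the most parsimonious account of the data: the lowest mean
  # fitted ploidy, then the lowest contamination, then the lowest
  # normalisation ploidy.
  tol <- rel_tol * max(min(O), lambda)
  cand <- which(O <= min(O) + tol, arr.ind = TRUE)
  pl <- round(go$ploidy[cand], 3)
  cand <- cand[order(pl, grid$rho[cand[, 1]], grid$c_tilde[cand[, 2]]), ,
               drop = FALSE][1, ]
  best <- cand
  rho <- grid$rho[best[1]]
  c_tilde <- go$c_tilde_opt[best[1], best[2]]
  fit <- finalize_fit(segments, rho, c_tilde, max_copies, amp_t_min,
                      lambda, objective = O[best[1], best[2]],
                      strong_sd = strong_sd)
  fit$grid <- grid
  fit$anchors <- anchors

  # Genome-doubling ambiguity.  Scaling all allele counts and the
  # contamination odds u = 2*rho/(1-rho) by a factor alpha reproduces the
  # observed signals exactly, so a doubled solution (alpha = 2, at
  # correspondingly higher contamination) is always an alias of the data.
  # Halving is only constructible when every fitted major and minor count
  # is even - exactly the profiles that are genuinely ambiguous - and is
  # then preferred (lower ploidy) unless the data clearly reject it;
  # tetraploid-versus-diploid calls need an external anchor, which is why
  # the ambiguity is flagged rather than silently resolved.
  if (is.null(anchors)) {
    # Reduce to the most parsimonious member of the alias family: halve
    # while every fitted allele count is even (u -> u/2, c_tilde -> c_tilde/2),
    # and strip a ubiquitous (1,1) background (u -> u + 2, c_tilde -> c_tilde - 2)
    # while every fitted minor count is >= 1.  Each reduction is adopted
    # only if the data do not clearly reject it.
    for (it in 1:4) {
      fitted <- fit$segments[!fit$segments$amplified, , drop = FALSE]
      if (!nrow(fitted)) break
      obj0 <- fit$objective
      adopt_tol <- double_rel_tol * max(obj0, lambda)
      flag_tol <- rel_tol * max(obj0, lambda)
      u <- 2 * fit$rho / (1 - fit$rho)
      reduced <- FALSE
      for (mode in c("halve", "shift")) {
        if (mode == "halve") {
          if (!all(fitted$major %% 2 == 0) || !all(fitted$minor %% 2 == 0))
            next
          u_a <- u / 2
          ct_a <- fit$c_tilde / 2
          maj <- fitted$major / 2; min_ <- fitted$minor / 2
        } else {
          if (!all(fitted$minor >= 1)) next
          u_a <- u + 2
          ct_a <- fit$c_tilde - 2
          maj <- fitted$major - 1; min_ <- fitted$minor - 1
          # stripping must not leave a large segment nullisomic
          big <- (fitted$end - fitted$start + 1) > 10e6
          if (any(big & maj + min_ == 0)) next
        }
        rho_a <- u_a / (2 + u_a)
        if (ct_a < min(grid$c_tilde) || rho_a > max(grid$rho)) next
        oa <- eval_assignment(fitted, maj, min_, rho_a, ct_a, lambda,
                              strong_sd)
        if (oa <= obj0 + adopt_tol) {
          alt <- fit
          fit <- finalize_fit(segments, rho_a, ct_a, max_copies, amp_t_min,
                              lambda, objective = oa, strong_sd = strong_sd)
          fit$grid <- grid
          fit$ambiguous <- abs(oa - obj0) <= flag_tol
          fit$alternative <- list(rho = alt$rho, c_tilde = alt$c_tilde,
                                  overall_ploidy = alt$overall_ploidy)
          reduced <- TRUE
          break
        }
      }
      if (!reduced) break
    }
    # the doubled alias always exists; flag it when the data cannot
    # distinguish it from the reported fit
    fitted <- fit$segments[!fit$segments$amplified, , drop = FALSE]
    if (nrow(fitted) && !fit$ambiguous) {
      obj0 <- fit$objective
      flag_tol <- rel_tol * max(obj0, lambda)
      u_d <- 4 * fit$rho / (1 - fit$rho)
      d <- list(rho = u_d / (2 + u_d), c_tilde = 2 * fit$c_tilde)
      if (d$c_tilde <= max(grid$c_tilde) &&
          all(2 * fitted$major <= max_copies)) {
        od <- eval_assignment(fitted, fitted$major * 2, fitted$minor * 2,
                              d$rho, d$c_tilde, lambda, strong_sd)
        if (od <= obj0 + flag_tol) {
          fit$ambiguous <- TRUE
          fit$alternative <- list(rho = d$rho, c_tilde = d$c_tilde,
                                  overall_ploidy = 2 * fit$overall_ploidy)
        }
      }
    }
  }
  fit
}

finalize_fit <- function(segments, rho, c_tilde, max_copies, amp_t_min,
                         lambda, objective, strong_sd = 0) {
  seg <- segments
  st <- lapply(seq_len(nrow(seg)), function(i)
    fit_segment_state(seg$mean_t[i], seg$mean_strong[i], seg$n_markers[i],
                      seg$n_het[i], rho, c_tilde, max_copies,
                      hom_only = seg$hom_only[i], strong_sd = strong_sd))
  seg$major <- vapply(st, `[[`, 0, "major")
  seg$minor <- vapply(st, `[[`, 0, "minor")
  seg$total <- seg$major + seg$minor
  seg$residual <- vapply(st, `[[`, 0, "residual")
  seg$amplified <- vapply(st, `[[`, TRUE, "amplified") &
    seg$mean_t > amp_t_min
  for (a in c("sample_id", "marker_extent", "het_rate"))
    attr(seg, a) <- attr(segments, a)
  class(seg) <- class(segments)

  core <- seg[!seg$amplified, , drop = FALSE]
  per_chr <- do.call(rbind, lapply(split(core, core$chrom), function(s)
    data.frame(chrom = s$chrom[1],
               total = weighted_mode(s$total, s$n_markers),
               n_markers = sum(s$n_markers), stringsAsFactors = FALSE)))
  per_chr <- per_chr[order(match(per_chr$chrom, unique(seg$chrom))), ]
  rownames(per_chr) <- NULL
  auto <- core[is_autosome(core$chrom), ]
  overall <- sum(auto$total * auto$n_markers) / sum(auto$n_markers)
  k <- nrow(unique(seg[, c("major", "minor")]))
  structure(list(sample_id = attr(segments, "sample_id"),
                 rho = rho, c_tilde = c_tilde, segments = seg,
                 per_chromosome = per_chr, overall_ploidy = overall,
                 ambiguous = FALSE, alternative = NULL,
                 objective = objective, n_distinct_states = k),
            class = "sample_fit")
}

#' Re-fit a sample under external per-chromosome copy-number anchors
#'
#' Restricts the grid search to `(rho, c_tilde)` combinations whose fitted
#' marker-weighted modal total on each anchored chromosome equals the
#' anchored value - the in-silico analogue of revising an array fit
#' against FISH counts.  Errors (naming the violated anchor) when no grid
#' point is compatible.
#'
#' @param fit a `sample_fit` from [fit_sample()].
#' @param anchors named list/vector, e.g. `c(chr2 = 4)`.
#' @param ... passed on to [fit_sample()].
#' @return a refitted `sample_fit` (with `ambiguous` cleared when the
#'   anchor resolves a doubling ambiguity).
#' @export
apply_anchor <- function(fit, anchors, ...) {
  stopifnot(inherits(fit, "sample_fit"), length(anchors) >= 1)
  seg <- fit$segments
  seg$major <- seg$minor <- seg$total <- seg$residual <- seg$amplified <- NULL
  fit_sample(seg, grid = fit$grid, anchors = as.list(anchors), ...)
}

#' @export
print.sample_fit <- function(x, ...) {
  cat("Sample fit", if (!is.null(x$sample_id)) paste0("(", x$sample_id, ")"),
      "\n")
  cat(sprintf("  contamination rho : %.2f\n", x$rho))
  cat(sprintf("  normalisation ploidy : %.2f\n", x$c_tilde))
  cat(sprintf("  overall ploidy : ~%.1fn%s\n", x$overall_ploidy,
              if (x$ambiguous) " (doubling-ambiguous)" else ""))
  cat("  segments :", nrow(x$segments), "in",
      x$n_distinct_states, "distinct states\n")
  invisible(x)
}

#' Write a per-sample fit report
#'
#' Writes the fitted segments as TSV and a JSON summary (rho, ploidy,
#' per-chromosome totals, flags).
#'
#' @param fit a `sample_fit`.
#' @param prefix output path prefix; writes `<prefix>.segments.tsv` and
#'   `<prefix>.fit.json`.
#' @return `prefix`, invisibly.
#' @export
write_fit_report <- function(fit, prefix) {
  utils::write.table(fit$segments, paste0(prefix, ".segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  js <- list(sample_id = fit$sample_id, rho = fit$rho,
             c_tilde = fit$c_tilde,
             overall_ploidy = round(fit$overall_ploidy, 1),
             ambiguous = fit$ambiguous,
             alternative = fit$alternative,
             per_chromosome = fit$per_chromosome)
  jsonlite::write_json(js, paste0(prefix, ".fit.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
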