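---
title: "Allele-specific copy number and near copy-neutral LOH: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific copy number and near copy-neutral LOH: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nearloh)
```

## The problem

SNP genotyping arrays record, per marker, a total hybridisation intensity
and a B-allele fraction (BAF).  In tumours this pair is far more
informative than array-CGH: it exposes loss of heterozygosity (LOH) even
when the total copy number is unchanged.  Copy-neutral LOH (e.g. an
allelic state of 2+0 in a diploid genome) is invisible to any
total-copy-only method.  In polyploid tumours the notion has to be
generalised: in a near-triploid genome, both 2+0 and 3+0 represent LOH
that is at least partially compensated by the remaining allele, and
`nearloh` calls any such state a *near copy-neutral LOH* (near-CN-LOH)
relative to the sample's own ploidy.

Two practical complications drive most of the design:

* **Stromal contamination.** Primary tumour DNA is a mixture of tumour
  and normal cells.  A fraction $\rho$ of diploid, heterozygous normal
  cells regenerates intermediate BAF values inside tumour LOH regions
  ("false heterozygous" genotype calls), which is what makes LOH
  detectable without a matched normal — and what biases naive copy-number
  readings.
* **Polyploidy.** Low-risk neuroblastomas often carry complex numerical
  karyotypes with 2–5 copies of each chromosome and no segmental
  changes.  Total intensity is only defined relative to the genome-wide
  normalisation, so per-chromosome integer states must be fitted jointly
  with the contamination and the normalisation ploidy.

## Signal model

For an allelic state with $a$ copies of the major and $b$ of the minor
allele, contamination $\rho$, and normalisation ploidy $\tilde c$ (the
total copy number that maps to a normalised ratio of 1):

$$c_{tot} = 2\rho + (1-\rho)(a+b), \qquad c_{str} = \rho + (1-\rho)a,$$
$$t = \frac{c_{tot}}{2\rho + (1-\rho)\tilde c}, \qquad
  f = \frac{c_{str}}{c_{tot}} \ (\text{defined as } 1 \text{ when } c_{tot}=0),$$

where $t$ is the normalised total ratio and $f$ the *mirrored* allele
fraction $\max(\mathrm{BAF}, 1-\mathrm{BAF})$ at germline-heterozygous
markers.  `expected_signals()` implements this.  Useful fixed points: any
balanced state gives $(t, f) = (\cdot, 0.5)$; a (2,0) state at
$\rho = 0.3$, $\tilde c = 2$ gives $(1.0, 0.85)$ — copy-neutral in $t$,
clearly displaced in $f$.

### Identifiability and aliasing

For fixed $(\rho, \tilde c)$ the map from states to $(t, f)$ is injective
(verified by enumeration over all states with total $\le 6$).  Across
parameters, however, the model has *exact* alias families: writing
$u = 2\rho/(1-\rho)$, scaling $(a, b, u, \tilde c)$ by any $\alpha$
reproduces the signals exactly (genome doubling at higher contamination),
and $(a+1, b+1)$ at $u + 2$, $\tilde c + 2$ does too (a ubiquitous
diploid background added to every state).  No likelihood can separate
these; `fit_sample()` therefore

* refines $\tilde c$ in closed form (weighted least squares) for every
  grid point's state assignment, so grid discretisation cannot
  accidentally favour one family;
* corrects the expected mirrored fraction for noise folding
  ($E[\max(X, 1-X)] = 0.5 + \sigma\sqrt{2/\pi}$ for $X\sim N(0.5,\sigma)$;
  without this the fit drifts toward spuriously imbalanced states);
* forbids nullisomy (0,0) on segments longer than 10 Mb or covering more
  than half a chromosome — focal homozygous deletions are real,
  whole-chromosome nullisomy is not, and admitting it opens the
  downward-shift alias of every balanced profile;
* among near-tied grid points (within `rel_tol`, default 2%) reports the
  most parsimonious account: lowest mean ploidy, then lowest
  contamination;
* explicitly attempts the halving and background-stripping reductions on
  the winning fit (adopted within `double_rel_tol`, default 25%, of the
  optimum — the reductions are exact aliases, so only micro-biases
  separate them) and flags the genome-doubling ambiguity instead of
  silently resolving it.  Anchoring a chromosome to an external count
  (`apply_anchor()`, the in-silico analogue of a FISH revision) restricts
  the grid and clears the flag.

The grid defaults ($\rho$ 0–0.9 by 0.02, $\tilde c$ 1.5–5 by 0.05 before
refinement) balance runtime against the ±0.05 contamination-recovery
target; both are exposed via `fit_grid()`.  States are capped at
`max_copies = 12`; segments whose ratio implies more (MYCN-class
amplicons) are excluded from the global objective — they would otherwise
drag the ploidy — and flagged `amplified`.  The per-segment objective
weights the $t$ term by the marker count and the $f$ term by the
het-informative marker count; a complexity penalty `lambda` (default
0.01, roughly one marker-equivalent of squared error) per distinct state
discourages spurious high-copy solutions.  Segments with essentially no
AB calls (rate < 5%) drop the fraction term and are restricted to
$b = 0$ states: a segment of any size without heterozygous genotypes
cannot retain a second allele.  This keeps LOH callable in pure
(uncontaminated) cell lines, where the mirrored track carries no
information.

## Segmentation

Chromosomes are partitioned by least-squares change-point search on three
standardised channels: $t$ (all markers), the mirrored fraction (AB
markers only) and the AB-call indicator.  The third channel is essential:
in an uncontaminated sample a copy-neutral 2+0 run leaves $t$ flat and
has no AB calls at all, so the only signature is the collapse of het
density.  Channels are standardised by robust difference-based variance
estimates (floored at $10^{-6}$ so noise-free input stays numerically
stable; the het channel uses $p(1-p)$), making a single penalty
applicable to their summed cost reduction.  The default penalty
$4\log n$ per change-point is an information-criterion-style term over
the three channels.

Candidate breakpoints come from greedy binary segmentation plus a
multi-scale interior-block scan run *within* each greedy segment (greedy
splits dilute a short interior run over its long flanks; and against the
whole series, any window carved next to a large step shows a spurious
gain — both standard failure modes).  Candidates are refined by local
re-optimisation and backward-pruned, so only breakpoints that pay for
themselves in the final model survive.  Segments shorter than
`min_markers` (default 25) are dissolved: a brief excursion leaves no
breakpoint, while a genuine boundary flanked by a short run keeps its
stronger side.  Coordinates are 1-based inclusive internally; BED export
is 0-based half-open.

After state fitting, `merge_adjacent()` collapses same-state neighbours
so one biological event is counted once; summaries are recomputed as
marker-weighted means.

## Event taxonomy and per-sample summaries

With $P = \mathrm{round}(\text{overall ploidy})$ (overall ploidy being
the marker-weighted mean autosomal total, amplicons excluded — the
paper-style "~2.3n" report rounds it to one decimal):

| state | condition | category |
|---|---|---|
| $b=0$, $2 \le a+b \le P$ | LOH compensated by the remaining allele | `NEAR_CN_LOH` |
| $b=0$, $a+b > P$ | LOH plus net gain | `GAIN_LOH` |
| $a+b < 2$ | classical hemizygous/homozygous loss | `LOSS_LOH` |
| $b\ge 1$, unequal, not the balanced split of its total | e.g. 3+1 vs 2+2 | `ALLELIC_IMBALANCE` |
| otherwise | | `BALANCED` |

Allelic imbalance is called but never counted in burden statistics.
Extents are `WHOLE_CHROMOSOME` (reaches both chromosome ends within
`tol_markers = 5` markers), `TELOMERIC` (exactly one end), else
`INTERSTITIAL`; whole-chromosome takes precedence.  Only autosomal
near-CN-LOH events of at least 1.5 Mb are counted.  Germline
identical-by-descent runs are counted as near-CN-LOH — without matched
normals they cannot be separated from somatic events.

Per-sample flags drive the cohort exclusions: `flat_profile` (no
aberrant segment), `mycn_amp_only` (the only aberration is an
amplification at the designated 2p locus) and `cnloh_only`; all three
indicate profiles dominated by stromal signal.  `compare_profiles()`
matches aberrations across related samples by reciprocal overlap
(default 0.5) *and* identical state; overlapping events failing either
condition are reported as partial — similar-looking lesions with
different breakpoints or copy number that likely arose independently.

## Cohort statistics

`apply_exclusions()` removes non-parent members of related groups (the
parent is the sample whose id equals the `related_group` label), then
flag-carrying tumours and cell lines; controls are flat by construction
and exempt.  Every removal is logged once.  Prevalence differences use
the two-sided Fisher exact test (sum of tables no more probable than the
observed, via `stats::fisher.test`; an independent hypergeometric
enumeration backs it in the tests).  Burden differences use the
Mann-Whitney U test with midranks: exact via dynamic programming over
the permutation distribution of the rank sum (correct under ties) when
$n_A n_B \le 400$, else the tie- and continuity-corrected normal
approximation.  Burden descriptives use linear-interpolation quantiles
(type 7) — the printed "25th–75th percentiles" style cannot
disambiguate the convention, so it is fixed and documented here.
Outcome comparisons (dead-of-disease vs no-evidence-of-disease) exclude
any other outcome label, overall and per extent subtype.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 134 tumours, 8
independent cell lines, 30 healthy controls; Poisson event counts with
means 0.89 / 2.4 / 0.10 per sample; extent mixtures (interstitial,
telomeric, whole-chromosome) of (0.50, 0.15, 0.35) for tumours,
(0.05, 0.74, 0.21) for cell lines, and interstitial-only for controls,
whose "events" are germline IBD runs forced homozygous.  Marker maps are
evenly spaced (default 12 kb, ~260k markers — 250K-array-like density)
over rounded chromosome lengths of the array-annotation era; only the
relative geometry matters.

Where the study does not state a value, the generator fixes one
realistic choice: tumour contamination uniform on 0.2–0.55 (primary
tumour DNA always carries stroma; cell lines and controls are pure);
tumour backgrounds 35% numerical near-triploid, 20% MYCN-amplified, 25%
11q-deletion, 20% flat; germline heterozygosity 0.3; interstitial events
2–10 Mb, telomeric 5–30 Mb (comfortably above the 1.5 Mb reporting
threshold); at most one event per chromosome, placed on feature-free
autosomes, so one biological event is one maximal constant-state run;
additive Gaussian noise (default SD 0.05) on both signals, fractions
truncated to [0,1]; genotype calls by thresholding the observed BAF,
`AB` within [0.1, 0.9] — with this window a (2,0) region re-enters the
het-callable range once contamination reaches 0.2, reproducing the
false-heterozygous behaviour of contaminated arrays, while noise-free
germline homozygotes (BAF exactly 0 or 1) are never miscalled.
Numerical near-triploid profiles have whole-chromosome states only, so
their injected LOH events are realised as whole-chromosome 2+0/3+0
regardless of the extent mixture.  Outcome labels are drawn
independently of burden (25% DOD / 60% NED / 15% unknown), matching the
reported absence of an outcome association.

What the generator does *not* emulate: raw probe intensities, GC/wave
artefacts, linkage disequilibrium between markers, subclonal
(non-integer) mixtures beyond the single stromal fraction, centromeres
(telomeric extent is defined by marker extent), and X-chromosome dosage
(X is carried flat for the exclusion plumbing).  Passing tests on this
generator therefore demonstrate correctness of the inference given the
stated signal model, not robustness to probe-level artefacts of real
arrays.

## Numerical choices and degenerate inputs

* Chromosomes with fewer than `min_markers` markers return one flagged
  segment.  Fully homozygous samples are flagged, not dropped.
* Ties in the per-segment state fit break toward the smaller total, then
  the larger minor count (the more balanced state).
* Grid selection ties prefer lower ploidy, then lower contamination,
  then lower $\tilde c$.
* Reference selection ranks control samples by the SD of
  $\log_2(\text{sample}/\text{candidate})$ over autosomal markers (scale
  invariant); the best 6 are averaged marker-wise before ratio
  normalisation.  Log2 appears only there; all fitting is on the linear
  scale.  The autosomal median of $t$ is exactly 1 after normalisation.
* Problem sizes in the test-suite: full 12 kb density only for the
  noise-free event-recovery check; contamination recovery uses 150 kb
  maps (~20k markers); statistical property tests use enumeration-scale
  inputs.

## Known limitations

* At contamination near $u$-integer points ($\rho = 0.5, 2/3, \dots$)
  the alias families above are exactly degenerate for profiles without
  LOH or strong imbalance; the parsimony rules then pick the
  lowest-ploidy account, which is the convention, not an inference.
* The exact Mann-Whitney branch is limited to $n_A n_B \le 400$; larger
  tied comparisons use the normal approximation, which can deviate by a
  few percent from the permutation p under extreme tie concentrations.
* Germline IBD and somatic CN-LOH are indistinguishable by design
  (no matched normals); burden comparisons against the control group are
  the only handle on the IBD contribution.
* The per-chromosome copy report is the marker-weighted modal total;
  "overall ploidy" is a marker-weighted mean — one of several defensible
  readings of an informally used term, stated here explicitly.
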