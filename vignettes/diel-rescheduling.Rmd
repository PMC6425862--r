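---
title: "Detecting rescheduled diel expression between CAM and C3 species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rescheduled diel expression between CAM and C3 species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielshift)
```

## The problem

Plants with crassulacean acid metabolism (CAM) open their stomata at night
and close them during the day — the inverse of the C3 rhythm. A gene whose
diel expression in a CAM species sits in the opposite half of the 24-h cycle
from its orthologs in C3 species is a candidate driver of that inversion.
`dielshift` implements the comparative screen for such *rescheduled*
ortholog groups: one CAM species against exactly two C3 species, each
observed as a genes × time-points FPKM matrix over a single 24-h cycle.

The screen is deliberately categorical. Each species' cycle is summarized by
two three-hour windows — *dusk* (the hours flanking lights-off) and *dawn*
(the hours flanking lights-on) — and each gene is classified as
dusk-enriched, dawn-enriched, or neither. Continuous phase estimation
(cosinor, JTK-CYCLE and relatives) is out of scope by design: the question
is which half of the cycle carries a gene's mass, not its precise peak hour.

## The procedure

### Preprocessing

1. **Resampling.** All species are brought onto a common 2-h grid. A species
   sampled every 4 h is resampled per gene with a not-a-knot cubic spline —
   the boundary condition used by the familiar pandas/scipy cubic
   interpolators, chosen because it reproduces any cubic polynomial exactly,
   which gives the interpolation a sharp test oracle. One subtlety: the dawn
   window includes hour 22, which lies beyond the last knot (hour 20) of a
   0–20 h 4-h grid. The spline's own end cubic is used there, exactly as
   scipy evaluates beyond the knot span. Negative interpolants are clamped
   to 0 (and counted), so resampling can never remove a gene.
2. **Filtering.** Genes with any negative value are dropped; genes with mean
   FPKM below 0.01 or with at least half of their sampling points equal to
   zero are dropped. Both thresholds are configurable
   (`min_mean_fpkm`, `max_zero_fraction`). The filter is idempotent and
   order-preserving.
3. **Normalization.** Each surviving gene's profile is reduced to its
   within-gene shape: values are scaled to integer pseudo-counts summing to
   exactly `normalization_scale` (default C = 1000) by largest-remainder
   rounding. The exact-test machinery downstream needs integers, and
   relative shape is the only thing a dawn-vs-dusk comparison should see;
   the transform is invariant under positive rescaling of a profile, so
   FPKM-scale differences between genes and species cancel. Larger C makes
   the per-gene test more sensitive (more pseudo-observations per gene);
   C = 1000 keeps roughly one count per 0.1% of a gene's mass. C is exposed
   in the configuration precisely so its effect can be checked; under the
   synthetic conditions used in the test suite, doubling or halving C moves
   no planted verdict.

### Window enrichment

For species s, let `S_dusk(g)` and `S_dawn(g)` be gene g's pseudo-count sums
over the dusk and dawn hours, and `T_dusk`, `T_dawn` the column totals over
all genes of that species. The dusk test for gene g is the right tail of the
Fisher exact test on

```
| S_dusk(g)            S_dawn(g)            |
| T_dusk - S_dusk(g)   T_dawn - S_dawn(g)   |
```

i.e. the hypergeometric probability of a first cell at least as large as
observed given the margins, accumulated on the log-factorial scale. The dawn
test swaps the columns. This layout measures over-representation of g's
counts in the focal window *relative to the transcriptome-wide dusk/dawn
balance*, using only quantities present in the two-column window-sum matrix.
It is isolated in a single internal table-builder so an alternative layout
is a one-function change. A direct consequence worth knowing: enrichment is
relative, so a hypothetical transcriptome in which every gene peaks at the
same hour has no enriched genes at all.

Benjamini–Hochberg FDR control is applied separately per species and per
window (the dusk p-vector and the dawn p-vector each get their own step-up)
at `alpha = 0.05`. A gene's phase is the rejected window, `neither` if none.
Rejection uses the standard step-up rule (reject iff q ≤ α, equivalently
p(i) ≤ iα/m at the step-up index); both windows rejecting simultaneously is
not possible in practice (the two tails overlap), but the code resolves it
by the smaller q-value, falling back to `neither` with a warning on an
exact tie.

### Rescheduling calls

For each ortholog group with at least one tested gene in all three species,
every (CAM gene, C3-A gene, C3-B gene) combination is evaluated against two
criteria:

1. the CAM gene's phase is `dawn` or `dusk`, and **both** C3 orthologs have
   the opposite phase. Opposition is by label, not hour arithmetic, because
   the light regimes may differ (a 10-h-light species uses dusk hours
   8/10/12 while a 12-h-light species uses 10/12/14);
2. the CAM gene's Spearman rank correlation with each C3 ortholog is
   strictly below −0.6 and the two C3 orthologs correlate strictly above
   0.6 with each other. The strict inequalities are intentional: boundary
   values fail. Correlations use mid-rank (average-rank) ties and are
   computed on the hours shared by each pair of sampling grids.

A combination passes if both criteria hold; a group is *rescheduled* if at
least one combination passes. All combinations are written out, so stricter
group-level rules (e.g. all-combinations-pass) can be applied downstream
without rerunning. Correlations are computed on the raw post-interpolation
expression by default; since Spearman is rank-based, within-gene monotone
transforms cannot change it, but `rho_on = "normalized"` is available
because rounding to pseudo-counts can in principle break rank ties
differently.

Two deliberately conservative behaviours: a group missing any of the three
species is skipped with a recorded reason rather than erroring, and a
constant profile (rank correlation undefined) yields `NA` correlations and
an `NA` criterion-2 flag — it can never support a rescheduled verdict.

## The synthetic generator

`generate_study()` simulates the processed form of a three-species diel
study: per-species FPKM matrices, ortholog groups, and a truth table. Each
gene's profile is

```
x_t = baseline * (1 + A * (1 + cos(2*pi*(t - peak)/24)) / 2) * exp(e_t),
e_t ~ N(0, sigma^2)
```

a cosine between `baseline` and `baseline * (1 + A)` with multiplicative
log-normal noise — non-negative by construction, unimodal, and with
closed-form expectations for the window sums. Defaults are 200 ortholog
groups of which 20 planted anti-phase (CAM peak at hour 12, C3 peaks at
hour 0), baseline 10 FPKM, amplitude ratio A = 3, noise sigma 0.2, two
species on the 2-h grid and one on the 4-h grid. Conserved groups draw one
shared peak uniformly from the sampling grid: real transcriptomes have peak
phases spread around the clock, and because the enrichment test is relative
to the transcriptome-wide balance, background phase diversity is a
structural requirement, not a convenience (see above). Setting
`conserved_peaks = "fixed"` collapses all conserved peaks onto one hour if
that degenerate regime is wanted.

The cosine is evaluated through the mirror-symmetric distance to the peak
(`cospi` of `d/12` with `d = min(u, 24 - u)`), so hours equidistant from the
peak give bitwise-equal values. Plain `cos()` breaks these mathematical ties
in the last floating-point ulp, which silently destroys the exact −1 rank
correlation of noise-free anti-phase trios; with the symmetric evaluation,
anti-phase profiles have exactly reversed rank orders and Spearman rho is
exactly −1.

What the generator does *not* emulate: read-level sampling noise
(FPKM uncertainty scales with expression; here noise is homoscedastic on the
log scale), non-sinusoidal waveforms (sharp evening peaks, double peaks),
correlated noise between time points, missing time points, and paralog
expression divergence within a species. Passing the planted-truth tests
therefore demonstrates that the statistical machinery is wired correctly
and has the expected operating characteristics under a clean signal model —
not that the pipeline's sensitivity on real RNA-seq data equals the
simulated one.

The generator seeds R's RNG from the spec's `seed`; identical specs give
byte-identical written studies on one platform. Cross-platform bit-identity
of the floating-point noise stream is not promised.

## Problem sizes and runtime choices

The test suite exercises the exact test against full enumeration of all
2×2 tables with total ≤ 20, the FDR step-up against 1,000 random p-vectors
of lengths 1–200, rank correlation against 1,000 random tied vectors plus
all 24 orderings at n = 4, null behaviour on 10 replicate 500-gene flat
studies, and planted-truth recovery on 10 replicate 200-group studies
(20 planted) — sizes at which the whole suite runs in about a minute while
the stochastic checks still have tight operating-characteristic bounds.
The acceptance script repeats the planted and null studies at the same
per-study sizes with 5 and 3 replicate seeds respectively.

## Known limitations

- The window test conditions on the transcriptome-wide dusk/dawn balance;
  phase calls for a species are therefore relative to its own transcriptome
  composition, and a species-wide skew (e.g. a transcriptome globally
  dusk-heavy) shifts every gene's baseline.
- With three-hour windows out of twelve sampling points, half the cycle is
  never inside either window; genes peaking mid-morning or mid-afternoon
  are structurally `neither` regardless of amplitude.
- The 1-CAM-vs-2-C3 contrast is fixed; the data model does not extend to
  other designs without changes to the rescheduling module.
- The literature-hit filter is a plain keyword scan over whatever snippets
  the hit records carry; whether titles, abstracts or full text were
  included is a property of the upstream export, not of this package.
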