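---
title: "Methods: rotational and translational mutation signatures in nucleosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rotational and translational mutation signatures in nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

DNA wrapped around a histone octamer is not uniformly exposed. Bases facing
away from the histone surface ("outward" rotational settings, recurring
every ~10.3 bp, the helical repeat on the octamer) are more flexible and
more prone to UV-induced cyclobutane pyrimidine dimer (CPD) formation,
while DNA near the central dyad is least accessible to repair machinery.
Both effects leave footprints in somatic mutation density from UV-exposed
tumors: a ~10 bp oscillation phased to the rotational setting, and a
"translational curvature" — mutation density rising from the core-particle
edges (offsets ±73) toward the dyad (offset 0).

`nucsig` quantifies both footprints in dyad-centered profiles. All profiles
index offsets −73..+73 (147 positions; configurable half-width), with the
dyad at 0. Two statistics summarize a profile:

* the **Lomb–Scargle periodogram** of the mean-centered profile, whose
  dominant period (after excluding periods > 100 bp) captures the
  rotational oscillation;
* the least-squares quadratic `y = a·x² + b·x + c` over offset `x` in bp,
  whose second derivative `2a` measures translational curvature (`a < 0`:
  dyad-peaked).

Raw observed counts confound chromatin effects with sequence composition,
so observed profiles are normalized by a **trinucleotide expected model**:
mutations per reference 3-mer context divided by the total give `freq(t)`;
per-site rates are `rate(t) = freq(t) · N / genome_count(t)` with
`genome_count(t)` the number of 3-mer centers in the eligible reference
territory; the expected profile sums `rate` over the contexts at each
offset. The ratio observed/expected is the **mutation enrichment**. Because
`Σ_t rate(t)·genome_count(t) = N` exactly, observed and expected share
units of counts, and refitting the model on the profiled mutation subset
with the profiled windows as territory forces mean enrichment ≈ 1 — the
self-normalization property the package tests.

Two scaling choices deserve emphasis, since the frequency-to-expectation
step could be read several ways:

* expected values use per-site genome-normalized *rates*, not raw context
  frequencies; this is the only scaling under which the expected and
  observed curves are directly comparable and the self-normalization
  identity holds;
* contexts are counted on the reference strand as written (64 contexts,
  no pyrimidine-strand collapsing); the dipyrimidine test itself is
  strand-symmetric (a C/T with a C/T neighbour, or an A/G with an A/G
  neighbour, i.e. a pyrimidine pair on the reverse strand).

## Pipeline stages and their parameters

| parameter | default | meaning |
|---|---|---|
| `min_score` | 10 | strong-nucleosome positioning-score threshold (score ≥ 10) |
| `weak_range` | (−40, −5) | weak-nucleosome score band, inclusive |
| `exclusion_radius` | 117 bp | greedy dyad caller masks \|Δ\| ≤ 117 around each call |
| `half_width` | 73 bp | core-particle window; 500 for the extended inter-nucleosome view |
| `period_min/max` | 3 / 150 bp | periodogram search range |
| `exclusion_max` | 100 bp | rotational analyses discard longer periods |
| `qc_threshold` | 100 | minimum mean mutations per bp for a stratum to be eligible |
| `xr_offset` | (8, 7) | XR-seq lesion dinucleotide distance upstream of the read 3′ end |

The dyad caller is a greedy priority-queue equivalent: it repeatedly takes
the highest remaining score at or above `min_score`, emits the position,
and masks everything within the exclusion radius *inclusive* — the
conservative reading of "within 117 bp", configurable. Ties break to the
lowest coordinate, then lexicographic chromosome, making calls fully
deterministic; chromosomes are processed independently (exclusion cannot
cross a chromosome, so per-chromosome queues equal a global queue).
Blacklist filtering removes a dyad when its whole 147-bp window intersects
a blacklisted interval — nucleosomes, not points, are excluded.

Lesion-position conventions are assay-specific and strand-aware: CPD-seq
intervals *are* the lesion dinucleotide; HS-Damage-seq lesions are the two
bases immediately 5′ of the read's 3′ end; XR-seq lesions sit `xr_offset`
bases upstream of the excision product's 3′ end. The XR-seq offset is
inherited from the upstream convention of that assay's processing chain and
therefore kept configurable; the synthetic generator and the extractor
share the configuration, so round-trip tests hold under any offset choice.
Both dinucleotide bases contribute to per-offset counts (an edge-straddling
lesion contributes one). Normalization divides per-offset cellular counts
by naked-DNA counts at the *same offsets* (not window totals), after
dividing each dataset by its total in-window dipyrimidine-mapped count
(sequencing depth). UV doses attached to the source libraries are metadata
only; no dose arithmetic is performed.

TS/NTS assignment: a mutation's lesion strand is the strand carrying the
pyrimidine (reference C/T → "+", A/G → "−"); it counts as transcribed-strand
when that strand is the gene's template strand. Whether strand should
instead follow the reported allele's gene-relative orientation is
genuinely ambiguous; this rule is the package's documented choice, and the
symmetric-cohort test pins its behaviour. Dyads inside genes of conflicting
strand are dropped and logged. Gene-body membership for transcription
strata is strand-agnostic (dyad coordinate within start..end), quartiles
are Low = bottom, Medium = middle two, High = top, computed from the
*median* expression per gene — where a mean is wanted instead, rank-based
quartiles change little, but the choice is kept explicit in the code.

## The synthetic generator: what it emulates, and what not

The generator is the package's test surface. Per-site mutation probability
is

    p(site) = r0 · w(trinuc) · (1 + A·cos(2π·o/T + φ)) · (1 + c_q·(1 − (o/73)²))

inside a dyad window (offset `o`), and `r0 · w(trinuc)` outside; only
dipyrimidine-context sites are eligible, substitutions are pyrimidine
transitions mirrored to the reference strand, sampling is without
replacement per site within a donor. Defaults: `A = 0.3`, `T = 10.3` bp,
`φ = π` (cosine maxima — outward settings — at offsets ±5.15 + 10.3k, the
dyad treated as inward; the phase of outward relative to the dyad is not an
identity the analysis depends on, so it is a knob), `c_q = 0.1`,
`r0 = 0.005` per donor over 20 donors. Probabilities are clipped to [0, 1];
the defaults never trigger clipping, and amplitudes that would make a
probability negative raise an error before sampling. Lesion reads are
sampled from the same modulated model (or flat, for naked-DNA controls) and
emitted so that each assay's extractor recovers the planted dinucleotide
exactly.

Sequence composition is controlled by per-base probabilities plus an
optional TT-enrichment at inward settings (`tt_inward_bias`), emulating the
genomic over-representation of TT at inward rotational positions that
confounds raw HS-Damage-seq oscillations. A full dinucleotide Markov model
was considered and rejected: the mutation-side `context_bias` and the
TT-inward knob cover the sequence-bias scenarios the analysis must
distinguish from chromatin effects.

What the generator does **not** emulate: alignment artifacts, sequencing
error, copy-number variation, selection, inter-donor rate heterogeneity,
and real linker-length distributions (dyads are placed uniformly subject to
a minimum spacing). Passing recovery tests therefore demonstrates that the
statistics recover planted signal under the stated generative model — not
that real data are free of confounders the model lacks.

## Numerical choices

* **Periodogram**: classical Lomb normalized periodogram with the
  phase-invariant τ correction, validated to 10 decimal places against an
  independent reference implementation on even and uneven grids. The grid
  is 2000 evenly spaced frequencies over [1/150, 1/3] bp⁻¹, giving ~0.03 bp
  period resolution near 10 bp. Masked offsets are simply absent — the
  uneven-sampling case Lomb–Scargle exists for. Constant profiles return an
  explicit no-signal result rather than an arbitrary argmax.
* **Peak significance**: a permutation envelope (shuffling profile values
  across offsets, taking the maximum power per shuffle) gives the null for
  "is the dominant peak real"; the package uses the envelope's maximum over
  200 shuffles when a hard bound is wanted.
* **Quadratic fits** use `lm` on unmasked offsets; `normalize = TRUE`
  divides by the unmasked mean first, putting cohorts of different depth on
  one scale. Mean-normalizing a planted quadratic of depth `c_q` shrinks
  the recovered second derivative by 1/(1 + 2c_q/3) (≈ 9% at c_q = 0.15) —
  inside the 25% recovery tolerance the tests use.
* **Subsampling survey**: subsets are drawn without replacement, stratified
  so the C:T pyrimidine-class ratio matches the full set; the expected
  model is refit per subset; a subset's dominant period is rounded to the
  nearest bp, so "~10 bp" means [9.5, 10.5) — a documented bracket, not an
  inference.
* **16-bin chi-square layout**: thirteen 9-bp and three 10-bp bins; a
  16-bin partition of 147 cannot be mirror-symmetric, so the 10-bp bins go
  at both edges and at the dyad (which always falls inside a 10-bp bin).
* **Axis inversion**: each profile's values are re-read as observations
  along the enrichment axis (bp positions become tallies) over a range
  whose ends are the combined min/max rounded to the nearest integer;
  values are tallied at full precision by default. The procedure is
  implemented as described by its originators, without reinterpretation;
  zero-spread profiles make it degenerate and raise an error. Dunn's
  post-hoc z statistics use the standard mean-rank formula with tie
  correction (implemented in-package; verified against the two-group
  Kruskal–Wallis identity z² = H).
* **Genome-count territory** for the expected model is configurable
  (whole genome, or any interval set such as the profiled windows or a
  blacklist-subtracted territory); whether blacklist territory should be
  excluded from the counts is left as a flag since either convention is
  defensible.

## Problem sizes

Test and verification runs use cohorts the package can simulate in
seconds-to-minutes while leaving the statistics well-powered: 2,000-dyad /
0.6-Mb cohorts (~17,000 in-window mutations) for rotational-recovery
replicates, 20,000-dyad / 3.4-Mb cohorts (~1.0–1.5 million in-window
mutations) for curvature recovery and stratified comparisons, 10,000 reads
per assay for convention round-trips, and 100 random ≤ 5-kb tracks for the
dyad-caller oracle. These sizes are the package's chosen study conditions;
recovery tolerances (±0.5 bp on the dominant period, 25% on the second
derivative) were fixed alongside them.

## Known limitations

* The positioning-score normalization of the upstream track (likelihood
  relative to nucleosome-free background) is a property of the input, not
  recomputed here.
* Expected models are trinucleotide-only; pentanucleotide or
  strand-asymmetric context models are out of scope.
* The axis-inversion comparison is sensitive to overall profile level, not
  shape; shape differences with equal levels are better served by the
  binned chi-square.
* Profiles are strandless and plotted in reference orientation; no
  mirroring is applied.
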