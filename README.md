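# nucsig — nucleosome-centered mutation-signature analysis

UV-induced mutations in melanoma are not uniformly distributed: within
strongly positioned nucleosomes, mutation density oscillates with a ~10 bp
period that tracks the rotational setting of the DNA on the histone octamer
(peaks at outward-facing dinucleotides), and rises toward the nucleosome
dyad, producing an overarching "translational curvature" across the 147-bp
core particle. Elevated cyclobutane pyrimidine dimer (CPD) formation at
outward settings explains the oscillation; steric hindrance of nucleotide
excision repair (NER) toward the dyad explains the curvature.

`nucsig` is an R package plus a set of analysis drivers for dissecting such
signals. It is aimed at computational genomicists working with somatic
mutation tables (ICGC dialect), per-base nucleosome positioning-score
tracks, and UV lesion/repair sequencing reads (CPD-seq, XR-seq,
HS-Damage-seq). The pipeline:

1. **Dyad calling** — greedy selection of the highest positioning score with
   a 117-bp exclusion radius around each call; strong (score ≥ 10) and weak
   (−40 ≤ score ≤ −5) classes; ENCODE-blacklist filtering of the full
   147-bp window.
2. **Dyad-centered profiles** — per-offset event counts over −73..+73
   (or any half-width) around all dyads, for mutations or lesion dinucleotide
   positions, optionally split by transcribed vs non-transcribed strand.
3. **Context normalization** — a trinucleotide expected-mutation model:
   `freq(t)` = share of mutations in context `t`;
   `rate(t) = freq(t) · N / genome_count(t)`; the expected profile is
   `E[o] = Σ_dyads rate(trinuc at dyad + o)` and the **mutation enrichment**
   is `O[o] / E[o]`. The model is refit on every analyzed subset.
4. **Periodicity and curvature** — Lomb–Scargle periodogram of the
   (mean-centered, possibly masked) profile with long-period exclusion
   (> 100 bp), and a quadratic fit `y = a·x² + b·x + c` whose second
   derivative `2a` quantifies translational curvature (`a < 0` =
   dyad-peaked); a stratified subsampling survey tests the robustness of the
   dominant period at acral-melanoma-like mutation counts.
5. **Stratification statistics** — chromatin-state / histone-peak /
   transcription-quartile strata with a ≥ 100 mutations-per-bp power
   threshold, the axis-inversion Kruskal–Wallis procedure with Dunn's
   post-hoc test, and a 16-bin (~10 bp) chi-square that compares count
   profiles with the rotational oscillation binned away.

A first-class synthetic-data module generates genomes, dyads, mutation
tables, and assay reads with injected rotational (cosine, period 10.3 bp)
and translational (quadratic) signal, so the entire pipeline is testable
with no external downloads.

## Worked example

The numbered drivers under `analysis/` run the whole study on a simulated
cohort (5,000 strongly positioned nucleosomes, ~116,000 dipyrimidine
mutations from 20 donors, planted amplitude A = 0.3 at 10.3 bp and
quadratic depth c_q = 0.1):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_call_nucleosomes.R
Rscript analysis/03_mutation_enrichment.R
Rscript analysis/04_lesion_repair.R
Rscript analysis/05_stratification.R
```

Output of the core analysis (03):

```
116472 dipyrimidine-context SNVs enter the analysis
dominant enrichment period: 10.29 bp (planted 10.3)
normalized curvature 2a = -5.4e-05 (dyad-peaked: a < 0 is TRUE)
subsampling survey: 100.0% of 200 subsets share the full-set period (10.29 bp)
```

The dominant Lomb–Scargle period recovers the planted helical repeat to the
frequency-grid resolution; the negative fitted `a` says mutation enrichment
peaks at the dyad; and 1%-scale subsets still detect the same period, so a
failure to see periodicity in a 100-fold smaller cohort would not be a
power artifact. The stratified run (05) plants descending curvature across
Low/Medium/High transcription cohorts and recovers strictly descending
|2a| (−1.09e−4, −6.0e−5, −2.2e−5), a significant axis-inversion
Kruskal–Wallis (p = 0.022) with Low-vs-High the most divergent Dunn pair,
and a 16-bin chi-square between the extremes of p ≈ 1e−43. The lesion run
(04) recovers the 10.3-bp period from normalized CPD enrichment and a
positive repair curvature (2a = +1.2e−4) from XR-seq reads simulated with a
repair deficit toward the dyad.

Each profile is a TSV of `offset, value, n_nucleosomes` under `results/`.

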