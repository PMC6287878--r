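#!/usr/bin/env Rscript
# Lesion formation and repair across the nucleosome: CPD-seq enrichment
# (cells over naked DNA), mutagenic-CPD (mCPD) filtering, XR-seq repair
# normalized by naked HS-Damage-seq, and the extended 1000-bp window that
# shows neighboring nucleosomes.

suppressMessages(library(nucsig))

datadir <- "results/data"
genome <- read_genome_fasta(file.path(datadir, "genome.fa"))
dyads <- read_dyads_bed(file.path("results", "dyads_called.bed"))

read_assay <- function(stem, assay) {
  bed <- read_bed6(file.path(datadir, stem))
  extract_lesion_positions(bed, assay, genome = genome)
}

cpd_cells <- read_assay("cpdseq_cells.bed", "cpdseq")
cpd_naked <- read_assay("cpdseq_naked.bed", "cpdseq")
cpd <- normalized_lesion_profile(cpd_cells, cpd_naked, dyads)
pg_cpd <- periodogram(cpd, exclusion_max = 100)
message(sprintf("CPD enrichment dominant period: %.2f bp",
                pg_cpd$dominant_period))

mcpd <- normalized_lesion_profile(filter_mcpd(cpd_cells),
                                  filter_mcpd(cpd_naked), dyads,
                                  kind = "mcpd_enrichment")
message(sprintf("mCPD records: %d of %d CPDs (TT dimers removed)",
                nrow(filter_mcpd(cpd_cells)), nrow(cpd_cells)))

xr <- read_assay("xrseq_cells.bed", "xrseq")
hs_naked <- read_assay("hsdamageseq_naked.bed", "hsdamageseq")
rep_prof <- repair_profile(xr, hs_naked, dyads)
fit_rep <- fit_quadratic(rep_prof, normalize = TRUE)
message(sprintf("repair curvature 2a = %.3g", fit_rep$second_derivative))

ext <- profile_events(
  data.table::data.table(chrom = rep(cpd_cells$chrom, 2),
                         pos0 = c(cpd_cells$five_prime,
                                  cpd_cells$three_prime)),
  dyads, half_width = 500, kind = "cpd_extended")

write_profile_tsv(cpd, "results/cpd_enrichment.tsv")
write_profile_tsv(mcpd, "results/mcpd_enrichment.tsv")
write_profile_tsv(rep_prof, "results/repair_profile.tsv")
write_profile_tsv(ext, "results/cpd_extended_1000bp.tsv")
write_fit_tsv(fit_rep, "results/repair_curvature_fit.tsv")
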