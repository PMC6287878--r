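#!/usr/bin/env Rscript
# Simulate the study cohort: a genome with strongly positioned nucleosomes,
# a melanoma-like mutation table with planted 10.3-bp rotational periodicity
# and dyad-peaked translational curvature, and lesion/repair reads for the
# three assay conventions. Everything downstream reads the files written
# here.

suppressMessages(library(nucsig))

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(genome_length = 1500000L, n_dyads = 5000L,
                        base_mut_rate = 0.005, n_donors = 20L,
                        rot_amplitude = 0.3, rot_period = 10.3,
                        curv_coeff = 0.1, seed = 20240901L)
print(cfg)

gen <- generate_genome(cfg)
write_genome_fasta(gen, file.path(outdir, "genome.fa"))
write_dyads_bed(gen$dyads, file.path(outdir, "dyads_planted.bed"))

track <- synthetic_score_track(gen, seed = cfg$seed)
write_score_track_bedgraph(track, file.path(outdir, "scores.bedGraph"))

mut <- generate_mutations(gen)
write_icgc_tsv(mut, file.path(outdir, "mutations.tsv"))
message(sprintf("simulated %d mutations from %d donors over %d dyads",
                nrow(mut), cfg$n_donors, nrow(gen$dyads)))

# lesion formation follows the mutation-like signal; excision repair keeps
# the rotational oscillation but is depleted toward the dyad (steric
# hindrance), so its reads are drawn with inverted translational curvature
repair_cfg <- cfg
repair_cfg$curv_coeff <- -0.3
for (assay in c("cpdseq", "xrseq", "hsdamageseq")) {
  cfg_a <- if (assay == "xrseq") repair_cfg else cfg
  cells <- generate_lesion_reads(gen, config = cfg_a, assay = assay,
                                 n_reads = 200000L)
  naked <- generate_lesion_reads(gen, assay = assay, n_reads = 200000L,
                                 flat = TRUE, seed_offset = 9L)
  write_reads_bed(cells, file.path(outdir, sprintf("%s_cells.bed", assay)))
  write_reads_bed(naked, file.path(outdir, sprintf("%s_naked.bed", assay)))
}
message("wrote cohort files under ", outdir)
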