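# shared fixture builders; everything is generated in code at test time

# small synthetic cohort: genome + dyads + annotated internal mutation table
make_cohort <- function(genome_length = 3e5, n_dyads = 1000, seed = 1,
                        rot_amplitude = 0.3, curv_coeff = 0.1,
                        base_mut_rate = 0.005, n_donors = 20, ...) {
  cfg <- synthetic_config(genome_length = genome_length, n_dyads = n_dyads,
                          seed = seed, rot_amplitude = rot_amplitude,
                          curv_coeff = curv_coeff,
                          base_mut_rate = base_mut_rate,
                          n_donors = n_donors, ...)
  gen <- generate_genome(cfg)
  mut <- suppressMessages(
    annotate_context(mutations_from_icgc(generate_mutations(gen)), gen))
  list(cfg = cfg, gen = gen, mut = mut)
}

# naive O(n^2) greedy dyad caller: full re-scan for the maximum each round
naive_greedy_dyads <- function(pos, score, min_score, radius) {
  alive <- score >= min_score
  called <- integer(0)
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[order(-score[cand], pos[cand])][1]
    called <- c(called, pos[best])
    alive <- alive & abs(pos - pos[best]) > radius
  }
  sort(called)
}

# random sparse score track on one chromosome
random_track <- function(n_pos = 200, span = 5000, chrom = "chr1") {
  pos <- sort(sample.int(span, n_pos)) - 1L
  # duplicate scores on purpose to exercise tie-breaking
  score <- round(runif(n_pos, -50, 30), 1)
  data.table::data.table(chrom = chrom, pos = pos, score = score)
}

# ICGC-dialect table with given rows
icgc_row <- function(donor = "DO1", specimen = "SP1", chrom = "chrS",
                     start = 100L, ref = "C", alt = "T",
                     assembly = "GRCh37") {
  data.table::data.table(
    icgc_donor_id = donor, icgc_specimen_id = specimen, chromosome = chrom,
    chromosome_start = start, chromosome_end = start,
    reference_genome_allele = ref, mutated_to_allele = alt,
    mutation_type = "single base substitution",
    assembly_version = assembly)
}

# genome object from a literal sequence string
literal_genome <- function(sequence, chrom = "chrS") {
  structure(list(chrom = chrom, sequence = sequence,
                 dyads = data.table::data.table(
                   chrom = character(0), position = integer(0),
                   score = numeric(0), strength = character(0))),
            class = "synthetic_genome")
}
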