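test_that("assay conventions place lesions as specified, strand-aware", {
  # HS-Damage-seq: + strand read ending at 100 -> lesion bases 98,99
  r <- data.table::data.table(chrom = "chrS", start = 0L, end = 100L,
                              strand = "+")
  l <- extract_lesion_positions(r, "hsdamageseq")
  expect_equal(c(l$five_prime, l$three_prime), c(98L, 99L))
  # - strand read [100, 200): 3' end at 100, last two bases 100,101
  r2 <- data.table::data.table(chrom = "chrS", start = 100L, end = 200L,
                               strand = "-")
  l2 <- extract_lesion_positions(r2, "hsdamageseq")
  expect_equal(l2$five_prime, 101L)   # 5'-most base on the minus strand
  expect_equal(l2$three_prime, 100L)
  # XR-seq offsets (8,7): + strand 3' end at 200 -> lesion at 192,193
  r3 <- data.table::data.table(chrom = "chrS", start = 150L, end = 200L,
                               strand = "+")
  l3 <- extract_lesion_positions(r3, "xrseq", xr_offset = c(8L, 7L))
  expect_equal(c(l3$five_prime, l3$three_prime), c(192L, 193L))
  # CPD-seq: the deposited interval is the dinucleotide
  r4 <- data.table::data.table(chrom = "chrS", start = 55L, end = 57L,
                               strand = "+")
  l4 <- extract_lesion_positions(r4, "cpdseq")
  expect_equal(c(l4$five_prime, l4$three_prime), c(55L, 56L))
})

test_that("reads shorter than the required offset are skipped and logged", {
  r <- data.table::data.table(chrom = "chrS", start = c(0L, 10L),
                              end = c(5L, 11L), strand = "+")
  out <- suppressMessages(extract_lesion_positions(r, "xrseq"))
  expect_equal(nrow(out), 0L)
})

test_that("generator-to-extractor round trip is exact for every assay", {
  co <- make_cohort(genome_length = 2e5, n_dyads = 600, seed = 41,
                    n_donors = 1)
  for (assay in c("cpdseq", "xrseq", "hsdamageseq")) {
    reads <- generate_lesion_reads(co$gen, assay = assay, n_reads = 2000)
    planted <- attr(reads, "lesions")
    expect_true(all(c("+", "-") %in% reads$strand))
    got <- extract_lesion_positions(reads, assay, genome = co$gen)
    expect_identical(got$five_prime, planted$five_prime)
    expect_identical(got$three_prime, planted$three_prime)
    expect_identical(got$dinuc, planted$dinuc)
    # every planted dinucleotide is a dipyrimidine on its own strand
    expect_true(all(got$dinuc %in% c("CC", "CT", "TC", "TT")))
  }
})

test_that("filter_mcpd removes TT and non-dipyrimidine dinucleotides", {
  l <- data.table::data.table(chrom = "chrS", five_prime = 1:4,
                              three_prime = 2:5, strand = "+",
                              dinuc = c("TT", "CC", "CT", "GA"),
                              assay = "cpdseq")
  out <- suppressMessages(filter_mcpd(l))
  expect_setequal(out$dinuc, c("CC", "CT"))
  only_tt <- l[l$dinuc == "TT"]
  expect_equal(nrow(filter_mcpd(only_tt)), 0L)
})

test_that("each lesion contributes 2 inside the window and 1 at the edge", {
  dy <- data.table::data.table(chrom = "chrS", position = 1000L,
                               score = 15, strength = "strong")
  l <- data.table::data.table(chrom = "chrS",
                              five_prime = c(1000L, 1073L, 926L),
                              three_prime = c(1001L, 1074L, 927L),
                              strand = "+", dinuc = "TT", assay = "cpdseq")
  counts <- nucsig:::lesion_base_counts(l, dy)
  # brute force: window covers offsets -73..+73 = positions 927..1073
  expect_equal(sum(counts$values), 2 + 1 + 1)
  expect_equal(counts$values[counts$offsets == 0], 1)
  expect_equal(counts$values[counts$offsets == 73], 1)
  expect_equal(counts$values[counts$offsets == -73], 1)
})

test_that("identical numerator and denominator give a profile of ones", {
  co <- make_cohort(genome_length = 1e5, n_dyads = 300, seed = 42,
                    n_donors = 1)
  reads <- generate_lesion_reads(co$gen, assay = "cpdseq", n_reads = 5000)
  l <- extract_lesion_positions(reads, "cpdseq", genome = co$gen)
  p <- suppressMessages(normalized_lesion_profile(l, l, co$gen$dyads))
  expect_true(all(p$values[!is.na(p$values)] == 1))
})

test_that("depth normalization cancels a doubled naked library", {
  co <- make_cohort(genome_length = 1e5, n_dyads = 300, seed = 43,
                    n_donors = 1)
  cells <- extract_lesion_positions(
    generate_lesion_reads(co$gen, assay = "cpdseq", n_reads = 4000),
    "cpdseq", genome = co$gen)
  naked <- extract_lesion_positions(
    generate_lesion_reads(co$gen, assay = "cpdseq", n_reads = 3000,
                          flat = TRUE, seed_offset = 9L),
    "cpdseq", genome = co$gen)
  p1 <- suppressMessages(normalized_lesion_profile(cells, naked,
                                                   co$gen$dyads))
  p2 <- suppressMessages(normalized_lesion_profile(cells,
                                                   rbind(naked, naked),
                                                   co$gen$dyads))
  expect_equal(p1$values, p2$values)
})

test_that("rotational signal in cellular lesions survives normalization", {
  co <- make_cohort(genome_length = 4e5, n_dyads = 1500, seed = 44,
                    rot_amplitude = 0.4, curv_coeff = 0, n_donors = 1)
  cells <- extract_lesion_positions(
    generate_lesion_reads(co$gen, assay = "cpdseq", n_reads = 2e5),
    "cpdseq", genome = co$gen)
  naked <- extract_lesion_positions(
    generate_lesion_reads(co$gen, assay = "cpdseq", n_reads = 2e5,
                          flat = TRUE, seed_offset = 9L),
    "cpdseq", genome = co$gen)
  p <- suppressMessages(normalized_lesion_profile(cells, naked,
                                                  co$gen$dyads))
  pg <- periodogram(p, exclusion_max = 100)
  expect_lt(abs(pg$dominant_period - co$cfg$rot_period), 0.5)
})

test_that("repair deficit toward the dyad yields positive curvature", {
  cfg <- synthetic_config(genome_length = 4e5, n_dyads = 1500, seed = 45,
                          rot_amplitude = 0, curv_coeff = 0)
  gen <- generate_genome(cfg)
  cfg_dip <- cfg; cfg_dip$curv_coeff <- -0.4  # fewer events near the dyad
  xr <- extract_lesion_positions(
    generate_lesion_reads(gen, config = cfg_dip, assay = "xrseq",
                          n_reads = 2e5),
    "xrseq", genome = gen)
  hs_naked <- extract_lesion_positions(
    generate_lesion_reads(gen, config = cfg, assay = "hsdamageseq",
                          n_reads = 2e5, flat = TRUE, seed_offset = 9L),
    "hsdamageseq", genome = gen)
  p <- suppressMessages(repair_profile(xr, hs_naked, gen$dyads))
  fit <- fit_quadratic(p, normalize = TRUE)
  expect_gt(fit$a, 0)
})

test_that("reverse-complementing genome and reads mirrors the profile", {
  co <- make_cohort(genome_length = 1e5, n_dyads = 300, seed = 46,
                    n_donors = 1)
  reads <- generate_lesion_reads(co$gen, assay = "cpdseq", n_reads = 20000)
  l <- extract_lesion_positions(reads, "cpdseq", genome = co$gen)
  naked <- extract_lesion_positions(
    generate_lesion_reads(co$gen, assay = "cpdseq", n_reads = 20000,
                          flat = TRUE, seed_offset = 9L),
    "cpdseq", genome = co$gen)
  p <- suppressMessages(normalized_lesion_profile(l, naked, co$gen$dyads))

  L <- nchar(co$gen$sequence)
  rc <- function(lt) data.table::data.table(
    chrom = lt$chrom,
    five_prime = L - 1L - lt$five_prime,
    three_prime = L - 1L - lt$three_prime,
    strand = ifelse(lt$strand == "+", "-", "+"),
    dinuc = lt$dinuc, assay = lt$assay)
  dy_rc <- data.table::data.table(chrom = co$gen$dyads$chrom,
                                  position = L - 1L - co$gen$dyads$position,
                                  score = co$gen$dyads$score,
                                  strength = co$gen$dyads$strength)
  p_rc <- suppressMessages(normalized_lesion_profile(rc(l), rc(naked),
                                                     dy_rc))
  expect_equal(p_rc$values, rev(p$values))
})
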