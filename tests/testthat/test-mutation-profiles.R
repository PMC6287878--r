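test_that("load_mutations keeps SNVs, skips indels, dedups per donor", {
  tab <- rbind(
    icgc_row("DO1", "SP1", start = 100L, ref = "C", alt = "T"),
    icgc_row("DO1", "SP2", start = 100L, ref = "C", alt = "T"),  # same donor, 2nd specimen
    icgc_row("DO1", "SP1", start = 200L, ref = "T", alt = "C"),
    icgc_row("DO2", "SP3", start = 100L, ref = "C", alt = "T"),  # other donor kept
    icgc_row("DO2", "SP3", start = 300L, ref = "G", alt = "A"),
    icgc_row("DO2", "SP3", start = 400L, ref = "CA", alt = "T"), # indel
    icgc_row("DO2", "SP3", start = 500L, ref = "A", alt = "ATT") # indel
  )
  f <- tempfile(fileext = ".tsv")
  data.table::fwrite(tab, f, sep = "\t")
  out <- suppressMessages(load_mutations(f))
  log <- attr(out, "log")
  expect_equal(nrow(out), 4L)
  expect_equal(log$n_non_snv_skipped, 2L)
  expect_equal(log$n_duplicates_removed, 1L)
  # positions converted to 0-based
  expect_equal(sort(out[out$donor == "DO1", ]$pos0), c(99L, 199L))

  # empty file with header only
  f2 <- tempfile(fileext = ".tsv")
  data.table::fwrite(tab[0], f2, sep = "\t")
  expect_equal(nrow(suppressMessages(load_mutations(f2))), 0L)

  # unknown assembly tags skipped when a whitelist is given
  tab3 <- rbind(icgc_row(start = 100L), icgc_row(start = 200L,
                                                 assembly = "hg999"))
  f3 <- tempfile(fileext = ".tsv")
  data.table::fwrite(tab3, f3, sep = "\t")
  out3 <- suppressMessages(load_mutations(f3, assembly = "GRCh37"))
  expect_equal(nrow(out3), 1L)
  expect_equal(attr(out3, "log")$n_assembly_skipped, 1L)
})

test_that("annotate_context computes trinuc and the two-strand dipyr rule", {
  #          123456789
  g <- literal_genome("ATCAGACGT")
  mk <- function(pos1, ref) data.table::data.table(
    donor = "DO1", chrom = "chrS", pos0 = pos1 - 1L, ref = ref, alt = "N")
  # pos 3 = C with 5' neighbour T -> TC dipyrimidine
  out <- annotate_context(mk(3L, "C"), g)
  expect_equal(out$trinuc, "TCA")
  expect_true(out$dipyr)
  # pos 5 = G with 3' neighbour A (GA) -> reverse strand TC -> dipyr
  out <- annotate_context(mk(5L, "G"), g)
  expect_equal(out$trinuc, "AGA")
  expect_true(out$dipyr)
  # ACA center C flanked by purines on both strands -> not dipyr
  g2 <- literal_genome("AACAA")
  out <- annotate_context(data.table::data.table(
    donor = "DO1", chrom = "chrS", pos0 = 2L, ref = "C", alt = "T"), g2)
  expect_equal(out$trinuc, "ACA")
  expect_false(out$dipyr)
  # reference mismatch is excluded and logged
  bad <- suppressMessages(annotate_context(mk(3L, "G"), g))
  expect_equal(nrow(bad), 0L)
  expect_equal(attr(bad, "log")$n_ref_mismatch, 1L)
  # position at the chromosome end is excluded
  edge <- suppressMessages(annotate_context(mk(1L, "A"), g))
  expect_equal(nrow(edge), 0L)
})

test_that("profile_events counts per-offset with half-open window edges", {
  dy <- data.table::data.table(chrom = "chrS", position = 1000L,
                               score = 15, strength = "strong")
  ev <- data.table::data.table(chrom = "chrS",
                               pos0 = c(927L, 1000L, 1073L, 1074L, 926L))
  p <- profile_events(ev, dy)
  expect_equal(p$values[p$offsets == -73], 1)
  expect_equal(p$values[p$offsets == 0], 1)
  expect_equal(p$values[p$offsets == 73], 1)
  expect_equal(sum(p$values), 3)  # 1074 and 926 fall outside the window

  none <- profile_events(ev[0], dy)
  expect_true(all(none$values == 0))
  expect_equal(length(none$values), 147L)
})

test_that("profile totals conserve in-window event counts (brute force)", {
  co <- make_cohort(genome_length = 2e5, n_dyads = 600, seed = 31,
                    n_donors = 5)
  p <- profile_events(co$mut, co$gen$dyads)
  brute <- sum(vapply(co$mut$pos0, function(x)
    any(abs(x - co$gen$dyads$position) <= 73), logical(1)))
  expect_equal(sum(p$values), brute)
})

test_that("extended half_width run reproduces the core-particle counts", {
  co <- make_cohort(genome_length = 2e5, n_dyads = 600, seed = 32,
                    n_donors = 5)
  core <- profile_events(co$mut, co$gen$dyads, half_width = 73)
  ext <- profile_events(co$mut, co$gen$dyads, half_width = 500)
  sel <- ext$offsets >= -73 & ext$offsets <= 73
  expect_equal(ext$values[sel], core$values)
})

test_that("TS/NTS assignment follows the pyrimidine-strand rule", {
  # gene on + strand covering the dyad; template strand is "-"
  dy <- data.table::data.table(chrom = "chrS", position = 1000L,
                               score = 15, strength = "strong")
  genes <- data.table::data.table(chrom = "chrS", start = 800L, end = 1200L,
                                  strand = "+", gene_id = "G1")
  mut_c <- data.table::data.table(donor = "DO1", chrom = "chrS", pos0 = 1000L,
                                  ref = "C", alt = "T", trinuc = "TCA",
                                  dipyr = TRUE)
  res <- profile_events_stranded(mut_c, dy, genes)
  # ref C: pyrimidine on "+", which is not the template of a "+" gene -> NTS
  expect_equal(sum(res$NTS$values), 1)
  expect_equal(sum(res$TS$values), 0)
  # ref G: pyrimidine on "-" = template -> TS
  mut_g <- data.table::data.table(donor = "DO1", chrom = "chrS", pos0 = 1000L,
                                  ref = "G", alt = "A", trinuc = "AGA",
                                  dipyr = TRUE)
  res2 <- profile_events_stranded(mut_g, dy, genes)
  expect_equal(sum(res2$TS$values), 1)
  expect_equal(sum(res2$NTS$values), 0)

  expect_error(profile_events_stranded(mut_c, dy, NULL), "gene set")

  # dyad inside two genes of opposite strand is dropped
  genes2 <- rbind(genes, data.table::data.table(
    chrom = "chrS", start = 900L, end = 1100L, strand = "-",
    gene_id = "G2"))
  res3 <- suppressMessages(profile_events_stranded(mut_c, dy, genes2))
  expect_equal(res3$log$n_dyads_ambiguous, 1L)
  expect_equal(sum(res3$TS$values) + sum(res3$NTS$values), 0)
})

test_that("symmetric planted strands give balanced TS/NTS totals", {
  co <- make_cohort(genome_length = 2e5, n_dyads = 600, seed = 33,
                    n_donors = 10)
  genes <- data.table::data.table(chrom = "chrS", start = 0L,
                                  end = nchar(co$gen$sequence),
                                  strand = "+", gene_id = "G1")
  res <- profile_events_stranded(co$mut, co$gen$dyads, genes)
  ts <- sum(res$TS$values); nts <- sum(res$NTS$values)
  # generator is strand-symmetric: C/T refs vs G/A refs are exchangeable
  expect_lt(abs(ts - nts) / (ts + nts), 0.05)
})

test_that("profile TSV round-trip preserves values and masking", {
  p <- position_profile(c(rep(1.5, 70), NA, rep(2.25, 76)),
                        n_nucleosomes = 10L, kind = "enrichment")
  f <- tempfile(fileext = ".tsv")
  write_profile_tsv(p, f, header_lines = "demo")
  back <- read_profile_tsv(f)
  expect_equal(back$values, p$values)
  expect_equal(back$kind, "enrichment")
  expect_equal(back$n_nucleosomes, 10L)
})
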