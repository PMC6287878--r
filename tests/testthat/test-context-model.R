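test_that("frequencies are mutation-context counts over the total", {
  g <- literal_genome(paste0(strrep("ACAG", 30), strrep("TTTT", 25)))
  mut <- data.table::data.table(
    donor = "DO1", chrom = "chrS", pos0 = c(10L, 20L, 30L, 40L),
    ref = c("C", "C", "T", "T"), alt = "N",
    trinuc = c("ACA", "ACA", "TTT", "TTT"), dipyr = TRUE)
  m <- fit_trinuc_model(mut, g)
  expect_equal(unname(m$freq[c("ACA", "TTT")]), c(0.5, 0.5))
  expect_equal(sum(m$freq), 1)
})

test_that("dipyr-only model puts no mass on contexts without dipyrimidines", {
  expect_false(trinuc_has_dipyr("ACA"))  # reverse strand TGT: no YY pair
  expect_true(trinuc_has_dipyr("TCA"))   # TC on the reference strand
  expect_true(trinuc_has_dipyr("AGA"))   # GA -> TC on the reverse strand
  co <- make_cohort(genome_length = 1e5, n_dyads = 300, seed = 17,
                    n_donors = 5)
  m <- fit_trinuc_model(co$mut, co$gen, dipyr_only = TRUE)
  no_dipyr <- !trinuc_has_dipyr(names(m$freq))
  expect_true(all(m$freq[no_dipyr] == 0))
  expect_true(all(m$rate[no_dipyr] == 0))
})

test_that("rate x genome_counts sums back to the mutation total exactly", {
  co <- make_cohort(genome_length = 5e4, n_dyads = 150, seed = 18,
                    n_donors = 5)
  m <- fit_trinuc_model(co$mut, co$gen, dipyr_only = TRUE)
  expect_equal(sum(m$rate * m$genome_counts), m$n_mutations)
  # and within a restricted territory, against that territory's counts
  terr <- dyad_windows(co$gen$dyads)
  mt <- fit_trinuc_model(co$mut, co$gen, dipyr_only = TRUE,
                         territory = terr)
  expect_equal(sum(mt$rate * mt$genome_counts), mt$n_mutations)
})

test_that("expected_profile evaluates rate over dyad-window contexts", {
  # single dyad at position 100 in a known sequence; offset 0 context = ACA
  seqs <- strsplit(strrep("ACGT", 60), "")[[1]]
  seqs[100:102] <- c("A", "C", "A")  # 0-based 99..101, center 100
  g <- literal_genome(paste(seqs, collapse = ""))
  dy <- data.table::data.table(chrom = "chrS", position = 100L,
                               score = 15, strength = "strong")
  rate <- stats::setNames(numeric(64), nucsig:::all_trinucs())
  rate["ACA"] <- 0.5
  model <- structure(list(freq = rate / sum(rate), genome_counts = rate,
                          rate = rate, n_mutations = 1L,
                          dipyr_only = FALSE), class = "trinuc_model")
  p <- expected_profile(model, dy, g)
  expect_equal(p$values[p$offsets == 0], 0.5)
})

test_that("uniform rates over any genome give a flat expected profile", {
  co <- make_cohort(genome_length = 1e5, n_dyads = 300, seed = 19,
                    n_donors = 2)
  rate <- stats::setNames(rep(0.01, 64), nucsig:::all_trinucs())
  model <- structure(list(freq = rate / sum(rate), genome_counts = rate,
                          rate = rate, n_mutations = 1L,
                          dipyr_only = FALSE), class = "trinuc_model")
  p <- expected_profile(model, co$gen$dyads, co$gen)
  expect_equal(length(unique(round(p$values, 9))), 1L)
})

test_that("enrichment is the per-offset ratio with zero-expectation masking", {
  a <- position_profile(rep(4, 147), kind = "observed")
  b <- position_profile(rep(4, 147), kind = "expected")
  expect_true(all(enrichment(a, b)$values == 1))
  a$values[74] <- 10; b$values[74] <- 5
  expect_equal(enrichment(a, b)$values[74], 2)
  b$values[10] <- 0
  e <- suppressMessages(enrichment(a, b))
  expect_true(is.na(e$values[10]))
})

test_that("thinning in-window mutations puts expected above observed", {
  co <- make_cohort(genome_length = 3e5, n_dyads = 1000, seed = 23,
                    rot_amplitude = 0, curv_coeff = 0, n_donors = 20)
  off <- nucsig:::nearest_dyad_offset(co$mut$pos0,
                                      sort(co$gen$dyads$position), 73L)
  inw <- !is.na(off)
  # remove half the in-window mutations: nucleosome territory now less
  # mutated than the genome average the model is fit on
  drop <- which(inw)[seq_len(floor(sum(inw) / 2))]
  thinned <- co$mut[-drop]
  model <- fit_trinuc_model(thinned, co$gen, dipyr_only = TRUE)
  obs <- profile_events(thinned, co$gen$dyads)
  expd <- expected_profile(model, co$gen$dyads, co$gen)
  expect_gt(mean(expd$values), mean(obs$values))
  expect_gt(mean(expd$values > obs$values), 0.95)
})

test_that("refit on the profiled subset self-normalizes to mean ~1", {
  co <- make_cohort(genome_length = 3e5, n_dyads = 1000, seed = 24,
                    n_donors = 20)
  off <- nucsig:::nearest_dyad_offset(co$mut$pos0,
                                      sort(co$gen$dyads$position), 73L)
  mw <- co$mut[!is.na(off)]
  model <- fit_trinuc_model(mw, co$gen, dipyr_only = TRUE,
                            territory = dyad_windows(co$gen$dyads))
  obs <- profile_events(mw, co$gen$dyads)
  expd <- expected_profile(model, co$gen$dyads, co$gen)
  expect_equal(sum(expd$values), sum(obs$values), tolerance = 1e-9)
  e <- enrichment(obs, expd)
  expect_equal(mean(e$values, na.rm = TRUE), 1, tolerance = 0.03)
})

test_that("pure context bias creates no spurious short periodicity", {
  bias <- stats::setNames(rep(1, 64), nucsig:::all_trinucs())
  bias[grepl("TT", names(bias))] <- 3  # strong sequence bias, no rotation
  co <- make_cohort(genome_length = 3e5, n_dyads = 1000, seed = 25,
                    rot_amplitude = 0, curv_coeff = 0, n_donors = 20,
                    context_bias = bias)
  model <- fit_trinuc_model(co$mut, co$gen, dipyr_only = TRUE)
  obs <- profile_events(co$mut, co$gen$dyads)
  expd <- expected_profile(model, co$gen$dyads, co$gen)
  e <- enrichment(obs, expd)
  pg <- periodogram(e, exclusion_max = 100)
  env <- ls_null_envelope(e, n_perm = 100, prob = 0.95, seed = 7)
  expect_lt(pg$max_power, env)
})
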