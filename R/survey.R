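#' 147-bp windows around dyads as a territory table
#' @param dyads dyad `data.table`
#' @param half_width half-width in bp
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open)
#' @export
dyad_windows <- function(dyads, half_width = 73L) {
  data.table(chrom = dyads$chrom,
             start = dyads$position - as.integer(half_width),
             end = dyads$position + as.integer(half_width) + 1L)
}

#' Subsampling survey of enrichment periodicity
#'
#' Repeatedly draws small mutation subsets (default ~1/100 of the input,
#' matching a cohort with ~100-fold fewer mutations), keeping the C:T
#' pyrimidine-class ratio of the full set by sampling each class
#' proportionally without replacement. For every subset the expected model
#' is refit on the subset, the subset's enrichment profile is built, and the
#' dominant Lomb-Scargle period (periods > `exclusion_max` excluded) is
#' recorded, rounded to the nearest bp — so a dominant period in
#' \[9.5, 10.5\] counts as 10 bp.
#'
#' @param mutations annotated mutations ([annotate_context()]); with
#'   `dipyr_only` only dipyrimidine-context records are used
#' @param dyads dyad `data.table`
#' @param genome genome object
#' @param fraction fraction of mutations per subset
#' @param n_subsets number of subsets
#' @param seed integer seed (subset draws are deterministic given it)
#' @param exclusion_max long-period exclusion in bp
#' @param half_width window half-width
#' @param dipyr_only restrict to dipyrimidine-context mutations
#' @param territory reference territory for the context model; default = the
#'   dyad windows themselves
#' @return list: `histogram` (table of rounded dominant periods),
#'   `dominant_periods`, `full_set_period`, `fraction_matching_full`
#'   (fraction of subsets whose rounded period equals the full set's), and
#'   `n_per_subset`
#' @export
subsample_survey <- function(mutations, dyads, genome, fraction = 0.01,
                             n_subsets = 1000L, seed = 1L,
                             exclusion_max = 100, half_width = 73L,
                             dipyr_only = TRUE, territory = NULL) {
  tn <- all_trinucs()
  mut <- as.data.table(mutations)
  if (dipyr_only) mut <- mut[dipyr %in% TRUE]
  mut <- mut[!is.na(trinuc) & trinuc %in% tn]
  N <- nrow(mut)
  if (round(fraction * N) < 50L)
    warning("subsample_survey: fewer than 50 mutations per subset; ",
            "period estimates will be underpowered")

  territory <- territory %||% dyad_windows(dyads, half_width)
  genome_counts <- territory_trinuc_counts(genome, territory)
  M <- offset_context_counts(dyads, genome, half_width)

  ctx_idx <- match(mut$trinuc, tn)
  hw <- as.integer(half_width)
  dy <- dyads[order(dyads$chrom, dyads$position)]
  off <- rep(NA_integer_, N)
  for (ch in intersect(unique(mut$chrom), unique(dy$chrom))) {
    mi <- which(mut$chrom == ch)
    off[mi] <- nearest_dyad_offset(mut$pos0[mi],
                                   dy$position[dy$chrom == ch], hw)
  }
  pyr_class <- ifelse(mut$ref %in% c("C", "G"), "C", "T")
  idx_c <- which(pyr_class == "C"); idx_t <- which(pyr_class == "T")
  n_c <- round(fraction * length(idx_c))
  n_t <- round(fraction * length(idx_t))

  dominant_for <- function(rows) {
    n <- length(rows)
    freq <- tabulate(ctx_idx[rows], nbins = 64) / n
    rate <- ifelse(genome_counts > 0, freq * n / genome_counts, 0)
    expd <- as.numeric(rate %*% M)
    o <- off[rows]
    obs <- tabulate(o[!is.na(o)] + hw + 1L, nbins = 2L * hw + 1L)
    enr <- ifelse(expd > 0, obs / expd, NA_real_)
    if (sum(!is.na(enr)) < 10L) return(NA_real_)  # degenerate tiny subset
    pg <- periodogram(position_profile(enr, hw, nrow(dy), "enrichment"),
                      exclusion_max = exclusion_max)
    pg$dominant_period
  }

  full_period <- dominant_for(seq_len(N))
  with_seed(seed, {
    dominant <- vapply(seq_len(n_subsets), function(i) {
      rows <- c(if (n_c > 0) sample(idx_c, n_c),
                if (n_t > 0) sample(idx_t, n_t))
      dominant_for(rows)
    }, numeric(1))
  })
  rounded <- round(dominant)
  list(histogram = table(rounded),
       dominant_periods = dominant,
       full_set_period = full_period,
       fraction_matching_full = mean(rounded == round(full_period),
                                     na.rm = TRUE),
       n_per_subset = n_c + n_t)
}
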