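#' Dyad-relative offset of positions to their nearest dyad
#'
#' @param pos integer vector of 0-based positions (single chromosome)
#' @param dyads sorted integer vector of 0-based dyad positions on the same
#'   chromosome
#' @param half_width maximum absolute offset; positions farther than this
#'   from every dyad get `NA`
#' @return integer vector of offsets in `-half_width..half_width` or `NA`
#' @export
nearest_dyad_offset <- function(pos, dyads, half_width = 73L) {
  if (length(dyads) == 0L) return(rep(NA_integer_, length(pos)))
  i <- findInterval(pos, dyads)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(dyads))
  d_lo <- abs(pos - dyads[lo])
  d_hi <- abs(pos - dyads[hi])
  nearer <- ifelse(d_hi < d_lo, hi, lo)
  off <- pos - dyads[nearer]
  off[abs(off) > half_width] <- NA_integer_
  as.integer(off)
}

context_weight <- function(trinuc, context_bias) {
  if (is.null(context_bias)) return(rep(1, length(trinuc)))
  w <- context_bias[trinuc]
  w[is.na(w)] <- 1
  unname(w)
}

#' Simulate somatic mutations over a synthetic genome
#'
#' Every dipyrimidine-context position is a candidate site. Within a donor,
#' each site mutates independently with probability
#' `base_mut_rate * context_bias(trinuc) * rot * curv` where the rotational
#' and translational factors apply only inside a dyad window (see
#' [synthetic_config()]); sampling is without replacement per site per donor.
#' Substitutions are pyrimidine transitions recorded on the reference strand
#' (C>T, T>C, and G>A, A>G for lesions on the reverse strand).
#'
#' @param genome a [generate_genome()] result
#' @param dyads optional dyad position vector (0-based); defaults to the
#'   genome's own dyads
#' @param config a [synthetic_config()]; defaults to the genome's config
#' @param dup_fraction fraction of emitted mutations duplicated under a
#'   second specimen of the same donor, to exercise per-donor deduplication
#' @return `data.table` in ICGC simple-somatic dialect: `icgc_donor_id`,
#'   `icgc_specimen_id`, `chromosome`, `chromosome_start` (1-based),
#'   `chromosome_end`, `reference_genome_allele`, `mutated_to_allele`,
#'   `mutation_type`, `assembly_version`
#' @export
generate_mutations <- function(genome, dyads = NULL, config = NULL,
                               dup_fraction = 0) {
  config <- config %||% genome$config
  validate_synthetic_config(config)
  if (is.null(dyads)) dyads <- genome$dyads$position
  L <- nchar(genome$sequence)
  bases <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]

  idx <- 2:(L - 1L)                       # 1-based interior positions
  dipyr <- is_dipyr_context(bases[idx - 1L], bases[idx], bases[idx + 1L])
  site_pos1 <- idx[dipyr]                 # 1-based eligible sites
  trinuc <- paste0(bases[site_pos1 - 1L], bases[site_pos1],
                   bases[site_pos1 + 1L])

  p <- config$base_mut_rate * context_weight(trinuc, config$context_bias)
  off <- nearest_dyad_offset(site_pos1 - 1L, sort(dyads), 73L)
  inw <- !is.na(off)
  if (any(inw)) {
    fac <- modulation_factors(-73:73, config)
    p[inw] <- p[inw] * fac[off[inw] + 74L]
  }
  p <- pmin(p, 1)

  alt_map <- c(C = "T", T = "C", G = "A", A = "G")
  ref <- bases[site_pos1]

  with_seed(config$seed + 1L, {
    out <- vector("list", config$n_donors)
    for (d in seq_len(config$n_donors)) {
      hit <- which(runif(length(p)) < p)
      if (length(hit) == 0L) { out[[d]] <- NULL; next }
      out[[d]] <- data.table(
        icgc_donor_id = sprintf("DO%04d", d),
        icgc_specimen_id = sprintf("SP%04d", d),
        chromosome = genome$chrom,
        chromosome_start = site_pos1[hit],
        chromosome_end = site_pos1[hit],
        reference_genome_allele = ref[hit],
        mutated_to_allele = unname(alt_map[ref[hit]]),
        mutation_type = "single base substitution",
        assembly_version = "GRCh37"
      )
    }
    muts <- data.table::rbindlist(out)
    if (dup_fraction > 0 && nrow(muts) > 0) {
      ndup <- ceiling(dup_fraction * nrow(muts))
      dup <- muts[sample.int(nrow(muts), ndup)]
      dup[, icgc_specimen_id := sub("SP", "SQ", icgc_specimen_id)]
      muts <- rbind(muts, dup)
    }
    setorder(muts, icgc_donor_id, chromosome_start)
    muts[]
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
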