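#' Convert assay reads to CPD lesion dinucleotide positions
#'
#' Applies the assay-specific lesion-position convention, strand-aware:
#' * `cpdseq` — the deposited read interval *is* the lesion dinucleotide;
#' * `hsdamageseq` — the lesion is the 2 bases immediately 5' of the read's
#'   3' end (the last two read bases in read orientation);
#' * `xrseq` — the lesion dinucleotide sits `xr_offset` = (d5, d3) bases
#'   upstream of the excision product's 3' end (default 8 and 7; inherited
#'   from the upstream XR-seq convention and therefore configurable).
#'
#' Reads shorter than the required offset are skipped with a logged count.
#'
#' @param reads `data.table` with `chrom`, `start`, `end` (0-based
#'   half-open), `strand`
#' @param assay one of `"cpdseq"`, `"xrseq"`, `"hsdamageseq"`
#' @param genome optional genome object; when given, each record carries the
#'   lesion-strand dinucleotide sequence
#' @param xr_offset two integers (5' and 3' lesion base distance upstream of
#'   the XR-seq read 3' end)
#' @return `data.table` of lesion records: `chrom`, `five_prime`,
#'   `three_prime` (0-based genomic positions of the dinucleotide's 5' and
#'   3' base *on the lesion strand*), `strand`, `dinuc` (NA without a
#'   genome), `assay`
#' @export
extract_lesion_positions <- function(reads,
                                     assay = c("cpdseq", "xrseq",
                                               "hsdamageseq"),
                                     genome = NULL, xr_offset = c(8L, 7L)) {
  assay <- match.arg(assay)
  if (is.null(reads) || nrow(reads) == 0L) return(empty_lesions())
  len <- reads$end - reads$start
  min_len <- switch(assay, cpdseq = 2L, hsdamageseq = 2L,
                    xrseq = xr_offset[1])
  ok <- len >= min_len
  if (any(!ok)) msg("extract_lesion_positions: skipped %d reads shorter than %d bp",
                    sum(!ok), min_len)
  r <- reads[ok]
  plus <- r$strand == "+"
  lo <- integer(nrow(r))                      # genomic low base of the dinuc
  if (assay == "cpdseq") {
    lo <- r$start
  } else if (assay == "hsdamageseq") {
    lo <- ifelse(plus, r$end - 2L, r$start)
  } else {
    d5 <- xr_offset[1]; d3 <- xr_offset[2]
    lo <- ifelse(plus, r$end - d5, r$start + d3)
  }
  five <- ifelse(plus, lo, lo + 1L)
  three <- ifelse(plus, lo + 1L, lo)
  dinuc <- rep(NA_character_, nrow(r))
  if (!is.null(genome)) {
    seqs <- genome_sequences(genome)
    known <- r$chrom %in% names(seqs)
    dref <- substring(seqs[r$chrom[known]], lo[known] + 1L, lo[known] + 2L)
    dinuc[known] <- ifelse(plus[known], dref, revcomp(dref))
  }
  data.table(chrom = r$chrom, five_prime = as.integer(five),
             three_prime = as.integer(three), strand = r$strand,
             dinuc = dinuc, assay = assay)
}

#' Keep only mutagenic, cytosine-containing CPDs
#'
#' Retains CT, TC, CC dinucleotides; removes TT (non-mutagenic under the
#' C>T signature) and any non-dipyrimidine record (logged).
#'
#' @param lesions lesion records with `dinuc` populated
#' @return filtered lesion records
#' @export
filter_mcpd <- function(lesions) {
  if (nrow(lesions) == 0L) return(lesions)
  if (any(is.na(lesions$dinuc)))
    stop("filter_mcpd requires the dinuc column (extract with a genome)")
  keep <- lesions$dinuc %in% c("CT", "TC", "CC")
  n_tt <- sum(lesions$dinuc == "TT")
  n_other <- sum(!keep) - n_tt
  if (n_other > 0) msg("filter_mcpd: removed %d non-dipyrimidine records",
                       n_other)
  lesions[keep]
}

# per-offset counts with both dinucleotide bases contributing; a lesion fully
# inside a window adds 2, one straddling the window edge adds 1
lesion_base_counts <- function(lesions, dyads, half_width = 73L) {
  pos <- data.table(chrom = rep(lesions$chrom, 2L),
                    pos0 = c(lesions$five_prime, lesions$three_prime))
  profile_events(pos, dyads, half_width = half_width, kind = "lesion_bases")
}

# depth denominator: total in-window dipyrimidine-mapped base counts
lesion_depth <- function(lesions, dyads, half_width = 73L) {
  l <- lesions
  if (!any(is.na(l$dinuc))) {
    l <- l[l$dinuc %in% c("CC", "CT", "TC", "TT")]
  }
  sum(lesion_base_counts(l, dyads, half_width)$values)
}

#' Naked-DNA- and depth-normalized lesion profile
#'
#' `values[o] = (C_cell[o] / D_cell) / (C_naked[o] / D_naked)` where `C` are
#' per-offset lesion-base counts (both the 5' and 3' dinucleotide base
#' contribute) and `D` is each dataset's total in-window
#' dipyrimidine-mapped count (sequencing-depth normalization). The naked
#' ratio removes intrinsic sequence preference of lesion formation; offsets
#' with zero naked counts are masked and logged.
#'
#' @param in_cells lesion records from the cellular sample
#' @param naked lesion records from purified (naked) DNA
#' @param dyads dyad `data.table`
#' @param half_width window half-width
#' @param kind profile label
#' @return a [position_profile()]
#' @export
normalized_lesion_profile <- function(in_cells, naked, dyads,
                                      half_width = 73L,
                                      kind = "lesion_enrichment") {
  c_cell <- lesion_base_counts(in_cells, dyads, half_width)
  c_naked <- lesion_base_counts(naked, dyads, half_width)
  d_cell <- lesion_depth(in_cells, dyads, half_width)
  d_naked <- lesion_depth(naked, dyads, half_width)
  if (d_cell == 0 || d_naked == 0)
    stop("no in-window dipyrimidine-mapped reads in one of the datasets")
  vals <- (c_cell$values / d_cell) / (c_naked$values / d_naked)
  bad <- c_naked$values == 0
  vals[bad] <- NA_real_
  if (any(bad))
    msg("normalized_lesion_profile: masked %d offsets with zero naked counts",
        sum(bad))
  position_profile(vals, half_width = half_width,
                   n_nucleosomes = nrow(dyads), kind = kind)
}

#' Repair (XR-seq over naked HS-Damage-seq) profile
#'
#' Identical normalization to [normalized_lesion_profile()] with excision
#' repair events in the numerator and naked-DNA CPDs (HS-Damage-seq) in the
#' denominator: the two assays share the anti-CPD immunoprecipitation, so
#' the ratio cancels both sequence preference and antibody bias.
#'
#' @param xr_lesions XR-seq lesion records
#' @param hs_naked_lesions naked-DNA HS-Damage-seq lesion records
#' @param dyads dyad `data.table`
#' @param half_width window half-width
#' @return a [position_profile()] of kind `"repair"`
#' @export
repair_profile <- function(xr_lesions, hs_naked_lesions, dyads,
                           half_width = 73L) {
  normalized_lesion_profile(xr_lesions, hs_naked_lesions, dyads,
                            half_width = half_width, kind = "repair")
}
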