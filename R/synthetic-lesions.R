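#' Simulate lesion/repair assay reads over a synthetic genome
#'
#' Samples dipyrimidine dinucleotide lesion sites with the same rotational and
#' translational modulation as [generate_mutations()] (or flat, for
#' naked-DNA controls), then emits reads positioned so that the matching
#' assay convention in [extract_lesion_positions()] recovers each planted
#' site exactly:
#' * `cpdseq` — the read interval is the lesion dinucleotide itself;
#' * `xrseq` — excision products whose 3' end sits `xr_offset` bases
#'   downstream of the lesion (default 8 and 7 bases upstream of the 3' end);
#' * `hsdamageseq` — reads ending with the lesion as the 2 bases immediately
#'   5' of the read's 3' end.
#'
#' Lesions are sampled on both strands: YY dinucleotides on the reference
#' strand lie on "+", RR dinucleotides (YY on the reverse strand) on "-".
#'
#' @param genome a [generate_genome()] result
#' @param dyads optional dyad positions (0-based); default the genome's
#' @param config a [synthetic_config()]; default the genome's
#' @param assay one of `"cpdseq"`, `"xrseq"`, `"hsdamageseq"`
#' @param n_reads number of reads to emit
#' @param flat if TRUE, ignore rotational/translational modulation (naked
#'   DNA irradiated in vitro)
#' @param read_length read length for xrseq/hsdamageseq reads
#' @param xr_offset two integers: distances of the lesion's 5' and 3' base
#'   upstream of the excision product's 3' end
#' @param seed_offset added to the config seed so cellular and naked runs of
#'   one config differ
#' @return `data.table` of reads (`chrom`, `start`, `end` \[0-based
#'   half-open\], `strand`, `assay`) with the planted lesion table attached
#'   as attribute `"lesions"` (same columns as [extract_lesion_positions()])
#' @export
generate_lesion_reads <- function(genome, dyads = NULL, config = NULL,
                                  assay = c("cpdseq", "xrseq", "hsdamageseq"),
                                  n_reads = 10000L, flat = FALSE,
                                  read_length = NULL,
                                  xr_offset = c(8L, 7L),
                                  seed_offset = 2L) {
  assay <- match.arg(assay)
  config <- config %||% genome$config
  validate_synthetic_config(config)
  if (is.null(dyads)) dyads <- genome$dyads$position
  read_length <- read_length %||%
    switch(assay, cpdseq = 2L, xrseq = 26L, hsdamageseq = 100L)

  L <- nchar(genome$sequence)
  starts <- 0:(L - 2L)                               # 0-based dinuc starts
  di <- substring(genome$sequence, starts + 1L, starts + 2L)
  yy <- di %in% c("CC", "CT", "TC", "TT")            # lesion strand +
  rr <- di %in% c("GG", "GA", "AG", "AA")            # lesion strand -
  elig <- yy | rr
  site <- starts[elig]
  strand <- ifelse(yy[elig], "+", "-")
  dinuc_ref <- di[elig]

  w <- rep(1, length(site))
  if (!flat) {
    off <- nearest_dyad_offset(site, sort(dyads), 73L)
    inw <- !is.na(off)
    fac <- modulation_factors(-73:73, config)
    w[inw] <- fac[off[inw] + 74L]
  }

  if (n_reads == 0L) {
    reads <- data.table(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        assay = character(0))
    attr(reads, "lesions") <- empty_lesions(assay)
    return(reads)
  }

  with_seed(config$seed + seed_offset, {
    pick <- sample.int(length(site), n_reads, replace = TRUE, prob = w)
    p <- site[pick]                                   # dinuc genomic low base
    s <- strand[pick]
    dn_ref <- dinuc_ref[pick]
    # dinucleotide read on the lesion strand
    dn <- ifelse(s == "+", dn_ref, revcomp(dn_ref))
    plus <- s == "+"
    rs <- integer(n_reads); re <- integer(n_reads)
    if (assay == "cpdseq") {
      rs <- p; re <- p + 2L
    } else if (assay == "hsdamageseq") {
      # lesion = last two read bases in read orientation
      rs[plus] <- p[plus] + 2L - read_length; re[plus] <- p[plus] + 2L
      rs[!plus] <- p[!plus];                  re[!plus] <- p[!plus] + read_length
    } else {                                   # xrseq
      d5 <- xr_offset[1]; d3 <- xr_offset[2]
      # + strand: lesion low base at end - d5 => end = p + d5
      rs[plus] <- p[plus] + d5 - read_length; re[plus] <- p[plus] + d5
      # - strand: 3' end at genomic start; lesion bases (start+d3, start+d5)
      rs[!plus] <- p[!plus] - d3;             re[!plus] <- p[!plus] - d3 + read_length
    }
    reads <- data.table(chrom = genome$chrom, start = rs, end = re,
                        strand = s, assay = assay)
    five <- ifelse(plus, p, p + 1L)            # 5' base on the lesion strand
    three <- ifelse(plus, p + 1L, p)
    attr(reads, "lesions") <- data.table(
      chrom = genome$chrom, five_prime = as.integer(five),
      three_prime = as.integer(three), strand = s, dinuc = dn, assay = assay)
    reads
  })
}

empty_lesions <- function(assay = character(0)) {
  data.table(chrom = character(0), five_prime = integer(0),
             three_prime = integer(0), strand = character(0),
             dinuc = character(0), assay = character(0))
}
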