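#' Dyad-centered position profile
#'
#' A vector of values indexed by dyad-relative offset (`-half_width` ..
#' `+half_width`; 147 positions for the core particle). Values may be counts,
#' expected counts, enrichments, or normalized lesion/repair signal; masked
#' offsets are `NA`.
#'
#' @param values numeric vector of length `2 * half_width + 1`
#' @param half_width window half-width in bp (73 for the core particle)
#' @param n_nucleosomes number of dyads aggregated
#' @param kind free-text label (`"observed"`, `"expected"`, `"enrichment"`,
#'   ...)
#' @return object of class `position_profile`
#' @export
position_profile <- function(values, half_width = 73L, n_nucleosomes = 0L,
                             kind = "counts") {
  stopifnot(length(values) == 2L * half_width + 1L)
  structure(list(offsets = (-half_width):half_width,
                 values = as.numeric(values),
                 n_nucleosomes = n_nucleosomes, kind = kind),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf("position_profile [%s]: offsets %d..%d, %d nucleosomes, mean %.4g\n",
              x$kind, min(x$offsets), max(x$offsets), x$n_nucleosomes,
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.position_profile <- function(x, ...) {
  data.frame(offset = x$offsets, value = x$values,
             n_nucleosomes = x$n_nucleosomes)
}

#' Write / read a profile as TSV (offset, value, n_nucleosomes)
#' @param profile a `position_profile`
#' @param path file path
#' @param header_lines optional comment lines (prefixed `#`) written first
#' @export
write_profile_tsv <- function(profile, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), con)
  writeLines(sprintf("# kind=%s", profile$kind), con)
  writeLines("offset\tvalue\tn_nucleosomes", con)
  writeLines(sprintf("%d\t%s\t%d", profile$offsets,
                     formatC(profile$values, digits = 10, format = "g"),
                     profile$n_nucleosomes), con)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  kind <- sub("^# kind=", "", grep("^# kind=", lines, value = TRUE)[1])
  dt <- fread(text = lines[!startsWith(lines, "#")])
  hw <- max(dt$offset)
  position_profile(dt$value, half_width = hw,
                   n_nucleosomes = dt$n_nucleosomes[1],
                   kind = if (is.na(kind)) "counts" else kind)
}

#' Load an ICGC-dialect somatic mutation table
#'
#' Keeps single-nucleotide substitutions only (single-base A/C/G/T reference
#' and mutated alleles, reference != alternate); rows with multi-base alleles
#' or an unknown assembly tag are skipped with a logged count. When
#' `dedup_per_donor` is TRUE, a variant reported in multiple tumor specimens
#' of the same donor (same donor, chromosome, position, ref, alt) is kept
#' once — such mutations may predate metastasis and would otherwise be
#' double-counted.
#'
#' @param path TSV file (gzip-compressed accepted)
#' @param dedup_per_donor collapse per-donor duplicate variants
#' @param assembly accepted `assembly_version` tags; NULL accepts any
#' @return `data.table` with `donor`, `chrom`, `pos0` (0-based), `ref`,
#'   `alt`; skipped-row counts attached as attribute `"log"`
#' @export
load_mutations <- function(path, dedup_per_donor = TRUE,
                           assembly = NULL) {
  raw <- fread(path, sep = "\t", header = TRUE)
  mutations_from_icgc(raw, dedup_per_donor = dedup_per_donor,
                      assembly = assembly)
}

#' @rdname load_mutations
#' @param icgc an already-read ICGC-dialect `data.table` (e.g. from
#'   [generate_mutations()])
#' @export
mutations_from_icgc <- function(icgc, dedup_per_donor = TRUE,
                                assembly = NULL) {
  raw <- as.data.table(icgc)
  req <- c("icgc_donor_id", "chromosome", "chromosome_start",
           "reference_genome_allele", "mutated_to_allele")
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0)
    stop("mutation table lacks columns: ", paste(missing, collapse = ", "))
  n0 <- nrow(raw)
  if (!is.null(assembly) && "assembly_version" %in% names(raw)) {
    raw <- raw[assembly_version %in% assembly]
  }
  n_assembly_skipped <- n0 - nrow(raw)
  is_snv <- raw$reference_genome_allele %in% BASES &
    raw$mutated_to_allele %in% BASES &
    raw$reference_genome_allele != raw$mutated_to_allele
  n_nonsnv <- sum(!is_snv)
  snv <- raw[is_snv]
  out <- data.table(donor = snv$icgc_donor_id,
                    chrom = as.character(snv$chromosome),
                    pos0 = as.integer(snv$chromosome_start) - 1L,
                    ref = snv$reference_genome_allele,
                    alt = snv$mutated_to_allele)
  n_prededup <- nrow(out)
  if (dedup_per_donor) {
    out <- unique(out, by = c("donor", "chrom", "pos0", "ref", "alt"))
  }
  log <- list(n_rows = n0, n_assembly_skipped = n_assembly_skipped,
              n_non_snv_skipped = n_nonsnv,
              n_duplicates_removed = n_prededup - nrow(out),
              n_retained = nrow(out))
  msg("load_mutations: %d rows -> %d SNVs retained (%d non-SNV, %d assembly-skipped, %d per-donor duplicates removed)",
      n0, log$n_retained, n_nonsnv, n_assembly_skipped,
      log$n_duplicates_removed)
  setattr(out, "log", log)
  out[]
}

#' Annotate mutations with trinucleotide context and dipyrimidine status
#'
#' Adds `trinuc` (reference 3-mer centered on the position) and `dipyr`
#' (TRUE when the reference base forms a pyrimidine pair with a neighbour on
#' either strand, see [is_dipyr_context()]). Mutations whose reference
#' allele disagrees with the genome, or that sit at a chromosome end, are
#' excluded and counted in the attached log.
#'
#' @param mutations `data.table` from [load_mutations()]
#' @param genome a genome object (list with `chrom`, `sequence`) or a named
#'   character vector of chromosome sequences
#' @return annotated `data.table` (excluded rows dropped)
#' @export
annotate_context <- function(mutations, genome) {
  seqs <- genome_sequences(genome)
  mut <- as.data.table(mutations)
  mut[, `:=`(trinuc = NA_character_, dipyr = NA)]
  bad_chrom <- !(mut$chrom %in% names(seqs))
  lens <- nchar(seqs)[mut$chrom]
  at_end <- !bad_chrom & (mut$pos0 < 1L | mut$pos0 > lens - 2L)
  ok <- !bad_chrom & !at_end
  if (any(ok)) {
    tri <- substring(seqs[mut$chrom[ok]], mut$pos0[ok], mut$pos0[ok] + 2L)
    mut$trinuc[ok] <- tri
  }
  mismatch <- ok & substr(mut$trinuc, 2L, 2L) != mut$ref
  keep <- ok & !mismatch
  out <- mut[keep]
  out[, dipyr := is_dipyr_context(substr(trinuc, 1L, 1L), ref,
                                  substr(trinuc, 3L, 3L))]
  log <- list(n_ref_mismatch = sum(mismatch),
              n_out_of_range = sum(bad_chrom | at_end),
              n_retained = nrow(out))
  if (log$n_ref_mismatch + log$n_out_of_range > 0)
    msg("annotate_context: excluded %d ref-mismatch and %d out-of-range records",
        log$n_ref_mismatch, log$n_out_of_range)
  setattr(out, "log", log)
  out[]
}

# normalize genome argument to a named character vector of sequences
genome_sequences <- function(genome) {
  if (inherits(genome, "synthetic_genome") ||
      (is.list(genome) && !is.null(genome$sequence))) {
    out <- genome$sequence
    names(out) <- genome$chrom
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  if (methods::is(genome, "DNAStringSet"))
    return(stats::setNames(as.character(genome), names(genome)))
  stop("unrecognized genome representation")
}

#' Aggregate point events into a dyad-centered profile
#'
#' `values[o]` is the number of events at `dyad + o`, summed over dyads. An
#' event within `half_width` of several dyads (possible only when
#' `half_width` exceeds half the dyad spacing, as in extended 1000-bp runs)
#' contributes once per dyad at the respective offsets; events outside all
#' windows are ignored.
#'
#' @param events `data.table` with `chrom` and `pos0` (0-based positions)
#' @param dyads dyad `data.table` (`chrom`, `position`)
#' @param half_width window half-width in bp (73 = core particle; 500 =
#'   extended inter-nucleosome view)
#' @param kind profile label
#' @return a [position_profile()]
#' @export
profile_events <- function(events, dyads, half_width = 73L,
                           kind = "observed") {
  hw <- as.integer(half_width)
  n_off <- 2L * hw + 1L
  counts <- integer(n_off)
  if (!is.null(events) && nrow(events) > 0L && nrow(dyads) > 0L) {
    common <- intersect(unique(events$chrom), unique(dyads$chrom))
    for (ch in common) {
      ep <- events$pos0[events$chrom == ch]
      dp <- sort(dyads$position[dyads$chrom == ch])
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(ep + 1L, ep + 1L),
        IRanges::IRanges(dp - hw + 1L, dp + hw + 1L))
      off <- ep[S4Vectors::queryHits(ov)] - dp[S4Vectors::subjectHits(ov)]
      counts <- counts + tabulate(off + hw + 1L, nbins = n_off)
    }
  }
  position_profile(counts, half_width = hw, n_nucleosomes = nrow(dyads),
                   kind = kind)
}

#' Strand-resolved mutation profiles relative to transcription
#'
#' Assigns each dyad to at most one gene (dyad coordinate inside the gene
#' body; dyads hit by genes of conflicting strand are dropped and logged) and
#' splits in-window dipyrimidine mutations into transcribed-strand (TS) and
#' non-transcribed-strand (NTS) profiles. A mutation's lesion strand is the
#' strand carrying the pyrimidine (reference C/T: "+", A/G: "-"); it counts
#' as TS when that strand is the gene's template strand (the "-" strand of a
#' "+" gene and vice versa). Offsets stay in reference orientation.
#'
#' @param mutations annotated mutations ([annotate_context()])
#' @param dyads dyad `data.table`
#' @param genes `data.table` with `chrom`, `start`, `end` (0-based
#'   half-open), `strand` ("+"/"-"), `gene_id`
#' @param half_width window half-width
#' @return list with `TS` and `NTS` [position_profile()]s and `log`
#' @export
profile_events_stranded <- function(mutations, dyads, genes,
                                    half_width = 73L) {
  if (is.null(genes) || nrow(genes) == 0L)
    stop("profile_events_stranded requires a gene set")
  dg <- assign_dyads_to_genes(dyads, genes)
  kept_dyads <- dyads[dg$keep]
  gene_strand <- dg$strand[dg$keep]

  mut <- mutations[mutations$dipyr %in% TRUE]
  pyr_strand <- ifelse(mut$ref %in% PYRIMIDINES, "+", "-")

  hw <- as.integer(half_width)
  ts_counts <- integer(2L * hw + 1L)
  nts_counts <- integer(2L * hw + 1L)
  for (ch in intersect(unique(mut$chrom), unique(kept_dyads$chrom))) {
    mi <- which(mut$chrom == ch)
    di <- which(kept_dyads$chrom == ch)
    dp <- kept_dyads$position[di]
    o <- order(dp); dp <- dp[o]; gs <- gene_strand[di][o]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(mut$pos0[mi] + 1L, mut$pos0[mi] + 1L),
      IRanges::IRanges(dp - hw + 1L, dp + hw + 1L))
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    off <- mut$pos0[mi][q] - dp[s]
    template <- ifelse(gs[s] == "+", "-", "+")
    is_ts <- pyr_strand[mi][q] == template
    ts_counts <- ts_counts + tabulate(off[is_ts] + hw + 1L, 2L * hw + 1L)
    nts_counts <- nts_counts + tabulate(off[!is_ts] + hw + 1L, 2L * hw + 1L)
  }
  list(
    TS = position_profile(ts_counts, hw, nrow(kept_dyads), "TS"),
    NTS = position_profile(nts_counts, hw, nrow(kept_dyads), "NTS"),
    log = list(n_dyads_in_genes = nrow(kept_dyads),
               n_dyads_ambiguous = dg$n_ambiguous)
  )
}

# dyad -> gene strand assignment; ambiguous (conflicting strands) dropped
assign_dyads_to_genes <- function(dyads, genes) {
  gr_d <- GenomicRanges::GRanges(dyads$chrom,
                                 IRanges::IRanges(dyads$position + 1L,
                                                  dyads$position + 1L))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
  ov <- GenomicRanges::findOverlaps(gr_d, gr_g)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  strand <- rep(NA_character_, nrow(dyads))
  ambiguous <- logical(nrow(dyads))
  for (i in unique(q)) {
    st <- unique(genes$strand[s[q == i]])
    if (length(st) == 1L) strand[i] <- st else ambiguous[i] <- TRUE
  }
  n_amb <- sum(ambiguous)
  if (n_amb > 0) msg("dropped %d dyads in genes of conflicting strand", n_amb)
  list(keep = !is.na(strand) & !ambiguous, strand = strand,
       n_ambiguous = n_amb)
}
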