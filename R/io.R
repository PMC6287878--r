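#' Write a genome as FASTA / read a FASTA genome
#' @param genome a `synthetic_genome` or named character vector
#' @param path file path
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- genome_sequences(genome)
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write mutations in the ICGC simple-somatic TSV dialect
#' @param mutations a [generate_mutations()] table
#' @param path file path (".gz" suffix compresses)
#' @export
write_icgc_tsv <- function(mutations, path) {
  fwrite(mutations, path, sep = "\t")
  invisible(path)
}

#' Write reads / intervals as BED6
#' @param reads `data.table` with `chrom`, `start`, `end`, `strand` and
#'   optional `name`, `score`
#' @param path file path
#' @export
write_reads_bed <- function(reads, path) {
  bed <- data.table(chrom = reads$chrom, start = reads$start,
                    end = reads$end,
                    name = reads$name %||% reads$assay %||% ".",
                    score = reads$score %||% 0L,
                    strand = reads$strand %||% ".")
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED6 interval file
#' @param path BED file
#' @return `data.table` with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing columns filled with defaults)
#' @export
read_bed6 <- function(path) {
  bed <- fread(path, header = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  setnames(bed, cols[seq_len(ncol(bed))])
  if (!"name" %in% names(bed)) bed[, name := "."]
  if (!"score" %in% names(bed)) bed[, score := 0]
  if (!"strand" %in% names(bed)) bed[, strand := "."]
  bed[]
}

#' Synthesize a per-base positioning-score track from known dyads
#'
#' Writes each dyad's positioning score at its exact position over a noise
#' floor well below the calling threshold, so the greedy caller recovers the
#' planted dyads from file-based input. Used by the synthetic-demo preset to
#' exercise the bedGraph path end to end.
#'
#' @param genome a `synthetic_genome`
#' @param noise_sd standard deviation of the background score noise
#' @param seed integer seed
#' @return `data.table` score track (`chrom`, `pos`, `score`)
#' @export
synthetic_score_track <- function(genome, noise_sd = 1, seed = 1L) {
  L <- nchar(genome$sequence)
  with_seed(seed, {
    score <- stats::rnorm(L, mean = -20, sd = noise_sd)
    score[genome$dyads$position + 1L] <- genome$dyads$score
    data.table(chrom = genome$chrom, pos = 0:(L - 1L), score = score)
  })
}

#' Write a score track as bedGraph
#' @param track `data.table` (`chrom`, `pos`, `score`)
#' @param path output bedGraph
#' @export
write_score_track_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$pos + 1L,
                                                track$pos + 1L),
                               score = track$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
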