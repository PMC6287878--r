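#' Fit the trinucleotide expected-mutation model
#'
#' Counts mutations per reference trinucleotide context and divides by the
#' total to obtain context frequencies; per-site rates are then
#' `rate(t) = freq(t) * N_mut / genome_counts(t)`, where `genome_counts`
#' tallies trinucleotide centers over the eligible reference territory.
#' With that scaling, `sum(rate(t) * genome_counts(t)) == N_mut` exactly, so
#' observed and expected profiles share units of mutation counts. The model
#' must be refit on each analyzed mutation subset so the subset's own
#' context spectrum is normalized out.
#'
#' Contexts are counted on the reference strand as written (64 contexts, no
#' pyrimidine-strand collapsing). With `dipyr_only = TRUE`, only mutations
#' in dipyrimidine context enter the frequencies and only contexts
#' containing a dipyrimidine on either strand ([trinuc_has_dipyr()]) carry
#' mass; rates elsewhere are zero.
#'
#' @param mutations annotated mutations ([annotate_context()]) with `trinuc`
#'   (and `dipyr` when `dipyr_only`)
#' @param genome genome object or named character vector of sequences
#' @param dipyr_only restrict to dipyrimidine-context mutations and contexts
#' @param territory optional `data.table` (`chrom`, `start`, `end`, 0-based
#'   half-open) delimiting where genome trinucleotide centers are counted;
#'   NULL counts the whole genome. Refitting with territory = the profiled
#'   nucleosome windows gives mean enrichment ~1 by construction.
#' @return object of class `trinuc_model`: `freq`, `genome_counts`, `rate`
#'   (named 64-vectors), `n_mutations`, `dipyr_only`
#' @export
fit_trinuc_model <- function(mutations, genome, dipyr_only = FALSE,
                             territory = NULL) {
  tn <- all_trinucs()
  mut <- as.data.table(mutations)
  if (dipyr_only) mut <- mut[dipyr %in% TRUE]
  mut <- mut[!is.na(trinuc) & trinuc %in% tn]
  n_mut <- nrow(mut)
  if (n_mut == 0L) stop("no usable mutations to fit the context model")
  freq <- setNames(numeric(64), tn)
  tab <- table(mut$trinuc)
  freq[names(tab)] <- as.numeric(tab) / n_mut

  counts <- territory_trinuc_counts(genome, territory)
  if (dipyr_only) {
    eligible <- trinuc_has_dipyr(tn)
    if (any(freq[!eligible] > 0))
      stop("dipyr_only model received mutations in non-dipyrimidine contexts")
  }
  rate <- setNames(numeric(64), tn)
  nonzero <- counts > 0
  rate[nonzero] <- freq[nonzero] * n_mut / counts[nonzero]
  if (any(freq > 0 & !nonzero))
    stop("mutation context absent from the reference territory: ",
         paste(tn[freq > 0 & !nonzero], collapse = ", "))
  structure(list(freq = freq, genome_counts = counts, rate = rate,
                 n_mutations = n_mut, dipyr_only = dipyr_only),
            class = "trinuc_model")
}

#' @export
print.trinuc_model <- function(x, ...) {
  cat(sprintf("trinuc_model: %d mutations, %d contexts with mass%s\n",
              x$n_mutations, sum(x$freq > 0),
              if (x$dipyr_only) " (dipyrimidine-only)" else ""))
  invisible(x)
}

# count trinucleotide *centers* lying inside the territory (flanks may extend
# 1 bp beyond an interval edge); whole genome when territory is NULL
territory_trinuc_counts <- function(genome, territory = NULL) {
  seqs <- genome_sequences(genome)
  tn <- all_trinucs()
  counts <- setNames(numeric(64), tn)
  if (is.null(territory)) {
    for (ch in names(seqs)) {
      tf <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(seqs[[ch]]))
      counts[names(tf)] <- counts[names(tf)] + tf
    }
    return(counts)
  }
  terr <- as.data.table(territory)
  for (ch in intersect(unique(terr$chrom), names(seqs))) {
    s <- seqs[[ch]]; L <- nchar(s)
    iv <- terr[chrom == ch]
    centers <- unlist(lapply(seq_len(nrow(iv)), function(i) {
      seq.int(max(iv$start[i], 1L), min(iv$end[i] - 1L, L - 2L))
    }))
    centers <- unique(centers)                 # 0-based center positions
    tri <- substring(s, centers, centers + 2L)
    tab <- table(tri)
    keep <- names(tab) %in% tn
    counts[names(tab)[keep]] <- counts[names(tab)[keep]] +
      as.numeric(tab[keep])
  }
  counts
}

#' Trinucleotide-context counts per dyad-relative offset
#'
#' 64 x (2*half_width+1) matrix counting each trinucleotide context at each
#' offset over all dyad windows. Precomputing it lets [expected_profile()]
#' be re-evaluated cheaply under refit models (as the subsampling survey
#' does: the expected profile is just `rate %*% counts`).
#'
#' @param dyads dyad `data.table`
#' @param genome genome object
#' @param half_width window half-width in bp
#' @return numeric matrix with trinucleotide rownames; the number of usable
#'   dyads is attached as attribute `"n_dyads"`
#' @export
offset_context_counts <- function(dyads, genome, half_width = 73L) {
  seqs <- genome_sequences(genome)
  tn <- all_trinucs()
  hw <- as.integer(half_width)
  n_off <- 2L * hw + 1L
  M <- matrix(0, nrow = 64, ncol = n_off, dimnames = list(tn, NULL))
  n_dropped <- 0L
  for (ch in intersect(unique(dyads$chrom), names(seqs))) {
    s <- seqs[[ch]]; L <- nchar(s)
    dp <- dyads$position[dyads$chrom == ch]
    ok <- dp - hw >= 1L & dp + hw <= L - 2L   # flanks must stay on-chrom
    n_dropped <- n_dropped + sum(!ok)
    dp <- dp[ok]
    if (length(dp) == 0L) next
    pos <- outer(dp, (-hw):hw, "+")           # 0-based centers
    tri <- substring(s, pos, pos + 2L)
    ctx <- match(tri, tn)
    offc <- rep(seq_len(n_off), each = length(dp))
    tab <- table(factor(ctx, levels = 1:64), factor(offc, levels = seq_len(n_off)))
    M <- M + as.matrix(tab)
  }
  if (n_dropped > 0)
    msg("expected model: dropped %d dyads with windows off the chromosome",
        n_dropped)
  attr(M, "n_dyads") <- sum(dyads$chrom %in% names(seqs)) - n_dropped
  M
}

#' Expected-mutation profile from sequence context alone
#'
#' `values[o] = sum over dyads of rate(trinuc at dyad + o)`: the number of
#' mutations expected at each offset if only trinucleotide context mattered.
#' Dyads whose window (plus 1-bp flanks) runs off the chromosome are dropped
#' and logged.
#'
#' @param model a [fit_trinuc_model()]
#' @param dyads dyad `data.table`
#' @param genome genome object
#' @param half_width window half-width
#' @param context_counts optional precomputed [offset_context_counts()]
#'   matrix (for repeated evaluation with refit models)
#' @return a [position_profile()] of kind `"expected"`
#' @export
expected_profile <- function(model, dyads, genome, half_width = 73L,
                             context_counts = NULL) {
  M <- context_counts %||% offset_context_counts(dyads, genome, half_width)
  vals <- as.numeric(model$rate %*% M)
  position_profile(vals, half_width = half_width,
                   n_nucleosomes = attr(M, "n_dyads") %||% nrow(dyads),
                   kind = "expected")
}

#' Mutation enrichment: observed over expected
#'
#' Per-offset ratio of the observed profile to the expected profile. Offsets
#' with zero (or masked) expectation are masked (`NA`) and logged; downstream
#' fits skip masked offsets.
#'
#' @param observed,expected [position_profile()]s over identical offsets
#' @return a [position_profile()] of kind `"enrichment"`
#' @export
enrichment <- function(observed, expected) {
  stopifnot(identical(observed$offsets, expected$offsets))
  bad <- is.na(expected$values) | expected$values == 0
  vals <- observed$values / expected$values
  vals[bad] <- NA_real_
  if (any(bad)) msg("enrichment: masked %d offsets with zero expectation",
                    sum(bad))
  position_profile(vals, half_width = max(observed$offsets),
                   n_nucleosomes = observed$n_nucleosomes,
                   kind = "enrichment")
}

#' Serialize / load a trinucleotide model as TSV
#' @param model a `trinuc_model`
#' @param path file path
#' @export
write_trinuc_model_tsv <- function(model, path) {
  dt <- data.table(context = names(model$freq), freq = model$freq,
                   genome_count = model$genome_counts, rate = model$rate)
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
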