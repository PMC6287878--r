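#' Read a per-base nucleosome positioning-score track
#'
#' Imports a bedGraph (or WIG) track via `rtracklayer` and expands it to
#' per-base resolution.
#'
#' @param path bedGraph/WIG file
#' @return `data.table` with `chrom`, `pos` (0-based), `score`
#' @export
read_score_track <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  w <- df$end - df$start + 1L
  out <- data.table(
    chrom = rep(as.character(df$seqnames), w),
    pos = unlist(Map(seq.int, df$start - 1L, df$end - 1L)),
    score = rep(df$score, w))
  setorder(out, chrom, pos)
  if (any(!is.finite(out$score))) stop("score track contains non-finite values")
  out[]
}

#' Call nucleosome dyads by greedy score exclusion
#'
#' Iteratively selects the highest remaining positioning score at or above
#' `min_score`, emits that position as a dyad, and masks every position
#' within `exclusion_radius` bp (inclusive, `|delta| <= radius`) of it; stops
#' when no eligible position remains. Ties break to the lowest coordinate,
#' then lexicographic chromosome; chromosomes are processed independently
#' (exclusion never crosses a chromosome).
#'
#' @param track `data.table` with `chrom`, `pos` (0-based), `score` (e.g.
#'   from [read_score_track()])
#' @param min_score minimum score to call a dyad (strong threshold is 10)
#' @param exclusion_radius masking radius in bp (default 117)
#' @return `data.table` of dyads: `chrom`, `position`, `score`, `strength`
#'   (per [classify_strength()]), sorted by coordinate
#' @export
call_dyads <- function(track, min_score = 10, exclusion_radius = 117L) {
  stopifnot(exclusion_radius >= 0)
  if (is.null(track) || nrow(track) == 0L) return(empty_dyads())
  if (any(!is.finite(track$score))) stop("track scores must be finite")
  parts <- split(track, track$chrom)
  res <- lapply(names(parts), function(ch) {
    p <- parts[[ch]]
    pos <- call_dyads_chrom(p$pos, p$score, min_score, exclusion_radius)
    if (length(pos) == 0L) return(NULL)
    sc <- p$score[match(pos, p$pos)]
    data.table(chrom = ch, position = pos, score = sc,
               strength = classify_strength(sc))
  })
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L) return(empty_dyads())
  setorder(out, chrom, position)
  out[]
}

# single-chromosome greedy: order candidates once by (-score, pos) and sweep,
# checking a mask; equivalent to a priority queue with lazy deletion
call_dyads_chrom <- function(pos, score, min_score, radius) {
  keep <- score >= min_score
  pos <- pos[keep]; score <- score[keep]
  if (length(pos) == 0L) return(integer(0))
  o <- order(-score, pos)
  pos <- pos[o]; score <- score[o]
  lo <- min(pos); span <- max(pos) - lo + 1L
  masked <- logical(span)
  called <- integer(0)
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (masked[p - lo + 1L]) next
    called <- c(called, p)
    a <- max(p - radius, lo) - lo + 1L
    b <- min(p + radius, lo + span - 1L) - lo + 1L
    masked[a:b] <- TRUE
  }
  sort(called)
}

empty_dyads <- function() {
  data.table(chrom = character(0), position = integer(0),
             score = numeric(0), strength = character(0))
}

#' Classify nucleosome positioning strength
#'
#' Strong nucleosomes score at or above `strong_threshold`; weak nucleosomes
#' fall inside `weak_range` (both ends inclusive); anything else is
#' unclassified.
#'
#' @param score numeric vector of positioning scores
#' @param strong_threshold strong cutoff (default 10)
#' @param weak_range length-2 numeric, low and high bound of the weak class
#'   (default c(-40, -5))
#' @return character vector: `"strong"`, `"weak"`, or `"unclassified"`
#' @export
classify_strength <- function(score, strong_threshold = 10,
                              weak_range = c(-40, -5)) {
  out <- rep("unclassified", length(score))
  out[score >= strong_threshold] <- "strong"
  out[score >= weak_range[1] & score <= weak_range[2]] <- "weak"
  out
}

#' Remove dyads whose core particle overlaps blacklisted intervals
#'
#' A dyad is excluded when its 147-bp window (`position - 73` to
#' `position + 73`, inclusive) intersects any blacklist interval; the test is
#' on the whole nucleosome window, not the dyad point.
#'
#' @param dyads `data.table` of dyads (from [call_dyads()] or a generator)
#' @param blacklist `data.table`/data.frame with `chrom`, `start`, `end`
#'   (0-based half-open)
#' @return filtered dyads
#' @export
filter_blacklist <- function(dyads, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0L) return(dyads)
  if (any(blacklist$end <= blacklist$start))
    stop("malformed blacklist interval: end <= start")
  bl <- GenomicRanges::GRanges(blacklist$chrom,
                               IRanges::IRanges(blacklist$start + 1L,
                                                blacklist$end))
  win <- GenomicRanges::GRanges(dyads$chrom,
                                IRanges::IRanges(dyads$position - 73L + 1L,
                                                 dyads$position + 73L + 1L))
  hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(win, bl)))
  n_drop <- length(hit)
  if (n_drop > 0) msg("blacklist filter removed %d of %d dyads",
                      n_drop, nrow(dyads))
  if (n_drop == 0L) dyads else dyads[-hit]
}

#' Write / read dyads as BED6
#'
#' BED6 with name = strength class and score = positioning score, 0-based
#' half-open single-base intervals.
#' @param dyads dyad `data.table`
#' @param path output file
#' @export
write_dyads_bed <- function(dyads, path) {
  bed <- data.table(chrom = dyads$chrom, start = dyads$position,
                    end = dyads$position + 1L, name = dyads$strength,
                    score = dyads$score, strand = ".")
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_dyads_bed
#' @param path BED6 file of dyads
#' @export
read_dyads_bed <- function(path) {
  bed <- fread(path, header = FALSE,
               col.names = c("chrom", "start", "end", "name", "score",
                             "strand"))
  out <- data.table(chrom = bed$chrom, position = bed$start,
                    score = bed$score, strength = bed$name)
  setorder(out, chrom, position)
  out[]
}
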