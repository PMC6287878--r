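#' Assign dyads to strata by interval membership or transcription quartile
#'
#' Interval schemes (chromHMM states, histone peaks): a dyad joins a stratum
#' when its dyad coordinate lies inside an interval; dyads hit by intervals
#' of different labels within one scheme are dropped and logged. Expression
#' schemes: genes are ranked by expression and split into quartiles — Low =
#' bottom quartile, Medium = middle two, High = top — and dyads inside a
#' gene body (start..end, strand-agnostic) inherit the gene's class.
#'
#' @param dyads dyad `data.table`
#' @param scheme either intervals (`data.table` with `chrom`, `start`,
#'   `end` 0-based half-open, `label`) or an expression scheme: a
#'   `data.table` with `chrom`, `start`, `end`, `gene_id`, `expression`
#' @param name scheme name
#' @return object of class `stratification`: `name`, `stratum` (character
#'   per dyad, NA = unassigned), `n_ambiguous`, `levels`
#' @export
assign_strata <- function(dyads, scheme, name = "scheme") {
  sc <- as.data.table(scheme)
  if ("expression" %in% names(sc)) {
    sc[, label := expression_quartiles(sc$expression)]
  } else if (!"label" %in% names(sc)) {
    stop("scheme needs either a 'label' or an 'expression' column")
  }
  stratum <- rep(NA_character_, nrow(dyads))
  n_amb <- 0L
  if (nrow(sc) > 0L && nrow(dyads) > 0L) {
    gr_d <- GenomicRanges::GRanges(dyads$chrom,
                                   IRanges::IRanges(dyads$position + 1L,
                                                    dyads$position + 1L))
    gr_s <- GenomicRanges::GRanges(sc$chrom,
                                   IRanges::IRanges(sc$start + 1L, sc$end))
    ov <- GenomicRanges::findOverlaps(gr_d, gr_s)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    lab <- split(sc$label[s], q)
    for (key in names(lab)) {
      u <- unique(lab[[key]])
      i <- as.integer(key)
      if (length(u) == 1L) stratum[i] <- u else n_amb <- n_amb + 1L
    }
  }
  if (n_amb > 0) msg("assign_strata[%s]: dropped %d dyads with conflicting labels",
                     name, n_amb)
  structure(list(name = name, stratum = stratum, n_ambiguous = n_amb,
                 levels = sort(unique(stratum[!is.na(stratum)]))),
            class = "stratification")
}

# Low = bottom quartile, Medium = middle two quartiles, High = top quartile
expression_quartiles <- function(expr) {
  q <- rank(expr, ties.method = "average") / length(expr)
  out <- rep("Medium", length(expr))
  out[q <= 0.25] <- "Low"
  out[q > 0.75] <- "High"
  out
}

#' @export
print.stratification <- function(x, ...) {
  tab <- table(x$stratum, useNA = "ifany")
  cat(sprintf("stratification '%s': %s\n", x$name,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Per-stratum observed profiles with the power QC threshold
#'
#' Builds one observed-count profile per stratum and flags strata whose mean
#' mutations per bp fall below `qc_threshold` (default 100, the minimum used
#' to ensure enough power to see the periodicity) as ineligible.
#'
#' @param events events `data.table` (`chrom`, `pos0`)
#' @param dyads dyad `data.table`
#' @param strat a [assign_strata()] result
#' @param half_width window half-width
#' @param qc_threshold minimum mean events per bp position
#' @return named list per stratum: `profile`, `qc_mean_per_bp`, `eligible`,
#'   `n_dyads`
#' @export
stratum_profiles <- function(events, dyads, strat, half_width = 73L,
                             qc_threshold = 100) {
  out <- lapply(strat$levels, function(lv) {
    sel <- which(strat$stratum %in% lv)
    prof <- profile_events(events, dyads[sel], half_width = half_width,
                           kind = paste0("observed:", lv))
    qc <- mean(prof$values)
    list(profile = prof, qc_mean_per_bp = qc,
         eligible = qc >= qc_threshold, n_dyads = length(sel))
  })
  names(out) <- strat$levels
  out
}

#' Kruskal-Wallis (plus Dunn post hoc) on axis-inverted profiles
#'
#' Implements the axis-inversion procedure for comparing overall profile
#' levels: each profile's per-offset values are re-read as observations
#' along a continuous enrichment axis (the bp positions become the tallies),
#' over a shared range whose ends are the combined minimum and maximum
#' rounded to the nearest integer. Kruskal-Wallis then tests whether the
#' inverted distributions share a location, and Dunn's test compares all
#' pairs on the same inversion. Only the range ends are rounded; tallied
#' values keep full precision unless `tally_digits` is set. Profiles with no
#' spread make the inversion degenerate and raise an error.
#'
#' @param profiles list of [position_profile()]s over identical offsets
#' @param tally_digits optional decimal digits to round each value to before
#'   tallying (NULL, the default, tallies at full precision)
#' @param p_adjust_method multiplicity adjustment for the Dunn p-values
#' @return list: `H`, `df`, `p_value`, `dunn` (`data.table` of pairwise z
#'   and p), `range` (the rounded combined range)
#' @export
axis_inversion_kw <- function(profiles, tally_digits = NULL,
                              p_adjust_method = "none") {
  stopifnot(length(profiles) >= 2L)
  offs <- lapply(profiles, `[[`, "offsets")
  if (!all(vapply(offs, identical, logical(1), offs[[1]])))
    stop("profiles must share offsets")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("profile", seq_along(profiles))
  vals <- lapply(profiles, function(p) p$values[!is.na(p$values)])
  combined <- unlist(vals)
  rng <- c(round(min(combined)), round(max(combined)))
  tallied <- if (is.null(tally_digits)) vals else
    lapply(vals, round, digits = tally_digits)
  if (all(vapply(tallied, function(v) length(unique(v)) == 1L, logical(1))))
    stop("axis inversion degenerate: profiles have zero spread")
  groups <- factor(rep(names(profiles), lengths(tallied)),
                   levels = names(profiles))
  x <- unlist(tallied)
  kw <- kruskal.test(x, groups)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value,
       dunn = dunn_test(x, groups, p_adjust_method),
       range = rng)
}

# Dunn's post-hoc test: pairwise z on mean ranks with tie correction
dunn_test <- function(x, g, p_adjust_method = "none") {
  r <- rank(x)
  N <- length(x)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.table(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = p.adjust(p, method = p_adjust_method))
}

#' Binned chi-square comparison of two count profiles
#'
#' Partitions the 147 offsets into 16 contiguous ~10-bp bins (to remove the
#' rotational oscillation: thirteen 9-bp and three 10-bp bins, the 10-bp
#' bins placed at both edges and at the dyad — the closest a 16-bin layout
#' can get to symmetry about offset 0), sums the raw counts per bin, and
#' runs a chi-square homogeneity test on the 2 x 16 table. Expected cells
#' below 5 trigger a logged warning.
#'
#' @param profile_a,profile_b raw count [position_profile()]s (not
#'   enrichments) over -73..+73
#' @return list: `statistic`, `df`, `p_value`, `bins` (`data.table` of bin
#'   bounds and counts)
#' @export
binned_chisq <- function(profile_a, profile_b) {
  stopifnot(identical(profile_a$offsets, profile_b$offsets),
            length(profile_a$offsets) == 147L)
  sizes <- c(10L, rep(9L, 6L), 10L, rep(9L, 7L), 10L)
  stopifnot(sum(sizes) == 147L, length(sizes) == 16L)
  bin <- rep(seq_len(16L), times = sizes)
  ca <- as.numeric(tapply(profile_a$values, bin, sum))
  cb <- as.numeric(tapply(profile_b$values, bin, sum))
  if (sum(ca) == 0 || sum(cb) == 0) stop("binned_chisq needs non-zero totals")
  tab <- rbind(ca, cb)
  suppressWarnings(ct <- chisq.test(tab))
  if (any(ct$expected < 5))
    msg("binned_chisq: %d expected cells below 5", sum(ct$expected < 5))
  starts <- cumsum(c(0L, sizes[-16L])) - 73L
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value,
       bins = data.table(bin = seq_len(16L), start_offset = starts,
                         width = sizes, count_a = ca, count_b = cb))
}
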