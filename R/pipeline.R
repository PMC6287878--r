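preset_required_inputs <- function(preset) {
  switch(preset,
    "fig1" = c("scores", "mutations", "genome"),
    "fig2" = c("scores", "mutations", "genome"),
    "fig3" = c("scores", "genome", "cpd_cells", "cpd_naked"),
    "fig4" = c("scores", "mutations", "genome", "states"),
    "fig5" = c("scores", "mutations", "genome", "genes"),
    "s1" = c("scores", "mutations", "genome"),
    "s2" = c("scores", "mutations", "genome"),
    "s3" = c("scores", "genome", "cpd_cells", "cpd_naked", "hs_cells",
             "hs_naked"),
    "s4" = c("scores", "genome", "xr_reads", "hs_naked"),
    "s5" = c("scores", "genome", "cpd_cells", "cpd_naked", "peaks"),
    "s6" = c("scores", "genome", "cpd_cells", "cpd_naked", "xr_reads",
             "hs_naked", "genes"),
    "synthetic-demo" = character(0),
    stop("unknown preset: ", preset))
}

#' Run an analysis preset
#'
#' Orchestrates one figure-style computation: dyad calling from a score
#' track, mutation (or lesion) profiling, context normalization, Lomb-Scargle
#' periodogram and quadratic curvature fit, with every output TSV stamped
#' with a hash of the run configuration so reruns with an identical config
#' are byte-identical. The `synthetic-demo` preset needs no external files:
#' it generates a synthetic cohort, round-trips it through the file formats
#' (FASTA, bedGraph, ICGC TSV), and runs the full chain on the files it
#' wrote. File-based presets validate their required inputs and fail with an
#' actionable error naming the missing role.
#'
#' @param preset one of `fig1`-`fig5`, `s1`-`s6`, `synthetic-demo`
#' @param inputs named list of file paths (roles: `scores`, `mutations`,
#'   `genome`, `blacklist`, `states`, `peaks`, `genes`, `cpd_cells`,
#'   `cpd_naked`, `xr_reads`, `hs_cells`, `hs_naked`)
#' @param outdir output directory (created)
#' @param config a [synthetic_config()] (synthetic-demo only)
#' @param min_score,exclusion_radius,half_width dyad-calling and profiling
#'   parameters; defaults are the strong-nucleosome threshold 10, the 117-bp
#'   exclusion radius, and the 73-bp core-particle half-width
#' @param seed integer seed
#' @param dipyr_only restrict mutation analyses to dipyrimidine contexts
#' @return invisibly, a list of the main results (`dyads`, `observed`,
#'   `expected`, `enrichment_profile`, `periodogram`, `fit`, `log`)
#' @export
run_preset <- function(preset, inputs = list(), outdir = tempfile("nucsig_"),
                       config = synthetic_config(), min_score = 10,
                       exclusion_radius = 117L, half_width = 73L,
                       seed = 1L, dipyr_only = TRUE) {
  req <- preset_required_inputs(preset)
  for (role in req) {
    if (is.null(inputs[[role]]))
      stop(sprintf("preset '%s' is missing required input '%s'",
                   preset, role))
  }
  for (role in req) {
    if (!file.exists(inputs[[role]]))
      stop(sprintf("preset '%s': input '%s' file not found: %s",
                   preset, role, inputs[[role]]))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  run_cfg <- list(preset = preset, min_score = min_score,
                  exclusion_radius = exclusion_radius,
                  half_width = half_width, seed = seed,
                  dipyr_only = dipyr_only,
                  config = if (preset == "synthetic-demo") unclass(config))
  hash <- config_hash(run_cfg)
  stamp <- sprintf("nucsig run: preset=%s config=%s", preset, hash)

  if (preset == "synthetic-demo") {
    gen <- generate_genome(config)
    write_genome_fasta(gen, file.path(outdir, "genome.fa"))
    track <- synthetic_score_track(gen, seed = seed)
    write_score_track_bedgraph(track, file.path(outdir, "scores.bedGraph"))
    muts_tsv <- file.path(outdir, "mutations.tsv")
    write_icgc_tsv(generate_mutations(gen), muts_tsv)
    inputs <- list(scores = file.path(outdir, "scores.bedGraph"),
                   genome = file.path(outdir, "genome.fa"),
                   mutations = muts_tsv)
  }

  genome <- read_genome_fasta(inputs$genome)
  track <- read_score_track(inputs$scores)
  dyads <- call_dyads(track, min_score = min_score,
                      exclusion_radius = exclusion_radius)
  if (!is.null(inputs$blacklist))
    dyads <- filter_blacklist(dyads, read_bed6(inputs$blacklist))
  write_dyads_bed(dyads, file.path(outdir, "dyads.bed"))
  log <- list(n_dyads = nrow(dyads))

  res <- list(dyads = dyads, log = log)
  if (!is.null(inputs$mutations)) {
    mut <- annotate_context(load_mutations(inputs$mutations), genome)
    if (dipyr_only) mut <- mut[mut$dipyr %in% TRUE]
    log$n_mutations <- nrow(mut)
    model <- fit_trinuc_model(mut, genome, dipyr_only = dipyr_only)
    obs <- profile_events(mut, dyads, half_width = half_width)
    expd <- expected_profile(model, dyads, genome, half_width = half_width)
    enr <- enrichment(obs, expd)
    pg <- periodogram(enr, exclusion_max = 100)
    fit <- fit_quadratic(enr, normalize = TRUE)
    write_trinuc_model_tsv(model, file.path(outdir, "trinuc_model.tsv"))
    write_profile_tsv(obs, file.path(outdir, "observed.tsv"), stamp)
    write_profile_tsv(expd, file.path(outdir, "expected.tsv"), stamp)
    write_profile_tsv(enr, file.path(outdir, "enrichment.tsv"), stamp)
    write_periodogram_tsv(pg, file.path(outdir, "periodogram.tsv"), stamp)
    write_fit_tsv(fit, file.path(outdir, "curvature_fit.tsv"), stamp)
    res <- c(res, list(observed = obs, expected = expd,
                       enrichment_profile = enr, periodogram = pg,
                       fit = fit))
  }
  res$log <- log
  res$outdir <- outdir
  res$config_hash <- hash
  invisible(res)
}

#' Write a periodogram / curvature fit as TSV
#' @param pg a `periodogram_result`
#' @param path file path
#' @param header_lines optional comment lines
#' @export
write_periodogram_tsv <- function(pg, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(sprintf("# dominant_period=%s",
                     format(pg$dominant_period, digits = 10)), con)
  writeLines("period\tpower", con)
  writeLines(sprintf("%s\t%s", formatC(pg$period, digits = 10, format = "g"),
                     formatC(pg$power, digits = 10, format = "g")), con)
  invisible(path)
}

#' @rdname write_periodogram_tsv
#' @param fit a `curvature_fit`
#' @export
write_fit_tsv <- function(fit, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines("a\tb\tc\tsecond_derivative\tse_a\tnormalized\tn_points", con)
  writeLines(sprintf("%.10g\t%.10g\t%.10g\t%.10g\t%.10g\t%s\t%d",
                     fit$a, fit$b, fit$c, fit$second_derivative, fit$se_a,
                     fit$normalized, fit$n_points), con)
  invisible(path)
}
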