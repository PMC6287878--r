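#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generative model used by [generate_genome()],
#' [generate_mutations()] and [generate_lesion_reads()]. The model places
#' nucleosome dyads on a random genome and modulates per-site mutation (and
#' lesion) probability inside each 147-bp core particle with a rotational
#' cosine of period `rot_period` and a quadratic translational term, on top of
#' a trinucleotide-context bias:
#'
#' \deqn{p(site) = r_0 \cdot w(trinuc) \cdot
#'   (1 + A\cos(2\pi o / T + \phi)) \cdot (1 + c_q (1 - (o/73)^2))}
#'
#' for dyad-relative offset `o` in -73..+73, and \eqn{p = r_0 w(trinuc)}
#' outside all core particles. Probabilities are clipped to \[0, 1\]; the
#' defaults never trigger clipping.
#'
#' @param genome_length genome size in bp
#' @param n_dyads number of nucleosome dyads to place
#' @param min_dyad_spacing minimum pairwise dyad distance in bp (147 keeps
#'   core particles disjoint)
#' @param base_mut_rate per-site, per-donor mutation probability at
#'   dipyrimidine-context sites before modulation
#' @param n_donors number of simulated donors (tumors); sites are sampled
#'   without replacement within a donor, independently across donors
#' @param rot_amplitude unitless rotational amplitude `A >= 0`
#' @param rot_period rotational period in bp (10.3 = helical repeat on the
#'   histone surface)
#' @param rot_phase radians; the default `pi` puts cosine maxima (outward
#'   settings) at offsets ~±5.15 + 10.3k and treats the dyad as inward
#' @param curv_coeff unitless quadratic depth `c_q` (positive = dyad-peaked)
#' @param context_bias named numeric vector of relative weights per
#'   trinucleotide; unnamed contexts get weight 1
#' @param tt_inward_bias factor `>= 1` enriching TT dinucleotides at inward
#'   rotational settings of the generated sequence
#' @param base_probs length-4 named probability vector over A/C/G/T for the
#'   background sequence composition
#' @param seed integer seed; the same seed and config give bit-identical
#'   output
#' @return an object of class `synthetic_config`
#' @export
synthetic_config <- function(genome_length = 1500000L,
                             n_dyads = 5000L,
                             min_dyad_spacing = 147L,
                             base_mut_rate = 0.005,
                             n_donors = 20L,
                             rot_amplitude = 0.3,
                             rot_period = 10.3,
                             rot_phase = pi,
                             curv_coeff = 0.1,
                             context_bias = NULL,
                             tt_inward_bias = 1,
                             base_probs = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                             seed = 1L) {
  cfg <- structure(list(
    genome_length = as.integer(genome_length),
    n_dyads = as.integer(n_dyads),
    min_dyad_spacing = as.integer(min_dyad_spacing),
    base_mut_rate = base_mut_rate,
    n_donors = as.integer(n_donors),
    rot_amplitude = rot_amplitude,
    rot_period = rot_period,
    rot_phase = rot_phase,
    curv_coeff = curv_coeff,
    context_bias = context_bias,
    tt_inward_bias = tt_inward_bias,
    base_probs = base_probs,
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_dyads > 0 &&
      cfg$genome_length < cfg$n_dyads * cfg$min_dyad_spacing + 147L) {
    stop("infeasible packing: genome_length must be >= ",
         "n_dyads * min_dyad_spacing + 147")
  }
  if (cfg$rot_period <= 2) stop("rot_period must be > 2 bp")
  if (cfg$base_mut_rate <= 0 || cfg$base_mut_rate >= 1)
    stop("base_mut_rate must lie in (0, 1)")
  if (cfg$rot_amplitude < 0) stop("rot_amplitude must be >= 0")
  if (cfg$tt_inward_bias < 1) stop("tt_inward_bias must be >= 1")
  if (abs(sum(cfg$base_probs) - 1) > 1e-8 || any(cfg$base_probs < 0))
    stop("base_probs must be a probability vector over A/C/G/T")
  if (!identical(sort(names(cfg$base_probs)), BASES))
    stop("base_probs must be named A, C, G, T")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:",
      sprintf("%d bp genome, %d dyads (spacing >= %d bp)",
              x$genome_length, x$n_dyads, x$min_dyad_spacing), "\n")
  cat(sprintf("  mutation model: rate %.4g x %d donors, A = %.3g @ %.3g bp, c_q = %.3g\n",
              x$base_mut_rate, x$n_donors, x$rot_amplitude, x$rot_period,
              x$curv_coeff))
  invisible(x)
}

# rotational/translational modulation factors at dyad-relative offsets;
# errors out before any sampling if a factor could push a probability < 0
modulation_factors <- function(offsets, cfg) {
  rot <- 1 + cfg$rot_amplitude *
    cos(2 * pi * offsets / cfg$rot_period + cfg$rot_phase)
  curv <- 1 + cfg$curv_coeff * (1 - (offsets / 73)^2)
  if (any(rot < 0) || any(curv < 0)) {
    stop("rot_amplitude or curv_coeff makes a site probability negative")
  }
  rot * curv
}
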