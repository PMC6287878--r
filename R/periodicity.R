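#' Lomb-Scargle periodogram of a position profile
#'
#' Classical Lomb normalized periodogram (with the phase-invariant tau
#' correction) of the mean-centered profile, evaluated on `n_freq` evenly
#' spaced frequencies spanning `[1/period_max, 1/period_min]` — fine enough
#' that the grid step near 10 bp is well below 0.1 bp. Masked offsets are
#' simply absent from the (then unevenly sampled) series, which is exactly
#' the case Lomb-Scargle handles. `dominant_period` is the grid period of
#' maximal power after discarding periods above `exclusion_max` (long-period
#' trends leak power there; the rotational analysis excludes periods > 100
#' bp).
#'
#' @param profile a [position_profile()] (or numeric vector of values at
#'   offsets centered on 0)
#' @param period_min,period_max period search range in bp
#' @param exclusion_max discard periods above this before picking the
#'   dominant one; NULL keeps all
#' @param n_freq number of grid frequencies
#' @return object of class `periodogram_result`: `period`, `power`,
#'   `dominant_period` (NA with `no_signal = TRUE` for a constant profile),
#'   `max_power`, `exclusion_max`
#' @export
periodogram <- function(profile, period_min = 3, period_max = 150,
                        exclusion_max = NULL, n_freq = 2000L) {
  if (inherits(profile, "position_profile")) {
    x <- profile$offsets; y <- profile$values
  } else {
    y <- as.numeric(profile)
    x <- seq_along(y) - (length(y) + 1) / 2
  }
  keep <- !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10L) stop("periodogram needs >= 10 unmasked offsets")
  freq <- seq(1 / period_max, 1 / period_min, length.out = n_freq)
  period <- 1 / freq
  if (sd(y) == 0) {
    return(structure(list(period = period, power = rep(0, n_freq),
                          dominant_period = NA_real_, max_power = 0,
                          no_signal = TRUE, exclusion_max = exclusion_max),
                     class = "periodogram_result"))
  }
  pw <- lomb_power(x, y - mean(y), freq)
  sel <- if (is.null(exclusion_max)) rep(TRUE, n_freq) else
    period <= exclusion_max
  i <- which(sel)[which.max(pw[sel])]
  structure(list(period = period, power = pw,
                 dominant_period = period[i], max_power = pw[i],
                 no_signal = FALSE, exclusion_max = exclusion_max),
            class = "periodogram_result")
}

#' @export
print.periodogram_result <- function(x, ...) {
  if (isTRUE(x$no_signal)) {
    cat("periodogram_result: constant profile, no signal\n")
  } else {
    cat(sprintf("periodogram_result: dominant period %.2f bp (power %.3g%s)\n",
                x$dominant_period, x$max_power,
                if (!is.null(x$exclusion_max))
                  sprintf(", periods > %g bp excluded", x$exclusion_max)
                else ""))
  }
  invisible(x)
}

# classical Lomb periodogram, Scargle normalization (power / (2 * variance));
# vectorized over the frequency grid
lomb_power <- function(t, y, freq) {
  w <- 2 * pi * freq                       # angular frequencies, length m
  wt <- outer(w, t)                        # m x n
  tau_num <- rowSums(sin(2 * wt))
  tau_den <- rowSums(cos(2 * wt))
  wtau <- 0.5 * atan2(tau_num, tau_den)
  arg <- wt - wtau                         # w * (t - tau)
  ca <- cos(arg); sa <- sin(arg)
  yc <- as.numeric(ca %*% y)
  ys <- as.numeric(sa %*% y)
  p <- 0.5 * (yc^2 / rowSums(ca^2) + ys^2 / rowSums(sa^2))
  s2 <- sum(y^2) / (length(y) - 1)
  p / s2
}

#' Permutation null envelope for periodogram peak power
#'
#' Shuffles the unmasked profile values across offsets (destroying any
#' spatial structure while keeping the value distribution), recomputes the
#' peak periodogram power each time, and returns the requested quantile.
#' An observed peak below this envelope is indistinguishable from noise.
#'
#' @param profile a [position_profile()]
#' @param n_perm number of permutations
#' @param prob quantile of the null peak-power distribution
#' @param exclusion_max passed to [periodogram()]
#' @param seed integer seed
#' @return the envelope (numeric scalar), with the null peak powers as
#'   attribute `"null_powers"`
#' @export
ls_null_envelope <- function(profile, n_perm = 200L, prob = 0.95,
                             exclusion_max = 100, seed = 1L) {
  vals <- profile$values
  keep <- !is.na(vals)
  with_seed(seed, {
    powers <- vapply(seq_len(n_perm), function(i) {
      v <- vals
      v[keep] <- sample(vals[keep])
      p <- position_profile(v, half_width = max(profile$offsets),
                            n_nucleosomes = profile$n_nucleosomes,
                            kind = "perm")
      periodogram(p, exclusion_max = exclusion_max)$max_power
    }, numeric(1))
    out <- unname(quantile(powers, prob))
    attr(out, "null_powers") <- powers
    out
  })
}

#' Quadratic (translational curvature) fit of a profile
#'
#' Least-squares fit of `y = a x^2 + b x + c` with `x` the offset in bp;
#' masked offsets are skipped. The curvature statistic is the second
#' derivative `2a`; negative curvature (`a < 0`) means a dyad-peaked
#' profile. With `normalize = TRUE` the profile is first divided by its
#' unmasked mean, putting cohorts of different depth on a common scale.
#'
#' @param profile a [position_profile()]
#' @param normalize divide by the unmasked mean before fitting
#' @return object of class `curvature_fit`: `a`, `b`, `c`,
#'   `second_derivative` (= `2a`), `se_a` (standard error of `a`),
#'   `normalized`, `n_points`
#' @export
fit_quadratic <- function(profile, normalize = FALSE) {
  x <- profile$offsets; y <- profile$values
  keep <- !is.na(y)
  if (sum(keep) < 3L) stop("fit_quadratic needs >= 3 unmasked offsets")
  x <- x[keep]; y <- y[keep]
  if (normalize) y <- y / mean(y)
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  # suppress the "essentially perfect fit" note vcov emits on noiseless input
  se_a <- suppressWarnings(sqrt(diag(vcov(fit)))[["I(x^2)"]])
  structure(list(a = unname(cf[["I(x^2)"]]), b = unname(cf[["x"]]),
                 c = unname(cf[["(Intercept)"]]),
                 second_derivative = 2 * unname(cf[["I(x^2)"]]),
                 se_a = se_a, normalized = normalize,
                 n_points = sum(keep)),
            class = "curvature_fit")
}

#' @export
print.curvature_fit <- function(x, ...) {
  cat(sprintf("curvature_fit: a = %.4g (2a = %.4g, se(a) = %.2g)%s, %d points\n",
              x$a, x$second_derivative, x$se_a,
              if (x$normalized) ", mean-normalized" else "", x$n_points))
  invisible(x)
}
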