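#' Specification for a synthetic solubility-like regression problem
#'
#' Describes a reproducible regression data set with the statistical structure
#' the conformal machinery assumes: a handful of informative descriptors, many
#' pure-noise descriptors, and heteroscedastic measurement error whose scale
#' grows with one observable, molecular-weight-like "driver" descriptor.
#' Compounds with a large driver value are harder to predict, so normalized
#' conformal predictors have per-compound difficulty to exploit.
#'
#' Defaults are the package's standard study conditions: 5 informative
#' descriptors with effect sizes declining from 1.5 to 0.5 Log(S) per SD,
#' 50 noise descriptors, and error SD `0.2 + 0.6 * driver` Log(S), where the
#' driver is the first informative descriptor stored as an absolute value
#' (positive, right-skewed, as a molecular weight would be after scaling).
#'
#' @param n_samples number of compounds to simulate.
#' @param n_informative number of descriptors that enter the true response.
#' @param n_noise number of descriptors unrelated to the response.
#' @param effect_sizes numeric vector of length `n_informative`; linear
#'   coefficients of the informative descriptors (Log(S) units per SD).
#' @param hetero_driver_index index (into the full descriptor matrix) of the
#'   descriptor whose magnitude scales the error SD.
#' @param noise_base baseline error SD in Log(S) units (must be >= 0).
#' @param noise_slope increase in error SD per unit of the driver (>= 0).
#' @param seed integer seed; identical specs give byte-identical data.
#' @return An object of class `synth_spec`.
#' @seealso [generate_dataset()]
#' @export
synth_spec <- function(n_samples,
                       n_informative = 5L,
                       n_noise = 50L,
                       effect_sizes = seq(1.5, 0.5, length.out = n_informative),
                       hetero_driver_index = 1L,
                       noise_base = 0.2,
                       noise_slope = 0.6,
                       seed = 1L) {
  if (!is_count(n_samples)) stopf("n_samples must be a positive integer")
  if (!is_count(n_informative)) stopf("n_informative must be a positive integer")
  if (!(is_count(n_noise) || identical(as.numeric(n_noise), 0))) {
    stopf("n_noise must be a non-negative integer")
  }
  if (n_informative + n_noise < 1) stopf("need at least one descriptor")
  if (length(effect_sizes) != n_informative || !all(is.finite(effect_sizes))) {
    stopf("effect_sizes must be a finite vector of length n_informative")
  }
  p <- n_informative + n_noise
  if (!is_count(hetero_driver_index) || hetero_driver_index > p) {
    stopf("hetero_driver_index must index one of the %d descriptors", p)
  }
  if (!is.numeric(noise_base) || noise_base < 0 || !is.finite(noise_base)) {
    stopf("noise_base must be a non-negative number")
  }
  if (!is.numeric(noise_slope) || noise_slope < 0 || !is.finite(noise_slope)) {
    stopf("noise_slope must be a non-negative number")
  }
  if (!is_count(abs(seed) + 1)) stopf("seed must be an integer")
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_informative = as.integer(n_informative),
      n_noise = as.integer(n_noise),
      effect_sizes = as.numeric(effect_sizes),
      hetero_driver_index = as.integer(hetero_driver_index),
      noise_base = noise_base,
      noise_slope = noise_slope,
      seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

#' Generate a synthetic descriptor table
#'
#' Draws descriptors i.i.d. standard normal (the driver column is stored as
#' its absolute value so the noise scale is well defined and the column mimics
#' a positive size-like descriptor) and the target
#' `y = sum(effect_sizes * x_informative) + eps` with
#' `SD(eps) = noise_base + noise_slope * |x_driver|`.
#' Informative columns are named `sig_*`, noise columns `noise_*`.
#'
#' @param spec a [synth_spec()].
#' @return A [descriptor_table()] with `n_samples` rows; deterministic under
#'   the spec's seed.
#' @examples
#' tab <- generate_dataset(synth_spec(100, seed = 7))
#' dim(tab$X)
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synth_spec")) stopf("spec must be a synth_spec")
  p <- spec$n_informative + spec$n_noise
  with_seed(spec$seed, {
    X <- matrix(stats::rnorm(spec$n_samples * p), nrow = spec$n_samples, ncol = p)
    colnames(X) <- c(
      sprintf("sig_%02d", seq_len(spec$n_informative)),
      if (spec$n_noise > 0) sprintf("noise_%02d", seq_len(spec$n_noise))
    )
    X[, spec$hetero_driver_index] <- abs(X[, spec$hetero_driver_index])
    driver <- abs(X[, spec$hetero_driver_index])
    sd_eps <- spec$noise_base + spec$noise_slope * driver
    eps <- stats::rnorm(spec$n_samples, mean = 0, sd = sd_eps)
    y <- drop(X[, seq_len(spec$n_informative), drop = FALSE] %*% spec$effect_sizes) + eps
    descriptor_table(
      ids = sprintf("cmpd_%05d", seq_len(spec$n_samples)),
      X = X,
      y = y
    )
  })
}

#' Reference worked example for interval arithmetic
#'
#' A fixed literature-style reference case (1-pentanol in water): predicted
#' Log(S) of -0.42 with a normalized 90% confidence half-width of 0.802 and a
#' constant-width (AR) 90% half-width of 1.229. Used for exact checks of the
#' interval construction: the normalized interval is (-1.222, 0.382) and the
#' AR interval is (-1.649, 0.809).
#'
#' @return A list with elements `center`, `halfwidths` (named by confidence
#'   level, here `"90"`), and `ar_halfwidths` (same shape, AR baseline).
#' @export
worked_example <- function() {
  list(
    center = -0.42,
    halfwidths = c("90" = 0.802),
    ar_halfwidths = c("90" = 1.229)
  )
}
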