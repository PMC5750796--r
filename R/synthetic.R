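#' Default FTIR band table for the two-class tissue generator
#'
#' Gaussian band parameters emulating the major absorption bands of colon
#' tissue FTIR spectra and the directional differences between colitis and
#' cancerous tissue reported in the clinical FTIR literature:
#' lipid bands (1743 C=O; 2858/2924/2958 C-H stretch) are reduced, even
#' near-absent, in cancer; the nucleic-acid band at 1080 is stronger in
#' cancer; the carbohydrate band at 1160 is weaker in cancer; the 1240
#' (RNA) and 1310 (amide III) bands are weaker in colitis; the amide I/II
#' pair (1643/1550) is present in both classes with a lower 1550:1643
#' ratio in cancer; and the 1460:1400 intensity ordering flips between the
#' classes (1460 < 1400 in cancer, 1460 >= 1400 in colitis). The broad
#' 3300 N-H/O-H band is strong in both.
#'
#' Amplitudes are engineering values in absorbance units (the literature
#' reports directions, not magnitudes), chosen so the classes are
#' separable but overlap under the default per-sample variability.
#'
#' @return A data frame with columns `center` (cm^-1), `width` (Gaussian
#'   sd, cm^-1), `amp_colitis`, `amp_cancer` (mean class amplitudes,
#'   absorbance units) and `amp_cv` (coefficient of variation of the
#'   per-sample amplitude).
#' @export
default_band_table <- function() {
  data.frame(
    center      = c(1080, 1160, 1240, 1310, 1400, 1460, 1550, 1643, 1743,
                    2858, 2924, 2958, 3300),
    width       = c(  25,   20,   22,   18,   18,   18,   25,   28,   15,
                      18,   20,   14,  130),
    amp_colitis = c(0.25, 0.35, 0.20, 0.06, 0.25, 0.28, 0.55, 0.65, 0.30,
                    0.40, 0.60, 0.35, 0.90),
    amp_cancer  = c(0.45, 0.18, 0.35, 0.20, 0.30, 0.18, 0.60, 0.85, 0.06,
                    0.12, 0.20, 0.12, 1.00),
    amp_cv      = rep(0.6, 13)
  )
}

# run expr with a private, seeded RNG stream; caller's RNG state untouched
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate two-class FTIR-like tissue spectra
#'
#' Generates absorbance spectra on a regular wavenumber grid as a sum of
#' Gaussian bands with per-sample amplitude jitter, plus a random linear
#' baseline (drift), a per-sample multiplicative scatter factor
#' (log-normal), and additive white noise:
#' \deqn{x_i(\nu) = g_i [\sum_b a_{ib} e^{-(\nu-c_b)^2/2s_b^2}
#'   + \beta_{0i} + \beta_{1i}(\nu - \bar\nu)] + \epsilon_i(\nu)}
#' These are the artefacts that Savitzky-Golay smoothing and SNV
#' normalisation are designed to remove, so generated data exercise the
#' whole preprocessing and classification pipeline. Output is fully
#' deterministic given `seed`.
#'
#' @param n_per_class samples per class. Default 50.
#' @param seed integer RNG seed; the generator uses a private RNG stream
#'   and leaves the caller's RNG state untouched. Default 1.
#' @param bands band table as from [default_band_table()].
#' @param axis_range numeric `c(low, high)` cm^-1. Default `c(1000, 4000)`.
#' @param axis_step grid step in cm^-1. Default 2.
#' @param baseline_slope_sd sd of the random baseline slope (absorbance
#'   per cm^-1). Default `5e-5`.
#' @param baseline_intercept_sd sd of the random baseline offset. Default
#'   0.05.
#' @param scatter_lognorm_sd sd of the log of the multiplicative scatter
#'   factor. Default 0.1.
#' @param noise_sd sd of additive white noise (absorbance units). Default
#'   0.02.
#' @param labels length-2 character vector of class names. Default
#'   `c("cancer", "colitis")`, matching the band table's amplitude columns.
#' @return A [spectra_dataset()] with `2 * n_per_class` samples.
#' @examples
#' ds <- simulate_spectra(n_per_class = 5, seed = 42)
#' ds
#' @export
simulate_spectra <- function(n_per_class = 50L, seed = 1L,
                             bands = default_band_table(),
                             axis_range = c(1000, 4000), axis_step = 2,
                             baseline_slope_sd = 5e-5,
                             baseline_intercept_sd = 0.05,
                             scatter_lognorm_sd = 0.1,
                             noise_sd = 0.02,
                             labels = c("cancer", "colitis")) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("simulate_spectra: n_per_class must be >= 1")
  if (noise_sd < 0 || scatter_lognorm_sd < 0 || baseline_slope_sd < 0 ||
      baseline_intercept_sd < 0)
    stop("simulate_spectra: noise/scatter/baseline sds must be >= 0")
  req <- c("center", "width", "amp_colitis", "amp_cancer", "amp_cv")
  if (!all(req %in% names(bands)))
    stop("simulate_spectra: bands must have columns ",
         paste(req, collapse = ", "))
  if (any(bands$width <= 0) || any(bands$amp_colitis < 0) ||
      any(bands$amp_cancer < 0) || any(bands$amp_cv < 0))
    stop("simulate_spectra: invalid band parameters")
  wn <- seq(axis_range[1], axis_range[2], by = axis_step)
  if (any(bands$center < axis_range[1] | bands$center > axis_range[2]))
    stop("simulate_spectra: band center outside the axis range")

  # one unit-amplitude Gaussian profile per band (n_wavenumbers x n_bands)
  profiles <- vapply(seq_len(nrow(bands)), function(b) {
    exp(-(wn - bands$center[b])^2 / (2 * bands$width[b]^2))
  }, numeric(length(wn)))

  amp_col <- c(cancer = "amp_cancer", colitis = "amp_colitis")
  nu0 <- mean(wn)
  m <- 2L * n_per_class

  with_local_seed(seed, {
    x <- matrix(0, m, length(wn))
    lab <- character(m)
    ids <- character(m)
    row <- 0L
    for (cls in c("cancer", "colitis")) {
      mean_amp <- bands[[amp_col[[cls]]]]
      for (i in seq_len(n_per_class)) {
        row <- row + 1L
        amps <- pmax(mean_amp * (1 + bands$amp_cv * stats::rnorm(nrow(bands))),
                     0)
        signal <- drop(profiles %*% amps)
        slope <- stats::rnorm(1L, sd = baseline_slope_sd)
        intercept <- stats::rnorm(1L, sd = baseline_intercept_sd)
        scatter <- exp(stats::rnorm(1L, sd = scatter_lognorm_sd))
        x[row, ] <- scatter * (signal + intercept + slope * (wn - nu0)) +
          stats::rnorm(length(wn), sd = noise_sd)
        lab[row] <- if (cls == "cancer") labels[1] else labels[2]
        ids[row] <- sprintf("%s_%03d", lab[row], i)
      }
    }
    spectra_dataset(x, wn, lab, ids)
  })
}
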