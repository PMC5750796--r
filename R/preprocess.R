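#' Savitzky-Golay smoothing of spectra
#'
#' Applies a Savitzky-Golay least-squares polynomial smoothing filter to each
#' spectrum independently. The filter slides a window of `window` points
#' along the spectrum and replaces the centre value by the value of a
#' polynomial of degree `polyorder` fitted to the window; this suppresses
#' high-frequency random noise while preserving band shape. At the spectrum
#' boundaries the polynomial is fitted to the nearest full window of
#' available points and evaluated at the edge positions (no mirroring), so
#' the filter reproduces any polynomial of degree `polyorder` or lower
#' exactly at every position.
#'
#' @param ds a [spectra_dataset()].
#' @param window odd integer window width in points, >= 3. Default 5, the
#'   conventional width for 4 cm^-1-resolution FTIR spectra.
#' @param polyorder polynomial degree, < `window`. Default 2.
#' @return The smoothed `spectra_dataset` (same dimensions).
#' @export
savgol_smooth <- function(ds, window = 5L, polyorder = 2L) {
  stopifnot(inherits(ds, "spectra_dataset"))
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window < 3L || window %% 2L == 0L)
    stop("savgol_smooth: window must be an odd integer >= 3")
  if (polyorder < 0L || polyorder >= window)
    stop("savgol_smooth: polyorder must satisfy 0 <= polyorder < window")
  n <- ncol(ds$absorbance)
  if (n < window)
    stop("savgol_smooth: spectrum has ", n, " points, fewer than window ",
         window)
  sm <- t(apply(ds$absorbance, 1L, signal::sgolayfilt,
                p = polyorder, n = window))
  spectra_dataset(sm, ds$wavenumbers, ds$labels, ds$sample_ids,
                  regions = ds$regions)
}

#' Standard normal variate (SNV) normalisation
#'
#' Standardises each spectrum within each wavenumber region independently:
#' for sample i and region segment x, the output is
#' \deqn{x_{SNV} = (x - \bar{x}_i) / s_i}
#' where \eqn{\bar{x}_i} is the segment mean and \eqn{s_i} the segment
#' sample standard deviation (denominator n-1). SNV removes per-sample
#' multiplicative scatter, offset and slope interference: after SNV every
#' row-region has mean 0 and sample standard deviation 1, and
#' `snv(a*x + b) == snv(x)` for any a > 0.
#'
#' Regions default to the dataset's recorded regions (set by
#' [select_regions()]) or, failing that, a single region spanning the axis.
#'
#' @param ds a [spectra_dataset()].
#' @param regions optional list of `c(low, high)` cm^-1 intervals; each
#'   row-region segment is standardised on its own.
#' @return The normalised `spectra_dataset`.
#' @export
snv_normalize <- function(ds, regions = NULL) {
  stopifnot(inherits(ds, "spectra_dataset"))
  if (is.null(regions)) regions <- ds$regions
  if (is.null(regions))
    regions <- list(range(ds$wavenumbers))
  regions <- validate_regions(regions)
  member <- region_membership(ds$wavenumbers, regions)
  out <- ds$absorbance
  for (r in seq_along(regions)) {
    idx <- which(member == r)
    if (length(idx) == 0L) next
    if (length(idx) < 2L)
      stop("snv_normalize: region ", paste(regions[[r]], collapse = "-"),
           " contains fewer than 2 points")
    seg <- ds$absorbance[, idx, drop = FALSE]
    mu <- rowMeans(seg)
    sdv <- apply(seg, 1L, stats::sd)
    flat <- sdv == 0
    if (any(flat))
      stop("snv_normalize: zero within-region standard deviation for ",
           "sample(s) ", paste(ds$sample_ids[flat], collapse = ", "),
           " in region ", paste(regions[[r]], collapse = "-"))
    out[, idx] <- (seg - mu) / sdv
  }
  dropped <- is.na(member)
  if (any(dropped)) {
    out <- out[, !dropped, drop = FALSE]
    wn <- ds$wavenumbers[!dropped]
  } else wn <- ds$wavenumbers
  spectra_dataset(out, wn, ds$labels, ds$sample_ids, regions = regions)
}

#' Full spectra preprocessing pipeline
#'
#' Savitzky-Golay smoothing followed by region selection and region-wise SNV
#' normalisation, in that order (smoothing must see the raw spectrum; SNV
#' rescales it afterwards).
#'
#' @inheritParams savgol_smooth
#' @param regions list of `c(low, high)` cm^-1 intervals for region
#'   selection and region-wise SNV. Default
#'   `list(c(1000, 1800), c(2800, 3800))`, the two biologically informative
#'   windows of tissue FTIR spectra.
#' @return The preprocessed `spectra_dataset`.
#' @examples
#' ds <- simulate_spectra(n_per_class = 5, seed = 1)
#' prep <- preprocess_spectra(ds)
#' prep
#' @export
preprocess_spectra <- function(ds, window = 5L, polyorder = 2L,
                               regions = list(c(1000, 1800),
                                              c(2800, 3800))) {
  ds <- savgol_smooth(ds, window = window, polyorder = polyorder)
  ds <- select_regions(ds, regions)
  snv_normalize(ds)
}
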