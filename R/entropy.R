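#' Entropy-based feature weights
#'
#' Computes one weight per feature (wavenumber channel) from the Shannon
#' entropy of the column's value distribution across training samples. Each
#' column is normalised to a discrete distribution
#' \eqn{z_{ij} = x_{ij} / \sum_i x_{ij}}, its entropy
#' \eqn{H_j = -\beta \sum_i z_{ij} \log z_{ij}} with
#' \eqn{\beta = 1/\log(m)} lies in \[0, 1\], and the weights
#' \deqn{w_j = (1 - H_j) / (n - \sum_j H_j)}
#' sum to 1. A column that is constant across samples carries no
#' discriminative information, has entropy 1, and receives weight 0; the
#' lower a column's entropy (the more concentrated its mass on few
#' samples), the larger its weight.
#'
#' Columns containing zero or negative values (SNV output is signed) are
#' first shifted by `-min + eps` with `eps = 1e-12 * range` (or `1e-12` for
#' a constant column) so the normalisation is defined; strictly positive
#' columns enter unchanged. The convention `0 * log(0) = 0` applies.
#'
#' If every column has entropy exactly 1 (all columns constant) the weight
#' denominator vanishes; the function then falls back to uniform weights
#' `1/n` with a warning.
#'
#' @param x numeric matrix, m samples (rows) by n features (columns),
#'   m >= 2.
#' @return An object of class `"entropy_weights"`: list with `w` (n
#'   weights, summing to 1), `h` (n entropies in \[0, 1\]) and `beta`
#'   (`1/log(m)`).
#' @examples
#' entropy_weights(matrix(c(1, 3, 2, 2), nrow = 2))$w  # constant column -> 0
#' @export
entropy_weights <- function(x) {
  x <- as.matrix(x)
  m <- nrow(x)
  n <- ncol(x)
  if (m < 2L) stop("entropy_weights: at least 2 samples are required")
  if (anyNA(x) || any(!is.finite(x)))
    stop("entropy_weights: non-finite values in x")

  # establish positivity only where needed, preserving ordering and spread
  mins <- apply(x, 2L, min)
  needs <- mins <= 0
  if (any(needs)) {
    rng <- apply(x[, needs, drop = FALSE], 2L, function(v) diff(range(v)))
    eps <- ifelse(rng > 0, 1e-12 * rng, 1e-12)
    x[, needs] <- sweep(x[, needs, drop = FALSE], 2L, mins[needs] - eps, "-")
  }

  colsum <- colSums(x)
  if (any(colsum <= 0))
    stop("entropy_weights: non-positive column sum after shift")
  z <- sweep(x, 2L, colsum, "/")
  beta <- 1 / log(m)
  plogp <- ifelse(z > 0, z * log(z), 0)   # 0*log(0) := 0
  h <- -beta * colSums(plogp)
  h <- pmin(pmax(h, 0), 1)                # clamp fp noise at the boundaries
  denom <- n - sum(h)
  if (denom <= 0) {
    warning("entropy_weights: all features have maximal entropy; ",
            "falling back to uniform weights")
    w <- rep(1 / n, n)
  } else {
    w <- (1 - h) / denom
  }
  structure(list(w = w, h = h, beta = beta), class = "entropy_weights")
}

#' @export
print.entropy_weights <- function(x, ...) {
  cat("Entropy feature weights: n =", length(x$w),
      " sum(w) =", format(sum(x$w)), "\n")
  cat("  w: min", format(min(x$w), digits = 4),
      " median", format(stats::median(x$w), digits = 4),
      " max", format(max(x$w), digits = 4), "\n")
  invisible(x)
}

#' Entropy-weighted Euclidean distance
#'
#' \deqn{D(x, q) = \sqrt{\sum_j w_j (x_j - q_j)^2}}
#' With uniform weights `1/n` this is the Euclidean distance divided by
#' `sqrt(n)`.
#'
#' @param x,q numeric vectors of equal length.
#' @param w an [entropy_weights()] object or a numeric weight vector.
#' @return Non-negative scalar distance.
#' @export
weighted_distance <- function(x, q, w) {
  if (inherits(w, "entropy_weights")) w <- w$w
  if (length(x) != length(q) || length(x) != length(w))
    stop("weighted_distance: x, q and w must have equal length")
  sqrt(sum(w * (x - q)^2))
}
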