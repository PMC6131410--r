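#' First-order (intensity) features of an ROI
#'
#' Computes the 14 intensity-distribution features of a pixel multiset, in
#' canonical order: energy, entropy, kurtosis, maximum, mean, mean absolute
#' deviation, median, minimum, range, root mean square, skewness, standard
#' deviation, uniformity, variance.
#'
#' Moments are population moments (1/N); kurtosis is non-excess (a Gaussian
#' scores 3). Entropy (base 2) and uniformity are computed over the occupied
#' bins of an equal-width histogram with `histogram_levels` bins spanning the
#' value range; a constant input has entropy 0 and uniformity 1. For a
#' zero-variance input, skewness and kurtosis are defined as 0 so that
#' downstream standardization never sees non-finite values.
#'
#' @param values Numeric vector of in-ROI intensities (length >= 2).
#' @param histogram_levels Number of histogram bins for entropy/uniformity.
#' @return Named numeric vector of length 14.
#' @export
first_order_features <- function(values, histogram_levels = 64L) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("first-order features need at least 2 values")
  if (any(!is.finite(values))) stop("non-finite intensity values")
  n <- length(values)
  mu <- mean(values)
  dev <- values - mu
  m2 <- mean(dev^2)
  sk <- if (m2 > 0) mean(dev^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean(dev^4) / m2^2 else 0

  p <- histogram_probs(values, histogram_levels)
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  unif <- sum(p^2)

  c(energy = sum(values^2),
    entropy = ent,
    kurtosis = ku,
    maximum = max(values),
    mean = mu,
    mad = mean(abs(dev)),
    median = median(values),
    minimum = min(values),
    range = max(values) - min(values),
    rms = sqrt(mean(values^2)),
    skewness = sk,
    sd = sqrt(m2),
    uniformity = unif,
    variance = m2)
}

# equal-width histogram probabilities over [min, max]; constant input -> all
# mass in bin 1 (same binning rule as quantize())
histogram_probs <- function(values, nbins) {
  nbins <- as.integer(nbins)
  stopifnot(nbins >= 2L)
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    p <- numeric(nbins)
    p[1L] <- 1
    return(p)
  }
  w <- (hi - lo) / nbins
  lv <- 1L + as.integer(floor((values - lo) / w))
  lv[lv > nbins] <- nbins
  tabulate(lv, nbins) / length(values)
}
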