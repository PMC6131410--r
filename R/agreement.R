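#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Single-measure, absolute-agreement ICC from the two-way ANOVA
#' decomposition of an n subjects x k raters rating matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with the
#' F-based confidence interval of McGraw and Wong (Satterthwaite degrees
#' of freedom for the column mean square).
#'
#' @param ratings n x k numeric matrix (subjects in rows), or the rater-1
#'   vector when `ratings2` is given.
#' @param ratings2 Optional rater-2 vector, paired with `ratings`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `ci` (length 2), `n`, `k`, and the mean
#'   squares `msr`, `msc`, `mse`.
#' @export
icc_two_way_random <- function(ratings, ratings2 = NULL,
                               conf_level = 0.95) {
  if (!is.null(ratings2)) {
    stopifnot(length(ratings) == length(ratings2))
    ratings <- cbind(ratings, ratings2)
  }
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("at least 5 subjects are required")
  if (k < 2L) stop("at least 2 raters are required")
  if (any(!is.finite(ratings))) stop("ratings must be finite")

  grand <- mean(ratings)
  rowm <- rowMeans(ratings)
  colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  if (sst < .Machine$double.eps * max(1, abs(grand))^2 * n * k) {
    warning("zero total variance; ICC defined as 1")
    return(list(icc = 1, ci = c(1, 1), n = n, k = k,
                msr = msr, msc = msc, mse = mse))
  }

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- (msr - mse) / denom
  if (1 - icc < 1e-12) {
    # perfect agreement: the F-based interval degenerates
    return(list(icc = icc, ci = c(1, 1), n = n, k = k,
                msr = msr, msc = msc, mse = mse))
  }

  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci = c(max(-1, lower), min(1, upper)), n = n, k = k,
       msr = msr, msc = msc, mse = mse)
}

#' Simulate a second rater's ROI by seeded mask perturbation
#'
#' Applies a random one-pixel morphological dilation or erosion
#' (4-neighborhood) and random flips of boundary pixels, emulating the
#' small contouring differences between two readers drawing the same
#' lesion. The result is guaranteed non-empty with at least 16 pixels
#' (erosion is skipped when it would shrink the ROI below that).
#'
#' @param mask Logical ROI mask.
#' @param seed Integer seed.
#' @param p_flip Probability of flipping each boundary pixel.
#' @return Perturbed logical mask.
#' @export
perturb_mask <- function(mask, seed = 1L, p_flip = 0.15) {
  stopifnot(is.matrix(mask), is.logical(mask))
  shift <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  dil <- function(m) m | shift(m, 1, 0) | shift(m, -1, 0) |
    shift(m, 0, 1) | shift(m, 0, -1)
  ero <- function(m) m & shift(m, 1, 0) & shift(m, -1, 0) &
    shift(m, 0, 1) & shift(m, 0, -1)
  with_seed(seed, {
    op <- sample(c("dilate", "erode", "none"), 1L)
    m2 <- switch(op, dilate = dil(mask), erode = ero(mask), none = mask)
    if (sum(m2) < 16L) m2 <- mask
    boundary <- (dil(m2) & !ero(m2))
    flip <- boundary & matrix(runif(length(m2)) < p_flip,
                              nrow(m2), ncol(m2))
    m3 <- xor(m2, flip)
    if (sum(m3) < 16L) m3 <- m2
    m3
  })
}

#' Interobserver agreement summary grid
#'
#' Computes ICC(2,1) for each of the 730 features between two raters'
#' feature tables and summarizes the minimum and maximum ICC per
#' (direction x subband) cell: directions 0/45/90/135 degrees, subbands
#' `orig`, `HH`, `HL`, `LH`, `LL`. First-order features carry no
#' direction and are reported in a separate `firstorder` row.
#'
#' @param features_r1,features_r2 Feature tables (or matrices) sharing the
#'   730 feature columns and lesion order; a `lesion_id` column, if
#'   present, is used to align rows.
#' @return Data frame with a `direction` column and one `"min, max"`
#'   column per subband; attribute `"icc"` holds the per-feature ICCs.
#' @export
icc_summary_table <- function(features_r1, features_r2) {
  fn <- feature_names_730()
  for (tb in list(features_r1, features_r2)) {
    miss <- setdiff(fn, colnames(tb))
    if (length(miss)) {
      stop("feature schema mismatch; missing: ",
           paste(head(miss, 5L), collapse = ", "),
           if (length(miss) > 5L) " ...")
    }
  }
  if (is.data.frame(features_r1) && is.data.frame(features_r2) &&
      "lesion_id" %in% names(features_r1) &&
      "lesion_id" %in% names(features_r2)) {
    if (!setequal(features_r1$lesion_id, features_r2$lesion_id)) {
      stop("the two tables rate different lesions")
    }
    features_r2 <- features_r2[match(features_r1$lesion_id,
                                     features_r2$lesion_id), ]
  }
  A <- as.matrix(as.data.frame(features_r1)[, fn])
  B <- as.matrix(as.data.frame(features_r2)[, fn])
  if (nrow(A) != nrow(B)) stop("rating tables have different lesion counts")
  icc <- vapply(seq_along(fn), function(j) {
    suppressWarnings(icc_two_way_random(A[, j], B[, j])$icc)
  }, numeric(1))
  names(icc) <- fn

  dict <- feature_dictionary()
  subbands <- c("orig", "HH", "HL", "LH", "LL")
  dirs <- c("0", "45", "90", "135")
  grid <- matrix(NA_character_, length(dirs) + 1L, length(subbands),
                 dimnames = list(c(dirs, "firstorder"), subbands))
  cell <- function(v) {
    if (length(v) == 0L) return(NA_character_)
    sprintf("%.3f, %.3f", min(v), max(v))
  }
  for (sb in subbands) {
    for (d in dirs) {
      sel <- dict$subband == sb & !is.na(dict$angle) &
        dict$angle == as.integer(d)
      grid[d, sb] <- cell(icc[dict$name[sel]])
    }
    sel <- dict$subband == sb & dict$family == "firstorder"
    grid["firstorder", sb] <- cell(icc[dict$name[sel]])
  }
  out <- data.frame(direction = rownames(grid), grid,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "icc") <- icc
  out
}
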