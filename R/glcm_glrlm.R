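#' @name texture-matrices
#' @title Gray-level co-occurrence and run-length matrices
#'
#' @description
#' Texture matrices are built from a [quantize()]d patch at the four
#' directions 0, 45, 90 and 135 degrees. The image coordinate convention is
#' row-major with the row index increasing downward, so the direction
#' offsets (delta row, delta col) are: 0 deg = (0, 1), 45 deg = (-1, 1),
#' 90 deg = (-1, 0), 135 deg = (-1, -1).
#'
#' Only pixel pairs (or run pixels) with every endpoint inside the ROI mask
#' contribute; runs are additionally broken by the mask boundary and the
#' image edge.
NULL

ANGLES <- c(0L, 45L, 90L, 135L)

angle_offset <- function(angle) {
  switch(as.character(angle),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("angle must be one of 0, 45, 90, 135 (got ", angle, ")"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts every ordered in-mask pixel pair separated by the direction offset
#' scaled by `distance`, accumulates symmetrically (each pair contributes to
#' `(i, j)` and `(j, i)`), and normalizes to sum 1.
#'
#' @param patch A `quantized_patch` from [quantize()].
#' @param angle One of 0, 45, 90, 135.
#' @param distance Pixel offset magnitude (default 1).
#' @return Object of class `glc_matrix`: list with `P` (Ng x Ng probability
#'   matrix), `angle`, `distance`, `n_pairs` (ordered pair count before
#'   symmetrization).
#' @export
glcm <- function(patch, angle, distance = 1L) {
  stopifnot(inherits(patch, "quantized_patch"))
  off <- angle_offset(angle) * as.integer(distance)
  L <- patch$levels
  nr <- nrow(L); nc <- ncol(L)
  if (nr <= abs(off[1L]) || nc <= abs(off[2L])) {
    stop("no valid in-mask pixel pair at angle ", angle,
         " (distance ", distance, ")")
  }
  r1 <- max(1L, 1L - off[1L]):min(nr, nr - off[1L])
  c1 <- max(1L, 1L - off[2L]):min(nc, nc - off[2L])
  A <- L[r1, c1, drop = FALSE]
  B <- L[r1 + off[1L], c1 + off[2L], drop = FALSE]
  keep <- A > 0L & B > 0L
  if (!any(keep)) {
    stop("no valid in-mask pixel pair at angle ", angle,
         " (distance ", distance, ")")
  }
  i <- A[keep]; j <- B[keep]
  Ng <- patch$Ng
  counts <- matrix(tabulate((j - 1L) * Ng + i, Ng * Ng), Ng, Ng)
  sym <- counts + t(counts)
  structure(list(P = sym / sum(sym), angle = as.integer(angle),
                 distance = as.integer(distance), n_pairs = length(i)),
            class = "glc_matrix")
}

#' GLCM texture features
#'
#' Computes the 22 co-occurrence features in canonical order:
#' autocorrelation, cluster prominence, cluster shade, cluster tendency,
#' contrast, correlation, difference entropy, dissimilarity, energy,
#' entropy, homogeneity 1, homogeneity 2, informational measures of
#' correlation 1 and 2, inverse difference moment normalized, inverse
#' difference normalized, inverse variance, maximum probability, sum
#' average, sum entropy, sum variance, variance.
#'
#' Gray level indices run 1..Ng. All logarithms are base 2 with an additive
#' guard of 1e-12. Correlation is defined as 0 when either marginal standard
#' deviation is 0, and IMC1 as 0 when `max(HX, HY) = 0`.
#'
#' @param M A `glc_matrix` from [glcm()].
#' @return Named numeric vector of length 22.
#' @export
glcm_features <- function(M) {
  stopifnot(inherits(M, "glc_matrix"))
  P <- M$P
  if (abs(sum(P) - 1) > 1e-9) stop("GLCM is not normalized to sum 1")
  eps <- 1e-12
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P)          # marginal over i (== py by symmetry)
  py <- colSums(P)
  mux <- sum(seq_len(Ng) * px)
  muy <- sum(seq_len(Ng) * py)
  sigx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))

  # diagonal (difference) and cross-diagonal (sum) distributions
  d <- abs(i - j)
  pxmy <- vapply(0:(Ng - 1L), function(k) sum(P[d == k]), numeric(1))
  s <- i + j
  pxpy <- vapply(2:(2L * Ng), function(k) sum(P[s == k]), numeric(1))
  ks <- 2:(2L * Ng)

  autoc <- sum(i * j * P)
  cp4 <- (i + j - mux - muy)
  entropy <- -sum(P * log2(P + eps))
  HX <- -sum(px * log2(px + eps))
  HY <- -sum(py * log2(py + eps))
  pxpy_outer <- outer(px, py)
  HXY1 <- -sum(P * log2(pxpy_outer + eps))
  HXY2 <- -sum(pxpy_outer * log2(pxpy_outer + eps))
  imc1 <- if (max(HX, HY) > 0) (entropy - HXY1) / max(HX, HY) else 0
  imc2_arg <- 1 - exp(-2 * (HXY2 - entropy))
  imc2 <- if (imc2_arg > 0) sqrt(imc2_arg) else 0
  corr <- if (sigx > 0 && sigy > 0) {
    (sum(i * j * P) - mux * muy) / (sigx * sigy)
  } else 0
  sa <- sum(ks * pxpy)
  offdiag <- d > 0

  c(autocorrelation = autoc,
    cluster_prominence = sum(cp4^4 * P),
    cluster_shade = sum(cp4^3 * P),
    cluster_tendency = sum(cp4^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference_entropy = -sum(pxmy * log2(pxmy + eps)),
    dissimilarity = sum(d * P),
    energy = sum(P^2),
    entropy = entropy,
    homogeneity1 = sum(P / (1 + d)),
    homogeneity2 = sum(P / (1 + d^2)),
    imc1 = imc1,
    imc2 = imc2,
    idmn = sum(P / (1 + d^2 / Ng^2)),
    idn = sum(P / (1 + d / Ng)),
    inverse_variance = sum(P[offdiag] / d[offdiag]^2),
    maximum_probability = max(P),
    sum_average = sa,
    sum_entropy = -sum(pxpy * log2(pxpy + eps)),
    sum_variance = sum((ks - sa)^2 * pxpy),
    variance = sum((i - mux)^2 * P))
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along the direction; runs are
#' broken by the mask boundary and the image edge, and every in-mask pixel
#' belongs to exactly one run per direction.
#'
#' @param patch A `quantized_patch` from [quantize()].
#' @param angle One of 0, 45, 90, 135.
#' @return Object of class `glrl_matrix`: list with `R` (Ng x Lmax count
#'   matrix), `angle`, `Np` (in-mask pixel count), `Nr` (total run count).
#' @export
glrlm <- function(patch, angle) {
  stopifnot(inherits(patch, "quantized_patch"))
  angle <- as.integer(angle)
  angle_offset(angle)  # validates
  L <- patch$levels
  Np <- sum(L > 0L)
  if (Np == 0L) stop("empty ROI: no in-mask pixels")
  idx_r <- row(L); idx_c <- col(L)
  key <- switch(as.character(angle),
                "0"   = idx_r,
                "45"  = idx_r + idx_c,   # anti-diagonals, contiguous in
                "90"  = idx_c,           # column-major order
                "135" = idx_r - idx_c)
  lines <- split(as.vector(L), as.vector(key))
  Ng <- patch$Ng
  vals <- integer(0); lens <- integer(0)
  for (v in lines) {
    r <- rle(v)
    keep <- r$values > 0L
    if (any(keep)) {
      vals <- c(vals, r$values[keep])
      lens <- c(lens, r$lengths[keep])
    }
  }
  Lmax <- max(lens)
  R <- matrix(tabulate((lens - 1L) * Ng + vals, Ng * Lmax), Ng, Lmax)
  structure(list(R = R, angle = angle, Np = Np, Nr = length(vals)),
            class = "glrl_matrix")
}

#' GLRLM texture features
#'
#' The 11 standard run-length features: short/long run emphasis, gray-level
#' and run-length nonuniformity, run percentage (`Nr / Np`), low/high
#' gray-level run emphasis, and the four joint short/long x low/high
#' emphases. All sums over the run matrix are normalized by the total run
#' count `Nr` except run percentage.
#'
#' @param R A `glrl_matrix` from [glrlm()].
#' @return Named numeric vector of length 11.
#' @export
glrlm_features <- function(R) {
  stopifnot(inherits(R, "glrl_matrix"))
  if (R$Nr < 1L) stop("run-length matrix has no runs")
  Rm <- R$R
  Ng <- nrow(Rm); Lmax <- ncol(Rm)
  gl <- matrix(seq_len(Ng), Ng, Lmax)        # gray level index i
  rl <- matrix(seq_len(Lmax), Ng, Lmax, byrow = TRUE)  # run length j
  Nr <- R$Nr
  c(sre = sum(Rm / rl^2) / Nr,
    lre = sum(Rm * rl^2) / Nr,
    gln = sum(rowSums(Rm)^2) / Nr,
    rln = sum(colSums(Rm)^2) / Nr,
    run_percentage = Nr / R$Np,
    lglre = sum(Rm / gl^2) / Nr,
    hglre = sum(Rm * gl^2) / Nr,
    srlgle = sum(Rm / (gl^2 * rl^2)) / Nr,
    srhgle = sum(Rm * gl^2 / rl^2) / Nr,
    lrlgle = sum(Rm * rl^2 / gl^2) / Nr,
    lrhgle = sum(Rm * gl^2 * rl^2) / Nr)
}

#' Full texture feature block for one patch
#'
#' Concatenates the 22 GLCM and 11 GLRLM features for each of the four
#' directions (132 features), named `glcm_<feature>_<angle>` /
#' `glrlm_<feature>_<angle>`.
#'
#' @param patch A `quantized_patch`.
#' @param distance GLCM pixel offset (default 1).
#' @return Named numeric vector of length 132.
#' @export
texture_block <- function(patch, distance = 1L) {
  patch <- crop_patch(patch)
  out <- lapply(ANGLES, function(a) {
    fg <- glcm_features(glcm(patch, a, distance))
    fr <- glrlm_features(glrlm(patch, a))
    stats::setNames(c(fg, fr),
                    c(paste0("glcm_", names(fg), "_", a),
                      paste0("glrlm_", names(fr), "_", a)))
  })
  unlist(out)
}

# restrict the levels matrix to the mask bounding box; pairs and runs are
# unaffected because out-of-mask pixels only ever break, never join
crop_patch <- function(patch) {
  nz <- which(patch$levels > 0L, arr.ind = TRUE)
  rr <- range(nz[, 1L]); cc <- range(nz[, 2L])
  if (rr[1L] == 1L && cc[1L] == 1L &&
      rr[2L] == nrow(patch$levels) && cc[2L] == ncol(patch$levels)) {
    return(patch)
  }
  patch$levels <- patch$levels[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE]
  patch
}
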