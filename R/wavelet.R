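#' Coiflet filter coefficients
#'
#' Orthonormal decomposition filters (low- and high-pass) for the supported
#' coiflet wavelets. Coefficients are the standard published values,
#' orthonormal to machine precision.
#'
#' @param name `"coif1"` (6 taps, default) or `"coif2"` (12 taps).
#' @return List with `lo`, `hi` (numeric filter taps) and `length`.
#' @export
wavelet_filters <- function(name = "coif1") {
  lo <- switch(name,
    coif1 = c(-0.015655728135791993, -0.07273261951252645,
               0.3848648468648578,    0.8525720202116004,
               0.3378976624574818,   -0.07273261951252645),
    coif2 = c(-0.000720549445520347, -0.0018232088709110323,
               0.005611434819368834,  0.02368017194684777,
              -0.05943441864643109,  -0.07648859907828076,
               0.4170051844232391,    0.8127236354494135,
               0.3861100668227629,   -0.0673725547237256,
              -0.04146493678687178,   0.01638733646320364),
    stop("unsupported wavelet: ", name, " (use \"coif1\" or \"coif2\")"))
  L <- length(lo)
  # quadrature mirror: g[m] = (-1)^m h[L - 1 - m], m = 0..L-1
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)
  list(lo = lo, hi = hi, length = L)
}

# n x n orthogonal one-level analysis matrix for a periodized signal of even
# length n >= filter length: rows 1..n/2 are the low-pass filter circularly
# shifted by 2, rows n/2+1..n the high-pass.
dwt_matrix <- function(n, filt) {
  L <- filt$length
  k <- n %/% 2L
  W <- matrix(0, n, n)
  for (i in seq_len(k)) {
    cols <- ((2L * (i - 1L) + seq_len(L) - 1L) %% n) + 1L
    W[i, cols] <- W[i, cols] + filt$lo
    W[k + i, cols] <- W[k + i, cols] + filt$hi
  }
  W
}

# half-point symmetric extension by L-1 samples each side, then filter and
# keep every second sample; analysis only (no inverse is defined for this
# mode, see dwt2_subbands)
dwt_sym_1d <- function(X, filt) {
  # filters every column of X
  L <- filt$length
  n <- nrow(X)
  top <- X[rev(seq_len(L - 1L)), , drop = FALSE]
  bot <- X[rev(n - seq_len(L - 1L) + 1L), , drop = FALSE]
  Xe <- rbind(top, X, bot)
  k <- (n + L - 1L) %/% 2L
  lo <- matrix(0, k, ncol(X)); hi <- matrix(0, k, ncol(X))
  for (i in seq_len(k)) {
    rows <- 2L * i - 1L + seq_len(L) - 1L
    seg <- Xe[rows, , drop = FALSE]
    lo[i, ] <- filt$lo %*% seg
    hi[i, ] <- filt$hi %*% seg
  }
  list(lo = lo, hi = hi)
}

pad_even <- function(X) {
  if (nrow(X) %% 2L == 1L) X <- rbind(X, X[nrow(X), , drop = FALSE])
  if (ncol(X) %% 2L == 1L) X <- cbind(X, X[, ncol(X), drop = FALSE])
  X
}

#' One-level 2-D coiflet decomposition
#'
#' Separable discrete wavelet transform into four subbands. The first
#' subband letter is the filter applied along the row index (vertical
#' direction), the second along the column index: `LL` = low/low, `LH` =
#' low rows / high columns, `HL` = high rows / low columns, `HH` =
#' high/high.
#'
#' With the default `"periodic"` boundary the transform is orthogonal:
#' subband energies sum to the image energy and [idwt2()] reconstructs the
#' input to machine precision. Odd dimensions are first padded by
#' replicating the last row/column. The `"symmetric"` boundary uses
#' half-point symmetric extension; it is analysis-only and its subbands are
#' slightly larger than half size.
#'
#' @param image Numeric matrix, at least 8 x 8 and at least the filter
#'   length in each dimension.
#' @param wavelet `"coif1"` or `"coif2"`.
#' @param boundary `"periodic"` (default) or `"symmetric"`.
#' @return Object of class `subband_set`: list with `LL`, `LH`, `HL`, `HH`
#'   matrices, `wavelet_name`, `boundary_mode`, and `orig_dim`.
#' @export
dwt2_subbands <- function(image, wavelet = "coif1", boundary = "periodic") {
  stopifnot(is.matrix(image))
  filt <- wavelet_filters(wavelet)
  if (min(dim(image)) < max(8L, filt$length)) {
    stop("image is ", nrow(image), "x", ncol(image),
         "; minimum size for ", wavelet, " is ",
         max(8L, filt$length), " in each dimension")
  }
  orig_dim <- dim(image)
  boundary <- match.arg(boundary, c("periodic", "symmetric"))
  if (boundary == "periodic") {
    X <- pad_even(image)
    Wr <- dwt_matrix(nrow(X), filt)
    Wc <- dwt_matrix(ncol(X), filt)
    C <- Wr %*% X %*% t(Wc)
    hr <- nrow(X) %/% 2L; hc <- ncol(X) %/% 2L
    LL <- C[seq_len(hr), seq_len(hc), drop = FALSE]
    LH <- C[seq_len(hr), hc + seq_len(hc), drop = FALSE]
    HL <- C[hr + seq_len(hr), seq_len(hc), drop = FALSE]
    HH <- C[hr + seq_len(hr), hc + seq_len(hc), drop = FALSE]
  } else {
    rowpass <- dwt_sym_1d(image, filt)           # filter along row index
    lo_c <- dwt_sym_1d(t(rowpass$lo), filt)      # then along column index
    hi_c <- dwt_sym_1d(t(rowpass$hi), filt)
    LL <- t(lo_c$lo); LH <- t(lo_c$hi)
    HL <- t(hi_c$lo); HH <- t(hi_c$hi)
  }
  structure(list(LL = LL, LH = LH, HL = HL, HH = HH,
                 wavelet_name = wavelet, boundary_mode = boundary,
                 orig_dim = orig_dim),
            class = "subband_set")
}

#' Inverse one-level 2-D wavelet transform
#'
#' Reconstructs the image from a periodized `subband_set`; exact to machine
#' precision because the periodized transform is orthogonal.
#'
#' @param sb A `subband_set` with `boundary_mode = "periodic"`.
#' @return Numeric matrix with the original image dimensions.
#' @export
idwt2 <- function(sb) {
  stopifnot(inherits(sb, "subband_set"))
  if (sb$boundary_mode != "periodic") {
    stop("reconstruction is only defined for the periodic boundary mode")
  }
  filt <- wavelet_filters(sb$wavelet_name)
  C <- rbind(cbind(sb$LL, sb$LH), cbind(sb$HL, sb$HH))
  Wr <- dwt_matrix(nrow(C), filt)
  Wc <- dwt_matrix(ncol(C), filt)
  X <- t(Wr) %*% C %*% Wc
  X[seq_len(sb$orig_dim[1L]), seq_len(sb$orig_dim[2L]), drop = FALSE]
}

#' Downsample an ROI mask to the subband grid
#'
#' A coarse pixel is in-mask iff any of its 2 x 2 parents is in-mask
#' (max-pooling); odd input dimensions are padded with out-of-mask pixels.
#'
#' @param mask Logical matrix, at least 2 x 2.
#' @return Logical matrix of dimension `ceiling(dim(mask) / 2)`.
#' @export
downsample_mask <- function(mask) {
  stopifnot(is.matrix(mask), min(dim(mask)) >= 2L)
  if (nrow(mask) %% 2L == 1L) mask <- rbind(mask, FALSE)
  if (ncol(mask) %% 2L == 1L) mask <- cbind(mask, FALSE)
  nr <- nrow(mask) %/% 2L; nc <- ncol(mask) %/% 2L
  odd_r <- 2L * seq_len(nr) - 1L; odd_c <- 2L * seq_len(nc) - 1L
  coarse <- mask[odd_r, odd_c, drop = FALSE] |
    mask[odd_r + 1L, odd_c, drop = FALSE] |
    mask[odd_r, odd_c + 1L, drop = FALSE] |
    mask[odd_r + 1L, odd_c + 1L, drop = FALSE]
  if (!any(coarse)) stop("downsampled mask is empty")
  coarse
}

#' Wavelet-domain feature block
#'
#' Decomposes the image into four coiflet subbands, maps the ROI onto the
#' subband grid, and recomputes the 14 first-order and 132 texture features
#' on each subband: 4 x 146 = 584 features, prefixed `LL_`, `LH_`, `HL_`,
#' `HH_`. First-order features use the raw in-mask coefficients (with
#' entropy/uniformity over an Ng-bin histogram); texture features use the
#' coefficients re-quantized to Ng equal-width levels over the in-mask
#' coefficient range, which accommodates their signed values.
#'
#' @param image Numeric matrix (8-bit image).
#' @param mask Logical ROI mask of the same shape.
#' @param Ng Gray levels for quantization (default 64).
#' @param wavelet,boundary Passed to [dwt2_subbands()].
#' @param distance GLCM offset.
#' @return Named numeric vector of length 584.
#' @export
wavelet_block <- function(image, mask, Ng = 64L, wavelet = "coif1",
                          boundary = "periodic", distance = 1L) {
  stopifnot(identical(dim(image), dim(mask)))
  sb <- dwt2_subbands(image, wavelet, boundary)
  cm <- downsample_mask(mask)
  bands <- c("LL", "LH", "HL", "HH")
  bdim <- dim(sb$LL)
  if (any(dim(cm) > bdim)) stop("coarse mask larger than subband grid")
  if (any(dim(cm) < bdim)) {
    # symmetric-mode subbands exceed half size; center the coarse mask
    full <- matrix(FALSE, bdim[1L], bdim[2L])
    r0 <- (bdim[1L] - nrow(cm)) %/% 2L
    c0 <- (bdim[2L] - ncol(cm)) %/% 2L
    full[r0 + seq_len(nrow(cm)), c0 + seq_len(ncol(cm))] <- cm
    cm <- full
  }
  if (sum(cm) < 4L) {
    stop("coarse ROI has ", sum(cm), " pixels; too small for texture matrices")
  }
  out <- lapply(bands, function(b) {
    S <- sb[[b]]
    fo <- first_order_features(S[cm], histogram_levels = Ng)
    qp <- quantize(S, cm, Ng)
    tex <- texture_block(qp, distance)
    stats::setNames(c(fo, tex),
                    paste0(b, "_", c(paste0("firstorder_", names(fo)),
                                     names(tex))))
  })
  unlist(out)
}
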