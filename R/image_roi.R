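#' Read a grayscale lesion image
#'
#' Reads an 8-bit PNG or TIFF image and returns an integer intensity matrix
#' in `[0, 255]`. RGB images are converted to luminance (0.299 R + 0.587 G +
#' 0.114 B); an alpha channel, if present, is ignored.
#'
#' @param path Path to a PNG or TIFF file.
#' @return Integer matrix (rows = image rows, top row first) with values in
#'   `[0, 255]`.
#' @export
load_image <- function(path) {
  arr <- read_image_array(path)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    arr <- if (nc >= 3L) {
      0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr[, , 1L]
    }
  }
  img <- round(arr * 255)
  storage.mode(img) <- "integer"
  if (any(img < 0L | img > 255L)) {
    stop("image intensities outside [0, 255] after decoding: ", path)
  }
  img
}

read_image_array <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to read TIFF files: ", path)
    }
    arr <- tryCatch(tiff::readTIFF(path), error = function(e) {
      stop("failed to decode TIFF file ", path, ": ", conditionMessage(e))
    })
  } else {
    arr <- tryCatch(png::readPNG(path), error = function(e) {
      stop("failed to decode PNG file ", path, ": ", conditionMessage(e))
    })
  }
  arr
}

#' Read a binary ROI mask
#'
#' Any strictly positive pixel is in-ROI. The mask must be non-empty.
#'
#' @param path Path to a PNG/TIFF mask file.
#' @return Logical matrix.
#' @export
load_mask <- function(path) {
  arr <- read_image_array(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  m <- arr > 0
  if (!any(m)) stop("ROI mask is empty: ", path)
  m
}

#' Write an 8-bit grayscale PNG
#'
#' @param img Numeric or integer matrix with values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  stopifnot(is.matrix(img))
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

#' Convert an ROI polygon to a binary mask
#'
#' Vertices are (row, col) pairs in pixel coordinates; the polygon is filled
#' by the even-odd rule with pixel centers as test points.
#'
#' @param vertices Two-column numeric matrix of (row, col) vertices.
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return Logical mask matrix.
#' @export
polygon_to_mask <- function(vertices, dim) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2L, nrow(vertices) >= 3L)
  nr <- dim[1L]; nc <- dim[2L]
  vr <- vertices[, 1L]; vcol <- vertices[, 2L]
  nv <- length(vr)
  jj <- c(nv, seq_len(nv - 1L))
  mask <- matrix(FALSE, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # even-odd rule: count edge crossings of a horizontal ray per pixel center
  cross <- matrix(0L, nr, nc)
  for (k in seq_len(nv)) {
    r1 <- vr[k]; c1 <- vcol[k]; r2 <- vr[jj[k]]; c2 <- vcol[jj[k]]
    if (r1 == r2) next
    hits <- ((r1 > rows) != (r2 > rows)) &
      (cols < (c2 - c1) * (rows - r1) / (r2 - r1) + c1)
    cross <- cross + hits
  }
  mask[cross %% 2L == 1L] <- TRUE
  mask
}

#' Quantize in-ROI intensities to Ng gray levels
#'
#' Equal-width bins spanning the in-mask intensity range:
#' `level = 1 + floor((x - min) / w)` with `w = (max - min) / Ng`, capped at
#' `Ng`. A constant ROI maps to level 1. Pixels outside the mask carry the
#' sentinel value 0.
#'
#' @param image Numeric matrix (8-bit image or real-valued wavelet
#'   coefficients).
#' @param mask Logical matrix of the same shape.
#' @param Ng Number of gray levels (>= 2).
#' @return Object of class `quantized_patch`: list with `levels` (integer
#'   matrix, 0 outside the mask), `Ng`, and `bin_edges` (length `Ng + 1`).
#' @export
quantize <- function(image, mask, Ng = 64L) {
  stopifnot(is.matrix(image), is.matrix(mask))
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask dimensions differ: ",
         paste(dim(image), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"))
  }
  if (!any(mask)) stop("cannot quantize an empty ROI mask")
  Ng <- as.integer(Ng)
  if (is.na(Ng) || Ng < 2L) stop("Ng must be an integer >= 2")
  x <- image[mask]
  lo <- min(x); hi <- max(x)
  levels <- matrix(0L, nrow(image), ncol(image))
  if (hi == lo) {
    levels[mask] <- 1L
    edges <- seq(lo, lo + 1, length.out = Ng + 1L)
  } else {
    w <- (hi - lo) / Ng
    lv <- 1L + as.integer(floor((x - lo) / w))
    lv[lv > Ng] <- Ng
    levels[mask] <- lv
    edges <- seq(lo, hi, length.out = Ng + 1L)
  }
  structure(list(levels = levels, Ng = Ng, bin_edges = edges),
            class = "quantized_patch")
}
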