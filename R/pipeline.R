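#' Feature extraction configuration
#'
#' @param Ng Number of gray levels for quantization (default 64).
#' @param wavelet Coiflet name, `"coif1"` or `"coif2"`.
#' @param boundary Wavelet boundary mode, `"periodic"` or `"symmetric"`.
#' @param distance GLCM pixel offset (default 1).
#' @return List of class `extraction_config`.
#' @export
extraction_config <- function(Ng = 64L, wavelet = "coif1",
                              boundary = "periodic", distance = 1L) {
  Ng <- as.integer(Ng)
  stopifnot(Ng >= 2L, distance >= 1L)
  wavelet_filters(wavelet)  # validates name
  boundary <- match.arg(boundary, c("periodic", "symmetric"))
  structure(list(Ng = Ng, wavelet = wavelet, boundary = boundary,
                 distance = as.integer(distance)),
            class = "extraction_config")
}

#' Extract the full 730-feature radiomics vector for one lesion
#'
#' Concatenates, in fixed order: 14 first-order features of the raw in-ROI
#' intensities (`orig_firstorder_*`), 132 texture features of the quantized
#' ROI (`orig_glcm_*` / `orig_glrlm_*`, 33 per direction), and 584 wavelet
#' subband features (`LL_* , LH_*, HL_*, HH_*`). Identical inputs and
#' configuration give a bit-identical vector.
#'
#' @param image Integer/numeric matrix with values in `[0, 255]`.
#' @param mask Logical ROI mask, same shape, at least 16 in-ROI pixels.
#' @param config An [extraction_config()].
#' @return Named numeric vector of length 730, free of NaN/Inf.
#' @export
extract_all <- function(image, mask, config = extraction_config()) {
  stopifnot(inherits(config, "extraction_config"),
            is.matrix(image), is.matrix(mask))
  if (!identical(dim(image), dim(mask))) stop("image/mask shape mismatch")
  if (min(dim(image)) < 8L) stop("image must be at least 8x8")
  if (sum(mask) < 16L) {
    stop("ROI has ", sum(mask), " pixels; at least 16 are required")
  }
  fo <- first_order_features(image[mask], histogram_levels = config$Ng)
  qp <- quantize(image, mask, config$Ng)
  tex <- texture_block(qp, config$distance)
  wav <- wavelet_block(image, mask, Ng = config$Ng,
                       wavelet = config$wavelet,
                       boundary = config$boundary,
                       distance = config$distance)
  v <- c(stats::setNames(fo, paste0("orig_firstorder_", names(fo))),
         stats::setNames(tex, paste0("orig_", names(tex))),
         wav)
  if (length(v) != 730L) {
    stop("internal error: feature vector has length ", length(v))
  }
  bad <- !is.finite(v)
  if (any(bad)) {
    stop("non-finite features: ", paste(names(v)[bad], collapse = ", "))
  }
  v
}

#' Feature dictionary
#'
#' One row per feature of the 730-dimensional signature: canonical name,
#' subband (`orig`, `LL`, `LH`, `HL`, `HH`), family (`firstorder`, `glcm`,
#' `glrlm`) and direction in degrees (`NA` for first-order features).
#'
#' @return Data frame with columns `name`, `subband`, `family`, `angle`.
#' @export
feature_dictionary <- function() {
  nm <- feature_names_730()
  parts <- strsplit(nm, "_")
  subband <- vapply(parts, `[[`, "", 1L)
  family <- vapply(parts, `[[`, "", 2L)
  angle <- rep(NA_integer_, length(nm))
  tex <- family %in% c("glcm", "glrlm")
  angle[tex] <- as.integer(vapply(parts[tex], function(p) p[[length(p)]], ""))
  data.frame(name = nm, subband = subband, family = family, angle = angle,
             stringsAsFactors = FALSE)
}

feature_names_730 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      img <- matrix(rep(seq_len(16L) * 15L, 16L), 16L, 16L)
      msk <- matrix(TRUE, 16L, 16L)
      cache <<- names(extract_all(img, msk))
    }
    cache
  }
})

#' Batch feature extraction for a cohort
#'
#' Extracts the 730-feature vector for every lesion of a cohort table,
#' reading the images and masks from disk. Failures are collected in an
#' error manifest (attribute `"errors"` of the result, and listed in the
#' error message unless `skip_errors = TRUE`), never silently dropped.
#'
#' @param cohort Data frame with columns `lesion_id`, `class`, `machine`,
#'   `birads`, `image_path`, `mask_path` (as written by [generate_cohort()]).
#' @param config An [extraction_config()].
#' @param out_csv Optional path; features written as CSV with values fixed
#'   to 10 significant digits for reproducible diffs.
#' @param skip_errors If `FALSE` (default) any failed lesion aborts the run.
#' @return Data frame: `lesion_id`, `class`, `machine`, `birads`, then the
#'   730 feature columns; attribute `"errors"` holds the failure manifest.
#' @export
extract_cohort <- function(cohort, config = extraction_config(),
                           out_csv = NULL, skip_errors = FALSE) {
  need <- c("lesion_id", "image_path", "mask_path")
  if (!all(need %in% names(cohort))) {
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(cohort)
  feats <- vector("list", n)
  errors <- data.frame(lesion_id = character(0), error = character(0),
                       stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    res <- tryCatch({
      img <- load_image(cohort$image_path[k])
      msk <- load_mask(cohort$mask_path[k])
      extract_all(img, msk, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors, data.frame(
        lesion_id = as.character(cohort$lesion_id[k]),
        error = conditionMessage(res), stringsAsFactors = FALSE))
    } else {
      feats[[k]] <- res
    }
  }
  if (nrow(errors) > 0L && !skip_errors) {
    stop("feature extraction failed for ", nrow(errors), " lesion(s): ",
         paste(errors$lesion_id, collapse = ", "))
  }
  ok <- !vapply(feats, is.null, logical(1))
  fm <- do.call(rbind, feats[ok])
  meta_cols <- intersect(c("lesion_id", "class", "machine", "birads",
                           "size_mm", "age"), names(cohort))
  out <- cbind(cohort[ok, meta_cols, drop = FALSE],
               as.data.frame(fm, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  if (!is.null(out_csv)) {
    ser <- out
    num <- vapply(ser, is.numeric, logical(1)) &
      names(ser) %in% colnames(fm)
    ser[num] <- lapply(ser[num], signif, digits = 10L)
    write.csv(ser, out_csv, row.names = FALSE)
  }
  out
}

feature_matrix <- function(feature_table) {
  fn <- feature_names_730()
  miss <- setdiff(fn, names(feature_table))
  if (length(miss)) {
    stop("feature table is missing ", length(miss), " feature columns")
  }
  as.matrix(feature_table[, fn])
}
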