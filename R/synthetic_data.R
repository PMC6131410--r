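#' @name synthetic-data
#' @title Synthetic ultrasound lesion simulator
#'
#' @description
#' Ultrasound B-mode texture is dominated by speckle: the envelope of many
#' unresolved sub-wavelength scatterers, with Rayleigh-distributed
#' amplitudes and a spatial correlation set by the system's resolution
#' cell. The simulator reproduces exactly that structure — the modulus of
#' a complex Gaussian field low-pass filtered with an isotropic Gaussian
#' kernel — modulated by a piecewise mean field (darker, hypoechoic
#' lesion inside an elliptical ROI; brighter background outside), with an
#' optional smooth intra-lesion heterogeneity field, and a per-machine
#' brightness/contrast/gamma transform. All randomness is a pure function
#' of the supplied seeds.
NULL

#' Lesion simulation parameters
#'
#' @param class_label `"fibroadenoma"` or `"tnbc"`.
#' @param correlation_length_px Speckle smoothing kernel width (Gaussian
#'   sigma, pixels, >= 0.5). Shorter lengths give finer speckle.
#' @param heterogeneity_amp Amplitude (intensity units) of the smooth
#'   intra-lesion mean-field variation; 0 for a homogeneous lesion.
#' @param ellipse_axes_px Full axis lengths (row axis, col axis) of the
#'   lesion ellipse, pixels.
#' @param boundary_irregularity Amplitude of the radial Fourier
#'   perturbation of the lesion boundary; 0 gives an exact ellipse.
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical output.
#' @return List of class `lesion_params`.
#' @export
lesion_params <- function(class_label = c("fibroadenoma", "tnbc"),
                          correlation_length_px = 2.5,
                          heterogeneity_amp = 0,
                          ellipse_axes_px = c(36, 44),
                          boundary_irregularity = 0.05,
                          seed = 1L) {
  class_label <- match.arg(class_label)
  stopifnot(correlation_length_px >= 0.5, heterogeneity_amp >= 0,
            length(ellipse_axes_px) == 2L, all(ellipse_axes_px > 0),
            boundary_irregularity >= 0)
  structure(list(class_label = class_label,
                 correlation_length_px = correlation_length_px,
                 heterogeneity_amp = heterogeneity_amp,
                 ellipse_axes_px = as.numeric(ellipse_axes_px),
                 boundary_irregularity = boundary_irregularity,
                 seed = as.integer(seed)),
            class = "lesion_params")
}

#' Machine intensity transform
#'
#' Emulates platform differences in brightness, contrast and display gamma:
#' the stored image is `clip(gain * 255 * (I/255)^gamma + offset, 0, 255)`
#' (gamma, then gain, then offset, then clipping).
#'
#' @param machine_id Machine label.
#' @param gain Multiplicative contrast factor (> 0).
#' @param offset Additive brightness shift.
#' @param gamma Display gamma (> 0).
#' @return List of class `machine_effect`.
#' @export
machine_effect <- function(machine_id = "iU22", gain = 1, offset = 0,
                           gamma = 1) {
  stopifnot(gain > 0, gamma > 0, is.finite(offset))
  structure(list(machine_id = machine_id, gain = gain, offset = offset,
                 gamma = gamma),
            class = "machine_effect")
}

#' Default machine effects for the three simulated platforms
#'
#' Mild, machine-specific brightness/contrast/gamma differences; the
#' identity transform for the reference machine.
#'
#' @return Named list of [machine_effect()] objects.
#' @export
default_machine_effects <- function() {
  list(iU22 = machine_effect("iU22", gain = 1, offset = 0, gamma = 1),
       LOGIQE9 = machine_effect("LOGIQE9", gain = 1.12, offset = 6,
                                gamma = 0.95),
       HDI5000 = machine_effect("HDI5000", gain = 0.9, offset = -5,
                                gamma = 1.06))
}

#' Class-conditional lesion parameter priors
#'
#' The benign-like class draws long-correlation, homogeneous speckle; the
#' malignant-like class draws finer speckle with a nonzero intra-lesion
#' heterogeneity field, giving the texture features a real second-order
#' signal to find. `effect_size = 0` removes every between-class
#' difference (null condition); `effect_size = 1` is the default
#' separable condition.
#'
#' @param effect_size Multiplier in `[0, 1]` interpolating between the null
#'   and the fully separable condition.
#' @return Named list (per class) of sampling ranges.
#' @export
default_lesion_priors <- function(effect_size = 1) {
  stopifnot(effect_size >= 0, effect_size <= 1)
  base_corr <- c(2.2, 3.0)
  tnbc_corr <- base_corr + effect_size * (c(1.5, 2.4) - base_corr)
  list(
    fibroadenoma = list(correlation_length_range = base_corr,
                        heterogeneity_amp_range = c(0, 0),
                        boundary_irregularity = 0.05),
    tnbc = list(correlation_length_range = tnbc_corr,
                heterogeneity_amp_range = effect_size * c(8, 18),
                boundary_irregularity = 0.05)
  )
}

#' Default BI-RADS category distribution given pathology
#'
#' Conditional probabilities over categories 3, 4a, 4b, 4c, 5. The benign
#' class concentrates on 3/4a and the malignant class spreads toward 4b-5,
#' so the marginal mix resembles a biopsy-referred benign-dominant cohort
#' and the low-suspicion (3 + 4a) subgroup is enriched in hard cases.
#'
#' @return 2 x 5 matrix, rows `fibroadenoma`/`tnbc`, columns the categories.
#' @export
default_birads_table <- function() {
  m <- rbind(fibroadenoma = c(0.34, 0.56, 0.05, 0.03, 0.02),
             tnbc = c(0.05, 0.30, 0.20, 0.25, 0.20))
  colnames(m) <- c("3", "4a", "4b", "4c", "5")
  m
}

#' Cohort specification
#'
#' @param n_lesions Number of lesions (>= 2).
#' @param malignancy_rate Probability a lesion is malignant (default 0.206,
#'   the TNBC fraction of a 186/901 case mix).
#' @param machine_mix Named probability vector over machines; default
#'   `c(iU22 = 0.546, LOGIQE9 = 0.361, HDI5000 = 0.093)`.
#' @param birads_given_class Conditional BI-RADS table, rows
#'   `fibroadenoma`/`tnbc` (default [default_birads_table()]).
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_lesions, malignancy_rate = 0.206,
                        machine_mix = c(iU22 = 0.546, LOGIQE9 = 0.361,
                                        HDI5000 = 0.093),
                        birads_given_class = default_birads_table(),
                        seed = 1L) {
  n_lesions <- as.integer(n_lesions)
  if (is.na(n_lesions) || n_lesions < 2L) stop("n_lesions must be >= 2")
  if (malignancy_rate < 0 || malignancy_rate >= 1) {
    stop("malignancy_rate must be in [0, 1)")
  }
  if (abs(sum(machine_mix) - 1) > 1e-9) stop("machine_mix must sum to 1")
  if (is.null(names(machine_mix))) stop("machine_mix must be named")
  stopifnot(is.matrix(birads_given_class),
            all(rownames(birads_given_class) %in%
                  c("fibroadenoma", "tnbc")),
            all(abs(rowSums(birads_given_class) - 1) < 1e-9))
  structure(list(n_lesions = n_lesions, malignancy_rate = malignancy_rate,
                 machine_mix = machine_mix,
                 birads_given_class = birads_given_class,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# periodic Gaussian smoothing of a matrix via FFT
gauss_smooth_fft <- function(X, sigma) {
  nr <- nrow(X); nc <- ncol(X)
  dr <- pmin(0:(nr - 1L), nr - 0:(nr - 1L))
  dc <- pmin(0:(nc - 1L), nc - 0:(nc - 1L))
  K <- exp(-outer(dr^2, dc^2, `+`) / (2 * sigma^2))
  K <- K / sum(K)
  Re(fft(fft(X) * fft(K), inverse = TRUE)) / (nr * nc)
}

perturbed_ellipse_mask <- function(image_size, axes, irregularity,
                                   harmonics_coef = NULL) {
  nr <- image_size[1L]; nc <- image_size[2L]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  ar <- axes[1L] / 2; ac <- axes[2L] / 2
  if (cr - ar < 2 || cr + ar > nr - 1 || cc - ac < 2 || cc + ac > nc - 1) {
    stop("invalid geometry: ellipse with axes ", axes[1L], "x", axes[2L],
         " does not fit a ", nr, "x", nc, " image with a 2 px margin")
  }
  u <- (row(matrix(0, nr, nc)) - cr) / ar
  v <- (col(matrix(0, nr, nc)) - cc) / ac
  rho <- sqrt(u^2 + v^2)
  if (irregularity > 0 && !is.null(harmonics_coef)) {
    theta <- atan2(v, u)
    f <- matrix(1, nr, nc)
    K <- nrow(harmonics_coef)
    for (k in seq_len(K)) {
      kk <- k + 1L
      f <- f + irregularity * (harmonics_coef[k, 1L] * cos(kk * theta) +
                               harmonics_coef[k, 2L] * sin(kk * theta)) / k
    }
    f <- pmax(f, 0.3)
  } else {
    f <- 1
  }
  rho <= f
}

#' Generate one synthetic lesion image with its ROI mask
#'
#' See the package vignette for the image model. The mask depends only on
#' the geometry parameters and seed, never on the machine effect.
#'
#' @param params A [lesion_params()].
#' @param machine A [machine_effect()].
#' @param image_size `c(rows, cols)`, at least 32 x 32.
#' @param mean_background,mean_lesion Mean echo levels outside/inside the
#'   ROI before speckle modulation (defaults 110 and 70: hypoechoic lesion).
#' @return List with `image` (integer matrix in `[0, 255]`) and `mask`
#'   (logical matrix).
#' @export
generate_lesion <- function(params, machine = machine_effect(),
                            image_size = c(128L, 128L),
                            mean_background = 110, mean_lesion = 70) {
  stopifnot(inherits(params, "lesion_params"),
            inherits(machine, "machine_effect"))
  image_size <- as.integer(image_size)
  if (any(image_size < 32L)) stop("image_size must be at least 32x32")
  nr <- image_size[1L]; nc <- image_size[2L]
  with_seed(params$seed, {
    harm <- matrix(rnorm(8L), 4L, 2L)
    mask <- perturbed_ellipse_mask(image_size, params$ellipse_axes_px,
                                   params$boundary_irregularity, harm)
    # Rayleigh speckle: modulus of a low-pass-filtered complex Gaussian field
    re <- matrix(rnorm(nr * nc), nr, nc)
    im <- matrix(rnorm(nr * nc), nr, nc)
    sig <- params$correlation_length_px
    env <- sqrt(gauss_smooth_fft(re, sig)^2 + gauss_smooth_fft(im, sig)^2)
    env <- env / mean(env)
    # smooth intra-lesion heterogeneity field
    M <- matrix(mean_background, nr, nc)
    M[mask] <- mean_lesion
    if (params$heterogeneity_amp > 0) {
      H <- gauss_smooth_fft(matrix(rnorm(nr * nc), nr, nc),
                            mean(params$ellipse_axes_px) / 6)
      H <- H / sd(H)
      M[mask] <- M[mask] + params$heterogeneity_amp * H[mask]
    }
    I0 <- pmax(M, 5) * env
    img <- machine$gain * 255 * (pmin(pmax(I0, 0), 255) / 255)^machine$gamma +
      machine$offset
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    list(image = img, mask = mask)
  })
}

#' Generate a full synthetic cohort with images on disk
#'
#' Draws pathology labels, machines, BI-RADS categories, lesion geometry and
#' demographics from the cohort specification, simulates each lesion with
#' [generate_lesion()] and its assigned machine effect, and writes one
#' image + mask PNG pair per lesion.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @param priors Class-conditional priors, see [default_lesion_priors()].
#' @param machines Named list of [machine_effect()], covering every machine
#'   named in `spec$machine_mix`.
#' @param image_size Passed to [generate_lesion()].
#' @param write_images If `FALSE`, only the metadata table is drawn (same
#'   labels and demographics as with `TRUE`; the path columns are `NA`).
#' @return Data frame: `lesion_id`, `class`, `machine`, `birads`, `size_mm`,
#'   `age`, `image_path`, `mask_path`.
#' @export
generate_cohort <- function(spec, dir,
                            priors = default_lesion_priors(),
                            machines = default_machine_effects(),
                            image_size = c(128L, 128L),
                            write_images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  miss <- setdiff(names(spec$machine_mix), names(machines))
  if (length(miss)) stop("no machine_effect given for: ",
                         paste(miss, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- spec$n_lesions
  with_seed(spec$seed, {
    cls <- ifelse(rbinom(n, 1L, spec$malignancy_rate) == 1L,
                  "tnbc", "fibroadenoma")
    mach <- names(spec$machine_mix)[
      sample.int(length(spec$machine_mix), n, replace = TRUE,
                 prob = spec$machine_mix)]
    birads <- unname(vapply(cls, function(cl) {
      p <- spec$birads_given_class[cl, ]
      colnames(spec$birads_given_class)[
        sample.int(length(p), 1L, prob = p)]
    }, ""))
    axes <- cbind(runif(n, 20, 50), runif(n, 20, 50))
    age <- pmin(pmax(round(rnorm(n, 42, 12)), 13L), 90L)
    lesion_seeds <- sample.int(.Machine$integer.max - 1L, n)
    corr <- numeric(n); amp <- numeric(n); irr <- numeric(n)
    for (k in seq_len(n)) {
      pr <- priors[[cls[k]]]
      corr[k] <- runif(1L, pr$correlation_length_range[1L],
                       pr$correlation_length_range[2L])
      amp[k] <- runif(1L, pr$heterogeneity_amp_range[1L],
                      pr$heterogeneity_amp_range[2L])
      irr[k] <- pr$boundary_irregularity
    }
    size_mm <- round(rowMeans(axes) * 0.42, 1)  # ~0.42 mm per pixel
    id <- sprintf("lesion_%04d", seq_len(n))
    image_path <- file.path(dir, paste0(id, ".png"))
    mask_path <- file.path(dir, paste0(id, "_mask.png"))
    if (!write_images) {
      image_path <- rep(NA_character_, n)
      mask_path <- rep(NA_character_, n)
    }
    for (k in if (write_images) seq_len(n) else integer(0)) {
      lp <- lesion_params(cls[k], correlation_length_px = corr[k],
                          heterogeneity_amp = amp[k],
                          ellipse_axes_px = axes[k, ],
                          boundary_irregularity = irr[k],
                          seed = lesion_seeds[k])
      les <- generate_lesion(lp, machines[[mach[k]]], image_size)
      write_gray_png(les$image, image_path[k])
      write_gray_png(les$mask * 255L, mask_path[k])
    }
    data.frame(lesion_id = id, class = cls, machine = mach, birads = birads,
               size_mm = size_mm, age = age,
               image_path = image_path, mask_path = mask_path,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}
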