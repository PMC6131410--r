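# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately written as plain loops transcribing the defining
# formulas, sharing no code with the package internals.

oracle_offset <- function(angle) {
  switch(as.character(angle),
         "0" = c(0L, 1L), "45" = c(-1L, 1L),
         "90" = c(-1L, 0L), "135" = c(-1L, -1L))
}

# exhaustive enumeration of in-mask pixel pairs
oracle_glcm <- function(levels, angle, distance = 1L, Ng = max(levels)) {
  off <- oracle_offset(angle) * distance
  C <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(levels))) for (c in seq_len(ncol(levels))) {
    r2 <- r + off[1L]; c2 <- c + off[2L]
    if (r2 < 1 || r2 > nrow(levels) || c2 < 1 || c2 > ncol(levels)) next
    i <- levels[r, c]; j <- levels[r2, c2]
    if (i > 0 && j > 0) {
      C[i, j] <- C[i, j] + 1
      C[j, i] <- C[j, i] + 1
    }
  }
  C / sum(C)
}

# literal double-loop transcription of the 22 co-occurrence definitions
oracle_glcm_features <- function(P) {
  eps <- 1e-12
  Ng <- nrow(P)
  px <- numeric(Ng); py <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:Ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sigx <- 0; sigy <- 0
  for (i in 1:Ng) { sigx <- sigx + (i - mux)^2 * px[i]
                    sigy <- sigy + (i - muy)^2 * py[i] }
  sigx <- sqrt(sigx); sigy <- sqrt(sigy)
  pxmy <- numeric(Ng); pxpy <- numeric(2 * Ng)   # index k+1 / k
  for (i in 1:Ng) for (j in 1:Ng) {
    pxmy[abs(i - j) + 1] <- pxmy[abs(i - j) + 1] + P[i, j]
    pxpy[i + j] <- pxpy[i + j] + P[i, j]
  }
  f <- c(autocorrelation = 0, cluster_prominence = 0, cluster_shade = 0,
         cluster_tendency = 0, contrast = 0, correlation = 0,
         difference_entropy = 0, dissimilarity = 0, energy = 0,
         entropy = 0, homogeneity1 = 0, homogeneity2 = 0, imc1 = 0,
         imc2 = 0, idmn = 0, idn = 0, inverse_variance = 0,
         maximum_probability = 0, sum_average = 0, sum_entropy = 0,
         sum_variance = 0, variance = 0)
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]; d <- abs(i - j)
    f["autocorrelation"] <- f["autocorrelation"] + i * j * p
    f["cluster_prominence"] <- f["cluster_prominence"] +
      (i + j - mux - muy)^4 * p
    f["cluster_shade"] <- f["cluster_shade"] + (i + j - mux - muy)^3 * p
    f["cluster_tendency"] <- f["cluster_tendency"] +
      (i + j - mux - muy)^2 * p
    f["contrast"] <- f["contrast"] + d^2 * p
    f["dissimilarity"] <- f["dissimilarity"] + d * p
    f["energy"] <- f["energy"] + p^2
    f["entropy"] <- f["entropy"] - p * log2(p + 1e-12)
    f["homogeneity1"] <- f["homogeneity1"] + p / (1 + d)
    f["homogeneity2"] <- f["homogeneity2"] + p / (1 + d^2)
    f["idmn"] <- f["idmn"] + p / (1 + d^2 / Ng^2)
    f["idn"] <- f["idn"] + p / (1 + d / Ng)
    if (d > 0) f["inverse_variance"] <- f["inverse_variance"] + p / d^2
    f["variance"] <- f["variance"] + (i - mux)^2 * p
    HXY1 <- HXY1 - p * log2(px[i] * py[j] + eps)
    HXY2 <- HXY2 - px[i] * py[j] * log2(px[i] * py[j] + eps)
  }
  f["maximum_probability"] <- max(P)
  if (sigx > 0 && sigy > 0) {
    f["correlation"] <- (f[["autocorrelation"]] - mux * muy) / (sigx * sigy)
  }
  for (k in 0:(Ng - 1)) {
    f["difference_entropy"] <- f["difference_entropy"] -
      pxmy[k + 1] * log2(pxmy[k + 1] + eps)
  }
  for (k in 2:(2 * Ng)) {
    f["sum_average"] <- f["sum_average"] + k * pxpy[k]
    f["sum_entropy"] <- f["sum_entropy"] - pxpy[k] * log2(pxpy[k] + eps)
  }
  for (k in 2:(2 * Ng)) {
    f["sum_variance"] <- f["sum_variance"] +
      (k - f[["sum_average"]])^2 * pxpy[k]
  }
  HX <- -sum(px * log2(px + eps)); HY <- -sum(py * log2(py + eps))
  if (max(HX, HY) > 0) f["imc1"] <- (f[["entropy"]] - HXY1) / max(HX, HY)
  arg <- 1 - exp(-2 * (HXY2 - f[["entropy"]]))
  f["imc2"] <- if (arg > 0) sqrt(arg) else 0
  f
}

# explicit line walker with break conditions at mask boundary / image edge
oracle_glrlm <- function(levels, angle, Ng = max(levels)) {
  off <- oracle_offset(angle)
  nr <- nrow(levels); nc <- ncol(levels)
  inb <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  runs_v <- integer(0); runs_l <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- levels[r, c]
    if (v == 0) next
    pr <- r - off[1L]; pc <- c - off[2L]
    # start of a run: predecessor out of image, out of mask, or other level
    if (inb(pr, pc) && levels[pr, pc] == v) next
    len <- 1L
    nr2 <- r + off[1L]; nc2 <- c + off[2L]
    while (inb(nr2, nc2) && levels[nr2, nc2] == v) {
      len <- len + 1L
      nr2 <- nr2 + off[1L]; nc2 <- nc2 + off[2L]
    }
    runs_v <- c(runs_v, v); runs_l <- c(runs_l, len)
  }
  R <- matrix(0L, Ng, max(runs_l))
  for (k in seq_along(runs_v)) {
    R[runs_v[k], runs_l[k]] <- R[runs_v[k], runs_l[k]] + 1L
  }
  list(R = R, Nr = length(runs_v), Np = sum(levels > 0))
}

oracle_glrlm_features <- function(R, Nr, Np) {
  f <- c(sre = 0, lre = 0, gln = 0, rln = 0, run_percentage = Nr / Np,
         lglre = 0, hglre = 0, srlgle = 0, srhgle = 0, lrlgle = 0,
         lrhgle = 0)
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    r <- R[i, j]
    f["sre"] <- f["sre"] + r / j^2
    f["lre"] <- f["lre"] + r * j^2
    f["lglre"] <- f["lglre"] + r / i^2
    f["hglre"] <- f["hglre"] + r * i^2
    f["srlgle"] <- f["srlgle"] + r / (i^2 * j^2)
    f["srhgle"] <- f["srhgle"] + r * i^2 / j^2
    f["lrlgle"] <- f["lrlgle"] + r * j^2 / i^2
    f["lrhgle"] <- f["lrhgle"] + r * i^2 * j^2
  }
  for (i in seq_len(nrow(R))) f["gln"] <- f["gln"] + sum(R[i, ])^2
  for (j in seq_len(ncol(R))) f["rln"] <- f["rln"] + sum(R[, j])^2
  f[c("sre", "lre", "gln", "rln", "lglre", "hglre", "srlgle", "srhgle",
      "lrlgle", "lrhgle")] <-
    f[c("sre", "lre", "gln", "rln", "lglre", "hglre", "srlgle", "srhgle",
        "lrlgle", "lrhgle")] / Nr
  f
}

# circular filter + dyadic decimation, explicit loops
oracle_dwt1_cols <- function(X, filt) {
  n <- nrow(X); L <- length(filt)
  stopifnot(n %% 2 == 0)
  out <- matrix(0, n %/% 2, ncol(X))
  for (cc in seq_len(ncol(X))) {
    full <- numeric(n)
    for (t in seq_len(n)) {
      s <- 0
      for (m in seq_len(L)) {
        s <- s + filt[m] * X[((t - 1 + m - 1) %% n) + 1, cc]
      }
      full[t] <- s
    }
    out[, cc] <- full[seq(1, n, by = 2)]
  }
  out
}

oracle_dwt2 <- function(X, wavelet = "coif1") {
  filt <- usradiomics::wavelet_filters(wavelet)
  lo_r <- oracle_dwt1_cols(X, filt$lo)          # low-pass along rows
  hi_r <- oracle_dwt1_cols(X, filt$hi)
  list(LL = t(oracle_dwt1_cols(t(lo_r), filt$lo)),
       LH = t(oracle_dwt1_cols(t(lo_r), filt$hi)),
       HL = t(oracle_dwt1_cols(t(hi_r), filt$lo)),
       HH = t(oracle_dwt1_cols(t(hi_r), filt$hi)))
}

oracle_maxpool_mask <- function(mask) {
  if (nrow(mask) %% 2 == 1) mask <- rbind(mask, FALSE)
  if (ncol(mask) %% 2 == 1) mask <- cbind(mask, FALSE)
  out <- matrix(FALSE, nrow(mask) %/% 2, ncol(mask) %/% 2)
  for (r in seq_len(nrow(out))) for (c in seq_len(ncol(out))) {
    out[r, c] <- any(mask[(2 * r - 1):(2 * r), (2 * c - 1):(2 * c)])
  }
  out
}

# unpenalized logistic MLE by Newton-Raphson with step halving
oracle_logistic_mle <- function(X, y, tol = 1e-12, maxit = 100) {
  X1 <- cbind(1, X)
  beta <- numeric(ncol(X1))
  nll <- function(b) {
    eta <- drop(X1 %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- crossprod(X1, p - y)
    W <- p * (1 - p)
    H <- crossprod(X1 * W, X1)
    step <- solve(H, g)
    f0 <- nll(beta); s <- 1
    while (nll(beta - s * step) > f0 && s > 1e-8) s <- s / 2
    beta <- beta - s * drop(step)
    if (max(abs(s * step)) < tol) break
  }
  beta
}

# random quantized patch with an irregular mask, valid at all four angles
random_patch <- function(seed) {
  set.seed(seed)
  repeat {
    nr <- sample(8:16, 1); nc <- sample(8:16, 1)
    Ng <- sample(4:8, 1)
    img <- matrix(runif(nr * nc, 0, 255), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.75, nr, nc)
    if (sum(mask) < 16) next
    qp <- usradiomics::quantize(img, mask, Ng)
    ok <- TRUE
    for (a in c(0, 45, 90, 135)) {
      got <- tryCatch(usradiomics::glcm(qp, a), error = function(e) NULL)
      if (is.null(got)) { ok <- FALSE; break }
    }
    if (ok) return(qp)
  }
}

# small deterministic lesion for pipeline tests
demo_lesion <- function(seed = 5, class_label = "tnbc") {
  lp <- usradiomics::lesion_params(
    class_label,
    correlation_length_px = if (class_label == "tnbc") 1.2 else 2.6,
    heterogeneity_amp = if (class_label == "tnbc") 22 else 0,
    ellipse_axes_px = c(38, 46), boundary_irregularity = 0.05, seed = seed)
  usradiomics::generate_lesion(lp)
}
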