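quantized_from_levels <- function(levels, Ng = max(levels)) {
  # build a quantized_patch whose levels are exactly the given matrix
  img <- levels
  img[levels == 0L] <- 1L
  qp <- quantize(img, levels > 0L, Ng)
  stopifnot(identical(qp$levels, levels))
  qp
}

test_that("a constant 2x2 ROI concentrates all co-occurrence mass", {
  lev <- matrix(2L, 2L, 2L)
  qp <- quantize(matrix(128, 2L, 2L), matrix(TRUE, 2L, 2L), 4L)
  # constant ROI quantizes to level 1; use explicit levels for level 2
  qp$levels <- lev; qp$Ng <- 4L
  M <- glcm(qp, 0)
  expect_equal(M$P[2L, 2L], 1)
  expect_equal(sum(M$P), 1)
  f <- glcm_features(M)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["maximum_probability"]], 1)
})

test_that("the 1-row checkerboard gives the closed-form GLCM", {
  lev <- matrix(c(1L, 2L, 1L, 2L), 1L, 4L)
  qp <- structure(list(levels = lev, Ng = 2L, bin_edges = c(0, 0.5, 1)),
                  class = "quantized_patch")
  M <- glcm(qp, 0)
  expect_equal(M$P, matrix(c(0, 0.5, 0.5, 0), 2L, 2L))
  f <- glcm_features(M)
  expect_equal(f[["contrast"]], 1)
  expect_equal(f[["correlation"]], -1)
})

test_that("an identity-concentrated GLCM has zero contrast", {
  Ng <- 6L
  M <- structure(list(P = diag(Ng) / Ng, angle = 0L, distance = 1L,
                      n_pairs = Ng), class = "glc_matrix")
  f <- glcm_features(M)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["dissimilarity"]], 0)
  expect_equal(f[["maximum_probability"]], 1 / Ng)
})

test_that("GLCM matrices and features match exhaustive enumeration", {
  for (seed in 1:25) {
    qp <- random_patch(seed)
    for (a in c(0, 45, 90, 135)) {
      M <- glcm(qp, a)
      expect_equal(M$P, oracle_glcm(qp$levels, a, Ng = qp$Ng),
                   tolerance = 1e-12)
      expect_equal(glcm_features(M), oracle_glcm_features(M$P),
                   tolerance = 1e-12)
    }
  }
})

test_that("GLCM is symmetric and normalized for random patches", {
  for (seed in 26:35) {
    qp <- random_patch(seed)
    for (a in c(0, 45, 90, 135)) {
      M <- glcm(qp, a)
      expect_equal(sum(M$P), 1, tolerance = 1e-9)
      expect_equal(M$P, t(M$P))
      expect_equal(rowSums(M$P), colSums(M$P))
    }
  }
})

test_that("single-pixel ROIs cannot form pairs", {
  lev <- matrix(0L, 4L, 4L); lev[2L, 2L] <- 1L
  qp <- structure(list(levels = lev, Ng = 2L, bin_edges = c(0, 0.5, 1)),
                  class = "quantized_patch")
  expect_error(glcm(qp, 45), "45")
})

test_that("run matrices follow the run-length contract on simple rows", {
  # constant 1x4 row: one run of length 4
  lev <- matrix(3L, 1L, 4L)
  qp <- structure(list(levels = lev, Ng = 4L, bin_edges = 0:4),
                  class = "quantized_patch")
  R <- glrlm(qp, 0)
  expect_equal(R$Nr, 1L)
  expect_equal(R$R[3L, 4L], 1L)
  f <- glrlm_features(R)
  expect_equal(f[["sre"]], 1 / 16)
  expect_equal(f[["lre"]], 16)

  # strictly increasing row: four runs of length 1
  lev2 <- matrix(1:4, 1L, 4L)
  qp2 <- structure(list(levels = lev2, Ng = 4L, bin_edges = 0:4),
                   class = "quantized_patch")
  R2 <- glrlm(qp2, 0)
  expect_equal(R2$Nr, 4L)
  f2 <- glrlm_features(R2)
  expect_equal(f2[["sre"]], 1)
  expect_equal(f2[["lre"]], 1)
  expect_equal(f2[["run_percentage"]], 1)

  # constant 2x2 patch at 0 degrees: two horizontal runs of length 2
  lev3 <- matrix(1L, 2L, 2L)
  qp3 <- structure(list(levels = lev3, Ng = 2L, bin_edges = c(0, 0.5, 1)),
                   class = "quantized_patch")
  R3 <- glrlm(qp3, 0)
  expect_equal(R3$Nr, 2L)
  expect_equal(glrlm_features(R3)[["run_percentage"]], 0.5)
})

test_that("run matrices match the explicit line walker", {
  for (seed in 36:60) {
    qp <- random_patch(seed)
    for (a in c(0, 45, 90, 135)) {
      got <- glrlm(qp, a)
      want <- oracle_glrlm(qp$levels, a, Ng = qp$Ng)
      expect_identical(unname(got$R), unname(want$R))
      expect_identical(got$Nr, want$Nr)
      expect_identical(got$Np, want$Np)
      expect_equal(glrlm_features(got),
                   oracle_glrlm_features(want$R, want$Nr, want$Np),
                   tolerance = 1e-12)
    }
  }
})

test_that("runs conserve the in-mask pixel count in every direction", {
  for (seed in 61:70) {
    qp <- random_patch(seed)
    for (a in c(0, 45, 90, 135)) {
      R <- glrlm(qp, a)
      expect_equal(sum(sweep(R$R, 2L, seq_len(ncol(R$R)), `*`)), R$Np)
    }
  }
})

test_that("texture_block concatenates 132 features and respects rotation", {
  qp <- random_patch(71)
  tb <- texture_block(qp)
  expect_length(tb, 132L)
  expect_false(any(duplicated(names(tb))))
  expect_true(all(is.finite(tb)))
  # recomputation from independently built matrices
  for (a in c(0, 45, 90, 135)) {
    expect_equal(tb[paste0("glcm_", names(glcm_features(glcm(qp, a))),
                           "_", a)],
                 glcm_features(glcm(qp, a)), ignore_attr = TRUE)
  }

  # rotating the patch 90 degrees clockwise swaps 0<->90 and 45<->135
  rot <- function(m) t(m[nrow(m):1, , drop = FALSE])
  qr <- structure(list(levels = rot(qp$levels), Ng = qp$Ng,
                       bin_edges = qp$bin_edges),
                  class = "quantized_patch")
  tr <- texture_block(qr)
  swap <- c("0" = "90", "45" = "135", "90" = "0", "135" = "45")
  for (a in names(swap)) {
    orig <- tb[grepl(paste0("_", a, "$"), names(tb))]
    rotd <- tr[grepl(paste0("_", swap[[a]], "$"), names(tr))]
    expect_equal(unname(orig), unname(rotd), tolerance = 1e-12)
  }

  # a 4-fold symmetric patch has equal 0- and 90-degree GLCM blocks
  d2 <- outer(1:9, 1:9, function(i, j) (i - 5)^2 + (j - 5)^2)
  sym <- quantize(d2, d2 <= 16, 4L)
  fs <- texture_block(sym)
  expect_equal(unname(fs[grepl("glcm_.*_0$", names(fs))]),
               unname(fs[grepl("glcm_.*_90$", names(fs))]))
})
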