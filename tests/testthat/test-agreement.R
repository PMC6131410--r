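test_that("identical raters give ICC exactly 1", {
  x <- c(3.2, 5.1, 4.4, 7.8, 6.0, 2.9, 5.5)
  r <- icc_two_way_random(x, x)
  expect_equal(r$icc, 1)
  expect_true(all(r$ci <= 1))
})

test_that("ICC matches an independent ANOVA mean-squares computation", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(6:20, 1L)
    ratings <- matrix(rnorm(2 * n, 10, 3), n, 2L) +
      rnorm(n, 0, 2)  # subject effect
    got <- icc_two_way_random(ratings)
    # oracle: mean squares from stats::aov on the long layout
    long <- data.frame(y = as.vector(ratings),
                       subj = factor(rep(seq_len(n), 2L)),
                       rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1L]][
      , "Mean Sq"]
    msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
    want <- (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
    expect_equal(got$icc, want, tolerance = 1e-10)
    expect_equal(c(got$msr, got$msc, got$mse), c(msr, msc, mse),
                 tolerance = 1e-10)
    expect_lte(got$ci[1L], got$icc)
    expect_gte(got$ci[2L], got$icc)
  }
})

test_that("point estimate and CI agree with a frozen external reference", {
  # reference values computed with pingouin's ICC2 (absolute agreement,
  # single rater) on this fixed 10x2 rating matrix
  r1 <- c(10.1, 11.3, 9.8, 12.4, 10.9, 8.7, 11.8, 10.2, 9.5, 12.0)
  r2 <- c(10.4, 11.0, 10.1, 12.9, 10.5, 9.0, 11.4, 10.6, 9.2, 12.3)
  got <- icc_two_way_random(r1, r2)
  expect_equal(got$icc, 0.9569767004178119, tolerance = 1e-12)
  expect_equal(round(got$ci, 2), c(0.84, 0.99))
})

test_that("a constant inter-rater offset lowers absolute agreement", {
  set.seed(14)
  x <- rnorm(40, 20, 4)
  noisy <- x + rnorm(40, 0, 0.5)
  base <- icc_two_way_random(x, noisy)$icc
  shifted <- icc_two_way_random(x, noisy + 3)$icc
  expect_lt(shifted, base)
})

test_that("independent raters give ICC near zero", {
  set.seed(15)
  r <- icc_two_way_random(rnorm(500), rnorm(500))
  expect_lt(abs(r$icc), 0.1)
})

test_that("degenerate ratings are flagged", {
  expect_warning(r <- icc_two_way_random(rep(2, 8), rep(2, 8)),
                 "zero total variance")
  expect_equal(r$icc, 1)
  expect_error(icc_two_way_random(1:3, 1:3), "at least 5")
})

test_that("the agreement grid has the direction-by-subband shape", {
  set.seed(16)
  n <- 8L
  fn <- feature_names_730()
  A <- matrix(rnorm(n * 730), n, 730, dimnames = list(NULL, fn))
  f1 <- data.frame(lesion_id = paste0("L", 1:n), A, check.names = FALSE)
  f2 <- f1
  tab <- icc_summary_table(f1, f2)
  expect_equal(dim(tab), c(5L, 6L))
  expect_equal(tab$direction, c("0", "45", "90", "135", "firstorder"))
  expect_setequal(names(tab)[-1L], c("orig", "HH", "HL", "LH", "LL"))
  # identical raters: every cell is (1, 1)
  expect_true(all(tab[1:4, -1L] == "1.000, 1.000"))

  # perturbing exactly one 90-degree HH feature only drops that cell
  f3 <- f1
  f3[["HH_glcm_contrast_90"]] <- f3[["HH_glcm_contrast_90"]] + rnorm(n, 0, 5)
  tab2 <- icc_summary_table(f1, f3)
  changed <- tab2[1:4, -1L] != tab[1:4, -1L]
  expect_equal(sum(changed), 1L)
  expect_true(changed[3L, which(names(tab2)[-1L] == "HH")])

  # schema mismatch is reported
  expect_error(icc_summary_table(f1[, -5L], f2), "schema mismatch")
})

test_that("mask perturbation emulates a second reader plausibly", {
  les <- demo_lesion(seed = 17)
  m2 <- perturb_mask(les$mask, seed = 1L)
  expect_identical(m2, perturb_mask(les$mask, seed = 1L))
  expect_gte(sum(m2), 16L)
  jac <- sum(m2 & les$mask) / sum(m2 | les$mask)
  expect_gt(jac, 0.7)  # still essentially the same lesion
  expect_lt(jac, 1)
})
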