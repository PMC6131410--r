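# small synthetic design shared across the model tests
make_design <- function(n, p, k_true = 3L, beta = 1.2, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  eta <- X[, seq_len(k_true), drop = FALSE] %*% rep(beta, k_true)
  y <- rbinom(n, 1L, plogis(eta))
  list(X = X, y = y)
}

test_that("random splits are seeded, sized, and balanced in distribution", {
  d <- data.frame(class = rep(c("fibroadenoma", "tnbc"), c(80, 20)),
                  size_mm = rnorm(100, 15, 3), age = rnorm(100, 42, 10),
                  birads = sample(c("3", "4a", "4b"), 100, replace = TRUE))
  s1 <- split_train_validation(d, fraction = 0.5, seed = 4L)
  expect_equal(sum(s1$split == "train"), 50L)
  s2 <- split_train_validation(d, fraction = 0.5, seed = 4L)
  expect_identical(s1$split, s2$split)
  bal <- attr(s1, "balance")
  expect_setequal(bal$variable, c("size_mm", "age", "class", "birads"))
  expect_true(all(bal$p_value >= 0 & bal$p_value <= 1))
})

test_that("lambda at or above lambda_max yields the null model", {
  dd <- make_design(120, 15, seed = 2L)
  m <- fit_lasso_logistic(dd$X, dd$y, n_folds = 5L, seed = 1L)
  m0 <- fit_lasso_logistic(dd$X, dd$y, lambda_grid = m$lambda_max * c(2, 1),
                           n_folds = 5L, seed = 1L)
  expect_length(m0$selected_features, 0L)
  expect_equal(radiomics_score(m0, dd$X), rep(0, 120), ignore_attr = TRUE)
})

test_that("the unpenalized limit matches a Newton-Raphson oracle", {
  dd <- make_design(200, 5, seed = 3L)
  Xs <- scale(dd$X)
  want <- oracle_logistic_mle(Xs, dd$y)
  m <- fit_lasso_logistic(dd$X, dd$y, lambda_grid = 0, n_folds = 5L)
  got <- rep(0, 5); names(got) <- colnames(dd$X)
  got[m$selected_features] <- m$coefficients
  expect_lt(max(abs(got - want[-1L])), 1e-4)
  expect_lt(abs(m$intercept - want[1L]), 1e-4)
})

test_that("the coordinate-descent path agrees with glmnet", {
  skip_if_not_installed("glmnet")
  dd <- make_design(150, 12, seed = 4L)
  Xs <- scale(dd$X)
  lams <- c(0.1, 0.05, 0.01)
  m <- fit_lasso_logistic(dd$X, dd$y, lambda_grid = lams, n_folds = 5L)
  g <- glmnet::glmnet(Xs, dd$y, family = "binomial", alpha = 1,
                      lambda = lams, standardize = FALSE,
                      thresh = 1e-14)
  cf <- as.matrix(coef(g, s = m$lambda))
  got <- rep(0, 12); names(got) <- colnames(dd$X)
  got[m$selected_features] <- m$coefficients
  expect_lt(max(abs(got - cf[-1L, 1L])), 1e-4)
})

test_that("the number of selected features shrinks as lambda grows", {
  dd <- make_design(150, 20, seed = 5L)
  Xs <- scale(dd$X)
  lams <- lams0 <- exp(seq(log(0.3), log(0.003), length.out = 20))
  fitpath <- vapply(lams, function(l) {
    m <- fit_lasso_logistic(dd$X, dd$y, lambda_grid = l, n_folds = 5L)
    length(m$selected_features)
  }, numeric(1))
  expect_true(all(diff(fitpath) >= -1e-9))  # lambda decreasing -> growing
})

test_that("the radiomics score is the standardized linear combination", {
  m <- structure(list(
    selected_features = c("a", "b"),
    coefficients = c(a = 2, b = -1),
    standardization = list(mean = c(a = 10, b = 0), sd = c(a = 2, b = 1)),
    feature_names = c("a", "b")), class = "radiomics_model")
  expect_equal(radiomics_score(m, c(a = 13, b = 0.5)), 2 * 1.5 - 0.5)
  # matrix input, and the oracle dot product
  set.seed(6)
  X <- cbind(a = rnorm(20, 10, 2), b = rnorm(20))
  want <- 2 * (X[, "a"] - 10) / 2 - 1 * (X[, "b"] - 0) / 1
  expect_equal(radiomics_score(m, X), want, ignore_attr = TRUE)
  expect_error(radiomics_score(m, c(a = 1)), "missing selected feature")
})

test_that("the published conversion equation reproduces its worked examples", {
  cal <- score_calibration()
  expect_equal(cal$intercept, 0.6985)
  expect_equal(cal$slope, 1.6381)
  expect_equal(round(score_to_probability(cal, -3.83), 1), 0.4)
  expect_equal(round(score_to_probability(cal, 3.01), 1), 99.6)
  expect_equal(round(score_to_probability(cal, -2.19)), 5)
  expect_equal(round(score_to_probability(cal, 0.22)), 74)
  # strictly increasing, saturating, numerically stable
  s <- seq(-430, 430, length.out = 2001)
  p <- score_to_probability(cal, s)
  expect_true(all(diff(p) >= 0))
  expect_equal(p[1L], 0)
  expect_equal(p[length(p)], 100)
})

test_that("calibration refits recover their generating constants", {
  set.seed(9)
  s <- rnorm(20000, 0, 1.5)
  y <- rbinom(length(s), 1L, plogis(0.6985 + 1.6381 * s))
  cal <- calibrate_score(s, y)
  expect_lt(abs(cal$intercept - 0.6985) / 0.6985, 0.10)
  expect_lt(abs(cal$slope - 1.6381) / 1.6381, 0.10)
  # labels independent of the score: slope near zero
  y0 <- rbinom(length(s), 1L, 0.3)
  cal0 <- calibrate_score(s, y0)
  expect_lt(abs(cal0$slope), 0.1)
  # complete separation is capped with a warning
  expect_warning(calibrate_score(c(-2, -1, 1, 2), c(0, 0, 1, 1)), "separation")
})

test_that("AUC handles separation, ties, and matches pROC/DeLong", {
  expect_equal(auc_with_ci(c(1, 2, 3, 11, 12, 13),
                           c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(auc_with_ci(rep(1, 40), rep(c(0, 1), 20))$auc, 0.5)
  expect_error(auc_with_ci(1:5, rep(1, 5)), "both classes")

  skip_if_not_installed("pROC")
  set.seed(10)
  y <- rbinom(300, 1L, 0.3)
  s <- rnorm(300) + y
  got <- auc_with_ci(s, y)
  ref <- pROC::ci.auc(pROC::roc(y, s, quiet = TRUE), method = "delong")
  expect_equal(got$auc, as.numeric(ref[2L]), tolerance = 1e-10)
  expect_equal(got$ci, as.numeric(ref[c(1L, 3L)]), tolerance = 1e-6)
})

test_that("group comparisons give their null-case closed forms", {
  # Mann-Whitney at the exact null center (normal approximation): p = 1
  x <- c(1, 4, 5, 8); y <- c(2, 3, 6, 7)
  r <- compare_groups(c(x, y), rep(c("a", "b"), each = 4), "mann_whitney")
  expect_equal(r$p_value, 1)
  # chi-square with identical row distributions: statistic 0, p = 1
  v <- rep(c("u", "v"), each = 10)
  g <- rep(c("g1", "g2"), 10)
  r2 <- compare_groups(v, g, "chi_square")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  # pooled-variance Student t equals the textbook statistic
  a <- c(5.1, 4.9, 5.6, 4.7); b <- c(6.0, 6.3, 5.8, 6.1)
  r3 <- compare_groups(c(a, b), rep(c("a", "b"), each = 4), "student_t")
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  want <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(r3$statistic, want)
  expect_error(compare_groups(1:4, rep("a", 4), "kruskal_wallis"),
               "two groups")
})
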