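#' Split a cohort into training and validation sets
#'
#' Simple seeded random sampling (not stratified), with a balance report
#' comparing the two sets: Student's t test for `size_mm` and `age`,
#' chi-square for `class` and `birads`.
#'
#' @param table Cohort or feature table with a `class` column.
#' @param fraction Fraction assigned to the training set.
#' @param seed Integer seed.
#' @return `table` with an added `split` column (`"train"`/`"validation"`);
#'   attribute `"balance"` holds the report data frame.
#' @export
split_train_validation <- function(table, fraction = 0.5, seed = 1L) {
  stopifnot(is.data.frame(table), "class" %in% names(table),
            fraction > 0, fraction < 1)
  n <- nrow(table)
  if (n < 20L) stop("need at least 20 lesions to split")
  if (length(unique(table$class)) < 2L) {
    stop("both classes must be present before splitting")
  }
  idx <- with_seed(seed, sample.int(n, floor(n * fraction)))
  split <- rep("validation", n)
  split[idx] <- "train"
  for (s in c("train", "validation")) {
    if (length(unique(table$class[split == s])) < 2L) {
      stop("the ", s, " set contains a single class; ",
           "consider a stratified split or another seed")
    }
  }
  table$split <- split
  bal <- list()
  for (v in intersect(c("size_mm", "age"), names(table))) {
    r <- compare_groups(table[[v]], split, "student_t")
    bal[[v]] <- data.frame(variable = v, test = "student_t",
                           statistic = r$statistic, p_value = r$p_value)
  }
  for (v in intersect(c("class", "birads"), names(table))) {
    r <- compare_groups(table[[v]], split, "chi_square")
    bal[[v]] <- data.frame(variable = v, test = "chi_square",
                           statistic = r$statistic, p_value = r$p_value)
  }
  attr(table, "balance") <- do.call(rbind, c(bal, make.row.names = FALSE))
  table
}

lambda_grid_default <- function(lambda_max, nlambda = 100L,
                                min_ratio = 1e-3) {
  exp(seq(log(lambda_max), log(lambda_max * min_ratio),
          length.out = nlambda))
}

stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Fit a LASSO-penalized logistic model with AUC-maximizing lambda
#'
#' Features are z-scored internally (training statistics only; inside each
#' cross-validation fold the fold-training statistics are used, so no
#' information leaks from held-out lesions). For each lambda on a
#' log-spaced grid from `lambda_max` (the smallest lambda with an all-zero
#' solution) down to `min_ratio * lambda_max`, the mean out-of-fold AUC is
#' estimated by stratified k-fold cross-validation; the lambda maximizing
#' the mean AUC is chosen, ties broken toward the larger (sparser) lambda,
#' and the final coefficients come from a refit on the full training data.
#' The penalized likelihood is maximized by coordinate descent inside
#' iteratively reweighted least squares with an unpenalized intercept
#' (convergence when the largest coefficient change drops below `tol`).
#'
#' @param X Numeric feature matrix (lesions x features, named columns).
#' @param y Binary outcome (logical, 0/1, or the labels in `positive`).
#' @param lambda_grid Optional decreasing lambda sequence; by default 100
#'   log-spaced values spanning three decades below `lambda_max`.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Seed for fold assignment.
#' @param nlambda,min_ratio Grid size and span when `lambda_grid` is NULL.
#' @param positive Label treated as the event when `y` is not numeric.
#' @param tol Coordinate-descent convergence tolerance for the final refit.
#' @param cv_tol Tolerance inside CV folds. Fold fits only feed the AUC
#'   ranking of the lambda grid, which is insensitive to the last decimals
#'   of the coefficients, so a looser tolerance buys a large speedup with
#'   an unchanged CV curve.
#' @return Object of class `radiomics_model`: selected feature names,
#'   their coefficients, `lambda`, the CV curve (`cv_auc`), per-feature
#'   standardization statistics, and the refit intercept.
#' @export
fit_lasso_logistic <- function(X, y, lambda_grid = NULL, n_folds = 10L,
                               seed = 1L, nlambda = 100L, min_ratio = 1e-3,
                               positive = "tnbc", tol = 1e-7,
                               cv_tol = 1e-5) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.numeric(y) && !is.logical(y)) y <- y == positive
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("outcome y is constant")
  n <- nrow(X)
  if (n < n_folds) stop("need at least n_folds observations")
  keep <- apply(X, 2L, sd) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance feature(s)")
    X <- X[, keep, drop = FALSE]
  }
  mu <- colMeans(X)
  sg <- apply(X, 2L, sd)
  Xs <- scale(X, center = mu, scale = sg)

  # tiny inflation keeps the stored null point on the zero side of the
  # soft threshold under floating-point roundoff
  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / n * (1 + 1e-8)
  if (is.null(lambda_grid)) {
    lambda_grid <- lambda_grid_default(lambda_max, nlambda, min_ratio)
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  fold <- stratified_folds(y, n_folds, seed)
  cv_auc <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2L) next
    mu_f <- colMeans(X[tr, , drop = FALSE])
    sg_f <- apply(X[tr, , drop = FALSE], 2L, sd)
    ok <- sg_f > 0
    Xf <- scale(X[tr, ok, drop = FALSE], mu_f[ok], sg_f[ok])
    fit <- lasso_logistic_path_cpp(Xf, y[tr], lambda_grid, tol = cv_tol)
    Xv <- scale(X[!tr, ok, drop = FALSE], mu_f[ok], sg_f[ok])
    eta <- sweep(Xv %*% fit$coefficients, 2L, fit$intercepts, `+`)
    cv_auc[f, ] <- apply(eta, 2L, function(s) auc_rank(s, y[!tr]))
  }
  mean_auc <- colMeans(cv_auc, na.rm = TRUE)
  best <- max(mean_auc)
  pick <- min(which(mean_auc >= best - 1e-12))  # grid decreasing: larger lambda

  fit <- lasso_logistic_path_cpp(Xs, y, lambda_grid, tol = tol)
  beta <- fit$coefficients[, pick]
  beta[abs(beta) < 1e-8] <- 0  # below solver resolution
  names(beta) <- colnames(X)
  sel <- beta != 0
  structure(list(selected_features = colnames(X)[sel],
                 coefficients = beta[sel],
                 intercept = fit$intercepts[pick],
                 lambda = lambda_grid[pick],
                 lambda_max = lambda_max,
                 cv_auc_curve = data.frame(
                   lambda = lambda_grid,
                   mean_auc = mean_auc,
                   n_selected = colSums(abs(fit$coefficients) > 1e-8)),
                 standardization = list(mean = mu, sd = sg),
                 feature_names = colnames(X),
                 n_folds = n_folds, seed = seed),
            class = "radiomics_model")
}

#' @export
print.radiomics_model <- function(x, ...) {
  cat("LASSO-logistic radiomics model\n")
  cat("  lambda =", signif(x$lambda, 4),
      " (lambda_max =", signif(x$lambda_max, 4), ")\n")
  cat("  selected features:", length(x$selected_features), "of",
      length(x$feature_names), "\n")
  cat("  mean CV AUC at lambda:",
      signif(x$cv_auc_curve$mean_auc[
        which.min(abs(x$cv_auc_curve$lambda - x$lambda))], 4), "\n")
  invisible(x)
}

#' Radiomics score
#'
#' The linear combination of the selected, z-scored features weighted by
#' their LASSO coefficients. The model intercept is deliberately excluded:
#' the score-to-probability calibration carries its own intercept.
#'
#' @param model A `radiomics_model`.
#' @param features Named numeric vector, or a matrix / data frame with
#'   named columns (one row per lesion).
#' @return Numeric score(s).
#' @export
radiomics_score <- function(model, features) {
  stopifnot(inherits(model, "radiomics_model"))
  sel <- model$selected_features
  if (length(sel) == 0L) {
    nr <- if (is.null(dim(features))) 1L else nrow(features)
    return(numeric(nr))
  }
  if (is.null(dim(features))) {
    features <- matrix(features, 1L, dimnames = list(NULL, names(features)))
  }
  features <- as.matrix(as.data.frame(features)[, , drop = FALSE])
  miss <- setdiff(sel, colnames(features))
  if (length(miss)) {
    stop("missing selected feature(s): ", paste(miss, collapse = ", "))
  }
  Z <- scale(features[, sel, drop = FALSE],
             center = model$standardization$mean[sel],
             scale = model$standardization$sd[sel])
  drop(Z %*% model$coefficients[sel])
}

#' Score-to-probability calibration
#'
#' Logistic mapping from a radiomics score to a predicted malignancy
#' probability in percent. The default constants are the published
#' conversion equation for this signature.
#'
#' @param intercept,slope Calibration constants (defaults 0.6985, 1.6381).
#' @return List of class `score_calibration`.
#' @export
score_calibration <- function(intercept = 0.6985, slope = 1.6381) {
  stopifnot(is.finite(intercept), is.finite(slope))
  structure(list(intercept = intercept, slope = slope),
            class = "score_calibration")
}

#' Convert radiomics scores to predicted malignancy probabilities
#'
#' `p = 100 * exp(a + b s) / (1 + exp(a + b s))`, computed with a
#' numerically stable logistic so that extreme scores saturate at 0 or 100
#' instead of overflowing.
#'
#' @param cal A [score_calibration()].
#' @param s Numeric score(s).
#' @return Probabilities in percent, in `[0, 100]`.
#' @export
score_to_probability <- function(cal = score_calibration(), s) {
  stopifnot(inherits(cal, "score_calibration"), all(is.finite(s)))
  100 * plogis(cal$intercept + cal$slope * s)
}

#' Refit the score-to-probability calibration on a cohort
#'
#' Unpenalized univariate logistic regression of the malignancy label on
#' the radiomics score. Under complete separation the coefficients diverge;
#' they are then capped at +/- 30 and a warning is raised.
#'
#' @param scores Numeric radiomics scores.
#' @param labels Binary labels (logical/0-1, or labels with `positive`).
#' @param positive Event label when `labels` is not numeric.
#' @return A [score_calibration()]; attribute `"fit"` holds the glm.
#' @export
calibrate_score <- function(scores, labels, positive = "tnbc") {
  if (!is.numeric(labels) && !is.logical(labels)) labels <- labels == positive
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  fit <- suppressWarnings(glm(labels ~ scores, family = binomial()))
  cf <- coef(fit)
  separated <- !fit$converged || any(abs(cf) > 30) ||
    all(abs(stats::fitted(fit) - labels) < 1e-6)
  if (separated) {
    warning("possible complete separation: calibration coefficients capped")
    cf <- pmin(pmax(cf, -30), 30)
  }
  cal <- score_calibration(intercept = unname(cf[1L]), slope = unname(cf[2L]))
  attr(cal, "fit") <- fit
  cal
}

# tie-corrected rank (Mann-Whitney) AUC
auc_rank <- function(scores, labels) {
  pos <- labels == 1 | labels == TRUE
  m <- sum(pos); n0 <- sum(!pos)
  if (m == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n0)
}

#' AUC with a DeLong 95% confidence interval
#'
#' The area under the ROC curve is the tie-corrected Mann-Whitney
#' statistic; its variance is estimated from the DeLong placement values
#' and the CI is the normal-approximation interval truncated to `[0, 1]`.
#'
#' @param scores Numeric scores (larger = more malignant).
#' @param labels Binary labels (logical/0-1, or labels with `positive`).
#' @param positive Event label when `labels` is not numeric.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `auc`, `ci` (length 2), and `se`.
#' @export
auc_with_ci <- function(scores, labels, positive = "tnbc",
                        conf_level = 0.95) {
  if (!is.numeric(labels) && !is.logical(labels)) labels <- labels == positive
  labels <- as.numeric(labels)
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both classes must be present to compute an AUC")
  }
  sy <- sort(y)
  lt <- findInterval(x, sy, left.open = TRUE)   # y strictly below each x
  le <- findInterval(x, sy)                      # y <= each x
  v10 <- (lt + 0.5 * (le - lt)) / length(y)
  sx <- sort(x)
  lt2 <- length(x) - findInterval(y, sx)         # x strictly above each y
  ge <- length(x) - findInterval(y, sx, left.open = TRUE)
  v01 <- (lt2 + 0.5 * (ge - lt2)) / length(x)
  auc <- mean(v10)
  var_auc <- var(v10) / length(x) + var(v01) / length(y)
  se <- sqrt(var_auc)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  list(auc = auc, ci = ci, se = se)
}

#' Two-group and k-group comparison tests
#'
#' Thin dispatcher over the standard tests used in cohort tables:
#' Student's t (pooled variance), Mann-Whitney U (normal approximation
#' with tie correction, no continuity correction), Kruskal-Wallis, and
#' chi-square (no Yates correction). All p-values are two-sided.
#'
#' @param values Numeric values (or categorical labels for `chi_square`).
#' @param groups Group labels.
#' @param test One of `"student_t"`, `"mann_whitney"`, `"kruskal_wallis"`,
#'   `"chi_square"`.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(values, groups,
                           test = c("student_t", "mann_whitney",
                                    "kruskal_wallis", "chi_square")) {
  test <- match.arg(test)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("at least two groups are required")
  if (test %in% c("student_t", "mann_whitney") && nlevels(groups) != 2L) {
    stop(test, " requires exactly two groups")
  }
  r <- switch(test,
    student_t = t.test(values ~ groups, var.equal = TRUE),
    mann_whitney = wilcox.test(values[groups == levels(groups)[1L]],
                               values[groups == levels(groups)[2L]],
                               exact = FALSE, correct = FALSE),
    kruskal_wallis = kruskal.test(values, groups),
    chi_square = chisq.test(table(values, groups), correct = FALSE))
  list(statistic = unname(r$statistic), p_value = r$p.value,
       method = r$method)
}

#' Fit, score and summarize a cohort
#'
#' Runs the modelling stage end to end on an extracted feature table:
#' training-set LASSO fit, scores and calibrated probabilities for every
#' lesion, per-machine score summaries with a Kruskal-Wallis comparison
#' and per-machine AUCs (performance-by-machine table), an optional
#' single-machine subgroup refit, and the low-suspicion (BI-RADS 3 + 4a)
#' subgroup AUC (subgroup performance table).
#'
#' @param feature_table Output of [extract_cohort()] (must contain `class`,
#'   `machine`, `birads` and the 730 feature columns). A `split` column is
#'   added by seeded random sampling if absent.
#' @param split_fraction,split_seed Split controls when `split` is absent.
#' @param cv_seed,n_folds Cross-validation controls.
#' @param subgroup_machine Machine id for the homogeneous-subgroup refit
#'   (`NULL` to skip).
#' @param birads_low Categories defining the low-suspicion subgroup.
#' @param out_dir Optional directory; tables are written as CSV.
#' @return List of class `radiomics_report`: `model`, `calibration`,
#'   `scores` (per-lesion table), `machine_table`, `machine_kw`,
#'   `subgroup`, `balance`.
#' @export
run_analysis <- function(feature_table, split_fraction = 0.5,
                         split_seed = 1L, cv_seed = 1L, n_folds = 10L,
                         subgroup_machine = "iU22",
                         birads_low = c("3", "4a"), out_dir = NULL) {
  tab <- feature_table
  if (!"split" %in% names(tab)) {
    tab <- split_train_validation(tab, split_fraction, split_seed)
  }
  balance <- attr(tab, "balance")
  X <- feature_matrix(tab)
  y <- tab$class == "tnbc"
  tr <- tab$split == "train"
  model <- fit_lasso_logistic(X[tr, , drop = FALSE], y[tr],
                              n_folds = n_folds, seed = cv_seed)
  score <- radiomics_score(model, X)
  cal <- calibrate_score(score[tr], y[tr])
  prob <- score_to_probability(cal, score)
  scores <- data.frame(lesion_id = tab$lesion_id, class = tab$class,
                       machine = tab$machine, birads = tab$birads,
                       split = tab$split, score = score,
                       probability = prob, stringsAsFactors = FALSE)

  machine_table <- machine_performance_table(scores)
  machine_kw <- lapply(split(scores, scores$split), function(d) {
    if (length(unique(d$machine)) < 2L) return(NULL)
    compare_groups(d$score, d$machine, "kruskal_wallis")
  })

  subgroup <- NULL
  if (!is.null(subgroup_machine)) {
    sub <- tab[tab$machine == subgroup_machine, , drop = FALSE]
    cnt <- table(factor(sub$class, c("fibroadenoma", "tnbc")))
    if (any(cnt < 10L)) {
      warning("subgroup '", subgroup_machine, "' has fewer than 10 lesions ",
              "per class; skipping the subgroup refit")
    } else {
      subgroup <- subgroup_analysis(sub, birads_low, cv_seed, n_folds)
    }
  }

  out <- structure(list(model = model, calibration = cal, scores = scores,
                        machine_table = machine_table,
                        machine_kw = machine_kw,
                        subgroup = subgroup, balance = balance),
                   class = "radiomics_report")
  if (!is.null(out_dir)) write_report_tables(out, out_dir)
  out
}

machine_performance_table <- function(scores) {
  rows <- list()
  for (s in unique(scores$split)) for (m in unique(scores$machine)) {
    d <- scores[scores$split == s & scores$machine == m, ]
    if (nrow(d) == 0L) next
    ben <- d$score[d$class == "fibroadenoma"]
    mal <- d$score[d$class == "tnbc"]
    q <- quantile(d$score, c(0.25, 0.5, 0.75), names = FALSE)
    p_t <- if (length(ben) > 1L && length(mal) > 1L) {
      compare_groups(d$score, d$class, "student_t")$p_value
    } else NA_real_
    a <- if (length(ben) > 0L && length(mal) > 0L) {
      auc_with_ci(d$score, d$class == "tnbc")
    } else list(auc = NA_real_, ci = c(NA_real_, NA_real_))
    rows[[paste(s, m)]] <- data.frame(
      split = s, machine = m, n = nrow(d),
      median = q[2L], iqr_lo = q[1L], iqr_hi = q[3L],
      benign_mean = mean(ben), benign_sd = sd(ben),
      malignant_mean = mean(mal), malignant_sd = sd(mal),
      p_class_ttest = p_t, auc = a$auc,
      auc_lo = a$ci[1L], auc_hi = a$ci[2L],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

subgroup_analysis <- function(sub, birads_low, cv_seed, n_folds) {
  sub <- split_train_validation(sub, 0.75, cv_seed)
  Xs <- feature_matrix(sub)
  ys <- sub$class == "tnbc"
  trs <- sub$split == "train"
  msub <- fit_lasso_logistic(Xs[trs, , drop = FALSE], ys[trs],
                             n_folds = n_folds, seed = cv_seed)
  ssc <- radiomics_score(msub, Xs)
  rows <- list()
  sets <- list(train = trs, validation = !trs, total = rep(TRUE, nrow(sub)))
  for (grp in c("all", "birads_low")) {
    in_grp <- if (grp == "all") rep(TRUE, nrow(sub)) else
      sub$birads %in% birads_low
    for (sn in names(sets)) {
      keep <- sets[[sn]] & in_grp
      d_s <- ssc[keep]; d_y <- ys[keep]
      if (sum(d_y) == 0L || sum(!d_y) == 0L) next
      ben <- d_s[!d_y]; mal <- d_s[d_y]
      a <- auc_with_ci(d_s, d_y)
      p_mw <- if (length(ben) > 1L && length(mal) > 1L) {
        compare_groups(d_s, ifelse(d_y, "tnbc", "fibroadenoma"),
                       "mann_whitney")$p_value
      } else NA_real_
      rows[[paste(grp, sn)]] <- data.frame(
        group = grp, set = sn, n = sum(keep),
        benign_median = median(ben),
        benign_iqr_lo = quantile(ben, 0.25, names = FALSE),
        benign_iqr_hi = quantile(ben, 0.75, names = FALSE),
        malignant_median = median(mal),
        malignant_iqr_lo = quantile(mal, 0.25, names = FALSE),
        malignant_iqr_hi = quantile(mal, 0.75, names = FALSE),
        p_mann_whitney = p_mw,
        auc = a$auc, auc_lo = a$ci[1L], auc_hi = a$ci[2L],
        stringsAsFactors = FALSE)
    }
  }
  list(model = msub, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

write_report_tables <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$scores, file.path(out_dir, "scores.csv"),
            row.names = FALSE)
  write.csv(report$machine_table,
            file.path(out_dir, "performance_by_machine.csv"),
            row.names = FALSE)
  if (!is.null(report$balance)) {
    write.csv(report$balance, file.path(out_dir, "split_balance.csv"),
              row.names = FALSE)
  }
  if (!is.null(report$subgroup)) {
    write.csv(report$subgroup$table,
              file.path(out_dir, "subgroup_performance.csv"),
              row.names = FALSE)
  }
  invisible(out_dir)
}
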