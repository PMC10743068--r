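# ---------------------------------------------------------------------------
# Hybrid / tabular experiment family: mRS dichotomisation, the ASTRAL integer
# comparator, the penalised logistic-regression experiments (2/5/8 variables,
# with expert or network-predicted occlusion), Bayesian hyperparameter
# search, normalised coefficient profiles, VIF diagnostics and fold-paired
# t-tests.
# ---------------------------------------------------------------------------

#' Dichotomize the 90-day modified Rankin Scale
#'
#' Good outcome (0) is mRS <= 2 — independence; poor outcome (1) is
#' mRS > 2, up to death at 6.
#'
#' @param mrs90 Integer vector in 0..6.
#' @return Integer vector of 0 (good) / 1 (poor).
#' @export
dichotomize_mrs <- function(mrs90) {
  if (any(!is.finite(mrs90)) || any(mrs90 < 0 | mrs90 > 6) ||
      any(mrs90 != round(mrs90)))
    stop("mrs90 must be integers in 0..6")
  as.integer(mrs90 > 2)
}

#' Default ASTRAL point scheme
#'
#' One point per 5 completed years of age, one per NIHSS point, 2 points for
#' onset-to-admission delay over 3 h, 2 for a visual field defect, 3 for
#' decreased level of consciousness, and 1 for admission glucose above
#' 131 mg/dL or below 66 mg/dL. Exposed as a table so alternate calibrations
#' can be swapped in.
#'
#' @return A list of scheme parameters.
#' @export
astral_scheme <- function() {
  list(age_divisor = 5, delay_hours = 3, delay_points = 2L,
       visual_points = 2L, loc_points = 3L,
       glucose_high = 131, glucose_low = 66, glucose_points = 1L)
}

#' ASTRAL clinical score
#'
#' The integer prognostic score over the six clinical admission variables;
#' higher is worse. The raw score is the ranking statistic used for AUC.
#' Monotone non-decreasing in every risk component and additive across
#' components.
#'
#' @param cohort Data frame with columns `age`, `nihss`, `delay`,
#'   `visual_defect`, `loc`, `glucose`.
#' @param scheme Point scheme, see [astral_scheme()].
#' @return Integer score vector.
#' @export
astral_score <- function(cohort, scheme = astral_scheme()) {
  need <- c("age", "nihss", "delay", "visual_defect", "loc", "glucose")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("missing ASTRAL variables: ", paste(miss, collapse = ", "))
  if (any(!stats::complete.cases(cohort[need])))
    stop("ASTRAL variables contain missing values")
  with(cohort,
       floor(age / scheme$age_divisor) + nihss +
         scheme$delay_points * (delay > scheme$delay_hours) +
         scheme$visual_points * (visual_defect > 0) +
         scheme$loc_points * (loc > 0) +
         scheme$glucose_points *
           (glucose > scheme$glucose_high | glucose < scheme$glucose_low))
}

EXPERIMENT_VARS <- list(
  lr_2vars = c("age", "nihss"),
  lr_5vars = c("age", "nihss", "glucose", "aspects", "occlusion"),
  lr_5vars_sn = c("age", "nihss", "glucose", "aspects", "occlusion_sn"),
  lr_8vars = c("age", "nihss", "delay", "visual_defect", "loc", "glucose",
               "aspects", "occlusion"),
  astral = c("age", "nihss", "delay", "visual_defect", "loc", "glucose")
)

#' Experiment definition
#'
#' Named predictor subsets of the hybrid family: `lr_2vars` (age, NIHSS),
#' `lr_5vars` (+ glucose, ASPECTS, expert occlusion), `lr_5vars_sn` (same
#' but the occlusion probability predicted by the Siamese occlusion network,
#' column `occlusion_sn`), `lr_8vars` (six ASTRAL variables + ASPECTS +
#' occlusion) and `astral` (the clinical integer score, no fitting).
#'
#' @param name Experiment tag.
#' @return A `strokesight_experiment` list with `name`, `variables` and
#'   `occlusion_source`.
#' @export
experiment_def <- function(name = names(EXPERIMENT_VARS)) {
  name <- match.arg(name)
  structure(list(name = name, variables = EXPERIMENT_VARS[[name]],
                 occlusion_source = if (name == "lr_5vars_sn") "model" else "expert"),
            class = "strokesight_experiment")
}

#' Physiological bounds used for cohort cleaning
#'
#' Records with missing values or values outside these bounds are excluded
#' before modelling (complete-case analysis).
#'
#' @return Named list of `c(lo, hi)` bounds.
#' @export
cohort_bounds <- function() {
  list(age = c(18, 105), nihss = c(0, 42), delay = c(0, 168),
       visual_defect = c(0, 1), loc = c(0, 1), glucose = c(30, 600),
       aspects = c(0, 10), occlusion = c(0, 1), mrs90 = c(0, 6))
}

#' Clean a cohort table
#'
#' @param cohort Data frame of patient records.
#' @param bounds Bound table, see [cohort_bounds()]; only columns present in
#'   the cohort are checked.
#' @return The subset of rows with no missing and no out-of-bounds values;
#'   attribute `n_dropped` records the attrition.
#' @export
clean_cohort <- function(cohort, bounds = cohort_bounds()) {
  keep <- rep(TRUE, nrow(cohort))
  for (v in intersect(names(bounds), names(cohort))) {
    x <- cohort[[v]]
    keep <- keep & !is.na(x) & x >= bounds[[v]][1] & x <= bounds[[v]][2]
  }
  out <- cohort[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# --- Bayesian hyperparameter optimisation ------------------------------------

# 1-D Gaussian-process expected-improvement maximiser. RBF kernel with fixed
# relative length scale and a small nugget; candidates on a dense grid. Used
# to tune the log10 regularisation strength of the logistic fits.
bayes_opt_1d <- function(f, lower, upper, n_init = 5L, n_iter = 10L, seed = 1L) {
  with_seed(seed, {
    xs <- as.numeric(lhs::maximinLHS(n_init, 1)) * (upper - lower) + lower
    ys <- vapply(xs, f, 0)
    l <- 0.3 * (upper - lower)
    grid <- seq(lower, upper, length.out = 201)
    for (it in seq_len(n_iter)) {
      mu_y <- mean(ys); sd_y <- max(stats::sd(ys), 1e-9)
      yz <- (ys - mu_y) / sd_y
      K <- exp(-0.5 * (outer(xs, xs, "-") / l)^2) + diag(1e-6 + 1e-4, length(xs))
      Ks <- exp(-0.5 * (outer(grid, xs, "-") / l)^2)
      a <- solve(K, yz)
      mu <- as.numeric(Ks %*% a)
      v <- pmax(1 - rowSums((Ks %*% solve(K)) * Ks), 1e-12)
      s <- sqrt(v)
      best <- max(yz)
      z <- (mu - best) / s
      ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
      ei[vapply(grid, function(g) any(abs(g - xs) < 1e-9), TRUE)] <- -Inf
      xn <- grid[which.max(ei)]
      xs <- c(xs, xn)
      ys <- c(ys, f(xn))
    }
    list(x_best = xs[which.max(ys)], y_best = max(ys),
         history = data.frame(x = xs, y = ys))
  })
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sd, "/")
}

fit_penalized_lr <- function(X, y, alpha, lambda) {
  glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                 lambda = c(lambda * 2, lambda, lambda / 2),
                 standardize = FALSE)
}

predict_penalized_lr <- function(fit, X, lambda) {
  as.numeric(stats::predict(fit, newx = X, s = lambda, type = "response"))
}

coef_penalized_lr <- function(fit, lambda) {
  as.numeric(stats::coef(fit, s = lambda))[-1]
}

# inner-CV AUC objective for one (alpha, log10 lambda) setting
inner_cv_auc <- function(X, y, alpha, log10_lambda, inner_k = 5L, seed = 1L) {
  lambda <- 10^log10_lambda
  fold <- kfold_splits(y, inner_k, stratified = TRUE, seed = seed)
  aucs <- vapply(seq_len(inner_k), function(f) {
    tr <- fold != f; te <- fold == f
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L) return(NA_real_)
    fit <- fit_penalized_lr(X[tr, , drop = FALSE], y[tr], alpha, lambda)
    sc <- predict_penalized_lr(fit, X[te, , drop = FALSE], lambda)
    suppressWarnings(evaluate(sc, y[te])$auc)
  }, 0)
  mean(aucs, na.rm = TRUE)
}

# F1-maximising threshold over the training scores (used for ASTRAL, which
# has no probabilistic output)
best_f1_threshold <- function(scores, y) {
  cand <- sort(unique(scores))
  cand <- c(cand, max(cand) + 1)
  f1s <- vapply(cand, function(th)
    suppressWarnings(evaluate(as.numeric(scores >= th), y, threshold = 0.5)$f1), 0)
  cand[which.max(f1s)]
}

#' Run a cross-validated hybrid experiment
#'
#' For the logistic experiments: within each of `k` stratified outer folds
#' the predictors are standardised with training-fold statistics, the
#' regularisation strength (log10 lambda in \[-4, 1\]) and penalty (L1 or
#' L2) are tuned by Gaussian-process Bayesian optimisation of inner 5-fold
#' AUC, the final model is fit on the training fold, and AUC/F1 are measured
#' on the held-out fold. Standardised coefficients are recorded per fold.
#' For the `astral` experiment the integer score is the ranking statistic
#' and the F1 threshold is chosen on each training fold.
#'
#' @param def An [experiment_def()].
#' @param cohort A cleaned cohort data frame (see [clean_cohort()]) with the
#'   experiment's predictor columns and `mrs90`.
#' @param k Outer folds (default 10).
#' @param seed Integer seed.
#' @param bo_budget Total Bayesian-optimisation evaluations per fold
#'   (split between the two penalties); 0 falls back to ridge with
#'   lambda = 0.01, logged.
#' @return List with `metrics` (per-fold data frame), `coefficients`
#'   (folds x variables matrix, `NULL` for astral) and `hyper` (chosen
#'   penalty/lambda per fold).
#' @export
run_lr_experiment <- function(def, cohort, k = 10L, seed = 1L, bo_budget = 25L) {
  stopifnot(inherits(def, "strokesight_experiment"))
  y <- dichotomize_mrs(cohort$mrs90)
  if (def$name == "astral") {
    sc_all <- astral_score(cohort)
    metrics <- kfold_cv(function(tr, te, fs) {
      th <- best_f1_threshold(sc_all[tr], y[tr])
      # shift so the default 0.5 threshold in evaluate() matches th
      sc_all[te] - th + 0.5
    }, y, k = k, seed = seed)
    return(list(metrics = metrics, coefficients = NULL, hyper = NULL))
  }
  vars <- def$variables
  miss <- setdiff(vars, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  X0 <- as.matrix(cohort[vars])
  coefs <- matrix(NA_real_, k, length(vars), dimnames = list(NULL, vars))
  hyper <- data.frame(fold = integer(0), alpha = numeric(0), lambda = numeric(0))
  fit_predict <- function(tr, te, fs) {
    st <- standardize_fit(X0[tr, , drop = FALSE])
    Xtr <- standardize_apply(X0[tr, , drop = FALSE], st)
    Xte <- standardize_apply(X0[te, , drop = FALSE], st)
    ytr <- y[tr]
    if (bo_budget <= 0L) {
      alpha <- 0; lambda <- 0.01
      message("Bayesian-optimisation budget 0: falling back to ridge, lambda = 0.01")
    } else {
      half <- max(3L, bo_budget %/% 2L)
      n_init <- max(3L, half %/% 3L)
      picks <- lapply(c(0, 1), function(al)
        bayes_opt_1d(function(ll) inner_cv_auc(Xtr, ytr, al, ll, seed = fs),
                     lower = -4, upper = 1, n_init = n_init,
                     n_iter = max(0L, half - n_init), seed = fs + al))
      best_i <- which.max(vapply(picks, `[[`, 0, "y_best"))
      alpha <- c(0, 1)[best_i]
      lambda <- 10^picks[[best_i]]$x_best
    }
    fit <- fit_penalized_lr(Xtr, ytr, alpha, lambda)
    fidx <- length(hyper$fold) + 1L
    coefs[fidx, ] <<- coef_penalized_lr(fit, lambda)
    hyper <<- rbind(hyper, data.frame(fold = fidx, alpha = alpha, lambda = lambda))
    predict_penalized_lr(fit, Xte, lambda)
  }
  metrics <- kfold_cv(fit_predict, y, k = k, seed = seed)
  list(metrics = metrics, coefficients = coefs, hyper = hyper)
}

#' Predict the occlusion biomarker from CTA MIPs
#'
#' Runs a trained occlusion classifier over per-patient MIP images and
#' returns the sigmoid probability, used directly as the `occlusion_sn`
#' variable of the `lr_5vars_sn` experiment (probability form retains
#' information and AUC is threshold-free; threshold at 0.5 for a binary
#' variant).
#'
#' @param model A trained occlusion `strokesight_classifier`.
#' @param cta_mips List of [image2d()] MIPs, preprocessed like the model's
#'   training inputs.
#' @param binary Return 0/1 at threshold 0.5 instead of probabilities.
#' @return Numeric vector in \[0, 1\].
#' @export
predict_occlusion_feature <- function(model, cta_mips, binary = FALSE) {
  stopifnot(inherits(model, "strokesight_classifier"),
            grepl("^occlusion_", model$spec$architecture))
  p <- predict(model, cta_mips)
  if (binary) as.numeric(p >= 0.5) else p
}

#' Normalised coefficient profile across folds
#'
#' Within each fold the absolute standardised coefficients are scaled to sum
#' to one (so the profile is invariant to overall rescaling); the mean and
#' (n-1) standard deviation are then taken across folds and variables are
#' reported in decreasing mean order — the usual feature-importance proxy for
#' a standardised logistic model. Folds with an all-zero coefficient vector
#' are excluded with a warning.
#'
#' @param coefficients Folds x variables matrix from [run_lr_experiment()].
#' @return Data frame with `variable`, `mean`, `sd`, sorted by decreasing
#'   mean.
#' @export
normalized_coefficients <- function(coefficients) {
  a <- abs(as.matrix(coefficients))
  tot <- rowSums(a)
  drop <- tot == 0
  if (any(drop)) {
    warning(sum(drop), " fold(s) with all-zero coefficients excluded")
    a <- a[!drop, , drop = FALSE]
    tot <- tot[!drop]
  }
  if (nrow(a) == 0L) stop("no usable folds")
  nrm <- a / tot
  if (is.null(colnames(nrm))) colnames(nrm) <- paste0("x", seq_len(ncol(nrm)))
  out <- data.frame(variable = colnames(nrm),
                    mean = colMeans(nrm),
                    sd = if (nrow(nrm) == 1L) rep(0, ncol(nrm))
                         else apply(nrm, 2, stats::sd))
  out[order(-out$mean), , drop = FALSE]
}

#' Fold-paired t-test between two experiments
#'
#' Two-sided paired t-test on per-fold metric differences, the standard way
#' of comparing cross-validated models fold by fold. Conventions for the
#' degenerate cases: all differences exactly zero gives p = 1 (not
#' significant, logged); zero variance with a nonzero mean gives p = 0 with a
#' warning.
#'
#' @param metric_a,metric_b Per-fold metric vectors, fold-aligned, length
#'   >= 2.
#' @param alpha Significance level (default 0.05).
#' @return List with `p_value`, `significant`, `direction` (`"a"`, `"b"` or
#'   `"tie"`), `mean_diff` and `t`.
#' @export
paired_t_test <- function(metric_a, metric_b, alpha = 0.05) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2L)
  d <- metric_a - metric_b
  direction <- if (mean(d) > 0) "a" else if (mean(d) < 0) "b" else "tie"
  if (all(d == 0)) {
    message("all fold differences are exactly zero; p = 1 by convention")
    return(list(p_value = 1, significant = FALSE, direction = "tie",
                mean_diff = 0, t = 0))
  }
  if (stats::sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.eps)) {
    warning("zero variance of nonzero fold differences; p reported as 0")
    return(list(p_value = 0, significant = TRUE, direction = direction,
                mean_diff = mean(d), t = Inf * sign(mean(d))))
  }
  tt <- tryCatch(stats::t.test(metric_a, metric_b, paired = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) {  # numerically constant differences
    warning("zero variance of nonzero fold differences; p reported as 0")
    return(list(p_value = 0, significant = TRUE, direction = direction,
                mean_diff = mean(d), t = Inf * sign(mean(d))))
  }
  list(p_value = tt$p.value, significant = tt$p.value < alpha,
       direction = direction, mean_diff = mean(d),
       t = unname(tt$statistic))
}

#' Pairwise fold-paired t-test matrix
#'
#' @param metric_list Named list of per-fold metric vectors (one per
#'   experiment).
#' @param alpha Significance level.
#' @return Data frame of pairwise comparisons (`a`, `b`, `p_value`,
#'   `significant`, `direction`).
#' @export
compare_experiments <- function(metric_list, alpha = 0.05) {
  nms <- names(metric_list)
  rows <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    r <- paired_t_test(metric_list[[i]], metric_list[[j]], alpha)
    rows[[length(rows) + 1L]] <-
      data.frame(a = nms[i], b = nms[j], p_value = r$p_value,
                 significant = r$significant, direction = r$direction)
  }
  do.call(rbind, rows)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the remaining
#' predictors; values above 10 flag problematic multicollinearity. Perfect
#' collinearity is reported as `Inf` and flagged.
#'
#' @param design Numeric matrix or data frame of predictors (rows >
#'   columns, no constant column).
#' @param flag_threshold Flag level (default 10).
#' @return Data frame with `variable`, `vif`, `flagged`.
#' @export
vif <- function(design, flag_threshold = 10) {
  X <- as.matrix(design)
  if (nrow(X) <= ncol(X)) stop("need more rows than predictors")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant column in design")
  if (ncol(X) < 2L) stop("VIF needs at least two predictors")
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  data.frame(variable = colnames(X) %||% paste0("x", seq_len(ncol(X))),
             vif = vifs, flagged = vifs > flag_threshold)
}
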