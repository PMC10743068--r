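test_that("mRS dichotomisation agrees with the exhaustive lookup", {
  expect_equal(dichotomize_mrs(0:6), c(0L, 0L, 0L, 1L, 1L, 1L, 1L))
  expect_equal(dichotomize_mrs(2), 0L)
  expect_equal(dichotomize_mrs(3), 1L)
  expect_error(dichotomize_mrs(7), "0..6")
  expect_error(dichotomize_mrs(-1), "0..6")
  expect_error(dichotomize_mrs(2.5), "0..6")
})

test_that("ASTRAL score is additive and monotone in each risk component", {
  base <- data.frame(age = 0, nihss = 0, delay = 1, visual_defect = 0,
                     loc = 0, glucose = 100)
  expect_equal(astral_score(base), 0)
  ex <- data.frame(age = 71, nihss = 7, delay = 2, visual_defect = 1,
                   loc = 0, glucose = 120)
  expect_equal(astral_score(ex), 14 + 7 + 0 + 2 + 0 + 0)
  bumps <- list(age = 5, nihss = 1, delay = 4, visual_defect = 1, loc = 1,
                glucose = 60)
  for (v in names(bumps)) {
    up <- ex
    up[[v]] <- up[[v]] + bumps[[v]]
    expect_gte(astral_score(up), astral_score(ex))
  }
  # additivity: the joint bump equals the sum of marginal increments
  up_all <- ex
  for (v in names(bumps)) up_all[[v]] <- up_all[[v]] + bumps[[v]]
  inc <- vapply(names(bumps), function(v) {
    up <- ex; up[[v]] <- up[[v]] + bumps[[v]]
    astral_score(up) - astral_score(ex)
  }, 0)
  expect_equal(astral_score(up_all) - astral_score(ex), sum(inc))
  expect_error(astral_score(ex[-1]), "missing")
})

test_that("experiment definitions pin the variable subsets", {
  expect_equal(experiment_def("lr_2vars")$variables, c("age", "nihss"))
  expect_equal(experiment_def("lr_5vars")$variables,
               c("age", "nihss", "glucose", "aspects", "occlusion"))
  expect_equal(experiment_def("lr_5vars_sn")$variables,
               c("age", "nihss", "glucose", "aspects", "occlusion_sn"))
  expect_length(experiment_def("lr_8vars")$variables, 8L)
  expect_equal(experiment_def("lr_5vars_sn")$occlusion_source, "model")
  expect_equal(experiment_def("lr_5vars")$occlusion_source, "expert")
})

test_that("cohort cleaning drops missing and out-of-bounds records", {
  co <- gen_cohort(cohort_spec(n = 300, missing_rate = 0.03, seed = 70))$cohort
  cc <- clean_cohort(co)
  expect_true(all(stats::complete.cases(cc)))
  expect_lt(nrow(cc), nrow(co))
  expect_equal(nrow(cc) + attr(cc, "n_dropped"), nrow(co))
  bad <- co; bad$age[1] <- 130
  expect_false(1 %in% seq_len(nrow(clean_cohort(bad))) &&
                 clean_cohort(bad)$age[1] == 130)
})

test_that("cross-validated LR recovers generator coefficient signs", {
  gen <- gen_cohort(cohort_spec(n = 400, seed = 71))
  cohort <- clean_cohort(gen$cohort)
  res <- run_lr_experiment(experiment_def("lr_8vars"), cohort, k = 5,
                           seed = 11, bo_budget = 10)
  expect_equal(nrow(res$metrics), 5L)
  expect_true(all(res$metrics$auc > 0.5))
  mean_coef <- colMeans(res$coefficients)
  truth <- gen$truth$coefficients
  strong <- names(truth)[abs(truth) >= 0.25]
  expect_equal(sign(mean_coef[strong]), sign(truth[strong]))
  expect_equal(nrow(res$hyper), 5L)
  expect_true(all(res$hyper$alpha %in% c(0, 1)))
})

test_that("a zero-variance predictor is shrunk without crashing", {
  gen <- gen_cohort(cohort_spec(n = 200, seed = 72))
  cohort <- clean_cohort(gen$cohort)
  cohort$aspects <- 10  # constant
  res <- run_lr_experiment(experiment_def("lr_5vars"), cohort, k = 4,
                           seed = 3, bo_budget = 6)
  expect_true(all(abs(res$coefficients[, "aspects"]) < 1e-8))
})

test_that("the ASTRAL comparator runs through the same fold harness", {
  gen <- gen_cohort(cohort_spec(n = 300, seed = 73))
  cohort <- clean_cohort(gen$cohort)
  res <- run_lr_experiment(experiment_def("astral"), cohort, k = 5, seed = 4)
  expect_equal(nrow(res$metrics), 5L)
  expect_null(res$coefficients)
  expect_true(all(res$metrics$auc > 0.5))  # risk score must rank above chance
})

test_that("occlusion feature prediction emits probabilities", {
  set.seed(74)
  enc <- build_2d_encoder(encoder_spec("custom2d", 1L, frozen = TRUE))
  clf <- assemble_occlusion_model(classifier_spec("occlusion_single", enc, "GMP"))
  mips <- lapply(1:4, function(i) rand_image(24, 20, i))
  p <- predict_occlusion_feature(clf, mips)
  expect_true(all(p > 0 & p < 1))
  clf$head$par$W[] <- 0
  clf$head$par$b[] <- 0
  expect_equal(predict_occlusion_feature(clf, mips), rep(0.5, 4))
  expect_equal(predict_occlusion_feature(clf, mips, binary = TRUE), rep(1, 4))
})

test_that("normalised coefficients form a scale-invariant simplex profile", {
  m <- rbind(c(a = 3, b = -1), c(a = 6, b = -2))
  nc <- normalized_coefficients(m)
  expect_equal(nc$mean[nc$variable == "a"], 0.75)
  expect_equal(nc$mean[nc$variable == "b"], 0.25)
  expect_equal(sum(nc$mean), 1)
  expect_equal(nc$sd, c(0, 0))
  m2 <- rbind(c(3, -1), c(30, -10))  # fold 2 is fold 1 scaled by 10
  nc2 <- normalized_coefficients(m2)
  expect_equal(nc2$mean, nc$mean)
  expect_warning(normalized_coefficients(rbind(c(1, 1), c(0, 0))), "all-zero")
})

test_that("paired t-tests match the closed-form t distribution and conventions", {
  expect_message(r0 <- paired_t_test(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(r0$p_value, 1)
  expect_false(r0$significant)
  d10 <- c(rep(0.1, 3), 0.1001, 0.0999, rep(0.1, 5))
  r1 <- paired_t_test(d10 + (1:10) / 100, (1:10) / 100)
  expect_lt(r1$p_value, 1e-10)
  expect_true(r1$significant)
  expect_equal(r1$direction, "a")
  set.seed(75)
  for (i in 1:10) {
    a <- stats::rnorm(8); b <- stats::rnorm(8)
    r <- paired_t_test(a, b)
    d <- a - b
    tstat <- mean(d) / (stats::sd(d) / sqrt(8))
    expect_equal(r$t, tstat, tolerance = 1e-12)
    expect_equal(r$p_value, 2 * stats::pt(-abs(tstat), df = 7),
                 tolerance = 1e-12)
  }
  expect_warning(r2 <- paired_t_test(c(1, 2, 3) + 0.5, c(1, 2, 3)), "zero variance")
  expect_equal(r2$p_value, 0)
  cmp <- suppressWarnings(suppressMessages(
    compare_experiments(list(x = c(0.7, 0.8), y = c(0.6, 0.7),
                             z = c(0.6, 0.7)))))
  expect_equal(nrow(cmp), 3L)
  expect_equal(cmp$p_value[cmp$a == "y" & cmp$b == "z"], 1)
})

test_that("VIF equals the closed form on constructed correlation structures", {
  set.seed(76)
  # exactly orthogonal zero-mean design (Helmert contrasts)
  Q <- stats::contr.helmert(4)[rep(1:4, 75), 1:3]
  v <- vif(Q)
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-8)
  expect_false(any(v$flagged))
  # known pairwise correlation: x3 = 0.8 x1 + noise
  x1 <- stats::rnorm(5000); x2 <- stats::rnorm(5000)
  x3 <- 0.8 * x1 + sqrt(1 - 0.64) * stats::rnorm(5000)
  X <- cbind(x1, x2, x3)
  v2 <- vif(X)
  r2 <- summary(stats::lm(X[, 1] ~ X[, -1]))$r.squared
  expect_equal(v2$vif[1], 1 / (1 - r2), tolerance = 1e-10)
  expect_equal(v2$vif[1], 1 / (1 - 0.64), tolerance = 0.15)
  # perfect collinearity
  v3 <- vif(cbind(x1, x1, x2))
  expect_true(is.infinite(v3$vif[1]))
  expect_true(v3$flagged[1])
  expect_error(vif(cbind(x1, rep(1, 5000))), "constant")
  expect_error(vif(matrix(1:6 + stats::rnorm(6), 2, 3)), "more rows")
})

test_that("the GP optimiser finds a smooth 1-D maximum", {
  r <- bayes_opt_1d(function(x) -(x - 0.7)^2, lower = -2, upper = 2,
                    n_init = 4, n_iter = 8, seed = 5)
  expect_lt(abs(r$x_best - 0.7), 0.25)
  r2 <- bayes_opt_1d(function(x) -(x - 0.7)^2, lower = -2, upper = 2,
                     n_init = 4, n_iter = 8, seed = 5)
  expect_identical(r$history, r2$history)
})
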