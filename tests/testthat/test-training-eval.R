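test_that("stratified splits are proportional, disjoint and reproducible", {
  set.seed(50)
  y465 <- sample(rep(c(0, 1), c(300, 165)))
  s <- stratified_split(y465, c(365, 40, 60) / 465, seed = 5)
  expect_equal(vapply(s, length, 0L), c(train = 365L, val = 40L, test = 60L))
  expect_equal(sort(unlist(s, use.names = FALSE)), seq_along(y465))

  y100 <- rep(c(0, 1), c(70, 30))
  s2 <- stratified_split(y100, c(0.8, 0.1, 0.1), seed = 6)
  for (part in s2) {
    expect_lte(abs(sum(y100[part] == 1) - 0.3 * length(part)), 1)
  }
  expect_identical(stratified_split(y100, c(0.8, 0.1, 0.1), seed = 6), s2)
  expect_false(identical(stratified_split(y100, c(0.8, 0.1, 0.1), seed = 7), s2))
  expect_error(stratified_split(rep(0, 10), c(0.8, 0.1, 0.1)), "both classes")
  expect_error(stratified_split(rep(c(0, 1), c(98, 2)), c(0.8, 0.1, 0.1)),
               "too small")
})

test_that("evaluate matches the pairwise AUC oracle and the F1 closed form", {
  m <- suppressWarnings(evaluate(c(0.9, 0.8, 0.3), c(1, 0, 1)))
  expect_equal(m$auc, 0.5)
  expect_equal(m$f1, 0.5)  # TP=1, FP=1, FN=1
  expect_equal(evaluate(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  expect_equal(evaluate(rep(0.4, 6), rep(c(0, 1), 3))$auc, 0.5)
  set.seed(51)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    scores <- round(stats::runif(n), 2)  # rounding forces ties
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
    th <- stats::runif(1)
    m <- evaluate(scores, labels, th)
    expect_equal(m$auc, auc_pairwise(scores, labels))
    expect_equal(m$f1, f1_closed_form(scores, labels, th))
  }
  expect_warning(evaluate(c(0.1, 0.9), c(1, 1)), "one class")
  # single-class negatives trigger both the AUC and the degenerate-F1 warning
  expect_warning(expect_warning(evaluate(c(0.1, 0.2), c(0, 0)), "one class"),
                 "degenerate")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  scores <- stats::runif(60)
  labels <- stats::rbinom(60, 1, 0.4)
  got <- evaluate(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("model selection takes the earliest best validation epoch", {
  expect_equal(select_best_epoch(c(0.2, 0.7, 0.7, 0.5)), 2L)
  expect_equal(select_best_epoch(c(0.9)), 1L)
  expect_equal(select_best_epoch(c(0.1, 0.1, 0.1)), 1L)
})

test_that("the learning-rate schedule follows stepwise decay", {
  cfg <- train_config(150, 2e-4, 1e-3,
                      lr_schedule = list(factor = 0.1, every_n_epochs = 50L))
  expect_equal(effective_lr(cfg, 1), 2e-4)
  expect_equal(effective_lr(cfg, 50), 2e-4)
  expect_equal(effective_lr(cfg, 51), 2e-5)
  expect_equal(effective_lr(cfg, 120), 2e-4 * 0.01)
  expect_equal(effective_lr(train_config_mrs_image(), 299), 5e-4)
  occ <- train_config_occlusion()
  expect_equal(occ$epochs, 150L)
  expect_equal(occ$weight_decay, 1e-3)
  img <- train_config_mrs_image()
  expect_equal(img$epochs, 300L)
  expect_equal(img$batch_size, 32L)
  expect_equal(img$n_runs, 3L)
})

test_that("training is reproducible and fits a separable toy problem", {
  # planted 2D asymmetry: class 1 images have a bright left patch
  mk_img <- function(label, seed) {
    set.seed(seed)
    m <- matrix(stats::rnorm(24 * 20, 0, 1), 24, 20)
    if (label == 1) m[8:16, 3:8] <- m[8:16, 3:8] + 6
    image2d(m)
  }
  y <- rep(c(0, 1), each = 12)
  xs <- lapply(seq_along(y), function(i) mk_img(y[i], 100 + i))
  data <- list(x_train = xs[c(1:9, 13:21)], y_train = y[c(1:9, 13:21)],
               x_val = xs[c(10:12, 22:24)], y_val = y[c(10:12, 22:24)])
  mkclf <- function() {
    set.seed(60)
    assemble_occlusion_model(classifier_spec(
      "occlusion_single", build_2d_encoder(encoder_spec("custom2d", 1L)), "GMP"))
  }
  cfg <- train_config(epochs = 4, learning_rate = 2e-3, weight_decay = 1e-4,
                      batch_size = 6, seed = 9)
  f1 <- train(mkclf(), data, cfg)
  f2 <- train(mkclf(), data, cfg)
  expect_identical(nn_checksum(f1$model$encoder$net),
                   nn_checksum(f2$model$encoder$net))
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_equal(f1$best_epoch, select_best_epoch(f1$history$val_f1))
  # capacity check: training F1 reaches 1 on the separable set
  ptr <- predict(f1$model, data$x_train)
  expect_equal(evaluate(ptr, data$y_train)$f1, 1)
})

test_that("repeat_runs aggregates mean and n-1 standard deviation", {
  vals <- c(0.7, 0.8, 0.9)
  i <- 0
  r <- repeat_runs(function(seed) {
    i <<- i + 1
    c(auc = vals[i])
  }, n_runs = 3, seed = 2)
  expect_equal(r$summary$mean, 0.8)
  expect_equal(r$summary$sd, 0.1)
  expect_warning(repeat_runs(function(seed) c(auc = 0.5), n_runs = 1),
                 "single run")
  r3 <- repeat_runs(function(seed) c(auc = 0.62), n_runs = 3)
  expect_equal(r3$summary$sd, 0)
})

test_that("k-fold partitions are exhaustive, disjoint and stratified", {
  set.seed(53)
  y <- sample(rep(c(0, 1), c(270, 143)))  # 413 samples
  fold <- kfold_splits(y, 10, stratified = TRUE, seed = 3)
  sizes <- as.numeric(table(fold))
  expect_true(all(sizes %in% c(41, 42)))
  expect_equal(sum(sizes), 413)
  for (f in 1:10) {
    frac <- mean(y[fold == f])
    expect_lte(abs(sum(y[fold == f]) - mean(y) * sum(fold == f)), 1.5)
    expect_true(frac > 0 && frac < 1)
  }
  res <- kfold_cv(function(tr, te, fs) stats::runif(length(te)), y, k = 10,
                  seed = 3)
  expect_equal(nrow(res), 10L)
  expect_equal(sum(res$n_test), 413)
  expect_error(kfold_cv(function(tr, te, fs) stats::runif(length(te)),
                        rep(c(0, 1), c(98, 2)), k = 10, stratified = FALSE,
                        seed = 1),
               "absent")
})

test_that("training on permuted labels shows no skill (no-leakage guard)", {
  set.seed(54)
  # shared anatomy (a smooth blob) with subject-level intensity variation, so
  # the null feature space is not dominated by a single class-aligned axis
  mk_img <- function(label, seed) {
    set.seed(seed)
    base <- outer(stats::dnorm(seq(-2, 2, length.out = 20)),
                  stats::dnorm(seq(-2, 2, length.out = 16))) * 150
    m <- base * stats::runif(1, 0.8, 1.2) +
      matrix(stats::rnorm(20 * 16, 0, 2), 20, 16)
    if (label == 1) m[4:10, 2:6] <- m[4:10, 2:6] + 4
    image2d(m)
  }
  y <- rep(c(0, 1), 27)
  xs <- lapply(seq_along(y), function(i) mk_img(y[i], 500 + i))
  test_idx <- 31:54
  aucs <- vapply(1:12, function(r) {
    yp <- y
    set.seed(600 + r)
    yp[1:30] <- sample(y[1:30])  # permute training + validation labels
    set.seed(700 + r)
    clf <- assemble_occlusion_model(classifier_spec(
      "occlusion_single", build_2d_encoder(encoder_spec("custom2d", 1L)), "GMP"))
    fit <- train(clf, list(x_train = xs[1:24], y_train = yp[1:24],
                           x_val = xs[25:30], y_val = yp[25:30]),
                 train_config(epochs = 2, learning_rate = 1e-3,
                              weight_decay = 0, batch_size = 8,
                              seed = 800 + r))
    suppressWarnings(evaluate(predict(fit$model, xs[test_idx]),
                              y[test_idx])$auc)
  }, 0)
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})
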