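small_enc3d <- function(seed = 1) {
  set.seed(seed)
  build_custom_cnn3d(filters = c(4L, 8L, 8L, 16L))
}

small_enc2d <- function(seed = 1, frozen = FALSE) {
  set.seed(seed)
  build_2d_encoder(encoder_spec("custom2d", 1L, frozen = frozen))
}

rand_vol_batch <- function(d, n, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(prod(d) * n), c(d, 1, n))
}

test_that("global_pool reduces per channel with GMP >= GAP", {
  fm <- array(0, c(1, 1, 1, 3))
  fm[1, 1, 1, ] <- c(2, -1, 7)
  expect_equal(global_pool(fm, "GMP"), c(2, -1, 7))
  expect_equal(global_pool(fm, "GAP"), c(2, -1, 7))
  fm2 <- array(c(1, 2, 3), c(3, 1, 1, 1))
  expect_equal(global_pool(fm2, "GMP"), 3)
  expect_equal(global_pool(fm2, "GAP"), 2)
  set.seed(30)
  for (i in 1:5) {
    fm3 <- array(stats::rnorm(4 * 3 * 2 * 6), c(4, 3, 2, 6))
    expect_true(all(global_pool(fm3, "GMP") >= global_pool(fm3, "GAP")))
  }
})

test_that("classifier outputs are probabilities and specs are validated", {
  clf <- assemble_baseline(classifier_spec("baseline", small_enc3d(), "GMP"))
  p <- predict(clf, rand_vol_batch(c(10, 9, 8), 3, 31))
  expect_true(all(p > 0 & p < 1))
  expect_error(classifier_spec("mil", small_enc2d()), "mil_sigma")
  expect_error(classifier_spec("baseline", small_enc3d(), mil_sigma = "mean"),
               "only meaningful")
  expect_error(assemble_classifier(classifier_spec("baseline", small_enc2d())),
               "3D encoder")
  expect_error(assemble_classifier(
    classifier_spec("occlusion_single", small_enc3d())), "2D encoder")
})

test_that("baseline mirror collapses symmetric inputs to a constant output", {
  clf <- assemble_baseline(classifier_spec("baseline_mirror", small_enc3d(2), "GMP"))
  xs <- rand_vol_batch(c(9, 8, 7), 4, 32)
  for (i in 1:4) xs[, , , 1, i] <- (xs[, , , 1, i] + xs[9:1, , , 1, i]) / 2
  p <- predict(clf, xs)
  expect_equal(max(p) - min(p), 0, tolerance = 1e-12)
  # v and mirror(v) produce inputs differing only by sign
  v <- rand_vol_batch(c(9, 8, 7), 1, 33)
  vm <- v[9:1, , , , , drop = FALSE]
  lm1 <- clf_forward(clf, v)$logit
  lm2 <- clf_forward(clf, vm)$logit
  expect_true(is.finite(lm1) && is.finite(lm2))
})

test_that("siamese merges collapse on symmetric input and ignore hemisphere order", {
  for (arch in c("siamese_after", "siamese_before")) {
    clf <- assemble_siamese(classifier_spec(arch, small_enc3d(3), "GMP"))
    sym <- rand_vol_batch(c(10, 8, 7), 3, 34)
    for (i in 1:3) sym[, , , 1, i] <- (sym[, , , 1, i] + sym[10:1, , , 1, i]) / 2
    lg <- clf_forward(clf, sym)$logit
    expect_equal(max(lg) - min(lg), 0, tolerance = 1e-12,
                 label = paste(arch, "symmetric collapse"))
    x <- rand_vol_batch(c(10, 8, 7), 3, 35)
    xs <- x[10:1, , , , , drop = FALSE]  # hemisphere exchange
    expect_equal(clf_forward(clf, xs)$logit, clf_forward(clf, x)$logit,
                 tolerance = 1e-10, label = paste(arch, "swap invariance"))
  }
  # tangle builds and stays in range
  clf_t <- assemble_siamese(classifier_spec("siamese_tangle", small_enc3d(4), "GMP"))
  p <- predict(clf_t, rand_vol_batch(c(10, 8, 7), 2, 36))
  expect_true(all(p > 0 & p < 1))
})

test_that("singleton feature maps make siamese after and before coincide", {
  # encoder collapsing to 1x1x1: use a tiny input so the custom encoder's
  # two stride-2 blocks reduce 4x3x3 halves to singletons
  set.seed(37)
  enc <- build_custom_cnn3d(filters = c(4L, 8L, 8L, 16L))
  ca <- assemble_siamese(classifier_spec("siamese_after", enc, "GMP"))
  cb <- assemble_siamese(classifier_spec("siamese_before", enc, "GMP",
                                         trunk = "none"))
  cb$head$par <- ca$head$par
  x <- rand_vol_batch(c(9, 3, 3), 2, 38)
  fa <- clf_forward(ca, x)
  fb <- clf_forward(cb, x)
  expect_equal(fa$logit, fb$logit, tolerance = 1e-10)
})

test_that("MIL aggregation follows the stated identities", {
  h <- cbind(c(0, 4), c(2, 2))
  expect_equal(mil_aggregate(h, "mean"), c(1, 3))
  expect_equal(mil_aggregate(h, "max"), c(2, 4))
  single <- matrix(c(3, -1, 2), ncol = 1)
  prm <- list(V = matrix(stats::rnorm(12), 4, 3), w = stats::rnorm(4))
  expect_equal(mil_aggregate(single, "mean"), as.numeric(single))
  expect_equal(mil_aggregate(single, "max"), as.numeric(single))
  expect_equal(mil_aggregate(single, "attention", prm), as.numeric(single))
  # zero scorer => uniform weights => mean pooling
  set.seed(40)
  h2 <- matrix(stats::rnorm(5 * 7), 5, 7)
  prm0 <- list(V = matrix(stats::rnorm(20), 4, 5), w = rep(0, 4))
  expect_equal(mil_aggregate(h2, "attention", prm0), mil_aggregate(h2, "mean"),
               tolerance = 1e-12)
  # duplicated instances equal multiplicity-weighted means
  h3 <- cbind(c(1, 5), c(1, 5), c(4, 0))
  expect_equal(mil_aggregate(h3, "mean"), (2 * c(1, 5) + c(4, 0)) / 3)
  # max aggregation is monotone in any single instance feature
  h4 <- h3; h4[1, 3] <- h4[1, 3] + 2
  expect_true(all(mil_aggregate(h4, "max") >= mil_aggregate(h3, "max")))
  expect_error(mil_aggregate(matrix(numeric(0), 2, 0), "mean"), "empty")
})

test_that("MIL is permutation invariant: aggregators bit-exactly, models numerically", {
  # the aggregation itself accumulates in canonical order: bit-exact
  set.seed(41)
  h <- matrix(stats::rnorm(6 * 8), 6, 8)
  prm <- list(V = matrix(stats::rnorm(30), 5, 6), w = stats::rnorm(5))
  perm8 <- c(5, 2, 8, 1, 7, 3, 6, 4)
  for (sg in c("mean", "max", "attention"))
    expect_identical(mil_aggregate(h, sg, prm),
                     mil_aggregate(h[, perm8], sg, prm),
                     label = paste("bit-exact aggregation for", sg))
  # through the encoder, instance order only perturbs BLAS summation order
  for (sg in c("mean", "max", "attention")) {
    clf <- assemble_mil(classifier_spec("mil", small_enc2d(5), "GMP",
                                        mil_sigma = sg, attention_hidden = 6))
    bag <- array(stats::rnorm(14 * 12 * 6), c(14, 12, 1, 1, 6))
    perm <- c(4, 6, 1, 3, 5, 2)
    l1 <- clf_forward(clf, list(bag))$logit
    l2 <- clf_forward(clf, list(bag[, , , , perm, drop = FALSE]))$logit
    expect_equal(l1, l2, tolerance = 1e-12,
                 label = paste("permutation invariance for", sg))
  }
})

test_that("attention importance is a probability profile aligned to kept slices", {
  clf <- assemble_mil(classifier_spec("mil", small_enc2d(6), "GMP",
                                      mil_sigma = "attention", attention_hidden = 6))
  v <- array(0, c(20, 18, 9))
  v[4:16, 4:15, 3:8] <- 30
  bag <- extract_slice_bag(volume3d(v))
  si <- slice_importance(clf, bag)
  expect_equal(si$kept_index, bag$kept_indices)
  expect_equal(sum(si$importance), 1, tolerance = 1e-9)
  expect_true(all(si$importance >= 0))
  # single-slice bag
  v1 <- array(0, c(20, 18, 1)); v1[4:16, 4:15, 1] <- 30
  b1 <- extract_slice_bag(volume3d(v1))
  expect_equal(slice_importance(clf, b1)$importance, 1)
  # max variant: fractions over feature dimensions, [1, 0] when one wins all
  clfm <- assemble_mil(classifier_spec("mil", small_enc2d(6), "GMP",
                                       mil_sigma = "max"))
  stack <- array(0, c(12, 10, 1, 1, 2))
  stack[, , 1, 1, 1] <- 5   # instance 1 dominates every live feature
  sim <- slice_importance(clfm, stack)
  expect_gte(sim$importance[1], 0.9)  # dead (all-zero) channels tie and split
  expect_equal(sum(sim$importance), 1)
  # duplicated instances share (near-)ties: weight splits evenly between them
  tie <- array(stats::rnorm(12 * 10), c(12, 10, 1, 1, 2))
  tie[, , 1, 1, 2] <- tie[, , 1, 1, 1]
  expect_equal(slice_importance(clfm, tie)$importance, c(0.5, 0.5),
               tolerance = 0.05)
  expect_equal(sum(slice_importance(clfm, tie)$importance), 1)
  clme <- assemble_mil(classifier_spec("mil", small_enc2d(6), "GMP",
                                       mil_sigma = "mean"))
  expect_error(slice_importance(clme, stack), "mean")
})

test_that("occlusion models collapse on symmetric MIPs and ignore flips", {
  enc <- small_enc2d(7, frozen = TRUE)
  set.seed(42)
  base <- matrix(stats::rnorm(30 * 24), 30, 24)
  symm <- (base + base[, 24:1]) / 2
  imgs <- list(image2d(symm), image2d(symm * 3 + 1))
  for (arch in c("occlusion_siamese_flip", "occlusion_siamese_hemi")) {
    clf <- assemble_occlusion_model(classifier_spec(arch, enc, "GMP"))
    lg <- clf_forward(clf, imgs)$logit
    expect_equal(lg[1], lg[2], tolerance = 1e-10,
                 label = paste(arch, "symmetric collapse"))
  }
  clf_f <- assemble_occlusion_model(
    classifier_spec("occlusion_siamese_flip", enc, "GMP"))
  img <- matrix(stats::rnorm(30 * 24), 30, 24)
  l1 <- clf_forward(clf_f, list(image2d(img)))$logit
  l2 <- clf_forward(clf_f, list(image2d(img[, 24:1])))$logit
  expect_equal(l1, l2, tolerance = 1e-10)
  clf_a <- assemble_occlusion_model(
    classifier_spec("occlusion_siamese_after", enc, "GMP"))
  p <- predict(clf_a, list(image2d(img)))
  expect_true(p > 0 && p < 1)
})

test_that("gradients reach the head and unfrozen encoder in one training step", {
  clf <- assemble_siamese(classifier_spec("siamese_after", small_enc3d(8), "GMP"))
  x <- rand_vol_batch(c(10, 8, 7), 4, 43)
  y <- c(0, 1, 0, 1)
  fw <- clf_forward(clf, x, training = TRUE, keep_cache = TRUE)
  p <- 1 / (1 + exp(-fw$logit))
  clf_zero_grads(clf)
  clf_backward(clf, fw$cache, (p - y) / 4)
  expect_gt(sum(abs(clf$head$grad$W)), 0)
  expect_gt(sum(abs(clf$encoder$net$children[[1]]$children[[1]]$grad$W)), 0)
  # one Adam step on the fixed batch decreases the loss
  l0 <- -mean(y * log(p) + (1 - y) * log(1 - p))
  opt <- opt_adam(clf_param_refs(clf), lr = 0.003)
  opt_step(opt)
  p1 <- 1 / (1 + exp(-clf_forward(clf, x, training = TRUE)$logit))
  l1 <- -mean(y * log(p1) + (1 - y) * log(1 - p1))
  expect_lt(l1, l0)
})
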