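# ---------------------------------------------------------------------------
# Experiment harness: stratified splits, the two training protocols, model
# selection on validation F1, repeated runs, k-fold cross-validation and
# AUC/F1 computation with mean +/- sd aggregation.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' `train_config_mrs_image()` is the image-only outcome protocol: 300 epochs,
#' Adam, binary cross entropy, batch 32, weight decay 1e-4, learning rate
#' 5e-4, no schedule, 3 runs. `train_config_occlusion()` is the MIP occlusion
#' protocol: 150 epochs, weight decay 1e-3, learning rate 2e-4 multiplied by
#' 0.1 every 50 epochs.
#'
#' @param epochs Number of epochs.
#' @param learning_rate,weight_decay Adam settings (weight decay is the
#'   classic L2-in-gradient coupling).
#' @param batch_size Samples (or bags) per minibatch.
#' @param lr_schedule Optional `list(factor, every_n_epochs)`; the learning
#'   rate is `learning_rate * factor^floor((epoch - 1) / every_n_epochs)`.
#' @param n_runs Number of repeated runs (different weight initialisations).
#' @param seed Integer seed controlling initial weights, shuffling and any
#'   stochastic layers.
#' @return A `strokesight_train_config`.
#' @export
train_config <- function(epochs, learning_rate, weight_decay, batch_size = 32L,
                         lr_schedule = NULL, n_runs = 3L, seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, weight_decay >= 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 lr_schedule = lr_schedule, n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "strokesight_train_config")
}

#' @rdname train_config
#' @export
train_config_mrs_image <- function(seed = 1L) {
  train_config(epochs = 300L, learning_rate = 5e-4, weight_decay = 1e-4,
               batch_size = 32L, lr_schedule = NULL, n_runs = 3L, seed = seed)
}

#' @rdname train_config
#' @export
train_config_occlusion <- function(seed = 1L) {
  train_config(epochs = 150L, learning_rate = 2e-4, weight_decay = 1e-3,
               batch_size = 32L,
               lr_schedule = list(factor = 0.1, every_n_epochs = 50L),
               n_runs = 3L, seed = seed)
}

effective_lr <- function(config, epoch) {
  if (is.null(config$lr_schedule)) return(config$learning_rate)
  config$learning_rate *
    config$lr_schedule$factor^((epoch - 1L) %/% config$lr_schedule$every_n_epochs)
}

# largest-remainder allocation of n items to fractions
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits indices into three disjoint, exhaustive sets whose per-class counts
#' are within one sample of proportional allocation. With 465 labels and
#' fractions `c(365, 40, 60)/465` the sizes are exactly 365/40/60.
#' Deterministic given the seed.
#'
#' @param labels Binary (0/1) label vector.
#' @param fractions Length-3 positive fractions summing to 1 (train,
#'   validation, test).
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(labels, fractions, seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("both classes must be present")
  n <- length(labels)
  target <- largest_remainder(n, fractions)
  alloc <- t(vapply(classes, function(cl)
    largest_remainder(sum(labels == cl), fractions), integer(3)))
  # reconcile per-class allocations with the global split targets: repeatedly
  # move one sample from a split with excess to one with deficit, taking it
  # from the class currently most over-allocated in the excess split
  repeat {
    excess <- colSums(alloc) - target
    if (all(excess == 0L)) break
    s_from <- which.max(excess)
    s_to <- which.min(excess)
    exp_from <- vapply(classes, function(cl) sum(labels == cl), 0) * fractions[s_from]
    cl <- which.max(alloc[, s_from] - exp_from)
    alloc[cl, s_from] <- alloc[cl, s_from] - 1L
    alloc[cl, s_to] <- alloc[cl, s_to] + 1L
  }
  if (any(alloc < 1L))
    stop("a class is too small to appear in every split")
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      idx <- sample(which(labels == classes[ci]))
      a <- alloc[ci, ]
      out$train <- c(out$train, idx[seq_len(a[1])])
      out$val <- c(out$val, idx[a[1] + seq_len(a[2])])
      out$test <- c(out$test, idx[a[1] + a[2] + seq_len(a[3])])
    }
  })
  lapply(out, sort)
}

#' AUC and F1 of predicted probabilities
#'
#' AUC is the rank-based probability that a random positive outscores a
#' random negative, with ties counting one half (the Mann-Whitney
#' convention). F1 is computed at the given threshold (prediction positive
#' when score >= threshold); when a denominator degenerates to zero, F1 is
#' reported as 0 with a warning. With single-class labels the AUC is
#' undefined and returned as `NA` with a warning (F1 is still returned).
#'
#' @param scores Predicted probabilities (or any ranking statistic for AUC).
#' @param labels Binary 0/1 labels.
#' @param threshold Decision threshold for F1 (default 0.5).
#' @return List with `auc` and `f1`.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), length(scores) >= 2L)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  auc <- if (npos == 0L || nneg == 0L) {
    warning("AUC undefined: only one class present")
    NA_real_
  } else {
    r <- rank(scores)
    (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) {
    warning("F1 degenerate (no positives predicted or present); reporting 0")
    0
  } else 2 * tp / (2 * tp + fp + fn)
  list(auc = auc, f1 = f1)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a classifier
#'
#' Minimises binary cross entropy with Adam under the given configuration,
#' recording validation F1 after every epoch and returning the weights of
#' the epoch with the highest validation F1 (the earliest epoch on ties).
#' Fully seeded: the same seed, config and data give identical selected
#' weights.
#'
#' @param model An assembled `strokesight_classifier`.
#' @param data List with `x_train`, `y_train`, `x_val`, `y_val`; inputs are
#'   lists of volumes, images or slice bags matching the architecture.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best weights restored), `history` (per-epoch
#'   loss and validation F1), `best_epoch` and `best_val_f1`.
#' @export
train <- function(model, data, config, verbose = FALSE) {
  stopifnot(length(data$x_train) >= 1L, length(data$x_val) >= 1L)
  refs <- clf_param_refs(model)
  opt <- opt_adam(refs, config$learning_rate, config$weight_decay)
  ntr <- length(data$x_train)
  best <- list(f1 = -Inf, epoch = NA_integer_, snap = NULL)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_f1 = numeric(0), lr = numeric(0))
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      opt$lr <- effective_lr(config, epoch)
      ord <- sample(ntr)
      losses <- c()
      for (start in seq(1, ntr, by = config$batch_size)) {
        ii <- ord[start:min(start + config$batch_size - 1L, ntr)]
        fw <- clf_forward(model, data$x_train[ii], training = TRUE,
                          keep_cache = TRUE)
        p <- sigmoid(fw$logit)
        y <- data$y_train[ii]
        loss <- bce_loss(p, y)
        if (!is.finite(loss))
          stop(sprintf("NaN/Inf loss at epoch %d; lower the learning rate or check inputs", epoch))
        losses <- c(losses, loss)
        clf_zero_grads(model)
        clf_backward(model, fw$cache, (p - y) / length(ii))
        opt_step(opt)
      }
      vp <- predict(model, data$x_val)
      vf1 <- suppressWarnings(evaluate(vp, data$y_val)$f1)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = mean(losses),
                                     val_f1 = vf1, lr = opt$lr))
      if (vf1 > best$f1) {
        best$f1 <- vf1
        best$epoch <- epoch
        best$snap <- clf_snapshot(model)
      }
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val F1 %.3f", epoch,
                        mean(losses), vf1))
    }
  })
  if (!is.null(best$snap)) clf_restore(model, best$snap)
  list(model = model, history = hist, best_epoch = best$epoch,
       best_val_f1 = best$f1)
}

#' Select the best epoch from a validation-metric sequence
#'
#' The model-selection rule used by [train()], exposed for auditing: the
#' argmax of the per-epoch validation F1, with the earliest epoch winning
#' ties (less-overfit weights).
#'
#' @param val_f1 Numeric vector of per-epoch validation F1 scores.
#' @return Integer epoch index.
#' @export
select_best_epoch <- function(val_f1) {
  which.max(val_f1)  # which.max returns the first maximum: earliest tie wins
}

#' Repeat an experiment over weight-initialisation seeds
#'
#' Runs `run_fn` `n_runs` times with derived seeds (the runs differ only in
#' initialisation/shuffling randomness) and aggregates each returned metric
#' as mean and (n-1)-denominator standard deviation, the usual
#' "mean +/- sd over runs" report. With `n_runs = 1` the sd is reported as 0.
#'
#' @param run_fn Function of one argument (the run seed) returning a named
#'   numeric vector of metrics.
#' @param n_runs Number of runs (default 3).
#' @param seed Base seed from which per-run seeds are derived.
#' @return List with `runs` (per-run data frame) and `summary`
#'   (metric, mean, sd).
#' @export
repeat_runs <- function(run_fn, n_runs = 3L, seed = 1L) {
  stopifnot(n_runs >= 1L)
  rows <- lapply(seq_len(n_runs), function(r) {
    m <- run_fn((seed * 1000L + r) %% .Machine$integer.max)
    data.frame(run = r, t(m))
  })
  runs <- do.call(rbind, rows)
  metrics <- setdiff(names(runs), "run")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(runs[[m]]), 0),
    sd = vapply(metrics, function(m)
      if (n_runs == 1L) 0 else stats::sd(runs[[m]]), 0))
  if (n_runs == 1L)
    warning("single run: standard deviation degenerate, reported as 0")
  list(runs = runs, summary = summ)
}

#' Stratified (or plain) k-fold partition
#'
#' @param labels Binary labels.
#' @param k Number of folds (>= 2).
#' @param stratified Preserve the class ratio within +/- 1 sample per fold.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
kfold_splits <- function(labels, k, stratified = TRUE, seed = 1L) {
  stopifnot(k >= 2L)
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample(n)] <- rep_len(seq_len(k), n)
    }
  })
  fold
}

#' k-fold cross-validation of an experiment
#'
#' Partitions the data into k folds (each sample tested exactly once), calls
#' `fit_predict(train_idx, test_idx, fold_seed)` per fold to obtain scores on
#' the held-out fold, and evaluates AUC and F1 per fold. Folds are returned
#' in order for downstream paired tests. Rejects partitions that leave a
#' test fold single-class (fold AUC would be undefined).
#'
#' @param fit_predict Function `(train_idx, test_idx, fold_seed)` returning
#'   scores for `test_idx`.
#' @param labels Binary labels for all samples.
#' @param k Number of folds.
#' @param stratified Stratify folds (default TRUE).
#' @param seed Integer seed.
#' @param threshold F1 threshold passed to [evaluate()].
#' @return Data frame with `fold`, `auc`, `f1`, `n_test`.
#' @export
kfold_cv <- function(fit_predict, labels, k = 10L, stratified = TRUE,
                     seed = 1L, threshold = 0.5) {
  fold <- kfold_splits(labels, k, stratified, seed)
  for (f in seq_len(k))
    if (length(unique(labels[fold == f])) < 2L)
      stop("a class is absent from test fold ", f,
           "; use stratified folds or fewer folds")
  rows <- lapply(seq_len(k), function(f) {
    te <- which(fold == f)
    tr <- which(fold != f)
    sc <- fit_predict(tr, te, (seed * 100L + f) %% .Machine$integer.max)
    m <- evaluate(sc, labels[te], threshold)
    data.frame(fold = f, auc = m$auc, f1 = m$f1, n_test = length(te))
  })
  do.call(rbind, rows)
}
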