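# ---------------------------------------------------------------------------
# Classifier assembly: baseline / baseline-mirror heads, the three Siamese
# hemisphere-merge strategies, multiple-instance-learning bag models with
# mean/max/attention aggregation, and the MIP occlusion family. Every
# classifier ends in a one-unit linear layer + sigmoid. Forward passes return
# logits (the sigmoid is applied at prediction time); backward passes are
# hand-wired through the merge structure onto the shared encoder.
# ---------------------------------------------------------------------------

ARCHITECTURES <- c("baseline", "baseline_mirror", "siamese_after",
                   "siamese_before", "siamese_tangle", "mil",
                   "occlusion_single", "occlusion_siamese_flip",
                   "occlusion_siamese_hemi", "occlusion_siamese_after")

#' Classifier specification
#'
#' @param architecture One of `r paste(ARCHITECTURES, collapse=", ")`.
#' @param encoder An [encoder_spec()] or a built `strokesight_encoder`.
#' @param pooling Global pooling: `"GMP"` (per-channel max) or `"GAP"`
#'   (per-channel mean).
#' @param mil_sigma Bag aggregator for `mil`: `"mean"`, `"max"` or
#'   `"attention"`. Must be absent otherwise.
#' @param attention_hidden Hidden width of the attention scorer.
#' @param trunk For `siamese_before`: `"auto"` adds two inception modules
#'   after the merge when the encoder is the inception family (mirroring the
#'   original hemisphere-comparison network), `"none"` disables the trunk.
#' @return A `strokesight_classifier_spec`.
#' @export
classifier_spec <- function(architecture, encoder, pooling = c("GMP", "GAP"),
                            mil_sigma = NULL, attention_hidden = 64L,
                            trunk = "auto") {
  pooling <- match.arg(pooling)
  if (!architecture %in% ARCHITECTURES)
    stop("unknown architecture: ", architecture)
  if (architecture == "mil") {
    if (is.null(mil_sigma) || !mil_sigma %in% c("mean", "max", "attention"))
      stop("mil requires mil_sigma in mean/max/attention")
  } else if (!is.null(mil_sigma)) {
    stop("mil_sigma is only meaningful for the mil architecture")
  }
  structure(list(architecture = architecture, encoder = encoder,
                 pooling = pooling, mil_sigma = mil_sigma,
                 attention_hidden = as.integer(attention_hidden),
                 trunk = trunk),
            class = "strokesight_classifier_spec")
}

resolve_encoder <- function(e) {
  if (inherits(e, "strokesight_encoder")) return(e)
  if (inherits(e, "strokesight_encoder_spec")) {
    if (e$family %in% c("custom3d")) return(build_custom_cnn3d(e$in_channels))
    if (e$family == "inception3d") return(build_inception_encoder3d(in_channels = e$in_channels))
    if (grepl("^resnet3d-", e$family))
      return(build_resnet3d(as.integer(sub("resnet3d-", "", e$family)), e$in_channels))
    return(build_2d_encoder(e))
  }
  stop("encoder must be an encoder_spec() or a built encoder")
}

#' Assemble a classifier
#'
#' Builds the network described by a [classifier_spec()]: encoder (shared
#' across Siamese branches), merge strategy, global pooling and the
#' linear(1) + sigmoid head. See [assemble_baseline()], [assemble_siamese()],
#' [assemble_mil()] and [assemble_occlusion_model()] for the family
#' contracts.
#'
#' @param spec A [classifier_spec()].
#' @return A `strokesight_classifier`.
#' @export
assemble_classifier <- function(spec) {
  enc <- resolve_encoder(spec$encoder)
  arch <- spec$architecture
  is3d <- arch %in% c("baseline", "baseline_mirror", "siamese_after",
                      "siamese_before", "siamese_tangle")
  if (is3d && enc$ndim != 3L) stop(arch, " requires a 3D encoder")
  if (!is3d && enc$ndim != 2L) stop(arch, " requires a 2D encoder")
  trunk <- NULL
  merge_net <- NULL
  attention <- NULL
  head_in <- enc$out_channels
  if (arch == "siamese_before" && identical(spec$trunk, "auto") &&
      enc$family == "inception3d") {
    f <- enc$out_channels %/% 4L
    trunk <- nn_seq(inception_module3d(enc$out_channels, f),
                    inception_module3d(4L * f, f))
    head_in <- 4L * f
  }
  if (arch == "siamese_tangle") {
    cc <- enc$out_channels
    merge_net <- nn_seq(nn_conv(2L * cc, cc, 3L, stride = 1L, pad = 1L,
                                groups = cc),
                        nn_relu())
  }
  if (identical(spec$mil_sigma, "attention")) {
    h <- spec$attention_hidden
    attention <- nn_node("attn",
                         par = list(V = matrix(stats::rnorm(h * head_in, 0,
                                                            sqrt(1 / head_in)),
                                               nrow = h),
                                    w = stats::rnorm(h, 0, sqrt(1 / h))))
  }
  head <- nn_linear(head_in, 1L)
  structure(list(spec = spec, encoder = enc, trunk = trunk,
                 merge_net = merge_net, attention = attention, head = head),
            class = "strokesight_classifier")
}

#' @rdname assemble_classifier
#' @details `assemble_baseline` accepts `baseline` (whole registered volume
#'   in) or `baseline_mirror` (the volume minus its midsagittal mirror, so
#'   the network sees only interhemispheric asymmetry).
#' @export
assemble_baseline <- function(spec) {
  stopifnot(spec$architecture %in% c("baseline", "baseline_mirror"))
  assemble_classifier(spec)
}

#' @rdname assemble_classifier
#' @details `assemble_siamese` splits the volume into midline-aligned
#'   hemispheres, encodes both with one weight-shared encoder and merges by:
#'   `siamese_after` — absolute difference of the pooled feature vectors;
#'   `siamese_before` — element-wise absolute difference of the feature maps
#'   (optionally followed by a trunk) before pooling; `siamese_tangle` —
#'   channel-interleaving of the two feature maps followed by a learned
#'   grouped-convolution comparison (groups = encoder channels).
#' @export
assemble_siamese <- function(spec) {
  stopifnot(spec$architecture %in% c("siamese_after", "siamese_before",
                                     "siamese_tangle"))
  assemble_classifier(spec)
}

#' @rdname assemble_classifier
#' @details `assemble_mil` classifies a bag of axial slices: each instance is
#'   encoded, globally average-pooled to an instance feature vector, the bag
#'   is aggregated with `mil_sigma` (element-wise mean, element-wise max, or
#'   attention — a learned, normalised weighted mean), and the head scores
#'   the bag. Output is invariant to instance order.
#' @export
assemble_mil <- function(spec) {
  stopifnot(spec$architecture == "mil")
  assemble_classifier(spec)
}

#' @rdname assemble_classifier
#' @details `assemble_occlusion_model` classifies a CTA maximum intensity
#'   projection: `occlusion_single` (plain encoder), `occlusion_siamese_flip`
#'   (whole image vs its left-right flip, feature-map difference),
#'   `occlusion_siamese_hemi` (half images, feature-map difference) or
#'   `occlusion_siamese_after` (image vs flip, pooled-vector difference).
#' @export
assemble_occlusion_model <- function(spec) {
  stopifnot(grepl("^occlusion_", spec$architecture))
  assemble_classifier(spec)
}

#' @export
print.strokesight_classifier <- function(x, ...) {
  cat(sprintf("<classifier %s | encoder %s | pooling %s%s | %s trainable parameters>\n",
              x$spec$architecture, x$encoder$family, x$spec$pooling,
              if (!is.null(x$spec$mil_sigma)) paste0(" | sigma ", x$spec$mil_sigma) else "",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# --- exported pooling / aggregation operations -------------------------------

#' Global pooling of a feature map
#'
#' Reduces the spatial axes of a feature map to one value per channel: GMP
#' takes the per-channel maximum, GAP the per-channel mean. The last axis of
#' `fm` indexes channels; the leading 1-3 axes are spatial.
#'
#' @param fm Numeric array with 2-4 axes (spatial axes then channels).
#' @param mode `"GMP"` or `"GAP"`.
#' @return Numeric vector of length `channels`.
#' @export
global_pool <- function(fm, mode = c("GMP", "GAP")) {
  mode <- match.arg(mode)
  d <- dim(fm)
  if (is.null(d) || length(d) < 2L)
    stop("fm must be an array with spatial axes and a trailing channel axis")
  S <- prod(d[-length(d)])
  if (S < 1L) stop("feature map has empty spatial extent")
  m <- matrix(fm, S, d[length(d)])
  if (mode == "GMP") apply(m, 2, max) else colMeans(m)
}

# order-canonical row sums: bitwise invariant to column permutations
rowsum_sorted <- function(m) {
  apply(m, 1, function(r) sum(sort(r)))
}

#' Aggregate instance features into a bag feature
#'
#' The three multiple-instance aggregators: element-wise `mean`, element-wise
#' `max`, and `attention`, which scores each instance with
#' `u_k = w' tanh(V h_k)`, normalises `a = softmax(u)` over the bag and
#' returns the weighted mean `sum_k a_k h_k`. With a zero scoring vector `w`
#' the attention weights are uniform and the aggregation equals mean pooling.
#' All aggregators are permutation-invariant (sums are accumulated in a
#' canonical order, so even bit-level results do not depend on instance
#' order).
#'
#' @param instance_features A features-by-instances matrix, or a list of
#'   equal-length feature vectors.
#' @param sigma `"mean"`, `"max"` or `"attention"`.
#' @param params For `attention`: a list with projection matrix `V`
#'   (hidden x features) and scoring vector `w` (hidden).
#' @return The bag feature vector.
#' @export
mil_aggregate <- function(instance_features, sigma = c("mean", "max", "attention"),
                          params = NULL) {
  sigma <- match.arg(sigma)
  h <- if (is.list(instance_features)) do.call(cbind, instance_features)
       else as.matrix(instance_features)
  if (ncol(h) < 1L) stop("empty bag")
  if (sigma == "mean") return(rowsum_sorted(h) / ncol(h))
  if (sigma == "max") return(apply(h, 1, max))
  if (is.null(params) || is.null(params$V) || is.null(params$w))
    stop("attention aggregation needs params$V and params$w")
  a <- attention_weights(h, params$V, params$w)
  rowsum_sorted(h * rep(a, each = nrow(h)))
}

attention_weights <- function(h, V, w) {
  u <- as.numeric(crossprod(w, tanh(V %*% h)))  # 1 x K scores
  e <- exp(u - max(u))
  e / sum(sort(e))
}

# --- batch collation ---------------------------------------------------------

# Stack a list of Volume3D (equal shapes) into an (X,Y,Z,1,N) array.
volumes_to_batch <- function(vols) {
  d <- vols[[1]]$shape
  out <- array(0, c(d, 1L, length(vols)))
  for (i in seq_along(vols)) out[, , , 1L, i] <- vols[[i]]$voxels
  out
}

# Stack a list of Image2D into an (H,W,1,1,N) array.
images_to_batch <- function(imgs) {
  d <- imgs[[1]]$shape
  out <- array(0, c(d, 1L, 1L, length(imgs)))
  for (i in seq_along(imgs)) out[, , 1L, 1L, i] <- imgs[[i]]$pixels
  out
}

# A slice bag as an instance stack (H,W,1,1,K).
bag_to_stack <- function(bag) {
  images_to_batch(bag$instances)
}

collate_inputs <- function(clf, inputs) {
  arch <- clf$spec$architecture
  if (arch == "mil") {
    return(lapply(inputs, function(b)
      if (inherits(b, "strokesight_slicebag")) bag_to_stack(b) else b))
  }
  if (is.array(inputs)) return(inputs)
  if (inherits(inputs[[1]], "strokesight_volume")) return(volumes_to_batch(inputs))
  if (inherits(inputs[[1]], "strokesight_image")) return(images_to_batch(inputs))
  stop("cannot collate inputs for architecture ", arch)
}

flip_lr_batch <- function(x) {
  # LR is axis 1 for volumes, axis 2 (columns) for (PA, LR) images
  x[, dim(x)[2]:1, , , , drop = FALSE]
}

# --- forward / backward ------------------------------------------------------

enc_fwd <- function(clf, x, training) {
  enc <- clf$encoder
  d <- dim(x)
  if (d[4] == 1L && enc$in_channels > 1L) {
    x2 <- array(0, c(d[1:3], enc$in_channels, d[5]))
    for (cc in seq_len(enc$in_channels)) x2[, , , cc, ] <- x[, , , 1L, ]
    x <- x2
  }
  nn_forward(enc$net, x, training = training && !enc$frozen)
}

# split a (X,Y,Z,1,N) volume batch into aligned hemisphere stacks (2N batch)
stack_hemispheres <- function(x) {
  d <- dim(x)
  n <- d[1]
  h <- if (n %% 2L == 1L) (n - 1L) %/% 2L else n %/% 2L
  left <- x[seq_len(h), , , , , drop = FALSE]
  right <- x[n:(n - h + 1L), , , , , drop = FALSE]
  out <- array(0, c(h, d[2], d[3], d[4], 2L * d[5]))
  out[, , , , seq_len(d[5])] <- left
  out[, , , , d[5] + seq_len(d[5])] <- right
  out
}

# split an image batch (H=PA, W=LR, 1, C, N) at the LR midline
stack_image_halves <- function(x) {
  d <- dim(x)
  n <- d[2]
  h <- if (n %% 2L == 1L) (n - 1L) %/% 2L else n %/% 2L
  left <- x[, seq_len(h), , , , drop = FALSE]
  right <- x[, n:(n - h + 1L), , , , drop = FALSE]
  out <- array(0, c(d[1], h, d[3], d[4], 2L * d[5]))
  out[, , , , seq_len(d[5])] <- left
  out[, , , , d[5] + seq_len(d[5])] <- right
  out
}

gp_node <- function(clf) nn_gpool(clf$spec$pooling)

head_fwd <- function(clf, feat, training) nn_forward(clf$head, feat, training)

#' Classifier forward pass
#'
#' Runs a batch through the assembled classifier and returns the head logits
#' (apply `sigmoid` — or use [predict.strokesight_classifier()] — for
#' probabilities in (0, 1)).
#'
#' @param clf A `strokesight_classifier`.
#' @param inputs A collated batch array, a list of [volume3d()] /
#'   [image2d()] objects, or (for `mil`) a list of slice bags.
#' @param training Run batch norm in training mode.
#' @param keep_cache Keep intermediate activations for a backward pass.
#' @return List with `logit` (numeric vector, one per sample/bag) and,
#'   if requested, `cache`.
#' @export
clf_forward <- function(clf, inputs, training = FALSE, keep_cache = FALSE) {
  x <- collate_inputs(clf, inputs)
  arch <- clf$spec$architecture
  if (arch == "mil") return(mil_forward(clf, x, training, keep_cache))
  gp <- gp_node(clf)
  cache <- list(gp = gp)
  if (arch %in% c("baseline", "baseline_mirror", "occlusion_single")) {
    inp <- if (arch == "baseline_mirror") {
      xm <- x[dim(x)[1]:1, , , , , drop = FALSE]
      x - xm
    } else x
    fe <- enc_fwd(clf, inp, training)
    pg <- nn_forward(gp, fe$y, training)
    hz <- head_fwd(clf, pg$y, training)
    cache$enc <- fe$cache; cache$gpc <- pg$cache; cache$headc <- hz$cache
    cache$arch <- arch
    return(list(logit = as.numeric(hz$y),
                cache = if (keep_cache) cache else NULL))
  }
  # Siamese families (volume or MIP): build the 2N branch stack
  stacked <- switch(arch,
    siamese_after = , siamese_before = , siamese_tangle = stack_hemispheres(x),
    occlusion_siamese_flip = , occlusion_siamese_after = {
      d <- dim(x)
      out <- array(0, c(d[1:4], 2L * d[5]))
      out[, , , , seq_len(d[5])] <- x
      out[, , , , d[5] + seq_len(d[5])] <- flip_lr_batch(x)
      out
    },
    occlusion_siamese_hemi = stack_image_halves(x))
  N <- dim(x)[5]
  fe <- enc_fwd(clf, stacked, training)
  A <- fe$y[, , , , seq_len(N), drop = FALSE]
  B <- fe$y[, , , , N + seq_len(N), drop = FALSE]
  cache$enc <- fe$cache
  cache$N <- N
  cache$arch <- arch
  if (arch %in% c("siamese_after", "occlusion_siamese_after")) {
    pa <- nn_forward(gp, A, training)
    pb <- nn_forward(gp, B, training)
    m <- abs(pa$y - pb$y)
    hz <- head_fwd(clf, m, training)
    cache$pac <- pa$cache; cache$pbc <- pb$cache
    cache$sgn <- sign(pa$y - pb$y)
    cache$headc <- hz$cache
  } else if (arch %in% c("siamese_before", "occlusion_siamese_flip",
                         "occlusion_siamese_hemi")) {
    m <- abs(A - B)
    cache$sgn <- sign(A - B)
    t_out <- m
    if (!is.null(clf$trunk)) {
      tr <- nn_forward(clf$trunk, m, training)
      t_out <- tr$y
      cache$trunkc <- tr$cache
    }
    pg <- nn_forward(gp, t_out, training)
    hz <- head_fwd(clf, pg$y, training)
    cache$gpc <- pg$cache; cache$headc <- hz$cache
  } else { # siamese_tangle
    Cc <- dim(A)[4]
    dA <- dim(A)
    interleaved <- array(0, c(dA[1:3], 2L * Cc, N))
    interleaved[, , , 2L * seq_len(Cc) - 1L, ] <- A
    interleaved[, , , 2L * seq_len(Cc), ] <- B
    mg <- nn_forward(clf$merge_net, interleaved, training)
    pg <- nn_forward(gp, mg$y, training)
    hz <- head_fwd(clf, pg$y, training)
    cache$mergec <- mg$cache; cache$gpc <- pg$cache; cache$headc <- hz$cache
    cache$Cc <- Cc
  }
  list(logit = as.numeric(hz$y), cache = if (keep_cache) cache else NULL)
}

mil_forward <- function(clf, bags, training, keep_cache) {
  logits <- numeric(length(bags))
  caches <- vector("list", length(bags))
  gap <- nn_gpool("GAP")  # instance-level pooling
  for (i in seq_along(bags)) {
    fe <- enc_fwd(clf, bags[[i]], training)
    pi <- nn_forward(gap, fe$y, training)   # C x K instance features
    h <- pi$y
    K <- ncol(h)
    sg <- clf$spec$mil_sigma
    if (sg == "mean") {
      bagf <- matrix(rowsum_sorted(h) / K, ncol = 1)
      agg <- list()
    } else if (sg == "max") {
      am <- apply(h, 1, which.max)
      bagf <- matrix(h[cbind(seq_len(nrow(h)), am)], ncol = 1)
      agg <- list(argmax = am)
    } else {
      V <- clf$attention$par$V; w <- clf$attention$par$w
      t_k <- tanh(V %*% h)
      a <- attention_weights(h, V, w)
      bagf <- matrix(rowsum_sorted(h * rep(a, each = nrow(h))), ncol = 1)
      agg <- list(a = a, t_k = t_k)
    }
    hz <- head_fwd(clf, bagf, training)
    logits[i] <- as.numeric(hz$y)
    if (keep_cache)
      caches[[i]] <- list(enc = fe$cache, gpc = pi$cache, h = h, agg = agg,
                          headc = hz$cache, gap = gap)
  }
  list(logit = logits,
       cache = if (keep_cache) list(arch = "mil", bags = caches,
                                    gapnode = gap) else NULL)
}

#' Classifier backward pass
#'
#' Accumulates parameter gradients given the gradient of the loss with
#' respect to the logits. Frozen encoders are skipped (their activations
#' carry no trainable parameters upstream of the merge).
#'
#' @param clf A `strokesight_classifier`.
#' @param cache The cache from [clf_forward()] with `keep_cache = TRUE`.
#' @param dlogit Numeric vector, d loss / d logit per sample.
#' @return Invisibly, `NULL`; gradients are accumulated in the model.
#' @export
clf_backward <- function(clf, cache, dlogit) {
  arch <- cache$arch
  if (arch == "mil") return(mil_backward(clf, cache, dlogit))
  gp <- cache$gp
  dz <- matrix(dlogit, nrow = 1)
  if (arch %in% c("baseline", "baseline_mirror", "occlusion_single")) {
    g <- nn_backward(clf$head, cache$headc, dz)
    g <- nn_backward(gp, cache$gpc, g)
    if (!clf$encoder$frozen) nn_backward(clf$encoder$net, cache$enc, g)
    return(invisible(NULL))
  }
  N <- cache$N
  if (arch %in% c("siamese_after", "occlusion_siamese_after")) {
    g <- nn_backward(clf$head, cache$headc, dz)
    ga <- g * cache$sgn
    gb <- -ga
    gA <- nn_backward(gp, cache$pac, ga)
    gB <- nn_backward(gp, cache$pbc, gb)
  } else if (arch %in% c("siamese_before", "occlusion_siamese_flip",
                         "occlusion_siamese_hemi")) {
    g <- nn_backward(clf$head, cache$headc, dz)
    g <- nn_backward(gp, cache$gpc, g)
    if (!is.null(clf$trunk)) g <- nn_backward(clf$trunk, cache$trunkc, g)
    gA <- g * cache$sgn
    gB <- -gA
  } else { # tangle
    g <- nn_backward(clf$head, cache$headc, dz)
    g <- nn_backward(gp, cache$gpc, g)
    gT <- nn_backward(clf$merge_net, cache$mergec, g)
    Cc <- cache$Cc
    gA <- gT[, , , 2L * seq_len(Cc) - 1L, , drop = FALSE]
    gB <- gT[, , , 2L * seq_len(Cc), , drop = FALSE]
  }
  if (!clf$encoder$frozen) {
    dstack <- array(0, c(dim(gA)[1:4], 2L * N))
    dstack[, , , , seq_len(N)] <- gA
    dstack[, , , , N + seq_len(N)] <- gB
    nn_backward(clf$encoder$net, cache$enc, dstack)
  }
  invisible(NULL)
}

mil_backward <- function(clf, cache, dlogit) {
  for (i in seq_along(cache$bags)) {
    bc <- cache$bags[[i]]
    dz <- matrix(dlogit[i], 1, 1)
    dbag <- nn_backward(clf$head, bc$headc, dz)  # C x 1
    h <- bc$h
    K <- ncol(h)
    sg <- clf$spec$mil_sigma
    if (sg == "mean") {
      dh <- matrix(dbag, nrow(h), K) / K
    } else if (sg == "max") {
      dh <- matrix(0, nrow(h), K)
      dh[cbind(seq_len(nrow(h)), bc$agg$argmax)] <- dbag
    } else {
      a <- bc$agg$a; t_k <- bc$agg$t_k
      V <- clf$attention$par$V; w <- clf$attention$par$w
      dh <- dbag %*% matrix(a, 1)                      # a_k * dbag
      da <- as.numeric(crossprod(h, dbag))             # dbag . h_k
      du <- a * (da - sum(a * da))                     # softmax backward
      dpre <- (w %o% du) * (1 - t_k^2)                 # hidden x K
      if (clf$attention$trainable) {
        acc_grad(clf$attention, "V", dpre %*% t(h))
        acc_grad(clf$attention, "w", as.numeric(t_k %*% du))
      }
      dh <- dh + crossprod(V, dpre)
    }
    g <- nn_backward(bc$gap, bc$gpc, dh)
    if (!clf$encoder$frozen) nn_backward(clf$encoder$net, bc$enc, g)
  }
  invisible(NULL)
}

#' Predict outcome probabilities
#'
#' @param object A `strokesight_classifier`.
#' @param inputs Batch inputs (see [clf_forward()]).
#' @param batch_size Samples per forward chunk.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.strokesight_classifier <- function(object, inputs, batch_size = 16L, ...) {
  n <- if (is.array(inputs)) dim(inputs)[length(dim(inputs))] else length(inputs)
  out <- numeric(n)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (ii in idx) {
    sub <- if (is.array(inputs)) inputs[, , , , ii, drop = FALSE] else inputs[ii]
    r <- clf_forward(object, sub, training = FALSE, keep_cache = FALSE)
    out[ii] <- sigmoid(r$logit)
  }
  out
}

# parameter refs of all trainable classifier components
clf_param_refs <- function(clf) {
  refs <- list()
  if (!clf$encoder$frozen) refs <- c(refs, nn_param_refs(clf$encoder$net))
  if (!is.null(clf$trunk)) refs <- c(refs, nn_param_refs(clf$trunk))
  if (!is.null(clf$merge_net)) refs <- c(refs, nn_param_refs(clf$merge_net))
  if (!is.null(clf$attention)) refs <- c(refs, nn_param_refs(clf$attention))
  c(refs, nn_param_refs(clf$head))
}

clf_components <- function(clf) {
  parts <- list(clf$encoder$net)
  for (nm in c("trunk", "merge_net", "attention", "head"))
    if (!is.null(clf[[nm]])) parts <- c(parts, list(clf[[nm]]))
  parts
}

clf_snapshot <- function(clf) lapply(clf_components(clf), nn_snapshot)

clf_restore <- function(clf, snap) {
  parts <- clf_components(clf)
  for (i in seq_along(parts)) nn_restore(parts[[i]], snap[[i]])
  invisible(NULL)
}

clf_zero_grads <- function(clf) {
  for (p in clf_components(clf)) nn_zero_grads(p)
  invisible(NULL)
}

#' Per-slice importance of a multiple-instance classifier
#'
#' For attention aggregation, the importance of slice k is its attention
#' weight `a_k` (the profile sums to 1). For max aggregation it is the
#' fraction of feature dimensions whose bag-level maximum came from slice k,
#' with exact ties splitting the count equally. Mean aggregation spreads
#' weight uniformly by construction and has no informative profile, so it is
#' rejected.
#'
#' @param model A `mil` classifier with `max` or `attention` aggregation.
#' @param bag A slice bag from [extract_slice_bag()] (or an instance stack).
#' @return A data frame with `kept_index` (original axial slice index) and
#'   `importance`.
#' @export
slice_importance <- function(model, bag) {
  stopifnot(inherits(model, "strokesight_classifier"),
            model$spec$architecture == "mil")
  sg <- model$spec$mil_sigma
  if (sg == "mean")
    stop("slice importance is not defined for mean aggregation")
  stack <- if (inherits(bag, "strokesight_slicebag")) bag_to_stack(bag) else bag
  fe <- enc_fwd(model, stack, training = FALSE)
  h <- nn_forward(nn_gpool("GAP"), fe$y, FALSE)$y  # C x K
  K <- ncol(h)
  imp <- if (sg == "attention") {
    attention_weights(h, model$attention$par$V, model$attention$par$w)
  } else {
    cnt <- numeric(K)
    for (j in seq_len(nrow(h))) {
      mx <- max(h[j, ])
      winners <- which(h[j, ] == mx)
      cnt[winners] <- cnt[winners] + 1 / length(winners)
    }
    cnt / nrow(h)
  }
  ki <- if (inherits(bag, "strokesight_slicebag")) bag$kept_indices else seq_len(K)
  data.frame(kept_index = ki, importance = imp)
}
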