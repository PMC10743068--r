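#' @useDynLib strokesight, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal neural-network core.
#
# Feature maps are R arrays with dims (X, Y, Z, C, N): spatial axes first
# (2D images use Z = 1), then channel, then sample. Layers are environments
# (mutable, so gradient accumulation and optimizer updates are in place);
# networks are nested nodes with recursive forward/backward. Only what the
# classifier families need is implemented: convolution (via im2col + BLAS),
# depthwise convolution, batch norm, ReLU/swish, max/average pooling, global
# pooling, linear, residual blocks, inception-style concat branches and
# squeeze-excitation (forward only, for frozen encoders).
# ---------------------------------------------------------------------------

nn_node <- function(kind, cfg = list(), par = list(), buf = list(),
                    trainable = TRUE, children = list()) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$cfg <- cfg
  e$par <- par
  e$buf <- buf
  e$grad <- lapply(par, function(p) p * 0)
  e$trainable <- trainable
  e$children <- children
  class(e) <- "nn_node"
  e
}

as3 <- function(v) {
  v <- as.integer(v)
  if (length(v) == 1L) rep(v, 3L) else v
}

conv_out_shape <- function(sp, k, s, p) {
  (sp + 2L * p - k) %/% s + 1L
}

he_init <- function(fan_in, n) {
  stats::rnorm(n, 0, sqrt(2 / fan_in))
}

#' @noRd
nn_conv <- function(in_ch, out_ch, kernel, stride = 1L, pad = 0L,
                    groups = 1L, bias = TRUE) {
  k <- as3(kernel); s <- as3(stride); p <- as3(pad)
  stopifnot(in_ch %% groups == 0L, out_ch %% groups == 0L)
  cin_g <- in_ch %/% groups
  kprod <- prod(k)
  W <- matrix(he_init(kprod * cin_g, kprod * cin_g * out_ch),
              nrow = kprod * cin_g, ncol = out_ch)
  par <- list(W = W)
  if (bias) par$b <- numeric(out_ch)
  nn_node("conv",
          cfg = list(in_ch = in_ch, out_ch = out_ch, k = k, s = s, p = p,
                     groups = groups, bias = bias),
          par = par)
}

#' @noRd
nn_dwconv <- function(channels, kernel, stride = 1L, pad = 0L, bias = FALSE) {
  k <- as3(kernel)
  W <- matrix(he_init(prod(k), prod(k) * channels), nrow = prod(k),
              ncol = channels)
  par <- list(W = W)
  if (bias) par$b <- numeric(channels)
  nn_node("dwconv",
          cfg = list(channels = channels, k = k, s = as3(stride),
                     p = as3(pad), bias = bias),
          par = par)
}

#' @noRd
nn_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  nn_node("bn",
          cfg = list(channels = channels, momentum = momentum, eps = eps),
          par = list(gamma = rep(1, channels), beta = numeric(channels)),
          buf = list(rmean = numeric(channels), rvar = rep(1, channels)))
}

#' @noRd
nn_relu <- function() nn_node("relu")

#' @noRd
nn_swish <- function() nn_node("swish")

#' @noRd
nn_maxpool <- function(kernel, stride = NULL, pad = 0L) {
  k <- as3(kernel)
  nn_node("maxpool", cfg = list(k = k, s = as3(if (is.null(stride)) k else stride),
                                p = as3(pad)))
}

#' @noRd
nn_avgpool <- function(kernel, stride = NULL, pad = 0L) {
  k <- as3(kernel)
  nn_node("avgpool", cfg = list(k = k, s = as3(if (is.null(stride)) k else stride),
                                p = as3(pad)))
}

#' @noRd
nn_gpool <- function(mode = c("GMP", "GAP")) {
  nn_node("gpool", cfg = list(mode = match.arg(mode)))
}

#' @noRd
nn_linear <- function(in_features, out_features, bias = TRUE) {
  W <- matrix(stats::rnorm(out_features * in_features, 0, sqrt(1 / in_features)),
              nrow = out_features)
  par <- list(W = W)
  if (bias) par$b <- numeric(out_features)
  nn_node("linear", cfg = list(in_features = in_features,
                               out_features = out_features, bias = bias),
          par = par)
}

#' @noRd
nn_seq <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1]]) && !inherits(ch[[1]], "nn_node"))
    ch <- ch[[1]]
  nn_node("seq", children = ch)
}

#' @noRd
nn_residual <- function(body, downsample = NULL) {
  nn_node("residual", children = list(body = body, downsample = downsample))
}

#' @noRd
nn_concat <- function(branches) {
  nn_node("concat", children = branches)
}

#' @noRd
nn_se <- function(channels, reduced) {
  nn_node("se", cfg = list(channels = channels, reduced = reduced),
          par = list(W1 = matrix(he_init(channels, channels * reduced),
                                 nrow = reduced),
                     b1 = numeric(reduced),
                     W2 = matrix(he_init(reduced, channels * reduced),
                                 nrow = channels),
                     b2 = numeric(channels)))
}

# --- forward -----------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

conv_forward_group <- function(x, d, W, b, k, s, p) {
  cols <- cpp_im2col3d(x, d, k, s, p)
  M <- cols %*% W
  if (!is.null(b)) M <- M + rep(b, each = nrow(M))
  M
}

nn_forward <- function(node, x, training = FALSE) {
  switch(node$kind,
    seq = {
      caches <- vector("list", length(node$children))
      for (i in seq_along(node$children)) {
        r <- nn_forward(node$children[[i]], x, training)
        x <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x, cache = caches)
    },
    conv = {
      cfg <- node$cfg
      d <- dim(x)
      od <- conv_out_shape(d[1:3], cfg$k, cfg$s, cfg$p)
      g <- cfg$groups
      if (g == 1L) {
        M <- conv_forward_group(x, d, node$par$W, node$par$b,
                                cfg$k, cfg$s, cfg$p)
        y <- aperm(array(M, c(od, d[5], cfg$out_ch)), c(1, 2, 3, 5, 4))
      } else {
        cin_g <- cfg$in_ch %/% g; cout_g <- cfg$out_ch %/% g
        y <- array(0, c(od, cfg$out_ch, d[5]))
        for (j in seq_len(g)) {
          xi <- x[, , , ((j - 1) * cin_g + 1):(j * cin_g), , drop = FALSE]
          oc <- ((j - 1) * cout_g + 1):(j * cout_g)
          M <- conv_forward_group(xi, dim(xi), node$par$W[, oc, drop = FALSE],
                                  if (cfg$bias) node$par$b[oc] else NULL,
                                  cfg$k, cfg$s, cfg$p)
          y[, , , oc, ] <- aperm(array(M, c(od, d[5], cout_g)),
                                 c(1, 2, 3, 5, 4))
        }
      }
      list(y = y, cache = list(x = x, d = d, od = od))
    },
    dwconv = {
      cfg <- node$cfg
      d <- dim(x)
      od <- conv_out_shape(d[1:3], cfg$k, cfg$s, cfg$p)
      y <- array(cpp_dwconv3d(x, d, node$par$W, cfg$k, cfg$s, cfg$p),
                 c(od, d[4], d[5]))
      if (cfg$bias)
        y <- y + rep(node$par$b, each = prod(od)) # recycles over samples
      list(y = y, cache = list(d = d))
    },
    bn = {
      cfg <- node$cfg
      d <- dim(x)
      S <- prod(d[1:3]); C <- d[4]; N <- d[5]
      m <- matrix(aperm(x, c(1, 2, 3, 5, 4)), S * N, C)
      if (training) {
        mu <- colMeans(m)
        v <- colMeans(m * m) - mu * mu
        node$buf$rmean <- (1 - cfg$momentum) * node$buf$rmean + cfg$momentum * mu
        node$buf$rvar <- (1 - cfg$momentum) * node$buf$rvar + cfg$momentum * v
      } else {
        mu <- node$buf$rmean
        v <- node$buf$rvar
      }
      invstd <- 1 / sqrt(v + cfg$eps)
      xhat <- (m - rep(mu, each = S * N)) * rep(invstd, each = S * N)
      ym <- xhat * rep(node$par$gamma, each = S * N) +
        rep(node$par$beta, each = S * N)
      y <- aperm(array(ym, c(d[1:3], N, C)), c(1, 2, 3, 5, 4))
      list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d,
                               training = training))
    },
    relu = {
      y <- x * (x > 0)
      list(y = y, cache = list(mask = x > 0))
    },
    swish = {
      s <- sigmoid(x)
      list(y = x * s, cache = NULL)
    },
    maxpool = {
      cfg <- node$cfg
      d <- dim(x)
      od <- conv_out_shape(d[1:3], cfg$k, cfg$s, cfg$p)
      r <- cpp_maxpool3d(x, d, cfg$k, cfg$s, cfg$p)
      y <- array(r$values, c(od, d[4], d[5]))
      list(y = y, cache = list(argmax = r$argmax, xd = d))
    },
    avgpool = {
      cfg <- node$cfg
      d <- dim(x)
      od <- conv_out_shape(d[1:3], cfg$k, cfg$s, cfg$p)
      W <- matrix(1 / prod(cfg$k), prod(cfg$k), d[4])
      y <- array(cpp_dwconv3d(x, d, W, cfg$k, cfg$s, cfg$p), c(od, d[4], d[5]))
      list(y = y, cache = list(d = d, W = W))
    },
    gpool = {
      y <- global_pool_batch(x, node$cfg$mode)
      list(y = y$values, cache = list(d = dim(x), argmax = y$argmax))
    },
    linear = {
      y <- node$par$W %*% x
      if (node$cfg$bias) y <- y + node$par$b
      list(y = y, cache = list(x = x))
    },
    residual = {
      rb <- nn_forward(node$children$body, x, training)
      if (!is.null(node$children$downsample)) {
        rd <- nn_forward(node$children$downsample, x, training)
        pre <- rb$y + rd$y
        dcache <- rd$cache
      } else {
        pre <- rb$y + x
        dcache <- NULL
      }
      act <- node$cfg$activation %||% "relu"
      y <- if (act == "none") pre else pre * (pre > 0)
      list(y = y, cache = list(body = rb$cache, down = dcache,
                               mask = if (act == "none") NULL else pre > 0))
    },
    concat = {
      outs <- lapply(node$children, nn_forward, x = x, training = training)
      y <- do.call(abind_ch, lapply(outs, `[[`, "y"))
      list(y = y,
           cache = list(caches = lapply(outs, `[[`, "cache"),
                        chs = vapply(outs, function(o) dim(o$y)[4], 0)))
    },
    se = {
      d <- dim(x)
      S <- prod(d[1:3])
      s <- global_pool_batch(x, "GAP")$values          # C x N
      h <- node$par$W1 %*% s + node$par$b1
      h <- h * sigmoid(h)                              # swish
      g <- sigmoid(node$par$W2 %*% h + node$par$b2)    # C x N gates
      y <- x * aperm(array(rep(g, each = S), c(d[1:3], d[4], d[5])),
                     c(1, 2, 3, 4, 5))
      list(y = y, cache = NULL)
    },
    stop("unknown node kind: ", node$kind)
  )
}

# channel-axis (4th) concatenation of 5D arrays
abind_ch <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[4], 0)
  out <- array(0, c(d[1:3], sum(cs), d[5]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[4]
    out[, , , (at + 1):(at + cc), ] <- x
    at <- at + cc
  }
  out
}

# Global pooling over the spatial axes of a (X,Y,Z,C,N) array.
# Returns a C x N matrix; for GMP also the flat argmax per (channel, sample).
global_pool_batch <- function(x, mode) {
  d <- dim(x)
  S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  m <- x
  dim(m) <- c(S, C * N)
  if (mode == "GAP") {
    return(list(values = matrix(colMeans(m), C, N), argmax = NULL))
  }
  am <- integer(C * N)
  vals <- numeric(C * N)
  for (j in seq_len(C * N)) {
    am[j] <- which.max(m[, j])
    vals[j] <- m[am[j], j]
  }
  list(values = matrix(vals, C, N), argmax = am)
}

# --- backward ----------------------------------------------------------------

acc_grad <- function(node, name, g) {
  node$grad[[name]] <- node$grad[[name]] + g
  invisible(NULL)
}

nn_backward <- function(node, cache, gy) {
  switch(node$kind,
    seq = {
      for (i in rev(seq_along(node$children)))
        gy <- nn_backward(node$children[[i]], cache[[i]], gy)
      gy
    },
    conv = {
      cfg <- node$cfg
      d <- cache$d; od <- cache$od
      g <- cfg$groups
      N <- d[5]
      backg <- function(x_g, d_g, W, gy_g) {
        dM <- matrix(aperm(gy_g, c(1, 2, 3, 5, 4)), prod(od) * N)
        cols <- cpp_im2col3d(x_g, d_g, cfg$k, cfg$s, cfg$p)
        dW <- crossprod(cols, dM)
        db <- if (cfg$bias) colSums(dM) else NULL
        dcols <- dM %*% t(W)
        gx <- array(cpp_col2im3d(dcols, d_g, cfg$k, cfg$s, cfg$p), d_g)
        list(dW = dW, db = db, gx = gx)
      }
      if (g == 1L) {
        r <- backg(cache$x, d, node$par$W, gy)
        if (node$trainable) {
          acc_grad(node, "W", r$dW)
          if (cfg$bias) acc_grad(node, "b", r$db)
        }
        r$gx
      } else {
        cin_g <- cfg$in_ch %/% g; cout_g <- cfg$out_ch %/% g
        gx <- array(0, d)
        dW <- node$grad$W * 0
        db <- if (cfg$bias) numeric(cfg$out_ch) else NULL
        for (j in seq_len(g)) {
          ic <- ((j - 1) * cin_g + 1):(j * cin_g)
          oc <- ((j - 1) * cout_g + 1):(j * cout_g)
          xi <- cache$x[, , , ic, , drop = FALSE]
          r <- backg(xi, dim(xi), node$par$W[, oc, drop = FALSE],
                     gy[, , , oc, , drop = FALSE])
          dW[, oc] <- r$dW
          if (cfg$bias) db[oc] <- r$db
          gx[, , , ic, ] <- r$gx
        }
        if (node$trainable) {
          acc_grad(node, "W", dW)
          if (cfg$bias) acc_grad(node, "b", db)
        }
        gx
      }
    },
    bn = {
      cfg <- node$cfg
      d <- cache$d
      S <- prod(d[1:3]); C <- d[4]; N <- d[5]; M <- S * N
      gym <- matrix(aperm(gy, c(1, 2, 3, 5, 4)), M, C)
      xhat <- cache$xhat
      dgamma <- colSums(gym * xhat)
      dbeta <- colSums(gym)
      if (node$trainable) {
        acc_grad(node, "gamma", dgamma)
        acc_grad(node, "beta", dbeta)
      }
      dxhat <- gym * rep(node$par$gamma, each = M)
      if (cache$training) {
        t1 <- rep(colSums(dxhat) / M, each = M)
        t2 <- xhat * rep(colSums(dxhat * xhat) / M, each = M)
        dxm <- (dxhat - t1 - t2) * rep(cache$invstd, each = M)
      } else {
        dxm <- dxhat * rep(cache$invstd, each = M)
      }
      aperm(array(dxm, c(d[1:3], N, C)), c(1, 2, 3, 5, 4))
    },
    relu = gy * cache$mask,
    maxpool = {
      gx <- cpp_maxpool3d_bwd(gy, cache$argmax, prod(cache$xd))
      array(gx, cache$xd)
    },
    avgpool = {
      cfg <- node$cfg
      gx <- cpp_dwconv3d_bwd_x(gy, cache$d, cache$W, cfg$k, cfg$s, cfg$p)
      array(gx, cache$d)
    },
    gpool = {
      d <- cache$d
      S <- prod(d[1:3]); C <- d[4]; N <- d[5]
      if (node$cfg$mode == "GAP") {
        gxm <- matrix(0, S, C * N)
        gxm <- gxm + rep(as.numeric(gy) / S, each = S)
      } else {
        gxm <- matrix(0, S, C * N)
        gxm[cbind(cache$argmax, seq_len(C * N))] <- as.numeric(gy)
      }
      array(gxm, d)
    },
    linear = {
      if (node$trainable) {
        acc_grad(node, "W", gy %*% t(cache$x))
        if (node$cfg$bias) acc_grad(node, "b", rowSums(gy))
      }
      t(node$par$W) %*% gy
    },
    residual = {
      g <- if (is.null(cache$mask)) gy else gy * cache$mask
      gxb <- nn_backward(node$children$body, cache$body, g)
      if (!is.null(node$children$downsample)) {
        gxd <- nn_backward(node$children$downsample, cache$down, g)
        gxb + gxd
      } else {
        gxb + g
      }
    },
    concat = {
      chs <- cache$chs
      gx <- NULL
      at <- 0L
      for (i in seq_along(node$children)) {
        gi <- gy[, , , (at + 1):(at + chs[i]), , drop = FALSE]
        at <- at + chs[i]
        gb <- nn_backward(node$children[[i]], cache$caches[[i]], gi)
        gx <- if (is.null(gx)) gb else gx + gb
      }
      gx
    },
    swish = stop("backward through swish not supported (frozen encoders only)"),
    se = stop("backward through squeeze-excitation not supported (frozen encoders only)"),
    stop("no backward for node kind: ", node$kind)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- parameter plumbing ------------------------------------------------------

nn_modules <- function(node) {
  out <- list(node)
  for (ch in node$children)
    if (!is.null(ch)) out <- c(out, nn_modules(ch))
  out
}

nn_param_refs <- function(node, trainable_only = TRUE) {
  refs <- list()
  for (m in nn_modules(node)) {
    if (trainable_only && !m$trainable) next
    for (nm in names(m$par))
      refs[[length(refs) + 1L]] <- list(env = m, name = nm)
  }
  refs
}

nn_zero_grads <- function(node) {
  for (m in nn_modules(node))
    m$grad <- lapply(m$par, function(p) p * 0)
  invisible(NULL)
}

nn_snapshot <- function(node) {
  lapply(nn_modules(node), function(m) list(par = m$par, buf = m$buf))
}

nn_restore <- function(node, snap) {
  mods <- nn_modules(node)
  stopifnot(length(mods) == length(snap))
  for (i in seq_along(mods)) {
    mods[[i]]$par <- snap[[i]]$par
    mods[[i]]$buf <- snap[[i]]$buf
  }
  invisible(NULL)
}

nn_freeze <- function(node) {
  for (m in nn_modules(node)) m$trainable <- FALSE
  invisible(node)
}

nn_checksum <- function(node) {
  sum(vapply(nn_modules(node),
             function(m) sum(vapply(m$par, sum, 0)), 0))
}

#' Count trainable parameters of an encoder or classifier
#'
#' Sums the lengths of every trainable parameter array (convolution and
#' linear weights and biases, batch-norm scale and shift). Frozen modules
#' contribute zero. The count is additive over model components and does not
#' depend on parameter values or input size.
#'
#' @param model An encoder built by one of the `build_*` constructors, an
#'   assembled classifier, or a raw network node.
#' @return Integer: total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  node <- model_root_node(model)
  if (is.list(node) && !inherits(node, "nn_node")) {
    return(sum(vapply(node, count_parameters, 0)))
  }
  tot <- 0
  for (m in nn_modules(node)) {
    if (!m$trainable) next
    tot <- tot + sum(vapply(m$par, length, 0L))
  }
  as.integer(tot)
}

# Resolve the network node(s) inside higher-level wrappers.
model_root_node <- function(model) {
  if (inherits(model, "nn_node")) return(model)
  if (inherits(model, "strokesight_encoder")) return(model$net)
  if (inherits(model, "strokesight_classifier")) {
    parts <- list(model$encoder$net)
    if (!is.null(model$trunk)) parts <- c(parts, list(model$trunk))
    if (!is.null(model$merge_net)) parts <- c(parts, list(model$merge_net))
    if (!is.null(model$attention)) parts <- c(parts, list(model$attention))
    parts <- c(parts, list(model$head))
    return(parts)
  }
  stop("cannot count parameters of an object of class ",
       paste(class(model), collapse = "/"))
}

# --- optimizer ---------------------------------------------------------------

opt_adam <- function(refs, lr, weight_decay = 0, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$refs <- refs
  e$lr <- lr
  e$wd <- weight_decay
  e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L
  e$m <- lapply(refs, function(r) r$env$par[[r$name]] * 0)
  e$v <- lapply(refs, function(r) r$env$par[[r$name]] * 0)
  e
}

opt_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$refs)) {
    r <- opt$refs[[i]]
    g <- r$env$grad[[r$name]]
    if (opt$wd > 0) g <- g + opt$wd * r$env$par[[r$name]]
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    r$env$par[[r$name]] <- r$env$par[[r$name]] -
      opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  invisible(NULL)
}
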