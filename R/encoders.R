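# ---------------------------------------------------------------------------
# Encoder families: the compact custom 3D CNN, the inception-module 3D
# encoder, 3D-ified ResNets, their 2D counterparts and EfficientNets (2D,
# used frozen). Every builder returns a strokesight_encoder with an auditable
# parameter count and output-channel contract.
# ---------------------------------------------------------------------------

ENCODER_FAMILIES <- c("custom3d", "inception3d",
                      "resnet3d-18", "resnet3d-34", "resnet3d-50",
                      "custom2d",
                      "resnet2d-18", "resnet2d-34", "resnet2d-50",
                      "efficientnet2d-b0", "efficientnet2d-b1",
                      "efficientnet2d-b2")

#' Encoder specification
#'
#' @param family Encoder family tag; one of `r paste(ENCODER_FAMILIES, collapse=", ")`.
#' @param in_channels Input channels (1 for CT; 2D ImageNet-style families
#'   conventionally use 3, with single-channel images replicated).
#' @param frozen If `TRUE`, the encoder's parameters are excluded from
#'   optimisation (and from [count_parameters()]).
#' @param pretrained_weights Optional local path to an `.rds` parameter
#'   snapshot previously produced by [encoder_save_weights()]. No implicit
#'   downloading; absent weights mean random initialisation (the test mode).
#' @return A `strokesight_encoder_spec`.
#' @export
encoder_spec <- function(family, in_channels = 1L, frozen = FALSE,
                         pretrained_weights = NULL) {
  if (!family %in% ENCODER_FAMILIES)
    stop("unknown encoder family: ", family)
  structure(list(family = family, in_channels = as.integer(in_channels),
                 frozen = isTRUE(frozen),
                 pretrained_weights = pretrained_weights),
            class = "strokesight_encoder_spec")
}

new_encoder <- function(net, family, ndim, in_channels, out_channels,
                        frozen = FALSE) {
  if (frozen) nn_freeze(net)
  structure(list(net = net, family = family, ndim = ndim,
                 in_channels = in_channels, out_channels = out_channels,
                 frozen = frozen),
            class = "strokesight_encoder")
}

#' @export
print.strokesight_encoder <- function(x, ...) {
  cat(sprintf("<encoder %s: %dD, %d -> %d channels, %s, %s parameters>\n",
              x$family, x$ndim, x$in_channels, x$out_channels,
              if (x$frozen) "frozen" else "trainable",
              format(count_parameters(x$net), big.mark = ",")))
  invisible(x)
}

# kernel/stride/pad helpers that collapse the third axis for planar (2D) nets
kvec <- function(a, planar) if (planar) c(a, a, 1L) else rep(a, 3L)
pvec <- function(a, planar) if (planar) c(a, a, 0L) else rep(a, 3L)

conv_bn_relu <- function(in_ch, out_ch, k, s, p, bias = TRUE) {
  nn_seq(nn_conv(in_ch, out_ch, k, s, p, bias = bias), nn_bn(out_ch), nn_relu())
}

#' Build the compact custom CNN encoder
#'
#' Four convolution blocks with 8, 16, 32 and 64 filters, each a 3x3x3
#' convolution (padding 1) followed by batch normalisation and ReLU, with
#' strides 1, 2, 1, 2. For one input channel the trainable total is about
#' 73 thousand parameters — roughly 445 times fewer than a 3D ResNet-18 —
#' which is the point: CT outcome cohorts are small, and a low-capacity
#' encoder overfits less.
#'
#' @param in_channels Number of input channels (default 1).
#' @param filters Filter counts of the four blocks.
#' @param planar If `TRUE`, builds the 2D counterpart (3x3 kernels) used as
#'   the multiple-instance-learning slice encoder.
#' @return A `strokesight_encoder` with 64 output channels.
#' @export
build_custom_cnn3d <- function(in_channels = 1L, filters = c(8L, 16L, 32L, 64L),
                               planar = FALSE) {
  stopifnot(in_channels >= 1L, length(filters) == 4L)
  strides <- c(1L, 2L, 1L, 2L)
  ch <- c(in_channels, filters)
  blocks <- lapply(1:4, function(i)
    conv_bn_relu(ch[i], ch[i + 1], kvec(3L, planar),
                 if (planar) c(strides[i], strides[i], 1L) else strides[i],
                 pvec(1L, planar)))
  new_encoder(nn_seq(blocks), if (planar) "custom2d" else "custom3d",
              if (planar) 2L else 3L, in_channels, filters[4])
}

# Classic four-branch inception module with 1x1 dimensionality-reduction
# convolutions ahead of the 3^3 and 5^3 branches; each branch emits f
# channels, concatenated to 4f.
inception_module3d <- function(in_ch, f) {
  nn_concat(list(
    nn_seq(nn_conv(in_ch, f, 1L), nn_bn(f), nn_relu()),
    nn_seq(nn_conv(in_ch, f, 1L), nn_bn(f), nn_relu(),
           nn_conv(f, f, 3L, pad = 1L), nn_bn(f), nn_relu()),
    nn_seq(nn_conv(in_ch, f, 1L), nn_bn(f), nn_relu(),
           nn_conv(f, f, 5L, pad = 2L), nn_bn(f), nn_relu()),
    nn_seq(nn_maxpool(3L, stride = 1L, pad = 1L),
           nn_conv(in_ch, f, 1L), nn_bn(f), nn_relu())
  ))
}

#' Build the inception-module 3D encoder
#'
#' Four stacked 3D inception modules; each module runs parallel 1x1x1, 3x3x3
#' and 5x5x5 convolution branches (the latter two behind 1x1x1 reduction
#' convolutions, the classic design) plus a max-pool projection branch, all
#' with the same filter count and batch norm + ReLU per convolution, and
#' concatenates them, so the module output has four times its per-branch
#' filters. A
#' stride-2 average pool after the first module halves the spatial extent
#' once; the modules themselves preserve resolution. The default filter
#' allocation `c(4, 16, 16, 16)` keeps the computation manageable on
#' 91x109x91 grids.
#'
#' @param filters_per_im Per-branch filters of the four modules.
#' @param in_channels Input channels.
#' @return A `strokesight_encoder` with `4 * filters_per_im[4]` output
#'   channels (64 by default).
#' @export
build_inception_encoder3d <- function(filters_per_im = c(4L, 16L, 16L, 16L),
                                      in_channels = 1L) {
  if (length(filters_per_im) != 4L || any(filters_per_im <= 0))
    stop("filters_per_im must be four positive filter counts")
  f <- as.integer(filters_per_im)
  net <- nn_seq(
    inception_module3d(in_channels, f[1]),
    nn_avgpool(2L, stride = 2L),
    inception_module3d(4L * f[1], f[2]),
    inception_module3d(4L * f[2], f[3]),
    inception_module3d(4L * f[3], f[4])
  )
  new_encoder(net, "inception3d", 3L, in_channels, 4L * f[4])
}

basic_block <- function(in_ch, out_ch, stride, planar) {
  body <- nn_seq(
    nn_conv(in_ch, out_ch, kvec(3L, planar), c(stride, stride, if (planar) 1L else stride),
            pvec(1L, planar), bias = FALSE),
    nn_bn(out_ch), nn_relu(),
    nn_conv(out_ch, out_ch, kvec(3L, planar), 1L, pvec(1L, planar), bias = FALSE),
    nn_bn(out_ch))
  ds <- NULL
  if (stride != 1L || in_ch != out_ch)
    ds <- nn_seq(nn_conv(in_ch, out_ch, 1L,
                         c(stride, stride, if (planar) 1L else stride),
                         bias = FALSE),
                 nn_bn(out_ch))
  nn_residual(body, ds)
}

bottleneck_block <- function(in_ch, mid_ch, stride, planar) {
  out_ch <- mid_ch * 4L
  body <- nn_seq(
    nn_conv(in_ch, mid_ch, 1L, bias = FALSE), nn_bn(mid_ch), nn_relu(),
    nn_conv(mid_ch, mid_ch, kvec(3L, planar),
            c(stride, stride, if (planar) 1L else stride),
            pvec(1L, planar), bias = FALSE),
    nn_bn(mid_ch), nn_relu(),
    nn_conv(mid_ch, out_ch, 1L, bias = FALSE), nn_bn(out_ch))
  ds <- NULL
  if (stride != 1L || in_ch != out_ch)
    ds <- nn_seq(nn_conv(in_ch, out_ch, 1L,
                         c(stride, stride, if (planar) 1L else stride),
                         bias = FALSE),
                 nn_bn(out_ch))
  nn_residual(body, ds)
}

build_resnet <- function(depth, in_channels, planar) {
  cfgs <- list(`18` = list(reps = c(2, 2, 2, 2), bottleneck = FALSE),
               `34` = list(reps = c(3, 4, 6, 3), bottleneck = FALSE),
               `50` = list(reps = c(3, 4, 6, 3), bottleneck = TRUE))
  key <- as.character(depth)
  if (!key %in% names(cfgs)) stop("unsupported ResNet depth: ", depth)
  cfg <- cfgs[[key]]
  layers <- list(
    nn_conv(in_channels, 64L, kvec(7L, planar),
            c(2L, 2L, if (planar) 1L else 2L), pvec(3L, planar), bias = FALSE),
    nn_bn(64L), nn_relu(),
    nn_maxpool(kvec(3L, planar), c(2L, 2L, if (planar) 1L else 2L),
               pvec(1L, planar)))
  chans <- c(64L, 128L, 256L, 512L)
  in_ch <- 64L
  for (s in 1:4) {
    stride <- if (s == 1L) 1L else 2L
    for (b in seq_len(cfg$reps[s])) {
      if (cfg$bottleneck) {
        layers[[length(layers) + 1L]] <-
          bottleneck_block(in_ch, chans[s], if (b == 1L) stride else 1L, planar)
        in_ch <- chans[s] * 4L
      } else {
        layers[[length(layers) + 1L]] <-
          basic_block(in_ch, chans[s], if (b == 1L) stride else 1L, planar)
        in_ch <- chans[s]
      }
    }
  }
  net <- nn_seq(layers)
  new_encoder(net, sprintf("resnet%dd-%d", if (planar) 2L else 3L, depth),
              if (planar) 2L else 3L, in_channels, in_ch)
}

#' Build a 3D ResNet encoder
#'
#' The standard residual topology with every 2D operator replaced by its 3D
#' equivalent: a 7x7x7 stride-2 stem, 3x3x3 stride-2 max pool, and four
#' residual stages with stride-2 transitions (basic blocks for depths 18/34,
#' bottlenecks for 50). A 91x109x91 input is reduced to a 3x4x3 feature map
#' by the end of the encoder; final channels are 512 (18/34) or 2048 (50).
#'
#' @param depth 18, 34 or 50.
#' @param in_channels Input channels (default 1).
#' @return A `strokesight_encoder`.
#' @export
build_resnet3d <- function(depth = 18L, in_channels = 1L) {
  build_resnet(depth, in_channels, planar = FALSE)
}

# --- EfficientNet (2D, used frozen) -----------------------------------------

round_filters <- function(f, wmult, divisor = 8L) {
  f <- f * wmult
  new_f <- max(divisor, as.integer(f + divisor / 2) %/% divisor * divisor)
  if (new_f < 0.9 * f) new_f <- new_f + divisor
  as.integer(new_f)
}

round_repeats <- function(r, dmult) as.integer(ceiling(r * dmult))

mbconv <- function(in_ch, out_ch, expand, k, stride, se_ratio = 0.25) {
  mid <- in_ch * expand
  layers <- list()
  if (expand != 1L)
    layers <- c(layers, list(nn_conv(in_ch, mid, 1L, bias = FALSE),
                             nn_bn(mid), nn_swish()))
  layers <- c(layers, list(
    nn_dwconv(mid, c(k, k, 1L), c(stride, stride, 1L), c((k - 1L) %/% 2L, (k - 1L) %/% 2L, 0L)),
    nn_bn(mid), nn_swish(),
    nn_se(mid, max(1L, as.integer(in_ch * se_ratio))),
    nn_conv(mid, out_ch, 1L, bias = FALSE), nn_bn(out_ch)))
  body <- nn_seq(layers)
  if (stride == 1L && in_ch == out_ch) {
    blk <- nn_node("residual", children = list(body = body, downsample = NULL))
    blk$cfg$activation <- "none"
    blk
  } else body
}

build_efficientnet2d <- function(variant, in_channels = 3L) {
  mults <- list(b0 = c(1.0, 1.0), b1 = c(1.0, 1.1), b2 = c(1.1, 1.2))
  if (!variant %in% names(mults)) stop("unsupported EfficientNet variant: ", variant)
  wm <- mults[[variant]][1]; dm <- mults[[variant]][2]
  stages <- list(  # expand, kernel, stride, out, repeats
    c(1, 3, 1, 16, 1), c(6, 3, 2, 24, 2), c(6, 5, 2, 40, 2),
    c(6, 3, 2, 80, 3), c(6, 5, 1, 112, 3), c(6, 5, 2, 192, 4),
    c(6, 3, 1, 320, 1))
  stem_ch <- round_filters(32L, wm)
  layers <- list(nn_conv(in_channels, stem_ch, c(3L, 3L, 1L), c(2L, 2L, 1L),
                         c(1L, 1L, 0L), bias = FALSE),
                 nn_bn(stem_ch), nn_swish())
  in_ch <- stem_ch
  for (st in stages) {
    out_ch <- round_filters(st[4], wm)
    reps <- round_repeats(st[5], dm)
    for (r in seq_len(reps)) {
      layers[[length(layers) + 1L]] <-
        mbconv(in_ch, out_ch, as.integer(st[1]), as.integer(st[2]),
               if (r == 1L) as.integer(st[3]) else 1L)
      in_ch <- out_ch
    }
  }
  head_ch <- round_filters(1280L, wm)
  layers <- c(layers, list(nn_conv(in_ch, head_ch, 1L, bias = FALSE),
                           nn_bn(head_ch), nn_swish()))
  new_encoder(nn_seq(layers), paste0("efficientnet2d-", variant), 2L,
              in_channels, head_ch)
}

#' Build a 2D encoder from a specification
#'
#' Constructs the 2D slice/MIP encoders: the compact custom CNN, planar
#' ResNets 18/34/50, or EfficientNets B0/B1/B2. When
#' `spec$pretrained_weights` names a local snapshot it is loaded; otherwise
#' weights are randomly initialised (with `spec$frozen = TRUE` that gives the
#' random-frozen test mode — no downloads are ever attempted). Frozen
#' encoders never change during optimisation; single-channel images are
#' replicated to the encoder's expected channel count at the classifier
#' level.
#'
#' @param spec An [encoder_spec()] with a 2D family.
#' @return A `strokesight_encoder`.
#' @export
build_2d_encoder <- function(spec) {
  if (!inherits(spec, "strokesight_encoder_spec")) stop("spec must be an encoder_spec()")
  fam <- spec$family
  enc <- if (fam == "custom2d") {
    build_custom_cnn3d(spec$in_channels, planar = TRUE)
  } else if (grepl("^resnet2d-", fam)) {
    build_resnet(as.integer(sub("resnet2d-", "", fam)), spec$in_channels,
                 planar = TRUE)
  } else if (grepl("^efficientnet2d-", fam)) {
    build_efficientnet2d(sub("efficientnet2d-", "", fam), spec$in_channels)
  } else {
    stop("not a 2D encoder family: ", fam)
  }
  if (!is.null(spec$pretrained_weights))
    nn_restore(enc$net, readRDS(spec$pretrained_weights))
  if (spec$frozen) {
    nn_freeze(enc$net)
    enc$frozen <- TRUE
  }
  enc
}

#' Save or load encoder weights
#'
#' Weight files are plain parameter snapshots on a local path; nothing is
#' downloaded. `encoder_save_weights()` writes, [build_2d_encoder()] reloads
#' via `encoder_spec(pretrained_weights = path)`.
#'
#' @param encoder A `strokesight_encoder`.
#' @param path Destination `.rds` path.
#' @return `path`, invisibly.
#' @export
encoder_save_weights <- function(encoder, path) {
  saveRDS(nn_snapshot(encoder$net), path)
  invisible(path)
}

#' Run an encoder forward
#'
#' @param encoder A `strokesight_encoder`.
#' @param x A 5D array (X, Y, Z, C, N); 2D encoders take Z = 1. Single-channel
#'   input is replicated to the encoder's expected channel count.
#' @param training Batch-norm mode (ignored for frozen encoders, which always
#'   run in inference mode).
#' @return Feature-map array (X', Y', Z', C', N).
#' @export
encoder_forward <- function(encoder, x, training = FALSE) {
  d <- dim(x)
  if (d[4] == 1L && encoder$in_channels > 1L) {
    x2 <- array(0, c(d[1:3], encoder$in_channels, d[5]))
    for (cc in seq_len(encoder$in_channels)) x2[, , , cc, ] <- x[, , , 1L, ]
    x <- x2
  }
  nn_forward(encoder$net, x, training = training && !encoder$frozen)$y
}
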