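# Structural blocks: the stem, the channel-expansion residual (CER) block,
# and the bidirectional information fusion (BIF) head.

#' Configuration of a channel-expansion residual block
#'
#' The CER block triples the channel count of its input without spending any
#' learnable parameters on the expansion itself: three parallel max-pooling
#' branches with different windows (default 3/5/9, stride 2, paddings chosen
#' so all branches agree spatially) are concatenated along channels. An
#' aggregation path (1x1 -> 3x3 -> 1x1 convolutions at the expanded width,
#' each followed by batch norm) refines the concatenation, and a strided 1x1
#' projection of the block input provides the residual shortcut.
#'
#' @param in_channels Positive integer channel count of the block input.
#' @param pool_windows Integer triple of odd pooling window sizes
#'   (default `c(3, 5, 9)`).
#' @param stride Stride of the pooling branches and the residual projection
#'   (default 2, halving the spatial dimensions).
#' @param use_batchnorm Logical; include batch normalisation after each
#'   convolution (default `TRUE`).
#' @return An object of class `cer_config`.
#' @export
cer_config <- function(in_channels, pool_windows = c(3L, 5L, 9L),
                       stride = 2L, use_batchnorm = TRUE) {
  in_channels <- as.integer(in_channels)
  stopifnot(length(in_channels) == 1L, in_channels >= 1L,
            length(pool_windows) == 3L)
  pool_windows <- as.integer(pool_windows)
  if (any(pool_windows %% 2L == 0L)) stop("pool windows must be odd")
  structure(list(in_channels = in_channels,
                 pool_windows = pool_windows,
                 stride = as.integer(stride),
                 use_batchnorm = isTRUE(use_batchnorm),
                 out_channels = 3L * in_channels),
            class = "cer_config")
}

conv_bn <- function(in_ch, out_ch, k, stride, pad, use_bn, relu = TRUE) {
  mods <- list(nn_conv2d(in_ch, out_ch, k, stride, pad, bias = !use_bn))
  if (use_bn) mods <- c(mods, list(nn_batchnorm2d(out_ch)))
  if (relu) mods <- c(mods, list(nn_relu()))
  mods
}

# ---- stem ---------------------------------------------------------------

nn_stem <- function(stem_width, use_bn = TRUE) {
  seq <- nn_sequential(c(
    conv_bn(3L, stem_width, 7L, 2L, 3L, use_bn, relu = TRUE),
    list(nn_maxpool2d(3L, 2L, 1L))
  ))
  m <- new_module("stem", children = list(seq = seq))
  m$stem_width <- as.integer(stem_width)
  m$fwd <- function(self, x, train) {
    d <- dim(x)
    if (d[3] != 3L) {
      stop(sprintf("stem expects a 3-channel input, received %d channels",
                   d[3]))
    }
    if (d[1] %% 4L != 0L || d[2] %% 4L != 0L) {
      stop("stem input height and width must be divisible by 4")
    }
    nn_forward(self$children$seq, x, train)
  }
  m$bwd <- function(self, gy) nn_backward(self$children$seq, gy)
  m
}

#' Stem forward pass
#'
#' A 7x7 convolution (stride 2, padding 3, 3 -> `stem_width` channels, batch
#' norm + ReLU) followed by a 3x3 max pool (stride 2, padding 1); the spatial
#' dimensions are quartered.
#'
#' @param image A feature map of shape (3, H, W) with H and W divisible by 4.
#' @param stem_width Output channel count of the stem convolution.
#' @param block Optionally a prebuilt stem module.
#' @param seed Optional integer seed for weight initialisation.
#' @return A feature map of shape (`stem_width`, H/4, W/4).
#' @export
stem_forward <- function(image, stem_width = 16L, block = NULL, seed = NULL) {
  x <- fm_to_hwcn(image)
  if (is.null(block)) block <- with_seed(seed, nn_stem(stem_width))
  hwcn_to_fm(nn_forward(block, x, train = FALSE))
}

# ---- CER block ----------------------------------------------------------

nn_cer <- function(config) {
  stopifnot(inherits(config, "cer_config"))
  C <- config$in_channels
  C3 <- config$out_channels
  s <- config$stride
  bn <- config$use_batchnorm
  pools <- lapply(config$pool_windows, function(k) {
    nn_maxpool2d(k, s, (k - 1L) %/% 2L)
  })
  names(pools) <- paste0("pool", config$pool_windows)
  agg <- nn_sequential(c(
    conv_bn(C3, C3, 1L, 1L, 0L, bn, relu = TRUE),
    conv_bn(C3, C3, 3L, 1L, 1L, bn, relu = TRUE),
    conv_bn(C3, C3, 1L, 1L, 0L, bn, relu = FALSE)
  ))
  shortcut <- nn_sequential(conv_bn(C, C3, 1L, s, 0L, bn, relu = FALSE))
  m <- new_module("cer", children = c(pools, list(agg = agg,
                                                  shortcut = shortcut)))
  m$config <- config

  m$fwd <- function(self, x, train) {
    d <- dim(x)
    cfg <- self$config
    if (d[3] != cfg$in_channels) {
      stop(sprintf("cer block expected %d channels, received %d",
                   cfg$in_channels, d[3]))
    }
    if (d[1] < cfg$stride || d[2] < cfg$stride) {
      stop("spatial dimensions too small for the strided pooling branches")
    }
    pooled <- lapply(self$children[1:3], function(p) nn_forward(p, x, train))
    sp <- vapply(pooled, function(p) dim(p)[1:2], numeric(2))
    if (any(sp != sp[, 1])) stop("pooling branches disagree spatially")
    pc <- cat_channels(pooled)
    a <- nn_forward(self$children$agg, pc, train)
    r <- nn_forward(self$children$shortcut, x, train)
    y <- pmax(a + r, 0)
    self$cache <- list(mask = (a + r) > 0)
    y
  }

  m$bwd <- function(self, gy) {
    g <- gy * self$cache$mask
    gx <- nn_backward(self$children$shortcut, g)
    gp <- nn_backward(self$children$agg, g)
    C <- self$config$in_channels
    parts <- split_channels(gp, rep(C, 3L))
    for (i in 1:3) {
      gx <- gx + nn_backward(self$children[[i]], parts[[i]])
    }
    gx
  }
  m
}

#' Channel-expansion residual block forward pass
#'
#' @param F A feature map of shape (C, H, W) with `C == config$in_channels`.
#' @param config A [cer_config()] object.
#' @param block Optionally a prebuilt CER module.
#' @param seed Optional integer seed for weight initialisation.
#' @return A feature map of shape (3C, floor(H/2), floor(W/2)).
#' @export
cer_forward <- function(F, config = cer_config(dim(F)[1]), block = NULL,
                        seed = NULL) {
  x <- fm_to_hwcn(F)
  if (is.null(block)) block <- with_seed(seed, nn_cer(config))
  hwcn_to_fm(nn_forward(block, x, train = FALSE))
}

#' Learnable parameters in the channel-expansion stage of a CER block
#'
#' The expansion stage - three max-pooling branches and the channel
#' concatenation - contains no learnable parameters for any configuration;
#' the tripling of channels is free. Use [cer_param_count()] for the full
#' block.
#'
#' @param config A [cer_config()] object.
#' @return `0L`, always.
#' @export
cer_expansion_param_count <- function(config) {
  stopifnot(inherits(config, "cer_config"))
  0L
}

#' Total learnable parameters of a CER block
#'
#' @param config A [cer_config()] object.
#' @return Integer count over the aggregation convolutions, the residual
#'   projection and (if enabled) the batch-norm scale/shift pairs.
#' @export
cer_param_count <- function(config) {
  block <- with_seed(1L, nn_cer(config))
  as.integer(nn_n_params(block))
}

# ---- BIF block ----------------------------------------------------------

#' Configuration of the bidirectional information fusion block
#'
#' The BIF head fuses the two deepest stage outputs: the deep map `P3`
#' (shape C3 x h x w) is upsampled by 2 and concatenated with the mid-level
#' map `P2` (shape C2 x 2h x 2w); the merge is downsampled by a 3x3 stride-2
#' max pool and concatenated with `P3` again; a trailing 1x1 convolution
#' (+ batch norm + ReLU) expands the result to `out_channels`
#' (default 3 * C3).
#'
#' @param mid_channels Channel count C2 of the shallower input.
#' @param deep_channels Channel count C3 of the deeper input.
#' @param out_channels Output channel count; default `3 * deep_channels`.
#' @param upsample_mode `"nearest"` (default) or `"bilinear"`.
#' @param use_batchnorm Logical; default `TRUE`.
#' @return An object of class `bif_config`.
#' @export
bif_config <- function(mid_channels, deep_channels,
                       out_channels = 3L * deep_channels,
                       upsample_mode = c("nearest", "bilinear"),
                       use_batchnorm = TRUE) {
  upsample_mode <- match.arg(upsample_mode)
  mid_channels <- as.integer(mid_channels)
  deep_channels <- as.integer(deep_channels)
  out_channels <- as.integer(out_channels)
  stopifnot(mid_channels >= 1L, deep_channels >= 1L)
  if (out_channels < deep_channels) {
    stop("out_channels must be at least deep_channels")
  }
  structure(list(mid_channels = mid_channels,
                 deep_channels = deep_channels,
                 out_channels = out_channels,
                 upsample_mode = upsample_mode,
                 use_batchnorm = isTRUE(use_batchnorm)),
            class = "bif_config")
}

nn_bif <- function(config) {
  stopifnot(inherits(config, "bif_config"))
  C2 <- config$mid_channels
  C3 <- config$deep_channels
  mix <- nn_sequential(conv_bn(C2 + 2L * C3, config$out_channels, 1L, 1L, 0L,
                               config$use_batchnorm, relu = TRUE))
  m <- new_module("bif", children = list(
    up = nn_upsample2(config$upsample_mode),
    pool = nn_maxpool2d(3L, 2L, 1L),
    mix = mix
  ))
  m$config <- config

  m$fwd <- function(self, inputs, train) {
    cfg <- self$config
    p2 <- inputs$p2
    p3 <- inputs$p3
    d2 <- dim(p2)
    d3 <- dim(p3)
    if (d2[3] != cfg$mid_channels || d3[3] != cfg$deep_channels) {
      stop(sprintf(
        "bif block expected %d/%d mid/deep channels, received %d/%d",
        cfg$mid_channels, cfg$deep_channels, d2[3], d3[3]))
    }
    if (any(d2[1:2] != 2L * d3[1:2])) {
      stop("the mid-level input must have exactly twice the spatial size of the deep input")
    }
    U <- nn_forward(self$children$up, p3, train)
    M <- cat_channels(list(U, p2))
    D <- nn_forward(self$children$pool, M, train)
    E <- cat_channels(list(D, p3))
    y <- nn_forward(self$children$mix, E, train)
    self$cache <- list(d2 = d2, d3 = d3)
    y
  }

  m$bwd <- function(self, gy) {
    cfg <- self$config
    gE <- nn_backward(self$children$mix, gy)
    parts <- split_channels(gE, c(cfg$deep_channels + cfg$mid_channels,
                                  cfg$deep_channels))
    gM <- nn_backward(self$children$pool, parts[[1]])
    mparts <- split_channels(gM, c(cfg$deep_channels, cfg$mid_channels))
    g3 <- nn_backward(self$children$up, mparts[[1]]) + parts[[2]]
    list(p2 = mparts[[2]], p3 = g3)
  }
  m
}

#' Bidirectional information fusion forward pass
#'
#' @param P2 Mid-level feature map of shape (C2, 2h, 2w).
#' @param P3 Deep feature map of shape (C3, h, w).
#' @param config A [bif_config()] object; defaults to the channel counts of
#'   the supplied maps with `out_channels = 3 * C3`.
#' @param block Optionally a prebuilt BIF module.
#' @param seed Optional integer seed for weight initialisation.
#' @return A feature map of shape (`config$out_channels`, h, w).
#' @export
bif_forward <- function(P2, P3,
                        config = bif_config(dim(P2)[1], dim(P3)[1]),
                        block = NULL, seed = NULL) {
  x2 <- fm_to_hwcn(P2)
  x3 <- fm_to_hwcn(P3)
  if (is.null(block)) block <- with_seed(seed, nn_bif(config))
  hwcn_to_fm(nn_forward(block, list(p2 = x2, p3 = x3), train = FALSE))
}
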