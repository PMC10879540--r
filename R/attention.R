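# Adaptive channel attention: the kernel size of the two 1D convolutions in
# the channel-attention branch is derived from the channel count through the
# inverse Gaussian probability density function, so wider feature maps get
# narrower kernels without any manual tuning.

#' Parameters of the inverse-Gaussian kernel-size rule
#'
#' The channel-attention branch summarises a feature map into one scalar per
#' channel and passes the descriptor through two 1D convolutions whose kernel
#' size adapts to the channel count `C`. The rule treats the normalised
#' channel count `y = C / channel_normalizer` as the value of a Gaussian
#' density and inverts the density to recover the abscissa:
#' `x = sqrt(-2 * sigma^2 * ln(y * sigma * sqrt(2*pi))) + mu`,
#' which is then rounded to the nearest odd integer (ties away from zero)
#' and floored at 1.
#'
#' @param mu Mean offset of the Gaussian, in kernel-size units. Default 0.
#' @param sigma Standard-deviation parameter of the Gaussian; must be
#'   positive. Default 1.
#' @param channel_normalizer Positive divisor mapping a raw channel count to
#'   the density argument `y`. Default 2048, so every channel width up to
#'   `2048 / (sigma * sqrt(2*pi))` (about 817 at the defaults) is inside the
#'   domain of the logarithm.
#' @return An object of class `igpdf_params`.
#' @examples
#' p <- igpdf_params()
#' igpdf_kernel_size(48, p)   # 3
#' igpdf_kernel_size(432, p)  # 1
#' @export
igpdf_params <- function(mu = 0, sigma = 1, channel_normalizer = 2048) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a positive number")
  }
  if (!is.numeric(channel_normalizer) || length(channel_normalizer) != 1L ||
      !is.finite(channel_normalizer) || channel_normalizer <= 0) {
    stop("channel_normalizer must be a positive number")
  }
  structure(list(mu = mu, sigma = sigma,
                 channel_normalizer = channel_normalizer),
            class = "igpdf_params")
}

round_to_odd <- function(x) {
  # nearest odd integer, ties away from zero (x >= 0 here)
  2 * floor((x - 1) / 2 + 0.5) + 1
}

#' Adaptive 1D-convolution kernel size from a channel count
#'
#' Inverts the Gaussian probability density at `y = C / channel_normalizer`
#' to obtain a kernel size, rounded to the nearest odd integer (ties away
#' from zero) and floored at 1. The rule is non-increasing in the channel
#' count: wider maps receive narrower kernels.
#'
#' @param channel_count Positive integer channel count.
#' @param params An [igpdf_params()] object.
#' @return An odd integer kernel size, at least 1.
#' @examples
#' igpdf_kernel_size(48, igpdf_params())  # 3
#' @export
igpdf_kernel_size <- function(channel_count, params = igpdf_params()) {
  x <- igpdf_x(channel_count, params)
  max(1L, as.integer(round_to_odd(x)))
}

# Continuous abscissa of the inverted Gaussian density, before rounding.
igpdf_x <- function(channel_count, params = igpdf_params()) {
  stopifnot(inherits(params, "igpdf_params"))
  if (!is.numeric(channel_count) || length(channel_count) != 1L ||
      !is.finite(channel_count) || channel_count < 1 ||
      channel_count != round(channel_count)) {
    stop("channel_count must be a positive integer")
  }
  y <- channel_count / params$channel_normalizer
  a <- y * params$sigma * sqrt(2 * pi)
  if (a > 1 + 1e-12) {
    stop(sprintf(paste0("channel count %d is outside the valid domain: ",
                        "y * sigma * sqrt(2*pi) = %.6f > 1; increase ",
                        "channel_normalizer or decrease sigma"),
                 as.integer(channel_count), a))
  }
  a <- min(a, 1)
  sqrt(-2 * params$sigma^2 * log(a)) + params$mu
}

# ---- channel descriptors ------------------------------------------------

# Global average and max pooled per-channel descriptors of a (H,W,C,N)
# tensor, plus the spatial argmax needed for the max-pool backward.
channel_descriptors <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(hw, d[3] * d[4])
  avg <- matrix(colMeans(xm), d[3], d[4])
  tx <- t(xm)
  amx <- max.col(tx, ties.method = "first")
  mx <- matrix(tx[cbind(seq_len(nrow(tx)), amx)], d[3], d[4])
  list(avg = avg, max = mx, argmax = amx, hw = hw)
}

# ---- channel attention (shared 1D conv pair) ---------------------------

# Channel gate: both pooled descriptors run through the same two 1D
# convolutions (single lane, same-padding, ReLU between), are summed, and
# squashed with a sigmoid. Weight sharing across the avg/max branches means
# the branch caches are kept here rather than in child modules.
nn_channel_attention <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k %% 2L == 1L)
  par <- list(w1 = stats::rnorm(k, sd = sqrt(2 / k)), b1 = 0,
              w2 = stats::rnorm(k, sd = sqrt(2 / k)), b2 = 0)
  m <- new_module("channel_attention", par)
  m$k <- k

  conv1d_fwd <- function(w, b, x, p) {
    C <- nrow(x)
    xp <- rbind(matrix(0, p, ncol(x)), x, matrix(0, p, ncol(x)))
    z <- matrix(b, C, ncol(x))
    for (j in seq_along(w)) {
      z <- z + w[j] * xp[j + seq_len(C) - 1L, , drop = FALSE]
    }
    z
  }
  conv1d_bwd <- function(w, x, p, gz) {
    C <- nrow(x)
    xp <- rbind(matrix(0, p, ncol(x)), x, matrix(0, p, ncol(x)))
    gw <- vapply(seq_along(w), function(j) {
      sum(xp[j + seq_len(C) - 1L, , drop = FALSE] * gz)
    }, numeric(1))
    gxp <- matrix(0, nrow(xp), ncol(xp))
    for (j in seq_along(w)) {
      rows <- j + seq_len(C) - 1L
      gxp[rows, ] <- gxp[rows, ] + w[j] * gz
    }
    list(gw = gw, gb = sum(gz), gx = gxp[p + seq_len(C), , drop = FALSE])
  }

  m$fwd <- function(self, x, train) {
    if (dim(x)[3] < 1L) stop("feature map must have at least one channel")
    p <- (self$k - 1L) %/% 2L
    dsc <- channel_descriptors(x)
    br <- lapply(list(avg = dsc$avg, max = dsc$max), function(dd) {
      z1 <- conv1d_fwd(self$par$w1, self$par$b1, dd, p)
      r1 <- pmax(z1, 0)
      z2 <- conv1d_fwd(self$par$w2, self$par$b2, r1, p)
      list(d = dd, z1 = z1, r1 = r1, z2 = z2)
    })
    s <- br$avg$z2 + br$max$z2
    w <- 1 / (1 + exp(-s))
    self$cache <- list(dsc = dsc, br = br, w = w, p = p, d = dim(x))
    w                                       # (C, N)
  }

  # gw: gradient w.r.t. the (C,N) weight vector; returns gradient w.r.t. x.
  m$bwd <- function(self, gw) {
    cc <- self$cache
    p <- cc$p
    gs <- gw * cc$w * (1 - cc$w)
    gd <- list()
    for (nm in c("avg", "max")) {
      b <- cc$br[[nm]]
      o2 <- conv1d_bwd(self$par$w2, b$r1, p, gs)
      self$grad$w2 <- self$grad$w2 + o2$gw
      self$grad$b2 <- self$grad$b2 + o2$gb
      gz1 <- o2$gx * (b$z1 > 0)
      o1 <- conv1d_bwd(self$par$w1, b$d, p, gz1)
      self$grad$w1 <- self$grad$w1 + o1$gw
      self$grad$b1 <- self$grad$b1 + o1$gb
      gd[[nm]] <- o1$gx
    }
    d <- cc$d
    hw <- cc$dsc$hw
    gx <- array(rep(as.vector(gd$avg), each = hw) / hw, d)
    gxv <- as.vector(gx)
    q <- seq_along(cc$dsc$argmax)
    idx <- cc$dsc$argmax + (q - 1L) * hw
    gxv[idx] <- gxv[idx] + as.vector(gd$max)
    array(gxv, d)
  }
  m
}

# ---- spatial attention --------------------------------------------------

# Spatial gate: channel-wise mean and max maps stacked into two channels,
# one 7x7 convolution down to a single channel, then a sigmoid.
nn_spatial_attention <- function(kernel = 7L) {
  conv <- nn_conv2d(2L, 1L, kernel, stride = 1L, pad = (kernel - 1L) %/% 2L,
                    bias = TRUE)
  m <- new_module("spatial_attention", children = list(conv = conv))

  m$fwd <- function(self, x, train) {
    d <- dim(x)
    if (d[1] < 1L || d[2] < 1L) stop("spatial dimensions must be at least 1")
    hwn <- d[1] * d[2] * d[4]
    xm <- aperm(x, c(1L, 2L, 4L, 3L))
    dim(xm) <- c(hwn, d[3])
    mn <- rowMeans(xm)
    amc <- max.col(xm, ties.method = "first")
    mx <- xm[cbind(seq_len(hwn), amc)]
    S <- array(0, c(d[1], d[2], 2L, d[4]))
    S[, , 1L, ] <- array(mn, c(d[1], d[2], d[4]))
    S[, , 2L, ] <- array(mx, c(d[1], d[2], d[4]))
    z <- nn_forward(self$children$conv, S, train)
    y <- 1 / (1 + exp(-z))
    self$cache <- list(d = d, amc = amc, y = y)
    y                                       # (H, W, 1, N)
  }

  m$bwd <- function(self, gy) {
    cc <- self$cache
    d <- cc$d
    gz <- gy * cc$y * (1 - cc$y)
    gS <- nn_backward(self$children$conv, gz)
    gmn <- as.vector(gS[, , 1L, ])
    gmx <- as.vector(gS[, , 2L, ])
    hwn <- d[1] * d[2] * d[4]
    gxp <- matrix(rep(gmn / d[3], times = d[3]), hwn, d[3])
    idx <- cbind(seq_len(hwn), cc$amc)
    gxp[idx] <- gxp[idx] + gmx
    gxa <- array(gxp, c(d[1], d[2], d[4], d[3]))
    aperm(gxa, c(1L, 2L, 4L, 3L))
  }
  m
}

# ---- ACA block ----------------------------------------------------------

# Adaptive channel attention block with a residual shortcut. Default
# (multiplicative) composition gates the input by the channel weights, then
# by the spatial map computed from the gated tensor, and adds the input
# back: F' = F + M_S(w * F) * (w * F). The additive mode broadcasts the
# channel weights and the spatial map (computed on F itself) onto F.
nn_aca <- function(in_ch, igpdf = igpdf_params(),
                   combination = c("multiplicative", "additive")) {
  combination <- match.arg(combination)
  k <- igpdf_kernel_size(in_ch, igpdf)
  m <- new_module("aca",
                  children = list(ca = nn_channel_attention(k),
                                  sa = nn_spatial_attention()))
  m$in_ch <- as.integer(in_ch)
  m$kernel_size <- k
  m$combination <- combination

  m$fwd <- function(self, x, train) {
    d <- dim(x)
    if (d[3] != self$in_ch) {
      stop(sprintf("aca block expected %d channels, received %d",
                   self$in_ch, d[3]))
    }
    w <- nn_forward(self$children$ca, x, train)
    if (self$combination == "multiplicative") {
      Fc <- x * bc_channel(w, d)
      s <- nn_forward(self$children$sa, Fc, train)
      y <- x + bc_spatial(s, d) * Fc
      self$cache <- list(d = d, x = x, w = w, Fc = Fc, s = s)
    } else {
      s <- nn_forward(self$children$sa, x, train)
      y <- x + bc_channel(w, d) + bc_spatial(s, d)
      self$cache <- list(d = d)
    }
    y
  }

  m$bwd <- function(self, gy) {
    cc <- self$cache
    d <- cc$d
    if (self$combination == "multiplicative") {
      ds <- sum_channels(gy * cc$Fc)
      dFc <- gy * bc_spatial(cc$s, d)
      dFc <- dFc + nn_backward(self$children$sa, ds)
      dw <- sum_spatial(dFc * cc$x)
      gx <- gy + dFc * bc_channel(cc$w, d)
      gx + nn_backward(self$children$ca, dw)
    } else {
      gx <- gy +
        nn_backward(self$children$ca, sum_spatial(gy)) +
        nn_backward(self$children$sa, sum_channels(gy))
      gx
    }
  }
  m
}

# ---- CBAM baseline ------------------------------------------------------

# Standard convolutional block attention: a shared two-layer perceptron
# (C -> C/r -> C) on the pooled descriptors for the channel gate, then the
# 7x7 spatial gate, applied sequentially and multiplicatively. Used as the
# ablation baseline; no residual shortcut.
nn_cbam <- function(in_ch, reduction = 16L) {
  in_ch <- as.integer(in_ch)
  reduction <- as.integer(reduction)
  if (in_ch %% reduction != 0L) {
    stop(sprintf("channel count %d is not divisible by reduction ratio %d",
                 in_ch, reduction))
  }
  hid <- in_ch %/% reduction
  par <- list(W1 = matrix(stats::rnorm(hid * in_ch, sd = sqrt(2 / in_ch)),
                          hid, in_ch),
              b1 = numeric(hid),
              W2 = matrix(stats::rnorm(in_ch * hid, sd = sqrt(2 / hid)),
                          in_ch, hid),
              b2 = numeric(in_ch))
  m <- new_module("cbam", par,
                  children = list(sa = nn_spatial_attention()))
  m$in_ch <- in_ch
  m$reduction <- reduction

  m$fwd <- function(self, x, train) {
    d <- dim(x)
    if (d[3] != self$in_ch) {
      stop(sprintf("cbam block expected %d channels, received %d",
                   self$in_ch, d[3]))
    }
    dsc <- channel_descriptors(x)
    br <- lapply(list(avg = dsc$avg, max = dsc$max), function(dd) {
      z1 <- self$par$W1 %*% dd + self$par$b1
      r1 <- pmax(z1, 0)
      z2 <- self$par$W2 %*% r1 + self$par$b2
      list(d = dd, z1 = z1, r1 = r1, z2 = z2)
    })
    w <- 1 / (1 + exp(-(br$avg$z2 + br$max$z2)))
    F1 <- x * bc_channel(w, d)
    s <- nn_forward(self$children$sa, F1, train)
    y <- F1 * bc_spatial(s, d)
    self$cache <- list(d = d, x = x, dsc = dsc, br = br, w = w, F1 = F1,
                       s = s)
    y
  }

  m$bwd <- function(self, gy) {
    cc <- self$cache
    d <- cc$d
    ds <- sum_channels(gy * cc$F1)
    dF1 <- gy * bc_spatial(cc$s, d)
    dF1 <- dF1 + nn_backward(self$children$sa, ds)
    dw <- sum_spatial(dF1 * cc$x)
    gs <- dw * cc$w * (1 - cc$w)
    gd <- list()
    for (nm in c("avg", "max")) {
      b <- cc$br[[nm]]
      self$grad$W2 <- self$grad$W2 + tcrossprod(gs, b$r1)
      self$grad$b2 <- self$grad$b2 + rowSums(gs)
      gr1 <- crossprod(self$par$W2, gs) * (b$z1 > 0)
      self$grad$W1 <- self$grad$W1 + tcrossprod(gr1, b$d)
      self$grad$b1 <- self$grad$b1 + rowSums(gr1)
      gd[[nm]] <- crossprod(self$par$W1, gr1)
    }
    hw <- cc$dsc$hw
    gx <- dF1 * bc_channel(cc$w, d)
    gxv <- as.vector(gx) +
      as.vector(array(rep(as.vector(gd$avg), each = hw) / hw, d))
    q <- seq_along(cc$dsc$argmax)
    idx <- cc$dsc$argmax + (q - 1L) * hw
    gxv[idx] <- gxv[idx] + as.vector(gd$max)
    array(gxv, d)
  }
  m
}

# ---- user-facing wrappers ----------------------------------------------

#' Channel attention weights for a feature map
#'
#' Computes the per-channel gate of the adaptive channel attention block:
#' global average- and max-pooled descriptors pass through a shared pair of
#' 1D convolutions (ReLU between, same padding, no channel reduction), are
#' summed and squashed with a sigmoid.
#'
#' @param F A feature map: array of shape (C, H, W).
#' @param kernel_size Odd integer kernel size for the 1D convolutions,
#'   normally obtained from [igpdf_kernel_size()].
#' @param block Optionally a prebuilt attention module (for reuse of learned
#'   weights); if `NULL` a fresh one is initialised.
#' @param seed Optional integer seed for weight initialisation.
#' @return A numeric vector of length C with entries strictly in (0, 1).
#' @export
channel_attention <- function(F, kernel_size, block = NULL, seed = NULL) {
  x <- fm_to_hwcn(F)
  if (is.null(block)) {
    block <- with_seed(seed, nn_channel_attention(kernel_size))
  }
  as.vector(nn_forward(block, x, train = FALSE))
}

#' Spatial attention map for a feature map
#'
#' Stacks the channel-wise mean and max maps into a 2-channel tensor, applies
#' a learnable 7x7 convolution down to a single channel and a sigmoid.
#'
#' @inheritParams channel_attention
#' @return An array of shape (1, H, W) with entries strictly in (0, 1).
#' @export
spatial_attention <- function(F, block = NULL, seed = NULL) {
  x <- fm_to_hwcn(F)
  if (is.null(block)) block <- with_seed(seed, nn_spatial_attention())
  y <- nn_forward(block, x, train = FALSE)
  d <- dim(y)
  array(aperm(y, c(3L, 1L, 2L, 4L)), c(1L, d[1], d[2]))
}

#' Adaptive channel attention block forward pass
#'
#' Applies the ACA block to a feature map. The 1D-convolution kernel size is
#' derived from the channel count via [igpdf_kernel_size()]. In the default
#' multiplicative mode the input is gated by the channel weights, then by the
#' spatial map computed from the gated tensor, with a residual shortcut:
#' `F' = F + M_S(w * F) * (w * F)`. The additive mode instead broadcasts the
#' channel weight vector and the spatial map of `F` onto `F`.
#'
#' @param F A feature map: array of shape (C, H, W).
#' @param params An [igpdf_params()] object.
#' @param combination `"multiplicative"` (default) or `"additive"`.
#' @param block Optionally a prebuilt ACA module.
#' @param seed Optional integer seed for weight initialisation.
#' @return A feature map of exactly the same shape as `F`.
#' @export
aca_forward <- function(F, params = igpdf_params(),
                        combination = c("multiplicative", "additive"),
                        block = NULL, seed = NULL) {
  combination <- match.arg(combination)
  x <- fm_to_hwcn(F)
  if (is.null(block)) {
    block <- with_seed(seed, nn_aca(dim(x)[3], params, combination))
  }
  hwcn_to_fm(nn_forward(block, x, train = FALSE))
}

#' CBAM block forward pass (ablation baseline)
#'
#' Standard convolutional block attention: a shared two-layer perceptron
#' (C -> C/r -> C) channel gate followed by the 7x7 spatial gate, applied
#' sequentially and multiplicatively.
#'
#' @param F A feature map: array of shape (C, H, W).
#' @param reduction_ratio Positive integer; must divide the channel count.
#' @param block Optionally a prebuilt CBAM module.
#' @param seed Optional integer seed for weight initialisation.
#' @return A feature map of the same shape as `F`.
#' @export
cbam_forward <- function(F, reduction_ratio = 16L, block = NULL,
                         seed = NULL) {
  x <- fm_to_hwcn(F)
  if (is.null(block)) {
    block <- with_seed(seed, nn_cbam(dim(x)[3], reduction_ratio))
  }
  hwcn_to_fm(nn_forward(block, x, train = FALSE))
}
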