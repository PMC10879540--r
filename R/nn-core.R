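# Minimal CNN engine: forward + analytic backward passes for the handful of
# layer types the network family needs. Tensors are plain R arrays in
# (H, W, C, N) layout internally; the user-facing FeatureMap layout is
# (C, H, W) with an optional leading batch dimension, mirroring how layer
# tables for classification networks are usually printed.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Evaluates an expression under `set.seed(seed)` and restores the caller's
#' RNG state afterwards, so seeded constructors do not disturb the global
#' random stream.
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

zeros_like <- function(p) {
  if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
}

# ---- FeatureMap <-> internal layout ------------------------------------

#' @keywords internal
fm_to_hwcn <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("feature map must be a 3-D (C,H,W) or 4-D (N,C,H,W) array")
  }
  if (any(!is.finite(x))) stop("feature map contains non-finite values")
  if (length(d) == 3L) {
    y <- array(x, c(d, 1L))
    aperm(y, c(2L, 3L, 1L, 4L))            # (C,H,W,1) -> (H,W,C,1)
  } else {
    aperm(x, c(3L, 4L, 2L, 1L))            # (N,C,H,W) -> (H,W,C,N)
  }
}

#' @keywords internal
hwcn_to_fm <- function(x, batched = FALSE) {
  if (batched) {
    aperm(x, c(4L, 3L, 1L, 2L))            # (N,C,H,W)
  } else {
    y <- aperm(x, c(3L, 1L, 2L, 4L))       # (C,H,W,N)
    array(y, dim(y)[1:3])
  }
}

pad_hw <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

unpad_hw <- function(x, pad, dims) {
  if (pad == 0L) return(x)
  x[pad + seq_len(dims[1]), pad + seq_len(dims[2]), , , drop = FALSE]
}

# ---- im2col machinery ---------------------------------------------------

# Gather-index table for a (k x k, stride s) sliding window over a padded
# (Hp, Wp, C) volume. Columns are ordered kernel-offset fastest then channel,
# which matches the column-major flattening of a (k, k, C_in, C_out) weight
# array.
im2col_idx <- function(Hp, Wp, C, k, stride) {
  Hout <- (Hp - k) %/% stride + 1L
  Wout <- (Wp - k) %/% stride + 1L
  if (Hout < 1L || Wout < 1L) {
    stop(sprintf("window %d with stride %d does not fit a %dx%d input",
                 k, stride, Hp, Wp))
  }
  sp0 <- outer(seq.int(0L, by = stride, length.out = Hout) + 1L,
               seq.int(0L, by = stride, length.out = Wout) * Hp, "+")
  off <- outer(seq_len(k) - 1L, (seq_len(k) - 1L) * Hp, "+")
  idx_sp <- outer(as.vector(sp0), as.vector(off), "+")
  ia <- outer(as.vector(idx_sp), (seq_len(C) - 1L) * Hp * Wp, "+")
  dim(ia) <- c(nrow(idx_sp), k * k * C)
  list(ia = ia, Hout = Hout, Wout = Wout, npos = nrow(idx_sp), k2 = k * k)
}

# (Hp,Wp,C,N) -> matrix (npos*N) x (k2*C); row blocks are per-sample.
im2col <- function(P, info) {
  d <- dim(P)
  N <- d[4]
  plane <- d[1] * d[2] * d[3]
  npos <- info$npos
  X <- matrix(0, npos * N, ncol(info$ia))
  iav <- as.vector(info$ia)
  Pv <- as.vector(P)
  for (n in seq_len(N)) {
    X[(n - 1L) * npos + seq_len(npos), ] <- Pv[iav + (n - 1L) * plane]
  }
  X
}

# Scatter-add of a column matrix back onto the padded input volume. For a
# fixed kernel offset the output->input map is injective, so the inner
# assignments are collision-free.
col2im <- function(G, info, dims) {
  plane <- dims[1] * dims[2] * dims[3]
  N <- dims[4]
  npos <- info$npos
  k2 <- info$k2
  C <- dims[3]
  g <- numeric(plane * N)
  for (j in seq_len(k2)) {
    cols <- j + (seq_len(C) - 1L) * k2
    idx <- as.vector(info$ia[, cols])
    for (n in seq_len(N)) {
      vals <- as.vector(G[(n - 1L) * npos + seq_len(npos), cols])
      ii <- idx + (n - 1L) * plane
      g[ii] <- g[ii] + vals
    }
  }
  array(g, dims)
}

# ---- module base --------------------------------------------------------

new_module <- function(type, par = list(), buf = list(), children = list()) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$par <- par
  m$grad <- lapply(par, zeros_like)
  m$buf <- buf
  m$children <- children
  m$idx_cache <- list()
  m$cache <- NULL
  m$opt <- list()
  class(m) <- c(paste0("nn_", type), "nn_module")
  m
}

nn_forward <- function(m, x, train = FALSE) m$fwd(m, x, train)
nn_backward <- function(m, gy) m$bwd(m, gy)

nn_modules <- function(m) {
  out <- list(m)
  for (ch in m$children) out <- c(out, nn_modules(ch))
  out
}

nn_n_params <- function(m) {
  sum(vapply(nn_modules(m), function(mm) {
    sum(vapply(mm$par, length, integer(1)))
  }, numeric(1)))
}

nn_zero_grad <- function(m) {
  for (mm in nn_modules(m)) mm$grad <- lapply(mm$par, zeros_like)
  invisible(m)
}

# Overwrite every learnable parameter with a constant (used to realise the
# closed-form attention/block identities in tests and documentation).
nn_set_constant <- function(m, value = 0) {
  for (mm in nn_modules(m)) {
    mm$par <- lapply(mm$par, function(p) {
      p[] <- value
      p
    })
  }
  invisible(m)
}

# Flat named parameter/buffer state for checkpoints.
nn_state <- function(m, prefix = "") {
  out <- list()
  for (k in names(m$par)) out[[paste0(prefix, "par:", k)]] <- m$par[[k]]
  for (k in names(m$buf)) out[[paste0(prefix, "buf:", k)]] <- m$buf[[k]]
  chn <- names(m$children)
  if (length(m$children) && is.null(chn)) {
    chn <- as.character(seq_along(m$children))
  }
  for (i in seq_along(m$children)) {
    out <- c(out, nn_state(m$children[[i]], paste0(prefix, chn[i], "/")))
  }
  out
}

nn_load_state <- function(m, state, prefix = "") {
  for (k in names(m$par)) {
    key <- paste0(prefix, "par:", k)
    if (is.null(state[[key]])) stop("checkpoint is missing parameter ", key)
    m$par[[k]] <- state[[key]]
  }
  for (k in names(m$buf)) {
    key <- paste0(prefix, "buf:", k)
    if (is.null(state[[key]])) stop("checkpoint is missing buffer ", key)
    m$buf[[k]] <- state[[key]]
  }
  chn <- names(m$children)
  if (length(m$children) && is.null(chn)) {
    chn <- as.character(seq_along(m$children))
  }
  for (i in seq_along(m$children)) {
    nn_load_state(m$children[[i]], state, paste0(prefix, chn[i], "/"))
  }
  invisible(m)
}

# ---- conv2d -------------------------------------------------------------

nn_conv2d <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, bias = TRUE) {
  W <- array(stats::rnorm(k * k * in_ch * out_ch, sd = sqrt(2 / (k * k * in_ch))),
             c(k, k, in_ch, out_ch))
  par <- list(W = W)
  if (bias) par$b <- numeric(out_ch)
  m <- new_module("conv2d", par)
  m$k <- as.integer(k); m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$in_ch <- as.integer(in_ch); m$out_ch <- as.integer(out_ch); m$has_bias <- bias

  m$fwd <- function(self, x, train) {
    d <- dim(x)
    if (d[3] != self$in_ch) {
      stop(sprintf("conv2d expected %d input channels, received %d",
                   self$in_ch, d[3]))
    }
    P <- pad_hw(x, self$pad)
    dp <- dim(P)
    key <- paste(dp[1:3], collapse = "x")
    info <- self$idx_cache[[key]]
    if (is.null(info)) {
      info <- im2col_idx(dp[1], dp[2], dp[3], self$k, self$stride)
      self$idx_cache[[key]] <- info
    }
    X <- im2col(P, info)
    Wm <- self$par$W
    dim(Wm) <- c(self$k^2 * self$in_ch, self$out_ch)
    Y <- X %*% Wm
    if (self$has_bias) Y <- Y + rep(self$par$b, each = nrow(Y))
    N <- d[4]
    y <- array(Y, c(info$Hout, info$Wout, N, self$out_ch))
    self$cache <- list(X = X, info = info, d = d, dp = dp)
    aperm(y, c(1L, 2L, 4L, 3L))
  }

  m$bwd <- function(self, gy) {
    cc <- self$cache
    N <- cc$d[4]
    g <- aperm(gy, c(1L, 2L, 4L, 3L))
    dim(g) <- c(cc$info$npos * N, self$out_ch)
    gW <- crossprod(cc$X, g)
    dim(gW) <- dim(self$par$W)
    self$grad$W <- self$grad$W + gW
    if (self$has_bias) self$grad$b <- self$grad$b + colSums(g)
    Wm <- self$par$W
    dim(Wm) <- c(self$k^2 * self$in_ch, self$out_ch)
    Gcol <- tcrossprod(g, Wm)
    gP <- col2im(Gcol, cc$info, cc$dp)
    unpad_hw(gP, self$pad, cc$d)
  }
  m
}

# ---- max pooling --------------------------------------------------------

nn_maxpool2d <- function(k, stride, pad = 0L) {
  m <- new_module("maxpool2d", list())
  m$k <- as.integer(k); m$stride <- as.integer(stride); m$pad <- as.integer(pad)

  m$fwd <- function(self, x, train) {
    d <- dim(x)
    P <- pad_hw(x, self$pad, value = -Inf)
    dp <- dim(P)
    key <- paste(dp[1:3], collapse = "x")
    info <- self$idx_cache[[key]]
    if (is.null(info)) {
      info <- im2col_idx(dp[1], dp[2], dp[3], self$k, self$stride)
      self$idx_cache[[key]] <- info
    }
    N <- d[4]; C <- d[3]
    X <- im2col(P, info)
    A <- array(X, c(info$npos, N, info$k2, C))
    M <- aperm(A, c(1L, 2L, 4L, 3L))            # (pos, n, c, j)
    dim(M) <- c(info$npos * N * C, info$k2)
    mx <- do.call(pmax, lapply(seq_len(info$k2), function(j) M[, j]))
    am <- max.col(M, ties.method = "first")
    y <- array(mx, c(info$Hout, info$Wout, N, C))
    self$cache <- list(am = am, info = info, d = d, dp = dp)
    aperm(y, c(1L, 2L, 4L, 3L))
  }

  m$bwd <- function(self, gy) {
    cc <- self$cache
    info <- cc$info
    d <- cc$d; dp <- cc$dp
    N <- d[4]; C <- d[3]
    npos <- info$npos; k2 <- info$k2
    plane <- dp[1] * dp[2] * dp[3]
    g <- as.vector(aperm(gy, c(1L, 2L, 4L, 3L)))  # ordered (pos, n, c)
    r <- seq_along(cc$am) - 1L
    pos <- r %% npos + 1L
    nn <- (r %/% npos) %% N + 1L
    ch <- r %/% (npos * N) + 1L
    iav <- as.vector(info$ia)
    gP <- numeric(plane * N)
    for (j in seq_len(k2)) {
      sel <- which(cc$am == j)
      if (!length(sel)) next
      ii <- iav[pos[sel] + ((j - 1L) + (ch[sel] - 1L) * k2) * npos] +
        (nn[sel] - 1L) * plane
      gP[ii] <- gP[ii] + g[sel]
    }
    unpad_hw(array(gP, dp), self$pad, d)
  }
  m
}

# ---- batch normalisation ------------------------------------------------

nn_batchnorm2d <- function(C, eps = 1e-5, momentum = 0.1) {
  m <- new_module("batchnorm2d",
                  par = list(gamma = rep(1, C), beta = numeric(C)),
                  buf = list(running_mean = numeric(C), running_var = rep(1, C)))
  m$C <- as.integer(C); m$eps <- eps; m$momentum <- momentum

  m$fwd <- function(self, x, train) {
    d <- dim(x)
    xm <- aperm(x, c(1L, 2L, 4L, 3L))
    dim(xm) <- c(d[1] * d[2] * d[4], d[3])
    if (train) {
      mu <- colMeans(xm)
      xc <- xm - rep(mu, each = nrow(xm))
      v <- colMeans(xc * xc)
      self$buf$running_mean <- (1 - self$momentum) * self$buf$running_mean +
        self$momentum * mu
      self$buf$running_var <- (1 - self$momentum) * self$buf$running_var +
        self$momentum * v
    } else {
      mu <- self$buf$running_mean
      v <- self$buf$running_var
      xc <- xm - rep(mu, each = nrow(xm))
    }
    invstd <- 1 / sqrt(v + self$eps)
    xhat <- xc * rep(invstd, each = nrow(xm))
    ym <- xhat * rep(self$par$gamma, each = nrow(xm)) +
      rep(self$par$beta, each = nrow(xm))
    y <- array(ym, c(d[1], d[2], d[4], d[3]))
    self$cache <- list(xhat = xhat, invstd = invstd, d = d, train = train)
    aperm(y, c(1L, 2L, 4L, 3L))
  }

  m$bwd <- function(self, gy) {
    cc <- self$cache
    d <- cc$d
    gm <- aperm(gy, c(1L, 2L, 4L, 3L))
    dim(gm) <- c(d[1] * d[2] * d[4], d[3])
    n <- nrow(gm)
    self$grad$gamma <- self$grad$gamma + colSums(gm * cc$xhat)
    self$grad$beta <- self$grad$beta + colSums(gm)
    if (cc$train) {
      s1 <- colSums(gm)
      s2 <- colSums(gm * cc$xhat)
      gx <- (gm - rep(s1 / n, each = n) - cc$xhat * rep(s2 / n, each = n)) *
        rep(self$par$gamma * cc$invstd, each = n)
    } else {
      gx <- gm * rep(self$par$gamma * cc$invstd, each = n)
    }
    gxa <- array(gx, c(d[1], d[2], d[4], d[3]))
    aperm(gxa, c(1L, 2L, 4L, 3L))
  }
  m
}

# ---- simple elementwise layers -----------------------------------------

nn_relu <- function() {
  m <- new_module("relu", list())
  m$fwd <- function(self, x, train) {
    mask <- x > 0
    self$cache <- mask
    x * mask
  }
  m$bwd <- function(self, gy) gy * self$cache
  m
}

nn_sigmoid <- function() {
  m <- new_module("sigmoid", list())
  m$fwd <- function(self, x, train) {
    y <- 1 / (1 + exp(-x))
    self$cache <- y
    y
  }
  m$bwd <- function(self, gy) gy * self$cache * (1 - self$cache)
  m
}

# ---- global average pooling --------------------------------------------

nn_gap <- function() {
  m <- new_module("gap", list())
  m$fwd <- function(self, x, train) {
    d <- dim(x)
    xm <- x
    dim(xm) <- c(d[1] * d[2], d[3] * d[4])
    y <- matrix(colMeans(xm), d[3], d[4])
    self$cache <- d
    y
  }
  m$bwd <- function(self, gy) {
    d <- self$cache
    hw <- d[1] * d[2]
    array(rep(as.vector(gy), each = hw) / hw, d)
  }
  m
}

# ---- fully connected ----------------------------------------------------

nn_linear <- function(in_f, out_f, bias = TRUE) {
  par <- list(W = matrix(stats::rnorm(out_f * in_f, sd = sqrt(1 / in_f)),
                         out_f, in_f))
  if (bias) par$b <- numeric(out_f)
  m <- new_module("linear", par)
  m$has_bias <- bias
  m$fwd <- function(self, x, train) {
    self$cache <- x
    y <- self$par$W %*% x
    if (self$has_bias) y <- y + self$par$b
    y
  }
  m$bwd <- function(self, gy) {
    self$grad$W <- self$grad$W + tcrossprod(gy, self$cache)
    if (self$has_bias) self$grad$b <- self$grad$b + rowSums(gy)
    crossprod(self$par$W, gy)
  }
  m
}

# ---- 2x upsampling ------------------------------------------------------

# Row-interpolation matrix: output length nout from input length nin.
interp_matrix <- function(nout, nin, mode = c("nearest", "bilinear")) {
  mode <- match.arg(mode)
  M <- matrix(0, nout, nin)
  if (mode == "nearest") {
    src <- pmin(nin, pmax(1L, ceiling(seq_len(nout) * nin / nout)))
    M[cbind(seq_len(nout), src)] <- 1
  } else {
    s <- (seq_len(nout) - 0.5) * (nin / nout) + 0.5
    i0 <- pmin(nin, pmax(1L, floor(s)))
    i1 <- pmin(nin, i0 + 1L)
    fr <- pmin(1, pmax(0, s - i0))
    for (i in seq_len(nout)) {
      M[i, i0[i]] <- M[i, i0[i]] + (1 - fr[i])
      M[i, i1[i]] <- M[i, i1[i]] + fr[i]
    }
  }
  M
}

apply_interp <- function(x, Lh, Lw) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1], d[2] * d[3] * d[4])
  y1 <- Lh %*% xm
  dim(y1) <- c(nrow(Lh), d[2], d[3], d[4])
  y1 <- aperm(y1, c(2L, 1L, 3L, 4L))
  dim(y1) <- c(d[2], nrow(Lh) * d[3] * d[4])
  y2 <- Lw %*% y1
  dim(y2) <- c(nrow(Lw), nrow(Lh), d[3], d[4])
  aperm(y2, c(2L, 1L, 3L, 4L))
}

nn_upsample2 <- function(mode = c("nearest", "bilinear")) {
  mode <- match.arg(mode)
  m <- new_module("upsample2", list())
  m$mode <- mode
  m$fwd <- function(self, x, train) {
    d <- dim(x)
    key <- paste(d[1:2], collapse = "x")
    mats <- self$idx_cache[[key]]
    if (is.null(mats)) {
      mats <- list(Lh = interp_matrix(2L * d[1], d[1], self$mode),
                   Lw = interp_matrix(2L * d[2], d[2], self$mode))
      self$idx_cache[[key]] <- mats
    }
    self$cache <- list(d = d, mats = mats)
    apply_interp(x, mats$Lh, mats$Lw)
  }
  m$bwd <- function(self, gy) {
    cc <- self$cache
    apply_interp(gy, t(cc$mats$Lh), t(cc$mats$Lw))
  }
  m
}

# ---- sequential container ----------------------------------------------

nn_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) &&
      !inherits(mods[[1]], "nn_module")) {
    mods <- mods[[1]]
  }
  names(mods) <- sprintf("m%02d", seq_along(mods))
  m <- new_module("sequential", children = mods)
  m$fwd <- function(self, x, train) {
    for (ch in self$children) x <- nn_forward(ch, x, train)
    x
  }
  m$bwd <- function(self, gy) {
    for (ch in rev(self$children)) gy <- nn_backward(ch, gy)
    gy
  }
  m
}

# ---- channel concat/split ----------------------------------------------

cat_channels <- function(parts) {
  d1 <- dim(parts[[1]])
  Ctot <- sum(vapply(parts, function(p) dim(p)[3], numeric(1)))
  out <- array(0, c(d1[1], d1[2], Ctot, d1[4]))
  at <- 0L
  for (p in parts) {
    cp <- dim(p)[3]
    out[, , at + seq_len(cp), ] <- p
    at <- at + cp
  }
  out
}

split_channels <- function(x, sizes) {
  at <- 0L
  out <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    out[[i]] <- x[, , at + seq_len(sizes[i]), , drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

# Broadcast a (C,N) per-channel weight over (H,W,C,N).
bc_channel <- function(w, d) {
  array(rep(as.vector(w), each = d[1] * d[2]), d)
}

# Broadcast a (H,W,1,N) spatial map over (H,W,C,N).
bc_spatial <- function(s, d) {
  v <- as.vector(s)                        # ordered (h, w, n)
  a <- array(rep(v, times = d[3]), c(d[1], d[2], d[4], d[3]))
  aperm(a, c(1L, 2L, 4L, 3L))
}

# Reduce (H,W,C,N) over spatial dims -> (C,N).
sum_spatial <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  matrix(colSums(xm), d[3], d[4])
}

# Reduce (H,W,C,N) over channels -> (H,W,1,N).
sum_channels <- function(x) {
  d <- dim(x)
  xm <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  array(rowSums(xm), c(d[1], d[2], 1L, d[4]))
}
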