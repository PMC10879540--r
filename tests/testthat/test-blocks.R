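# Stem, CER and BIF blocks: shape arithmetic, parameter accounting,
# gradient routing.

test_that("stem quarters the spatial dims per the convolution arithmetic", {
  img <- random_fm(3, 64, 64, seed = 1)
  out <- stem_forward(img, stem_width = 8, seed = 1)
  # oracle: conv 7/2/3 then pool 3/2/1
  h1 <- conv_out_len(64, 7, 2, 3)
  h2 <- conv_out_len(h1, 3, 2, 1)
  expect_identical(dim(out), c(8L, as.integer(h2), as.integer(h2)))
  expect_identical(h2, 16)
  expect_error(stem_forward(random_fm(4, 64, 64)), "3-channel")
  expect_error(stem_forward(random_fm(3, 30, 30)), "divisible by 4")
})

test_that("cer triples channels and halves spatial dims for varied widths", {
  set.seed(3)
  for (C in c(1L, 3L, 8L, 16L)) {
    H <- sample(seq(10, 30, 2), 1)
    F <- array(rnorm(C * H * H), c(C, H, H))
    out <- cer_forward(F, cer_config(C), seed = C)
    expect_identical(dim(out), as.integer(c(3L * C, H %/% 2L, H %/% 2L)))
  }
})

test_that("the three pooling branches agree spatially for windows 3/5/9", {
  for (H in c(13, 26, 52, 104)) {
    sides <- vapply(c(3, 5, 9), function(k) {
      conv_out_len(H, k, 2, (k - 1) / 2)
    }, numeric(1))
    expect_true(all(sides == sides[1]))
  }
  # and the engine itself agrees on an odd size
  F <- random_fm(2, 13, 13, seed = 5)
  expect_identical(dim(cer_forward(F, cer_config(2), seed = 1)),
                   c(6L, 7L, 7L))
})

test_that("the channel-expansion stage is parameter-free; full counts match hand arithmetic", {
  for (C in c(1L, 5L, 16L, 32L)) {
    expect_identical(cer_expansion_param_count(cer_config(C)), 0L)
  }
  # hand enumeration for in_channels = 16 (convs bias-free, BN = 2 * 3C each):
  # aggregation 48*48*(1+9+1) + residual 16*48 = 26112, plus 4 BN * 96 = 384
  expect_identical(cer_param_count(cer_config(16)), 26112L + 384L)
  # without batch norm the convs carry biases instead
  expect_identical(cer_param_count(cer_config(16, use_batchnorm = FALSE)),
                   26112L + 3L * 48L + 48L)
})

test_that("a zero-weight cer block maps anything to zero", {
  blk <- ercpnet:::nn_cer(cer_config(2))
  ercpnet:::nn_set_constant(blk, 0)
  out <- cer_forward(random_fm(2, 8, 8, seed = 7), cer_config(2),
                     block = blk)
  expect_true(all(out == 0))
})

test_that("gradient flows through the cer residual when the aggregation path is dead", {
  # zero the aggregation weights (keeping shortcut weights) -> the block's
  # Jacobian equals that of the strided projection + BN + final ReLU alone
  cfg <- cer_config(2, use_batchnorm = FALSE)
  blk <- withr::with_seed(4, ercpnet:::nn_cer(cfg))
  ercpnet:::nn_set_constant(blk$children$agg, 0)
  x <- array(abs(rnorm(2 * 6 * 6)) + 0.1, c(6, 6, 2, 1))
  y <- ercpnet:::nn_forward(blk, x, train = FALSE)
  wts <- array(rnorm(length(y)), dim(y))
  ercpnet:::nn_zero_grad(blk)
  gx <- ercpnet:::nn_backward(blk, wts)
  # independent path: forward the shortcut alone
  f_short <- function(v) {
    xs <- array(v, dim(x))
    r <- ercpnet:::nn_forward(blk$children$shortcut, xs, FALSE)
    sum(pmax(r, 0) * wts)
  }
  ng <- numeric_gradient(f_short, x)
  expect_equal(as.numeric(gx), as.numeric(ng), tolerance = 1e-4)
})

test_that("bif fuses mid and deep maps to the configured width", {
  p2 <- random_fm(4, 8, 8, seed = 1)
  p3 <- random_fm(6, 4, 4, seed = 2)
  out <- bif_forward(p2, p3, seed = 3)
  expect_identical(dim(out), c(18L, 4L, 4L))     # default 3 * C3
  out2 <- bif_forward(p2, p3, bif_config(4, 6, out_channels = 11), seed = 3)
  expect_identical(dim(out2), c(11L, 4L, 4L))
  expect_error(bif_forward(random_fm(4, 6, 6), p3, bif_config(4, 6)),
               "twice the spatial size")
  expect_error(bif_forward(p2, p3, bif_config(5, 6)), "channels")
})

test_that("bif channel bookkeeping: an identity mix recovers the concat order", {
  # out_channels = (C3 + C2) + C3 = 10 with an identity 1x1 conv exposes the
  # concatenation [pooled merge of (upsampled P3, P2), then P3]
  cfg <- bif_config(2, 4, out_channels = 10, use_batchnorm = FALSE)
  blk <- ercpnet:::nn_bif(cfg)
  W <- array(0, c(1, 1, 10, 10))
  for (i in 1:10) W[1, 1, i, i] <- 1
  conv <- blk$children$mix$children[[1]]
  conv$par$W <- W
  conv$par$b <- numeric(10)
  p2 <- array(abs(random_fm(2, 4, 4, seed = 4)), c(2, 4, 4))
  p3 <- array(abs(random_fm(4, 2, 2, seed = 5)), c(4, 2, 2))
  out <- bif_forward(p2, p3, cfg, block = blk)
  # last C3 channels are P3 itself (identity conv + ReLU on positive input)
  expect_equal(out[7:10, , ], p3, tolerance = 1e-12)
  # first C3 + C2 channels equal the stride-2 max pool of concat(up(P3), P2)
  up <- ercpnet:::nn_upsample2("nearest")
  pool <- ercpnet:::nn_maxpool2d(3L, 2L, 1L)
  U <- ercpnet:::nn_forward(up, ercpnet:::fm_to_hwcn(p3), FALSE)
  M <- ercpnet:::cat_channels(list(U, ercpnet:::fm_to_hwcn(p2)))
  D <- ercpnet:::hwcn_to_fm(ercpnet:::nn_forward(pool, M, FALSE))
  expect_equal(out[1:6, , ], D, tolerance = 1e-12)
})

test_that("all-zero bif inputs give an all-zero fusion output", {
  z2 <- array(0, c(3, 6, 6))
  z3 <- array(0, c(5, 3, 3))
  out <- bif_forward(z2, z3, bif_config(3, 5, use_batchnorm = FALSE),
                     seed = 2)
  expect_true(all(out == 0))
})
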