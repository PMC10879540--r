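# Adaptive channel attention: kernel-size rule, channel/spatial gates,
# ACA block and the CBAM baseline.

test_that("inverse-Gaussian abscissa matches independently computed values", {
  p <- igpdf_params()
  # frozen with a 30-digit scalar calculator, x = sqrt(-2 ln(C/2048 * sqrt(2pi)))
  expect_equal(ercpnet:::igpdf_x(48, p), 2.38095755613024, tolerance = 1e-9)
  expect_equal(ercpnet:::igpdf_x(144, p), 1.86325905519266, tolerance = 1e-9)
  expect_equal(ercpnet:::igpdf_x(432, p), 1.12894186272865, tolerance = 1e-9)
  expect_equal(ercpnet:::igpdf_x(16, p), 2.80467172079548, tolerance = 1e-9)
  expect_equal(ercpnet:::igpdf_x(300, p), 1.41555499949562, tolerance = 1e-9)
})

test_that("kernel size rounds to the nearest odd integer and floors at 1", {
  p <- igpdf_params()
  expect_identical(igpdf_kernel_size(48, p), 3L)    # x = 2.381 -> 3
  expect_identical(igpdf_kernel_size(144, p), 1L)   # x = 1.863 -> 1
  expect_identical(igpdf_kernel_size(432, p), 1L)
  expect_identical(igpdf_kernel_size(16, p), 3L)    # x = 2.805 -> 3
  # at the domain edge y * sigma * sqrt(2pi) = 1 the radicand is 0, x = mu
  edge <- igpdf_params(mu = 0, sigma = 1, channel_normalizer = 10 * sqrt(2 * pi))
  expect_identical(igpdf_kernel_size(10, edge), 1L)
  # a tie (x exactly even) rounds away from zero
  expect_identical(ercpnet:::round_to_odd(2), 3)
  expect_identical(ercpnet:::round_to_odd(4), 5)
})

test_that("kernel-size rule errors outside its domain and on bad input", {
  # y * sigma * sqrt(2pi) = 2 -> negative radicand
  bad <- igpdf_params(channel_normalizer = 5 * sqrt(2 * pi))
  expect_error(igpdf_kernel_size(10, bad), "outside the valid domain")
  expect_error(igpdf_kernel_size(818, igpdf_params()), "818")
  expect_error(igpdf_kernel_size(0, igpdf_params()), "positive integer")
  expect_error(igpdf_kernel_size(2.5, igpdf_params()), "positive integer")
  expect_error(igpdf_params(sigma = 0), "positive")
  expect_error(igpdf_params(channel_normalizer = -1), "positive")
})

test_that("kernel size is a non-increasing odd integer over the whole domain", {
  p <- igpdf_params()
  ks <- vapply(1:817, igpdf_kernel_size, integer(1), params = p)
  expect_true(all(ks >= 1L))
  expect_true(all(ks %% 2L == 1L))
  expect_true(all(diff(ks) <= 0L))
})

test_that("channel attention treats constant maps identically in both branches", {
  # spatially uniform per channel -> avg and max descriptors coincide
  F <- aperm(array(rep(c(0.3, -1, 2, 0.7), each = 25), c(5, 5, 4)),
             c(3, 1, 2))
  x <- ercpnet:::fm_to_hwcn(F)
  dsc <- ercpnet:::channel_descriptors(x)
  expect_equal(dsc$avg, dsc$max)
  w <- channel_attention(F, kernel_size = 3, seed = 1)
  expect_length(w, 4L)
  expect_true(all(w > 0 & w < 1))
})

test_that("zeroed channel attention outputs 0.5 everywhere", {
  blk <- ercpnet:::nn_channel_attention(3L)
  ercpnet:::nn_set_constant(blk, 0)
  w <- channel_attention(random_fm(6, 4, 4), 3, block = blk)
  expect_equal(w, rep(0.5, 6))
})

test_that("spatial attention preserves spatial dims and is channel-permutation invariant", {
  F <- random_fm(3, 4, 4, seed = 3)
  blk <- ercpnet:::nn_spatial_attention()
  s <- spatial_attention(F, block = blk)
  expect_identical(dim(s), c(1L, 4L, 4L))
  expect_true(all(s > 0 & s < 1))
  s2 <- spatial_attention(F[c(2, 3, 1), , ], block = blk)
  expect_equal(s, s2)
  zblk <- ercpnet:::nn_spatial_attention()
  ercpnet:::nn_set_constant(zblk, 0)
  expect_equal(as.numeric(spatial_attention(F, block = zblk)),
               rep(0.5, 16))
})

test_that("aca_forward preserves shape and composes two 0.5 gates when zeroed", {
  F <- random_fm(2, 2, 2, seed = 2)
  blk <- ercpnet:::nn_aca(2L, igpdf_params(), "multiplicative")
  ercpnet:::nn_set_constant(blk, 0)
  out <- aca_forward(F, block = blk)
  # hand-composed: w = 0.5, Fc = 0.5 F, spatial gate 0.5 -> F + 0.25 F
  expect_equal(out, F + 0.25 * F, tolerance = 1e-12)
  expect_identical(dim(out), dim(F))
  # zero input stays zero under the multiplicative residual
  z <- array(0, c(4, 3, 3))
  expect_equal(aca_forward(z, seed = 1), z)
})

test_that("aca_forward additive mode follows the literal broadcast sum", {
  F <- random_fm(2, 3, 3, seed = 4)
  blk <- ercpnet:::nn_aca(2L, igpdf_params(), "additive")
  ercpnet:::nn_set_constant(blk, 0)
  expect_equal(aca_forward(F, combination = "additive", block = blk),
               F + 0.5 + 0.5, tolerance = 1e-12)
  expect_error(aca_forward(F, combination = "sideways"), "arg")
})

test_that("aca shapes are preserved across random channel/spatial sizes", {
  set.seed(9)
  for (i in 1:5) {
    C <- sample(1:12, 1); H <- sample(2:7, 1); W <- sample(2:7, 1)
    F <- array(rnorm(C * H * W), c(C, H, W))
    expect_identical(dim(aca_forward(F, seed = i)), c(C, H, W))
  }
})

test_that("the aca residual contributes an exact identity to the Jacobian", {
  # with all learnable weights zero both gates are input-independent (0.5),
  # so the Jacobian is exactly (1 + 0.25) * I
  F <- random_fm(2, 2, 2, seed = 6)
  blk <- ercpnet:::nn_aca(2L, igpdf_params(), "multiplicative")
  ercpnet:::nn_set_constant(blk, 0)
  f <- function(v) sum(aca_forward(array(v, dim(F)), block = blk) *
                         as.numeric(seq_along(F)))
  g <- numeric_gradient(function(x) f(x), array(F, dim(F)))
  expect_equal(as.numeric(g), 1.25 * seq_along(F), tolerance = 1e-5)
})

test_that("cbam applies two sequential multiplicative gates", {
  F <- random_fm(2, 2, 2, seed = 8)
  blk <- ercpnet:::nn_cbam(2L, 2L)
  ercpnet:::nn_set_constant(blk, 0)
  expect_equal(cbam_forward(F, 2, block = blk), 0.25 * F, tolerance = 1e-12)
  F2 <- random_fm(48, 6, 6, seed = 9)
  out <- cbam_forward(F2, 16, seed = 2)
  expect_identical(dim(out), dim(F2))
  expect_error(cbam_forward(random_fm(6, 3, 3), 4), "not divisible")
})

test_that("channel attention is invariant to spatial permutations", {
  F <- random_fm(5, 4, 4, seed = 11)
  blk <- ercpnet:::nn_channel_attention(3L)
  w1 <- channel_attention(F, 3, block = blk)
  perm <- sample(16)
  Fp <- F
  for (c in 1:5) {
    m <- F[c, , ]
    Fp[c, , ] <- matrix(as.numeric(m)[perm], 4, 4)
  }
  w2 <- channel_attention(Fp, 3, block = blk)
  expect_equal(w1, w2)
})
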