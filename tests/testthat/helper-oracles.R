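# Independent oracles used across the suite.

# Output side length of a k x k convolution/pooling window: the standard
# floor((n + 2p - k) / s) + 1 arithmetic, kept separate from the engine.
conv_out_len <- function(n, k, s, p) floor((n + 2 * p - k) / s) + 1

# Brute-force classification metrics: expand a confusion matrix back into
# (label, prediction) pairs and count directly.
brute_metrics <- function(cm) {
  K <- nrow(cm)
  labs <- preds <- integer(0)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      labs <- c(labs, rep(i - 1L, cm[i, j]))
      preds <- c(preds, rep(j - 1L, cm[i, j]))
    }
  }
  prec <- rec <- numeric(K)
  for (k in seq_len(K) - 1L) {
    prec[k + 1L] <- if (sum(preds == k) == 0) 0 else {
      sum(preds == k & labs == k) / sum(preds == k)
    }
    rec[k + 1L] <- if (sum(labs == k) == 0) 0 else {
      sum(preds == k & labs == k) / sum(labs == k)
    }
  }
  list(accuracy = mean(preds == labs), precision = prec, recall = rec,
       macro_precision = mean(prec), macro_recall = mean(rec))
}

# Nearest-centroid classifier on per-channel colour histograms; an
# independent check that the synthetic classes are separable at all.
hist_feature <- function(img, bins = 8) {
  f <- c()
  for (ch in 1:3) {
    f <- c(f, tabulate(cut(img[ch, , ], breaks = seq(0, 1, length = bins + 1),
                           include.lowest = TRUE, labels = FALSE), bins))
  }
  f / sum(f) * 3
}

hist_centroid_accuracy <- function(train, test) {
  X <- t(sapply(train$items, function(it) hist_feature(it$image)))
  y <- sapply(train$items, `[[`, "label")
  cent <- sapply(sort(unique(y)),
                 function(k) colMeans(X[y == k, , drop = FALSE]))
  Xt <- t(sapply(test$items, function(it) hist_feature(it$image)))
  yt <- sapply(test$items, `[[`, "label")
  pred <- apply(Xt, 1, function(v) which.min(colSums((cent - v)^2)) - 1)
  mean(pred == yt)
}

# Central-difference gradient of a scalar function of an array.
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Small random feature map in the user-facing (C,H,W) layout.
random_fm <- function(C, H, W, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(C * H * W), c(C, H, W))
}

tiny_net_config <- function(variant = "ercp_net", seed = 1L) {
  network_config(variant, stem_width = 2L, input_size = 32L,
                 num_classes = 2L, seed = seed)
}

tiny_set <- function(n_per = 4L, classes = 2L, size = 32L, seed = 5L) {
  generate_synthetic_dataset(synthetic_spec(num_classes = classes,
                                            per_class = n_per,
                                            image_size = size, seed = seed))
}
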