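# Training loop, plateau scheduler, metrics.

test_that("three stale epochs decay the learning rate by the 0.3 factor", {
  cfg <- train_config()
  s <- lr_scheduler_state(0.01)
  s <- plateau_step(s, 0.50, cfg)          # improvement, records best
  for (i in 1:3) s <- plateau_step(s, 0.50, cfg)  # three non-improving
  expect_equal(s$current_lr, 0.003, tolerance = 1e-12)
  expect_identical(s$epochs_since_improvement, 0L)
})

test_that("monotone improvement never changes the learning rate", {
  cfg <- train_config()
  s <- lr_scheduler_state(0.01)
  for (a in seq(0.1, 0.9, by = 0.1)) s <- plateau_step(s, a, cfg)
  expect_identical(s$current_lr, 0.01)
})

test_that("an improvement after stale epochs resets the counter without decay", {
  cfg <- train_config()
  s <- lr_scheduler_state(0.01)
  s <- plateau_step(s, 0.5, cfg)
  s <- plateau_step(s, 0.5, cfg)
  s <- plateau_step(s, 0.5, cfg)           # 2 stale epochs so far
  s <- plateau_step(s, 0.6, cfg)           # improvement on the next
  expect_identical(s$current_lr, 0.01)
  expect_identical(s$epochs_since_improvement, 0L)
  # equal-to-best does NOT count as improvement
  s2 <- lr_scheduler_state(0.01)
  s2 <- plateau_step(s2, 0.5, cfg)
  for (i in 1:3) s2 <- plateau_step(s2, 0.5, cfg)
  expect_lt(s2$current_lr, 0.01)
})

test_that("zero epochs leave the parameters untouched and the history empty", {
  net <- build_network(tiny_net_config(seed = 5))
  before <- lapply(ercpnet:::net_components(net), ercpnet:::nn_state)
  set <- tiny_set(n_per = 3L)
  res <- train_network(net, set, set, train_config(epochs = 0L))
  expect_identical(nrow(res$history), 0L)
  after <- lapply(ercpnet:::net_components(net), ercpnet:::nn_state)
  expect_identical(before, after)
})

test_that("training is seed-deterministic and the lr trace only falls by the decay factor", {
  set <- tiny_set(n_per = 4L, seed = 8L)
  run <- function() {
    net <- build_network(tiny_net_config(seed = 13))
    train_network(net, set, set,
                  train_config(epochs = 4L, batch_size = 4L, seed = 2L),
                  restore_best = FALSE)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$history, r2$history)
  lr <- r1$history$lr
  expect_true(all(diff(lr) <= 0))
  steps <- lr[-1] / lr[-length(lr)]
  expect_true(all(abs(steps - 1) < 1e-12 | abs(steps - 0.3) < 1e-12))
})

test_that("one full-batch SGD step updates the head bias by the analytic gradient", {
  # momentum 0, weight decay 0, one batch covering the whole set:
  # d(loss)/d(b) = rowMeans(softmax(logits) - onehot), evaluated at the
  # initial parameters.
  set <- tiny_set(n_per = 2L, seed = 4L)
  net <- build_network(tiny_net_config(seed = 17))
  b0 <- net$fc$par$b
  x <- ercpnet:::set_to_tensor(set)
  logits <- ercpnet:::net_forward(net, x$x, train = TRUE)
  p <- ercpnet:::softmax_cols(logits)
  onehot <- matrix(0, 2, ncol(p))
  onehot[cbind(x$y + 1L, seq_len(ncol(p)))] <- 1
  expected_step <- rowMeans(p - onehot)
  # rebuild identically and train one epoch = one full batch
  net2 <- build_network(tiny_net_config(seed = 17))
  lr <- 0.05
  train_network(net2, set, set,
                train_config(epochs = 1L, batch_size = 4L, init_lr = lr,
                             momentum = 0, weight_decay = 0, seed = 1L),
                restore_best = FALSE)
  expect_equal(net2$fc$par$b, b0 - lr * expected_step, tolerance = 1e-10)
})

test_that("training rejects empty or mislabelled sets", {
  net <- build_network(tiny_net_config(seed = 1))
  empty <- labeled_image_set(list(), "a")
  expect_error(train_network(net, empty, empty, train_config(epochs = 1L)),
               "empty")
  bad <- tiny_set(n_per = 2L, classes = 3L)   # labels 0..2 vs 2-class net
  expect_error(train_network(net, bad, bad, train_config(epochs = 1L)),
               "num_classes")
})

test_that("confusion matrices count true/predicted pairs exactly", {
  cm <- compute_confusion(c(0, 1, 1, 1), c(0, 0, 1, 1), 2)
  expect_identical(unclass(cm),
                   matrix(c(1L, 0L, 1L, 2L), 2, 2,
                          dimnames = list(true = 0:1, predicted = 0:1)))
  p <- c(2, 0, 1, 1, 2)
  expect_identical(diag(unclass(compute_confusion(p, p, 3))),
                   c(`0` = 1L, `1` = 2L, `2` = 2L))
  expect_identical(sum(compute_confusion(integer(0), integer(0), 4)), 0L)
  expect_error(compute_confusion(c(0, 5), c(0, 1), 2), "\\[0, 2\\)")
})

test_that("metrics match hand arithmetic and flag degenerate classes", {
  cm <- matrix(c(8, 2, 2, 8), 2, 2, byrow = TRUE)
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$per_class_precision, c(0.8, 0.8))
  expect_equal(m$per_class_recall, c(0.8, 0.8))
  # perfect diagonal
  md <- compute_metrics(diag(c(3, 4, 5)))
  expect_equal(md$accuracy, 1)
  expect_equal(md$macro_precision, 1)
  # an absent class: zero row -> recall 0, flagged
  cm2 <- matrix(c(5, 0, 0, 0), 2, 2, byrow = TRUE)
  m2 <- compute_metrics(cm2)
  expect_equal(m2$per_class_recall[2], 0)
  expect_true(m2$degenerate_recall[2])
  expect_error(compute_metrics(matrix(0, 2, 2)), "positive")
})

test_that("metrics agree with brute-force recomputation on random matrices", {
  set.seed(42)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    cm <- matrix(rpois(K * K, 3), K, K)
    if (sum(cm) == 0) cm[1, 1] <- 1
    m <- compute_metrics(cm)
    b <- brute_metrics(cm)
    expect_equal(m$accuracy, b$accuracy, tolerance = 1e-12)
    expect_equal(m$per_class_precision, b$precision, tolerance = 1e-12)
    expect_equal(m$per_class_recall, b$recall, tolerance = 1e-12)
    expect_equal(m$macro_precision, b$macro_precision, tolerance = 1e-12)
    expect_equal(m$macro_recall, b$macro_recall, tolerance = 1e-12)
  }
})

test_that("macro metrics are invariant under simultaneous class permutation", {
  set.seed(7)
  cm <- matrix(rpois(16, 4), 4, 4)
  perm <- sample(4)
  m1 <- compute_metrics(cm)
  m2 <- compute_metrics(cm[perm, perm])
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$macro_precision, m2$macro_precision)
  expect_equal(m1$macro_recall, m2$macro_recall)
})

test_that("weighted averaging weights classes by support", {
  cm <- matrix(c(9, 1, 3, 7), 2, 2, byrow = TRUE)
  mw <- compute_metrics(cm, average = "weighted")
  b <- brute_metrics(cm)
  expect_equal(mw$macro_recall,
               (10 * b$recall[1] + 10 * b$recall[2]) / 20)
  cm2 <- matrix(c(9, 1, 0, 0, 3, 7, 0, 0, 0, 0, 2, 0, 0, 0, 0, 38), 4, 4,
                byrow = TRUE)
  mw2 <- compute_metrics(cm2, average = "weighted")
  w <- rowSums(cm2) / sum(cm2)
  b2 <- brute_metrics(cm2)
  expect_equal(mw2$macro_precision, sum(w * b2$precision))
})
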