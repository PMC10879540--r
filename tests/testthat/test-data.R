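# Folder ingestion, augmentation, stratified splitting.

test_that("image folders load with a lexicographic vocabulary and stable order", {
  skip_if_not_installed("EBImage")
  dir <- tempfile("imgset")
  set <- tiny_set(n_per = 3L, classes = 2L, size = 32L, seed = 1L)
  # write under deliberately unsorted class names
  set$label_names <- c("ba", "ab")
  write_image_folder(set, dir)
  loaded <- load_image_folder(dir, size = 32L)
  expect_identical(loaded$label_names, c("ab", "ba"))
  expect_length(loaded$items, 6L)
  labs <- vapply(loaded$items, `[[`, numeric(1), "label")
  expect_identical(sort(unique(labs)), c(0, 1))
  expect_true(all(vapply(loaded$items, function(it) {
    all(dim(it$image) == c(3L, 32L, 32L))
  }, logical(1))))
  loaded2 <- load_image_folder(dir, size = 32L)
  expect_identical(loaded, loaded2)
  # empty class directory errors
  dir.create(file.path(dir, "zz_empty"))
  expect_error(load_image_folder(dir, 32L), "no images")
  unlink(dir, recursive = TRUE)
})

test_that("pixel data survives the PNG round trip", {
  skip_if_not_installed("EBImage")
  dir <- tempfile("roundtrip")
  set <- tiny_set(n_per = 1L, classes = 2L, size = 24L, seed = 3L)
  write_image_folder(set, dir)
  loaded <- load_image_folder(dir, size = 24L)
  # 8-bit quantisation is the only loss
  expect_equal(loaded$items[[1]]$image, set$items[[1]]$image,
               tolerance = 1 / 255)
  unlink(dir, recursive = TRUE)
})

test_that("flips are involutions and the null augmentation is the identity", {
  img <- tiny_set(n_per = 1L, classes = 2L, size = 16L)$items[[1]]$image
  cfg_id <- augment_config(p_hflip = 0, p_vflip = 0, max_rotation_deg = 0,
                           noise_sigma = 0)
  expect_equal(augment_image(img, cfg_id, rng_state = 4L), img)
  cfg_flips <- augment_config(p_hflip = 1, p_vflip = 1, max_rotation_deg = 0,
                              noise_sigma = 0)
  once <- augment_image(img, cfg_flips, rng_state = 4L)
  twice <- augment_image(once, cfg_flips, rng_state = 4L)
  expect_false(isTRUE(all.equal(once, img)))
  expect_equal(twice, img)
})

test_that("augmentation preserves shape and range and is seed-deterministic", {
  img <- tiny_set(n_per = 1L, classes = 2L, size = 16L)$items[[1]]$image
  a1 <- augment_image(img, augment_config(), rng_state = 11L)
  a2 <- augment_image(img, augment_config(), rng_state = 11L)
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(img))
  expect_true(all(a1 >= 0 & a1 <= 1))
  expect_error(augment_image(img * 2, augment_config(), 1L), "\\[0, 1\\]")
})

test_that("rotation angles are uniform on [0, max] with the expected mean", {
  cfg <- augment_config()
  angles <- ercpnet:::with_seed(123L, {
    vapply(1:10000, function(i) ercpnet:::augment_draws(cfg)$angle,
           numeric(1))
  })
  expect_true(all(angles >= 0 & angles <= 35))
  # mean of U(0,35) is 17.5 with sd 35/sqrt(12)/100 per 10k draws
  se <- 35 / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(angles) - 17.5), 3 * se)
})

test_that("splits honour the 6:2:2 floors, stratification and exhaustiveness", {
  # one class, 100 items -> 60/20/20
  mk <- function(n) {
    labeled_image_set(lapply(seq_len(n), function(i) {
      list(image = array(0.5, c(3, 4, 4)), label = 0L)
    }), "only")
  }
  sp <- split_dataset(mk(100), seed = 1)
  expect_identical(lengths(lapply(sp, `[[`, "items")),
                   c(train = 60L, val = 20L, test = 20L))
  sp10 <- split_dataset(mk(10), seed = 1)
  expect_identical(lengths(lapply(sp10, `[[`, "items")),
                   c(train = 6L, val = 2L, test = 2L))
  sp11 <- split_dataset(mk(11), seed = 1)
  expect_identical(lengths(lapply(sp11, `[[`, "items")),
                   c(train = 7L, val = 2L, test = 2L))
  expect_error(split_dataset(mk(2)), "at least 3")
})

test_that("splits are disjoint, exhaustive and per-class balanced", {
  set <- tiny_set(n_per = 11L, classes = 3L, size = 16L, seed = 9L)
  # tag every image with a unique corner pixel so items are identifiable
  for (i in seq_along(set$items)) set$items[[i]]$image[1, 1, 1] <- i / 1000
  sp <- split_dataset(set, seed = 4)
  ids <- lapply(sp, function(s) {
    vapply(s$items, function(it) it$image[1, 1, 1], numeric(1))
  })
  expect_identical(unname(sort(unlist(ids))), (1:33) / 1000)
  expect_identical(length(intersect(ids$train, ids$val)), 0L)
  expect_identical(length(intersect(ids$train, ids$test)), 0L)
  for (s in sp) {
    labs <- vapply(s$items, `[[`, numeric(1), "label")
    expect_identical(as.integer(table(factor(labs, levels = 0:2))),
                     rep(length(labs) %/% 3L, 3L))
  }
})
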