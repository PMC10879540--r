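# Labeled image sets: folder ingestion, augmentation, stratified splitting.

#' Construct a labeled image set
#'
#' @param items List of `list(image = , label = )` pairs; images are
#'   (3, H, W) arrays with values in `[0, 1]`, labels 0-based integers.
#' @param label_names Ordered character vocabulary; label `k` maps to
#'   `label_names[k + 1]`.
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(items, label_names) {
  stopifnot(is.list(items), is.character(label_names))
  K <- length(label_names)
  for (it in items) {
    d <- dim(it$image)
    if (is.null(d) || length(d) != 3L || d[1] != 3L) {
      stop("every image must be a (3, H, W) array")
    }
    if (it$label < 0 || it$label >= K) {
      stop(sprintf("label %d outside [0, %d)", it$label, K))
    }
  }
  structure(list(items = items, label_names = label_names),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  labs <- vapply(x$items, `[[`, numeric(1), "label")
  cat(sprintf("<labeled_image_set> %d images, %d classes (%s)\n",
              length(x$items), length(x$label_names),
              paste(table(factor(labs, levels = seq_along(x$label_names) - 1)),
                    collapse = "/")))
  invisible(x)
}

c_sort <- function(x) sort(x, method = "radix")

#' Load a class-per-directory image folder
#'
#' Reads a directory whose subdirectories are class names containing
#' PNG/JPEG images, decodes and resizes every image to `size` x `size`, and
#' scales values to `[0, 1]`. The class vocabulary is the lexicographically
#' sorted (byte order) list of subdirectory names, and files within a class
#' are visited in the same order, so re-loading a folder is deterministic.
#'
#' @param path Directory of class-named subdirectories.
#' @param size Output side length in pixels (default 416).
#' @return A [labeled_image_set()].
#' @export
load_image_folder <- function(path, size = 416L) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("load_image_folder requires the EBImage package")
  }
  classes <- c_sort(list.dirs(path, full.names = FALSE, recursive = FALSE))
  if (!length(classes)) stop("no class subdirectories in ", path)
  items <- list()
  for (k in seq_along(classes)) {
    files <- c_sort(list.files(file.path(path, classes[k]),
                               pattern = "\\.(png|jpe?g)$",
                               ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) {
      stop("class directory contains no images: ",
           file.path(path, classes[k]))
    }
    for (f in files) {
      img <- tryCatch(EBImage::readImage(f),
                      error = function(e) stop("unreadable image file: ", f))
      img <- EBImage::resize(img, w = size, h = size)
      a <- as.array(img)
      if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
      if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
      fm <- aperm(a, c(3L, 2L, 1L))            # (x, y, C) -> (C, H, W)
      fm <- pmin(pmax(fm, 0), 1)
      items[[length(items) + 1L]] <- list(image = fm, label = k - 1L)
    }
  }
  labeled_image_set(items, classes)
}

#' Augmentation configuration
#'
#' The training-time recipe: random horizontal flip, random vertical flip,
#' random rotation by an angle drawn uniformly from `[0, max_rotation_deg]`
#' degrees, and additive Gaussian noise, applied in that order.
#'
#' @param p_hflip,p_vflip Flip probabilities (defaults 0.5).
#' @param max_rotation_deg Maximum rotation angle in degrees (default 35).
#' @param noise_sigma Gaussian noise standard deviation as a fraction of the
#'   dynamic range (default 0.01).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(p_hflip = 0.5, p_vflip = 0.5,
                           max_rotation_deg = 35, noise_sigma = 0.01) {
  stopifnot(p_hflip >= 0, p_hflip <= 1, p_vflip >= 0, p_vflip <= 1,
            max_rotation_deg >= 0, noise_sigma >= 0)
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip,
                 max_rotation_deg = max_rotation_deg,
                 noise_sigma = noise_sigma),
            class = "augment_config")
}

#' Rotate an image about its centre
#'
#' Inverse-mapped rotation with bilinear interpolation; source coordinates
#' outside the image are clamped to the nearest edge pixel (edge-value
#' fill), so no artificial background colour is introduced.
#'
#' @param image A (3, H, W) array.
#' @param angle_deg Rotation angle in degrees (counter-clockwise).
#' @return The rotated (3, H, W) array.
#' @export
rotate_image <- function(image, angle_deg) {
  d <- dim(image)
  H <- d[2]; W <- d[3]
  th <- angle_deg * pi / 180
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  gi <- matrix(seq_len(H), H, W) - ci
  gj <- matrix(seq_len(W), H, W, byrow = TRUE) - cj
  si <- pmin(H, pmax(1, ci + cos(th) * gi + sin(th) * gj))
  sj <- pmin(W, pmax(1, cj - sin(th) * gi + cos(th) * gj))
  i0 <- floor(si); j0 <- floor(sj)
  i1 <- pmin(H, i0 + 1); j1 <- pmin(W, j0 + 1)
  fi <- si - i0; fj <- sj - j0
  out <- array(0, d)
  for (ch in 1:3) {
    f <- image[ch, , ]
    v <- (1 - fi) * (1 - fj) * f[cbind(c(i0), c(j0))] +
      (1 - fi) * fj * f[cbind(c(i0), c(j1))] +
      fi * (1 - fj) * f[cbind(c(i1), c(j0))] +
      fi * fj * f[cbind(c(i1), c(j1))]
    out[ch, , ] <- v
  }
  out
}

#' Apply the stochastic augmentation recipe to one image
#'
#' Applies, in order: horizontal flip with probability `p_hflip`, vertical
#' flip with probability `p_vflip`, rotation by an angle drawn uniformly
#' from `[0, max_rotation_deg]`, and additive Gaussian noise clipped back to
#' `[0, 1]`. The result is fully determined by `rng_state`.
#'
#' @param image A (3, H, W) array with values in `[0, 1]`.
#' @param config An [augment_config()].
#' @param rng_state Integer seed driving all random draws.
#' @return The augmented image; same shape, values in `[0, 1]`.
#' @export
augment_image <- function(image, config = augment_config(), rng_state = 1L) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[1] != 3L) {
    stop("image must be a (3, H, W) array")
  }
  if (any(image < 0 | image > 1)) stop("image values must lie in [0, 1]")
  with_seed(rng_state, {
    dr <- augment_draws(config)
    if (dr$hflip) image <- image[, , rev(seq_len(d[3]))]
    if (dr$vflip) image <- image[, rev(seq_len(d[2])), ]
    if (dr$angle > 0) image <- rotate_image(image, dr$angle)
    if (config$noise_sigma > 0) {
      image <- image + array(stats::rnorm(length(image),
                                          sd = config$noise_sigma), d)
    }
    pmin(pmax(image, 0), 1)
  })
}

# The stochastic choices of one augmentation, taken from the current RNG
# stream: flip indicators and the uniform rotation angle.
augment_draws <- function(config) {
  u <- stats::runif(2L)
  list(hflip = u[1] < config$p_hflip,
       vflip = u[2] < config$p_vflip,
       angle = stats::runif(1L, 0, config$max_rotation_deg))
}

#' Stratified train/validation/test split
#'
#' Splits a labeled image set per class: each class's items are shuffled
#' (seeded) and `floor(n * r_val)` go to validation, `floor(n * r_test)` to
#' test, and the remainder to training, where the fractions come from
#' `ratios` (default 6:2:2). The partitions are disjoint and exhaustive.
#'
#' @param set A [labeled_image_set()].
#' @param ratios Positive numeric triple, default `c(6, 2, 2)`.
#' @param seed Integer seed for the per-class shuffles.
#' @return A list with elements `train`, `val`, `test`, each a
#'   `labeled_image_set` sharing the original vocabulary.
#' @export
split_dataset <- function(set, ratios = c(6, 2, 2), seed = 1L) {
  stopifnot(inherits(set, "labeled_image_set"), length(ratios) == 3L,
            all(ratios > 0))
  if (!length(set$items)) stop("cannot split an empty set")
  labs <- vapply(set$items, `[[`, numeric(1), "label")
  s <- sum(ratios)
  parts <- list(train = integer(), val = integer(), test = integer())
  with_seed(seed, {
    for (k in c_sort(unique(as.character(labs)))) {
      idx <- which(labs == as.numeric(k))
      n <- length(idx)
      if (n < 3L) {
        stop(sprintf("class %s has only %d items; at least 3 are needed",
                     k, n))
      }
      idx <- idx[sample.int(n)]
      nv <- floor(n * ratios[2] / s)
      nt <- floor(n * ratios[3] / s)
      parts$val <- c(parts$val, idx[seq_len(nv)])
      parts$test <- c(parts$test, idx[nv + seq_len(nt)])
      parts$train <- c(parts$train, idx[-seq_len(nv + nt)])
    }
  })
  lapply(parts, function(ii) {
    labeled_image_set(set$items[ii], set$label_names)
  })
}
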