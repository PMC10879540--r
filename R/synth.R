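# Deterministic synthetic leaf-disease image generator. Renders a leaf-like
# ellipse on a soil-toned background and stamps a class-specific lesion
# motif (spots, rings or stripes of a class-specific colour, count and
# size), so every other module is testable without external downloads. The
# images are cartoons, not photographs: classes separate mainly by lesion
# colour and geometry.

#' Specification of a synthetic leaf-disease image set
#'
#' @param num_classes Number of disease classes (>= 2).
#' @param per_class Images per class (>= 1).
#' @param image_size Side length in pixels (>= 16).
#' @param seed Integer seed; the same spec always expands to byte-identical
#'   pixel data.
#' @param lesion_count_range Integer range of lesions per image
#'   (default 4-7).
#' @param radius_range Lesion radius range as a fraction of the image side
#'   (default 0.07-0.13), sized so lesions carry a clear chromatic signal
#'   relative to the leaf.
#' @param palette Optional `num_classes` x 3 matrix of lesion RGB colours in
#'   `[0, 1]`; the default assigns well-separated non-green hues.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(num_classes = 4L, per_class = 64L,
                           image_size = 64L, seed = 1L,
                           lesion_count_range = c(4L, 7L),
                           radius_range = c(0.07, 0.13),
                           palette = NULL) {
  num_classes <- as.integer(num_classes)
  per_class <- as.integer(per_class)
  image_size <- as.integer(image_size)
  if (num_classes < 2L) stop("num_classes must be at least 2")
  if (per_class < 1L) stop("per_class must be at least 1")
  if (image_size < 16L) {
    stop("image_size too small for lesion motifs (minimum 16)")
  }
  if (is.null(palette)) {
    # hues confined to [0.55, 1.25) mod 1: blues through reds to orange,
    # staying clear of the leaf's green band so lesions are chromatically
    # distinct from healthy tissue
    hues <- (0.55 + 0.70 * (seq_len(num_classes) - 1L) / num_classes) %% 1
    palette <- t(grDevices::col2rgb(grDevices::hsv(hues, 0.85, 0.9))) / 255
  }
  stopifnot(nrow(palette) == num_classes, ncol(palette) == 3L)
  structure(list(num_classes = num_classes, per_class = per_class,
                 image_size = image_size, seed = as.integer(seed),
                 lesion_count_range = as.integer(lesion_count_range),
                 radius_range = radius_range, palette = palette),
            class = "synthetic_spec")
}

# Stamp one lesion onto (S,S) channel matrices in place.
stamp_lesion <- function(img, type, cx, cy, r, col, leaf_mask, gx, gy) {
  mask <- switch(type,
    spot = (gx - cx)^2 + (gy - cy)^2 <= r^2,
    ring = {
      d2 <- (gx - cx)^2 + (gy - cy)^2
      d2 <= r^2 & d2 >= (0.55 * r)^2
    },
    stripe = {
      th <- atan2(cy - nrow(gx) / 2, cx - ncol(gx) / 2)
      abs((gx - cx) * sin(th) - (gy - cy) * cos(th)) <= 0.5 * r
    })
  mask <- mask & leaf_mask
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[mask] <- 0.1 * pl[mask] + 0.9 * col[ch]
    img[, , ch] <- pl
  }
  img
}

render_leaf_image <- function(spec, class_k) {
  S <- spec$image_size
  gx <- matrix(seq_len(S), S, S)                 # row (y) coordinate
  gy <- matrix(seq_len(S), S, S, byrow = TRUE)   # column (x) coordinate
  img <- array(0, c(S, S, 3L))
  bg <- c(0.42, 0.32, 0.20) + stats::runif(3L, -0.04, 0.04)
  for (ch in 1:3) {
    img[, , ch] <- bg[ch] + matrix(stats::rnorm(S * S, sd = 0.02), S, S)
  }
  # leaf ellipse with jittered centre, axes and orientation
  cx <- S / 2 + stats::runif(1L, -0.04, 0.04) * S
  cy <- S / 2 + stats::runif(1L, -0.04, 0.04) * S
  a <- stats::runif(1L, 0.33, 0.40) * S
  b <- stats::runif(1L, 0.25, 0.32) * S
  th <- stats::runif(1L, 0, pi)
  u <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
  v <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
  leaf <- (u / a)^2 + (v / b)^2 <= 1
  leaf_col <- c(0.20, 0.52, 0.16) + stats::runif(3L, -0.04, 0.04)
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[leaf] <- leaf_col[ch] + stats::rnorm(sum(leaf), sd = 0.02)
    img[, , ch] <- pl
  }
  # class motif
  type <- c("spot", "ring", "stripe")[(class_k - 1L) %% 3L + 1L]
  col <- spec$palette[class_k, ]
  n_lesions <- sample(seq(spec$lesion_count_range[1],
                          spec$lesion_count_range[2]), 1L)
  inside <- which(leaf)
  for (i in seq_len(n_lesions)) {
    pos <- inside[sample.int(length(inside), 1L)]
    r <- stats::runif(1L, spec$radius_range[1], spec$radius_range[2]) * S
    img <- stamp_lesion(img, type, (pos - 1L) %% S + 1L,
                        (pos - 1L) %/% S + 1L, r, col, leaf, gx, gy)
  }
  aperm(pmin(pmax(img, 0), 1), c(3L, 1L, 2L))    # (C, H, W)
}

#' Generate a deterministic synthetic leaf-disease image set
#'
#' Renders `num_classes * per_class` images: each has a leaf-like green
#' ellipse on a soil-toned background, stamped with the class's lesion
#' motif (class-specific colour and shape, per-image positional jitter).
#' The output is balanced across classes and byte-identical for the same
#' spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A [labeled_image_set()] with classes named `"class_00"`,
#'   `"class_01"`, ...
#' @examples
#' set <- generate_synthetic_dataset(synthetic_spec(num_classes = 2,
#'                                                  per_class = 3,
#'                                                  image_size = 32))
#' length(set$items)  # 6
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    items <- vector("list", spec$num_classes * spec$per_class)
    i <- 0L
    for (k in seq_len(spec$num_classes)) {
      for (j in seq_len(spec$per_class)) {
        i <- i + 1L
        items[[i]] <- list(image = render_leaf_image(spec, k),
                           label = k - 1L)
      }
    }
    labeled_image_set(items,
                      sprintf("class_%02d", seq_len(spec$num_classes) - 1L))
  })
}

#' Write a labeled image set as a class-per-directory PNG tree
#'
#' Produces the same folder layout that [load_image_folder()] reads, which
#' makes the generator usable as a fixture writer for command-line runs.
#'
#' @param set A [labeled_image_set()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_image_folder <- function(set, dir) {
  stopifnot(inherits(set, "labeled_image_set"))
  counts <- integer(length(set$label_names))
  for (it in set$items) {
    cls <- set$label_names[it$label + 1L]
    sub <- file.path(dir, cls)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    counts[it$label + 1L] <- counts[it$label + 1L] + 1L
    png::writePNG(aperm(it$image, c(2L, 3L, 1L)),
                  file.path(sub, sprintf("img_%04d.png",
                                         counts[it$label + 1L])))
  }
  invisible(dir)
}
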