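# Grad-CAM: gradient-weighted class activation mapping at a chosen stage.

#' Grad-CAM heatmap for one image and class
#'
#' Runs the network in evaluation mode, takes the gradient of the
#' target-class logit (pre-softmax score) with respect to the chosen stage's
#' activation, averages that gradient spatially into per-channel weights,
#' forms the rectified weighted channel sum, upsamples it bilinearly to the
#' input resolution and min-max normalises it to `[0, 1]` (a constant map
#' normalises to all zeros).
#'
#' @param net An `ercp_network`.
#' @param image A (3, S, S) array with `S == config$input_size`.
#' @param target_class 0-based class index in `[0, num_classes)`.
#' @param layer_name Name of a recorded stage output (see
#'   [shape_summary()] for the names, e.g. `"ACA-Block_3"`); default is the
#'   last attention stage (or the last CER stage for the plain variant).
#' @return An S x S matrix of class `heatmap` with values in `[0, 1]`.
#' @export
grad_cam <- function(net, image, target_class, layer_name = NULL) {
  cfg <- net$config
  if (target_class < 0 || target_class >= cfg$num_classes) {
    stop(sprintf("target_class must lie in [0, %d)", cfg$num_classes))
  }
  x <- fm_to_hwcn(image)
  net_forward(net, x, train = FALSE, record = TRUE)
  att <- attention_label(cfg$variant)
  valid <- setdiff(names(net$acts),
                   c("Input", "Global average pool",
                     "Fully connected layer"))
  if (is.null(layer_name)) {
    layer_name <- if (is.null(att)) {
      sprintf("CER-Block_%d", cfg$num_stages)
    } else {
      sprintf("%s_%d", att, cfg$num_stages)
    }
  }
  if (!layer_name %in% valid) {
    stop("unknown layer name '", layer_name, "'; valid layers: ",
         paste(valid, collapse = ", "))
  }
  dlogits <- matrix(0, cfg$num_classes, 1L)
  dlogits[target_class + 1L, 1L] <- 1
  net_backward(net, dlogits, record = TRUE)
  A <- net$acts[[layer_name]]
  G <- net$act_grads[[layer_name]]
  if (is.null(G)) {
    stop("no gradient is recorded at layer '", layer_name,
         "' (stem sub-layers are not Grad-CAM targets)")
  }
  d <- dim(A)
  Am <- A; dim(Am) <- c(d[1] * d[2], d[3])
  Gm <- G; dim(Gm) <- c(d[1] * d[2], d[3])
  w <- colMeans(Gm)
  cam <- matrix(pmax(Am %*% w, 0), d[1], d[2])
  S <- dim(x)[1:2]
  Lh <- interp_matrix(S[1], d[1], "bilinear")
  Lw <- interp_matrix(S[2], d[2], "bilinear")
  up <- Lh %*% cam %*% t(Lw)
  rng <- max(up) - min(up)
  hm <- if (rng < 1e-12) {
    matrix(0, S[1], S[2])
  } else {
    (up - min(up)) / rng
  }
  structure(hm, class = c("heatmap", class(hm)))
}

#' Overlay a heatmap on an image
#'
#' Blends a blue-to-red colour ramp of the heatmap with the original image,
#' for visual inspection of the attended regions.
#'
#' @param image A (3, H, W) array in `[0, 1]`.
#' @param heatmap An H x W matrix in `[0, 1]` from [grad_cam()].
#' @param alpha Blend weight of the heatmap colours (default 0.5).
#' @return A (3, H, W) array in `[0, 1]`.
#' @export
gradcam_overlay <- function(image, heatmap, alpha = 0.5) {
  h <- as.numeric(heatmap)
  ramp <- rbind(pmin(1, 2 * h),                       # red rises
                pmax(0, 1 - abs(2 * h - 1)),          # green mid
                pmax(0, 1 - 2 * h))                   # blue falls
  d <- dim(image)
  col <- array(0, d)
  for (ch in 1:3) col[ch, , ] <- matrix(ramp[ch, ], d[2], d[3])
  pmin(pmax((1 - alpha) * image + alpha * col, 0), 1)
}
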