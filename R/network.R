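# Network assembly: stem + three CER(+attention) stages + head, in four
# ablation variants, with the printed layer/tensor-size contract exposed
# through shape_summary().

#' Network configuration
#'
#' Describes one of the four network variants:
#' * `er_net` - stem + 3 CER stages + classification head (432 features);
#' * `er_net_cbam` - each CER stage followed by a CBAM block;
#' * `erc_net` - each CER stage followed by an ACA block;
#' * `ercp_net` (default) - `erc_net` plus the BIF fusion head on the
#'   stage-2/stage-3 outputs (1296 features).
#'
#' Stage k emits `stem_width * 3^k` channels, so the default progression is
#' 16 -> 48 -> 144 -> 432, and the BIF head expands to 1296.
#'
#' @param variant One of `"er_net"`, `"er_net_cbam"`, `"erc_net"`,
#'   `"ercp_net"`.
#' @param stem_width Channel width of the stem convolution (default 16).
#' @param num_stages Number of CER stages (default 3).
#' @param num_classes Number of output classes (default 38).
#' @param input_size Input image side length; must be divisible by
#'   `2^(num_stages + 2)` (default 416).
#' @param igpdf An [igpdf_params()] object for the ACA kernel-size rule.
#' @param combination ACA composition mode, `"multiplicative"` or
#'   `"additive"`.
#' @param reduction_ratio CBAM reduction ratio (default 16).
#' @param bif_out_channels Output channels of the BIF head; default
#'   `3 * stem_width * 3^num_stages`.
#' @param upsample_mode Upsampling mode inside the BIF head.
#' @param use_batchnorm Logical; default `TRUE`.
#' @param seed Optional integer seed controlling parameter initialisation in
#'   [build_network()].
#' @return An object of class `network_config`.
#' @export
network_config <- function(variant = c("ercp_net", "er_net", "er_net_cbam",
                                       "erc_net"),
                           stem_width = 16L, num_stages = 3L,
                           num_classes = 38L, input_size = 416L,
                           igpdf = igpdf_params(),
                           combination = c("multiplicative", "additive"),
                           reduction_ratio = 16L,
                           bif_out_channels = NULL,
                           upsample_mode = c("nearest", "bilinear"),
                           use_batchnorm = TRUE, seed = NULL) {
  variant <- match.arg(variant)
  combination <- match.arg(combination)
  upsample_mode <- match.arg(upsample_mode)
  stem_width <- as.integer(stem_width)
  num_stages <- as.integer(num_stages)
  num_classes <- as.integer(num_classes)
  input_size <- as.integer(input_size)
  stopifnot(stem_width >= 1L, num_stages >= 1L)
  if (num_classes < 2L) stop("num_classes must be at least 2")
  if (input_size %% 2L^(num_stages + 2L) != 0L) {
    stop(sprintf("input_size %d must be divisible by 2^(num_stages + 2) = %d",
                 input_size, 2L^(num_stages + 2L)))
  }
  if (variant == "ercp_net" && num_stages < 2L) {
    stop("the fusion-head variant needs at least 2 stages")
  }
  deep <- as.integer(stem_width * 3L^num_stages)
  structure(list(variant = variant, stem_width = stem_width,
                 num_stages = num_stages, num_classes = num_classes,
                 input_size = input_size, igpdf = igpdf,
                 combination = combination,
                 reduction_ratio = as.integer(reduction_ratio),
                 bif_out_channels = as.integer(bif_out_channels %||%
                                                 (3L * deep)),
                 upsample_mode = upsample_mode,
                 use_batchnorm = isTRUE(use_batchnorm),
                 seed = seed),
            class = "network_config")
}

attention_label <- function(variant) {
  switch(variant,
         er_net = NULL,
         er_net_cbam = "CBAM-Block",
         erc_net = "ACA-Block",
         ercp_net = "ACA-Block")
}

#' Build a network from a configuration
#'
#' Parameter initialisation is fan-scaled Gaussian and fully controlled by
#' `config$seed`: two builds with the same seed have bitwise-identical
#' initial parameters.
#'
#' @param config A [network_config()] object.
#' @return An object of class `ercp_network`.
#' @examples
#' cfg <- network_config("ercp_net", num_classes = 5, seed = 1)
#' net <- build_network(cfg)
#' count_parameters(net)
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  build <- function() {
    net <- new.env(parent = emptyenv())
    net$config <- config
    net$stem <- nn_stem(config$stem_width, config$use_batchnorm)
    net$stages <- vector("list", config$num_stages)
    for (k in seq_len(config$num_stages)) {
      cin <- as.integer(config$stem_width * 3L^(k - 1L))
      cer <- nn_cer(cer_config(cin, use_batchnorm = config$use_batchnorm))
      att <- switch(config$variant,
                    er_net = NULL,
                    er_net_cbam = nn_cbam(3L * cin, config$reduction_ratio),
                    nn_aca(3L * cin, config$igpdf, config$combination))
      net$stages[[k]] <- list(cer = cer, att = att)
    }
    deep <- as.integer(config$stem_width * 3L^config$num_stages)
    if (config$variant == "ercp_net") {
      mid <- as.integer(config$stem_width * 3L^(config$num_stages - 1L))
      net$bif <- nn_bif(bif_config(mid, deep,
                                   out_channels = config$bif_out_channels,
                                   upsample_mode = config$upsample_mode,
                                   use_batchnorm = config$use_batchnorm))
      feat <- config$bif_out_channels
    } else {
      net$bif <- NULL
      feat <- deep
    }
    net$gap <- nn_gap()
    net$fc <- nn_linear(feat, config$num_classes, bias = TRUE)
    net$feat <- feat
    class(net) <- "ercp_network"
    net
  }
  with_seed(config$seed, build())
}

net_components <- function(net) {
  att <- attention_label(net$config$variant)
  out <- list(stem = net$stem)
  for (k in seq_along(net$stages)) {
    out[[sprintf("CER-Block_%d", k)]] <- net$stages[[k]]$cer
    if (!is.null(att)) {
      out[[sprintf("%s_%d", att, k)]] <- net$stages[[k]]$att
    }
  }
  if (!is.null(net$bif)) out[["BIF-Block"]] <- net$bif
  out[["Fully connected layer"]] <- net$fc
  out
}

# Internal forward on a (H,W,C,N) tensor; returns logits (K x N). With
# record = TRUE the named stage activations are stashed on the network for
# shape tracing and Grad-CAM.
net_forward <- function(net, x, train = FALSE, record = FALSE) {
  cfg <- net$config
  att <- attention_label(cfg$variant)
  acts <- list()
  rec <- function(name, val) if (record) acts[[name]] <<- val
  rec("Input", x)
  stem_seq <- net$stem$children$seq$children
  n_conv <- length(stem_seq) - 1L
  h <- x
  d <- dim(x)
  if (d[3] != 3L || d[1] != cfg$input_size || d[2] != cfg$input_size) {
    stop(sprintf(
      "network expects 3 x %d x %d inputs, received %d x %d x %d",
      cfg$input_size, cfg$input_size, d[3], d[1], d[2]))
  }
  for (i in seq_len(n_conv)) h <- nn_forward(stem_seq[[i]], h, train)
  rec("Conv", h)
  h <- nn_forward(stem_seq[[length(stem_seq)]], h, train)
  rec("MaxPool", h)
  stage_out <- vector("list", cfg$num_stages)
  for (k in seq_len(cfg$num_stages)) {
    h <- nn_forward(net$stages[[k]]$cer, h, train)
    rec(sprintf("CER-Block_%d", k), h)
    if (!is.null(net$stages[[k]]$att)) {
      h <- nn_forward(net$stages[[k]]$att, h, train)
      rec(sprintf("%s_%d", att, k), h)
    }
    stage_out[[k]] <- h
  }
  if (!is.null(net$bif)) {
    h <- nn_forward(net$bif,
                    list(p2 = stage_out[[cfg$num_stages - 1L]],
                         p3 = stage_out[[cfg$num_stages]]),
                    train)
    rec("BIF-Block", h)
  }
  feats <- nn_forward(net$gap, h, train)
  rec("Global average pool", feats)
  logits <- nn_forward(net$fc, feats, train)
  rec("Fully connected layer", logits)
  if (record) net$acts <- acts
  logits
}

# Backward from d(loss)/d(logits); accumulates parameter gradients and (with
# record = TRUE) stashes the gradient arriving at each recorded stage
# activation for Grad-CAM.
net_backward <- function(net, dlogits, record = FALSE) {
  cfg <- net$config
  att <- attention_label(cfg$variant)
  grads <- list()
  rec <- function(name, val) if (record) grads[[name]] <<- val
  g <- nn_backward(net$fc, dlogits)
  g <- nn_backward(net$gap, g)
  ns <- cfg$num_stages
  if (!is.null(net$bif)) {
    rec("BIF-Block", g)
    gb <- nn_backward(net$bif, g)
    g_stage <- gb$p3
    g_mid_extra <- gb$p2
  } else {
    g_stage <- g
    g_mid_extra <- NULL
  }
  for (k in rev(seq_len(ns))) {
    if (!is.null(net$stages[[k]]$att)) {
      rec(sprintf("%s_%d", att, k), g_stage)
      g_stage <- nn_backward(net$stages[[k]]$att, g_stage)
    }
    rec(sprintf("CER-Block_%d", k), g_stage)
    g_stage <- nn_backward(net$stages[[k]]$cer, g_stage)
    if (!is.null(g_mid_extra) && k == ns) {
      g_stage <- g_stage + g_mid_extra
      g_mid_extra <- NULL
    }
  }
  gx <- nn_backward(net$stem, g_stage)
  if (record) net$act_grads <- grads
  invisible(gx)
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

as_batch_hwcn <- function(batch) {
  d <- dim(batch)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("batch must be a (C,H,W) array or an (N,C,H,W) array")
  }
  fm_to_hwcn(batch)
}

#' Class probabilities for a batch of images
#'
#' Runs the network in evaluation mode (batch-norm uses running statistics,
#' so the pass is deterministic) and applies a softmax to the logits.
#'
#' @param object An `ercp_network` built by [build_network()].
#' @param newdata A (3, S, S) array or an (N, 3, S, S) batch, with
#'   `S == config$input_size`.
#' @param ... Unused.
#' @return An N x K matrix of class probabilities; each row sums to 1.
#' @export
predict.ercp_network <- function(object, newdata, ...) {
  x <- as_batch_hwcn(newdata)
  logits <- net_forward(object, x, train = FALSE)
  t(softmax_cols(logits))
}

#' Layer-by-layer output shapes
#'
#' Runs one tracing forward pass and records the output shape of every named
#' layer, in architectural order: Input, stem Conv and MaxPool, each CER and
#' attention stage, the BIF head (if present), global average pooling, the
#' fully connected layer input width and the softmax output width.
#'
#' @param net An `ercp_network`.
#' @param input_shape Optional `c(C, H, W)` triple; defaults to
#'   `c(3, input_size, input_size)`.
#' @return A data frame with columns `layer`, `channels`, `height`, `width`
#'   (the latter two `NA` for the vector-valued head layers).
#' @examples
#' net <- build_network(network_config(input_size = 64, stem_width = 4,
#'                                     num_classes = 3, seed = 1))
#' shape_summary(net)
#' @export
shape_summary <- function(net, input_shape = NULL) {
  cfg <- net$config
  input_shape <- input_shape %||% c(3L, cfg$input_size, cfg$input_size)
  x <- array(0, c(input_shape[2], input_shape[3], input_shape[1], 1L))
  net_forward(net, x, train = FALSE, record = TRUE)
  acts <- net$acts
  rows <- lapply(names(acts), function(nm) {
    a <- acts[[nm]]
    if (nm == "Global average pool") {
      data.frame(layer = nm, channels = nrow(a), height = 1L, width = 1L)
    } else if (nm == "Fully connected layer") {
      data.frame(layer = nm, channels = net$feat, height = NA_integer_,
                 width = NA_integer_)
    } else {
      d <- dim(a)
      data.frame(layer = nm, channels = d[3], height = d[1], width = d[2])
    }
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(layer = "Softmax",
                               channels = cfg$num_classes,
                               height = NA_integer_, width = NA_integer_))
  rownames(out) <- NULL
  out
}

#' Total learnable parameter count
#'
#' @param net An `ercp_network`.
#' @return Integer: the number of learnable scalars across all layers. See
#'   [parameter_table()] for the per-layer breakdown.
#' @export
count_parameters <- function(net) {
  comps <- net_components(net)
  as.integer(sum(vapply(comps, nn_n_params, numeric(1))))
}

#' Per-layer parameter counts
#'
#' @param net An `ercp_network`.
#' @return A data frame with columns `layer` and `parameters`; pooling and
#'   concatenation stages contribute zero and are not listed.
#' @export
parameter_table <- function(net) {
  comps <- net_components(net)
  data.frame(layer = names(comps),
             parameters = vapply(comps, nn_n_params, numeric(1)))
}

#' @export
print.ercp_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ercp_network> variant=%s  input=%dx%d  classes=%d  parameters=%s\n",
              cfg$variant, cfg$input_size, cfg$input_size, cfg$num_classes,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
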