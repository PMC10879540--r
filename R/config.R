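# Key-value (YAML) configuration files for the command-line interface.

#' Read a network/training configuration file
#'
#' The file is YAML with optional top-level sections `network`, `train` and
#' `augment`; keys mirror the arguments of [network_config()],
#' [train_config()] and [augment_config()], with the kernel-size rule
#' parameters nested under `network: igpdf: {mu, sigma,
#' channel_normalizer}`. Missing keys fall back to the package defaults.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `network`, `train` and `augment` (the last
#'   `NULL` unless an `augment` section is present).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such configuration file: ", path)
  raw <- yaml::read_yaml(path)
  nw <- raw$network %||% list()
  ig <- nw$igpdf %||% list()
  igp <- igpdf_params(mu = ig$mu %||% 0, sigma = ig$sigma %||% 1,
                      channel_normalizer = ig$channel_normalizer %||% 2048)
  netcfg <- network_config(
    variant = nw$variant %||% "ercp_net",
    stem_width = nw$stem_width %||% 16L,
    num_stages = nw$num_stages %||% 3L,
    num_classes = nw$num_classes %||% 38L,
    input_size = nw$input_size %||% 416L,
    igpdf = igp,
    combination = nw$combination %||% "multiplicative",
    reduction_ratio = nw$reduction_ratio %||% 16L,
    bif_out_channels = nw$bif_out_channels,
    upsample_mode = nw$upsample_mode %||% "nearest",
    use_batchnorm = nw$use_batchnorm %||% TRUE,
    seed = nw$seed)
  tr <- raw$train %||% list()
  traincfg <- train_config(
    batch_size = tr$batch_size %||% 16L,
    init_lr = tr$init_lr %||% 0.01,
    epochs = tr$epochs %||% 100L,
    momentum = tr$momentum %||% 0.9,
    weight_decay = tr$weight_decay %||% 1e-4,
    lr_decay_factor = tr$lr_decay_factor %||% 0.3,
    patience_epochs = tr$patience_epochs %||% 3L,
    seed = tr$seed %||% 1L)
  aug <- NULL
  if (!is.null(raw$augment)) {
    a <- raw$augment
    aug <- augment_config(p_hflip = a$p_hflip %||% 0.5,
                          p_vflip = a$p_vflip %||% 0.5,
                          max_rotation_deg = a$max_rotation_deg %||% 35,
                          noise_sigma = a$noise_sigma %||% 0.01)
  }
  list(network = netcfg, train = traincfg, augment = aug)
}
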