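# Versioned, self-describing checkpoints: the network configuration travels
# with the parameters, so a checkpoint alone is enough to rebuild the model.

#' Save a network checkpoint
#'
#' Writes a versioned RDS file embedding the [network_config()] plus every
#' parameter and batch-norm buffer; [load_checkpoint()] rebuilds the network
#' from it on any machine.
#'
#' @param net An `ercp_network`.
#' @param path Output file path.
#' @param extra Optional named list stored alongside (e.g. label names,
#'   training history).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  stopifnot(inherits(net, "ercp_network"))
  obj <- list(format = "ercpnet-checkpoint", version = 1L,
              config = net$config,
              state = lapply(net_components(net), nn_state),
              extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A list with `net` (the rebuilt `ercp_network`) and `extra`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "ercpnet-checkpoint")) {
    stop("not an ercpnet checkpoint: ", path)
  }
  if (obj$version > 1L) {
    stop("checkpoint version ", obj$version, " is newer than this package")
  }
  net <- build_network(obj$config)
  comps <- net_components(net)
  if (!setequal(names(comps), names(obj$state))) {
    stop("checkpoint layer names do not match the rebuilt network")
  }
  for (nm in names(comps)) nn_load_state(comps[[nm]], obj$state[[nm]])
  list(net = net, extra = obj$extra)
}
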