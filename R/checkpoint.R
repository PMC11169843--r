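#' Save a training checkpoint
#'
#' Serialises the architecture string, input shape, all weights and
#' thresholds, the leak, the stage tag, the epoch counter and the RNG
#' seed to a JSON file with full double precision, so that a re-train
#' stage (or an analysis run) can resume exactly where a pre-train stage
#' stopped.
#'
#' @param params An `scnn_params` object.
#' @param arch The matching `scnn_arch`.
#' @param path Destination file.
#' @param stage Stage tag recorded in the file.
#' @param epoch Epoch counter recorded in the file.
#' @param seed Seed recorded in the file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, arch, path, stage = "pretrain",
                            epoch = 0L, seed = NA_integer_) {
  stopifnot(inherits(params, "scnn_params"), inherits(arch, "scnn_arch"))
  # doubles are stored as %.17g strings: that many significant digits
  # round-trip IEEE doubles exactly, which plain JSON numbers do not
  # guarantee through every writer
  payload <- list(
    format = "dtscnn-checkpoint",
    version = 1L,
    arch = arch$text,
    input_shape = arch$input_shape,
    leak = sprintf("%.17g", params$leak),
    stage = stage,
    epoch = as.integer(epoch),
    seed = seed,
    layers = lapply(params$layers, function(l) {
      if (is.null(l)) return(list(kind = "pool"))
      out <- list(w = sprintf("%.17g", as.vector(l$W)), w_dim = dim(l$W))
      if (!is.null(l$vth)) out$vth <- sprintf("%.17g", l$vth)
      out
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return List with `params`, `arch`, `stage`, `epoch`, `seed`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("no such checkpoint: %s", path), call. = FALSE)
  }
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) stop("corrupt checkpoint archive: ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(payload$format, "dtscnn-checkpoint")) {
    stop("not a checkpoint archive", call. = FALSE)
  }
  if (!identical(as.integer(payload$version), 1L)) {
    stop(sprintf("unsupported checkpoint version %s", payload$version),
         call. = FALSE)
  }
  arch <- parse_arch(payload$arch, payload$input_shape)
  layers <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    pl <- payload$layers[[i]]
    if (is.null(pl$w)) next
    l <- list(W = matrix(as.numeric(pl$w), pl$w_dim[1], pl$w_dim[2]))
    if (!is.null(pl$vth)) l$vth <- as.numeric(pl$vth)
    layers[[i]] <- l
  }
  params <- structure(list(leak = as.numeric(payload$leak), layers = layers,
                           arch_text = payload$arch),
                      class = "scnn_params")
  list(params = params, arch = arch, stage = payload$stage,
       epoch = as.integer(payload$epoch), seed = payload$seed)
}

#' Read a training configuration file
#'
#' YAML (or JSON, which YAML subsumes) files with keys matching
#' [train_config()] arguments: `timesteps`, `lr`, `lr_decay`,
#' `decay_interval`, `epochs`, `batch_size`, `dropout`, `leak`, `seed`,
#' `stage`, `pooling`, `temporal_membrane_path`, plus free keys such as
#' `arch`, `input_shape` and dataset settings which are returned
#' alongside.
#'
#' @param path Config file.
#' @param overrides Named list applied on top of the file (flags win over
#'   file values).
#' @return List with `cfg` (a [train_config()]) and `extra` (the
#'   remaining keys).
#' @export
read_train_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  known <- c("timesteps", "lr", "lr_decay", "decay_interval", "epochs",
             "leak", "dropout_p", "batch_size", "seed", "stage",
             "pooling", "temporal_membrane_path", "threshold_init",
             "threshold_floor", "momentum")
  if (!is.null(raw$dropout) && is.null(raw$dropout_p)) {
    raw$dropout_p <- raw$dropout
  }
  args <- raw[intersect(names(raw), known)]
  cfg <- do.call(train_config, args)
  list(cfg = cfg, extra = raw[setdiff(names(raw), c(known, "dropout"))])
}
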