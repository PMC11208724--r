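# Plain-text (JSON) model checkpoints: parameter tensors plus a manifest
# (dimensions, vocabulary hash, configuration, seed) sufficient to reload
# and replay a run.

#' Save a fitted model to a JSON checkpoint
#'
#' @param model A `cliffopt_model`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_cliffopt <- function(model, path) {
  ser_params <- lapply(model$params, function(m) {
    list(dim = dim(m), data = as.vector(m))
  })
  payload <- list(
    format = "cliffopt-checkpoint-1",
    vocab_hash = model$vocab_hash,
    config = unclass(model$config),
    best_epoch = model$best_epoch,
    params = ser_params,
    history = if (!is.null(model$history)) as.data.frame(model$history) else NULL
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [write_cliffopt()].
#' @return A `cliffopt_model`.
#' @export
read_cliffopt <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "cliffopt-checkpoint-1")) {
    stop("not a cliffopt checkpoint")
  }
  if (!identical(payload$vocab_hash, vocabulary_hash())) {
    stop("checkpoint was written under a different element vocabulary")
  }
  params <- lapply(payload$params, function(p) {
    matrix(p$data, p$dim[1], p$dim[2])
  })
  cfg <- do.call(cliffopt_config, payload$config[names(payload$config) %in%
                                                   names(formals(cliffopt_config))])
  structure(
    list(params = params, final_params = params, best_params = params,
         best_epoch = payload$best_epoch, config = cfg,
         history = if (!is.null(payload$history))
           tibble::as_tibble(payload$history) else NULL,
         vocab_hash = payload$vocab_hash),
    class = "cliffopt_model"
  )
}

#' Write a run manifest
#'
#' Records seed, configuration hash, vocabulary hash and timestamps before
#' a run writes any artifact, so the run can be replayed.
#'
#' @param path Output JSON path.
#' @param seed Integer seed of the run.
#' @param config The configuration list in force.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, config) {
  cfg_txt <- paste(names(unlist(config)), unlist(config), collapse = ";")
  jsonlite::write_json(
    list(seed = seed, config_hash = .text_hash(cfg_txt),
         vocabulary_hash = vocabulary_hash(),
         package_version = as.character(utils::packageVersion("cliffopt")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE)
  invisible(path)
}
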