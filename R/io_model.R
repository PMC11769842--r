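# Plain-text model persistence: config as YAML, parameters as JSON with
# explicit array dims, so model directories are portable and diffable.

serialize_obj <- function(x) {
  if (is.array(x) || is.matrix(x)) {
    list(.array = TRUE, dim = dim(x), data = as.numeric(x))
  } else if (is.list(x)) {
    lapply(x, serialize_obj)
  } else {
    x
  }
}

deserialize_obj <- function(x) {
  if (is.list(x)) {
    if (isTRUE(x$.array)) {
      return(array(as.numeric(unlist(x$data)), unlist(x$dim)))
    }
    return(lapply(x, deserialize_obj))
  }
  x
}

#' Write a model to a directory
#'
#' Writes `config.yaml` and `params.json` (plain text).
#'
#' @param model an [assemble_model()] result (fitted or not).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- unclass(model$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  par <- model$params
  par$basis <- NULL  # regenerated deterministically from the config
  jsonlite::write_json(serialize_obj(par), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a model from a directory written by [write_model()]
#'
#' @param dir model directory.
#' @return an `equiace_model`.
#' @export
read_model <- function(dir) {
  cfg_l <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(model_config, c(
    list(preset = "custom"),
    cfg_l[c("elements", "r_cut", "T", "nu", "l_max", "L_max", "n_channels",
            "embedding", "radial_mode", "coupling", "nonlinearity", "readout",
            "lambda", "lambda_mode", "n_basis", "p", "mlp_widths",
            "max_poly_degree", "envelope", "init", "seed")]
  ))
  cfg$preset <- cfg_l$preset
  model <- assemble_model(cfg)
  stored <- deserialize_obj(jsonlite::read_json(file.path(dir, "params.json"),
                                                simplifyVector = FALSE))
  model$params <- restore_params(model$params, stored)
  model
}

# Overlay stored numeric parameters onto the freshly assembled skeleton
# (keeps e.g. the regenerated delta-basis table).
restore_params <- function(skel, stored) {
  for (nm in names(stored)) {
    if (nm == "basis") next
    val <- stored[[nm]]
    ref <- skel[[nm]]
    skel[[nm]] <- align_param(ref, val)
  }
  skel
}

align_param <- function(ref, val) {
  if (is.array(ref) || is.matrix(ref)) {
    src <- if (is.list(val) && !is.null(val$data)) val$data else val
    return(array(as.numeric(unlist(src)), dim(ref)))
  }
  if (is.list(ref)) {
    for (i in seq_along(ref)) {
      if (i <= length(val) && !is.null(val[[i]])) {
        ref[[i]] <- align_param(ref[[i]], val[[i]])
      }
    }
    return(ref)
  }
  if (is.numeric(ref) && length(ref) > 1) {
    return(stats::setNames(as.numeric(unlist(val)), names(ref)))
  }
  v <- unlist(val)
  if (is.null(v)) ref else v
}
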