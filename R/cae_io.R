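## Model checkpoints are a single JSON file: architecture, training control,
## class levels, standardization constants and every weight tensor with its
## dimensions, written with 17 significant digits so doubles round-trip
## exactly.

tensor_to_list <- function(m) list(dim = dim(m) %||% length(m), data = as.vector(m))
tensor_from_list <- function(tl) {
  v <- as.numeric(tl$data)
  if (length(tl$dim) > 1L) array(v, unlist(tl$dim)) else v
}

params_to_json <- function(p) rapply(p, tensor_to_list, how = "replace",
                                     classes = c("matrix", "array", "numeric"))
params_from_json <- function(p) {
  if (is.list(p) && identical(sort(names(p)), c("data", "dim")))
    return(tensor_from_list(p))
  lapply(p, params_from_json)
}

#' Save a fitted CAE as a JSON checkpoint
#'
#' Writes the architecture description, training configuration, class levels,
#' standardization constants and all weights to one JSON file. The format is
#' plain text and round-trips exactly: [read_cae()] restores a model whose
#' predictions are bit-identical.
#'
#' @param object a `"cae"` fit.
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
write_cae <- function(object, file) {
  stopifnot(inherits(object, "cae"))
  payload <- list(
    format = "soilcae-checkpoint",
    version = 1L,
    arch = unclass(object$arch),
    control = unclass(object$control),
    levels = object$levels,
    center = object$center,
    scale = object$scale,
    seed = object$seed,
    training_accuracy = object$training_accuracy,
    history = object$history,
    params = params_to_json(object$params)
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           dataframe = "columns")
  writeLines(json, file)
  invisible(file)
}

#' Restore a CAE from a JSON checkpoint
#'
#' @param file path written by [write_cae()].
#' @return a `"cae"` object.
#' @export
read_cae <- function(file) {
  p <- jsonlite::fromJSON(readLines(file, warn = FALSE),
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE,
                          simplifyVector = TRUE)
  if (!identical(p$format, "soilcae-checkpoint"))
    fail("not a soilcae checkpoint: ", file)
  arch <- p$arch
  arch$blocks <- lapply(arch$blocks, function(b) lapply(b, as.integer))
  arch$input_len <- as.integer(arch$input_len)
  arch$latent <- as.integer(arch$latent)
  arch$classes <- as.integer(arch$classes)
  arch$flat <- as.integer(arch$flat)
  class(arch) <- "cae_architecture"
  control <- p$control
  class(control) <- "cae_control"
  hist <- as.data.frame(p$history, stringsAsFactors = FALSE)
  structure(list(arch = arch, control = control,
                 params = params_from_json(p$params),
                 levels = p$levels,
                 center = unlist(p$center), scale = unlist(p$scale),
                 history = hist, seed = p$seed,
                 training_accuracy = p$training_accuracy,
                 call = NULL),
            class = "cae")
}
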