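# LVQ model serialization: JSON header + base64 little-endian double
# payload for the prototype matrix, so round-trips are bit-exact.

#' Write an LVQ model to disk
#'
#' JSON file holding shapes, the class map, learning settings and the
#' prototype matrix as a base64-encoded little-endian double payload
#' (row-major). [read_lvq_model()] restores the model bit for bit;
#' the training history is not serialized.
#'
#' @param model An `lvq_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lvq_model <- function(model, path) {
  stopifnot(inherits(model, "lvq_model"))
  payload <- writeBin(as.numeric(t(model$prototypes)), raw(),
                      size = 8, endian = "little")
  obj <- list(
    format = "assr-lvq",
    version = "1",
    n_inputs = model$n_inputs,
    hn = nrow(model$prototypes),
    n_classes = model$n_classes,
    classes = model$classes,
    proto_class = model$proto_class,
    alpha = model$alpha,
    epochs = model$epochs,
    epochs_run = model$epochs_run,
    win_counts = model$win_counts,
    trained = model$trained,
    seed = model$seed,
    endian = "little",
    prototypes_base64 = jsonlite::base64_enc(payload)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an LVQ model written by [write_lvq_model()]
#'
#' @param path File path.
#' @return An `lvq_model`.
#' @export
read_lvq_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "assr-lvq")) {
    stop_assr("Not an assr-lvq model file.", class = "assr_format_error")
  }
  if (!identical(obj$version, "1")) {
    stop_assr(sprintf("Unsupported model file version '%s'.", obj$version),
              class = "assr_format_error")
  }
  raw_payload <- jsonlite::base64_dec(obj$prototypes_base64)
  vals <- readBin(raw_payload, numeric(), n = obj$hn * obj$n_inputs,
                  size = 8, endian = "little")
  model <- new_lvq_model(matrix(vals, nrow = obj$hn, byrow = TRUE),
                         obj$proto_class, obj$classes, obj$seed)
  model$alpha <- obj$alpha
  model$epochs <- as.integer(obj$epochs)
  model$epochs_run <- as.integer(obj$epochs_run)
  model$win_counts <- as.integer(obj$win_counts)
  model$trained <- isTRUE(obj$trained)
  model
}
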