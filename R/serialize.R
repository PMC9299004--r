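#' Serialise a fitted model to JSON
#'
#' Writes a versioned JSON document with the node identifiers, the
#' per-level block assignments of both sides, the description-length
#' components, the configuration and the seed.  Identical seeds and
#' configurations produce byte-identical files.
#'
#' @param model A `domain_topic_model` or `chained_model`.
#' @param path Output file; `NULL` returns the JSON string.
#' @return Invisibly `path`, or the JSON string when `path` is `NULL`.
#' @export
write_model_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "domain_topic_model") ||
              inherits(model, "chained_model"))
  obj <- list(
    format = "domtopics-model/1",
    type = class(model)[1L],
    left_nodes = model$graph$left,
    right_nodes = model$graph$right,
    left_type = model$graph$left_type,
    right_type = model$graph$right_type,
    edges = model$graph$edges,
    levels = lapply(model$partition$levels, function(lv)
      list(left = lv$left, right = lv$right)),
    dl_total = model$dl$total,
    dl_components = model$dl$components,
    seed = model$seed,
    config = if (!is.null(model$config)) {
      cf <- unclass(model$config)
      cf$betas <- as.character(cf$betas)   # Inf survives as text
      cf
    })
  if (inherits(model, "chained_model")) {
    obj$field <- model$field
    obj$doc_blocks_present <- model$doc_blocks_present
    obj$left_labels <- model$left_labels
  }
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null")
  if (is.null(json)) stop("serialisation failed")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path, useBytes = TRUE)
  invisible(path)
}

#' Read a model back from JSON
#'
#' @param path Path to a file written by [write_model_json()] (or a JSON
#'   string).
#' @return A `domain_topic_model` or `chained_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "domtopics-model/1"))
    stop("not a recognised model file")
  graph <- bipartite_graph(obj$left_nodes, obj$right_nodes, obj$edges,
                           right_type = obj$right_type)
  levels <- lapply(seq_len(nrow_safe(obj$levels)), function(l)
    list(left = as.integer(obj$levels$left[[l]]),
         right = as.integer(obj$levels$right[[l]])))
  partition <- nested_partition(levels)
  config <- if (!is.null(obj$config)) {
    cf <- obj$config[intersect(names(obj$config), names(formals(fit_config)))]
    cf$betas <- as.numeric(cf$betas)
    do.call(fit_config, cf)
  }
  model <- dtm_from_state(graph, partition, config = config)
  model$seed <- obj$seed
  if (identical(obj$type, "chained_model")) {
    model$field <- obj$field
    model$doc_blocks_present <- as.integer(obj$doc_blocks_present)
    model$left_labels <- obj$left_labels
    class(model) <- "chained_model"
  }
  model
}

nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
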