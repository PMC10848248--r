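# Model container, featurized records, and checkpoint serialization.

#' Build a featurized record for one molecule-conformer pair
#'
#' @param mol A `molecule_record`.
#' @param conformer A matching `conformer` (optional for 2D-only work).
#' @param target Scalar regression target in eV (NA when unlabeled).
#' @param graph Optionally a precomputed `molecular_graph` (graphs are
#'   conformer-independent, so share one per molecule).
#' @return A `reorg_record` list.
#' @export
make_record <- function(mol, conformer = NULL, target = NA_real_, graph = NULL) {
  if (is.null(graph)) graph <- build_graph(mol)
  ic <- if (!is.null(conformer)) extract_internal_coords(mol, conformer) else NULL
  structure(
    list(
      molecule_id = mol$id,
      graph = graph,
      conformer = conformer,
      internal_coords = ic,
      target = as.numeric(target)
    ),
    class = "reorg_record"
  )
}

#' Featurize molecules with their conformer ensembles
#'
#' @param mols List of `molecule_record` objects.
#' @param conformer_sets List (parallel to `mols`) of lists of conformers.
#' @param targets Named numeric vector of targets keyed by molecule id (eV),
#'   or NULL for unlabeled records.
#' @return Flat list of `reorg_record`s, one per molecule-conformer pair.
#' @export
featurize_dataset <- function(mols, conformer_sets, targets = NULL) {
  stopifnot(length(mols) == length(conformer_sets))
  out <- vector("list", sum(lengths(conformer_sets)))
  pos <- 1L
  for (k in seq_along(mols)) {
    graph <- build_graph(mols[[k]])
    tgt <- if (is.null(targets)) NA_real_ else unname(targets[[mols[[k]]$id]])
    for (conf in conformer_sets[[k]]) {
      out[[pos]] <- make_record(mols[[k]], conf, target = tgt, graph = graph)
      pos <- pos + 1L
    }
  }
  out
}

#' Create an untrained model (encoder + regression head)
#'
#' The encoder weights are drawn from `config$init_seed` and fixed; the head
#' is the trainable component.
#'
#' @param config An `encoder_config`.
#' @param task One of `"vertical_ip"`, `"vertical_ea"`, `"lambda_direct"`.
#' @param head_dim Hidden width of the regression head.
#' @return A `reorg_model`.
#' @export
make_model <- function(config, task = "lambda_direct", head_dim = 32L) {
  task <- match.arg(task, c("vertical_ip", "vertical_ea", "lambda_direct"))
  structure(
    list(
      config = config,
      encoder_weights = init_encoder(config),
      head = init_head(config$hidden_dim, head_dim, init_seed = config$init_seed + 1L),
      task = task,
      featurization_version = FEATURIZATION_VERSION,
      log = NULL
    ),
    class = "reorg_model"
  )
}

#' @export
print.reorg_model <- function(x, ...) {
  cat(
    "<reorg_model> task ", x$task, ", encoder ", x$config$kind,
    " (hidden ", x$config$hidden_dim, ", seed ", x$config$init_seed, ")",
    if (is.null(x$log)) " [untrained]" else " [trained]", "\n",
    sep = ""
  )
  invisible(x)
}

#' Embed one featurized record with a model's encoder
#' @param model A `reorg_model` (or `list(config, weights)` params).
#' @param record A `reorg_record`.
#' @export
embed_record <- function(model, record) {
  params <- list(config = model$config, weights = model$encoder_weights)
  encode(params, record$graph,
    conformer = record$conformer,
    internal_coords = record$internal_coords
  )
}

embedding_matrix <- function(model, records) {
  t(vapply(records, function(r) embed_record(model, r), numeric(model$config$hidden_dim)))
}

#' Predict scalars (eV) for featurized records
#' @param model A `reorg_model`.
#' @param records List of `reorg_record`s.
#' @return Numeric vector, one prediction per record.
#' @export
predict_records <- function(model, records) {
  if (length(records) == 0L) {
    return(numeric())
  }
  E <- embedding_matrix(model, records)
  if (!is.null(model$scaler)) {
    E <- sweep(sweep(E, 2L, model$scaler$center), 2L, model$scaler$scale, `/`)
  }
  predict_scalar(E, model$head)
}

#' Save a model checkpoint
#'
#' The checkpoint is a JSON container holding the config, encoder and head
#' weights, and the featurization version; [load_model()] refuses to load a
#' checkpoint whose featurization version differs from the installed one.
#'
#' @param model A `reorg_model`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  ser <- list(
    container = "reorglam-checkpoint-1",
    featurization_version = model$featurization_version,
    task = model$task,
    config = unclass(model$config),
    encoder_weights = model$encoder_weights,
    head = model$head,
    scaler = model$scaler,
    log = model$log
  )
  ser <- ser[!vapply(ser, is.null, logical(1))]
  jsonlite::write_json(ser, path,
    auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor", null = "null"
  )
  invisible(path)
}

# Rebuild weight structures from their JSON form (row-major nested arrays).
json_to_weights <- function(x) {
  if (!is.list(x)) {
    return(as.numeric(x))
  }
  if (!is.null(names(x)) && any(nzchar(names(x)))) {
    return(lapply(x, json_to_weights))
  }
  if (length(x) > 0L && is.list(x[[1L]])) {
    if (is.null(names(x[[1L]]))) {
      return(do.call(rbind, lapply(x, function(r) as.numeric(unlist(r)))))
    }
    return(lapply(x, json_to_weights))
  }
  as.numeric(unlist(x))
}

#' Load a model checkpoint
#' @param path Checkpoint path written by [save_model()].
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(ser$container, "reorglam-checkpoint-1")) {
    stop("not a reorglam checkpoint: ", path)
  }
  if (!identical(ser$featurization_version, FEATURIZATION_VERSION)) {
    stop(
      "checkpoint featurization version '", ser$featurization_version,
      "' does not match installed version '", FEATURIZATION_VERSION, "'"
    )
  }
  config <- do.call(make_encoder_config, ser$config[c(
    "kind", "hidden_dim", "n_layers", "distance_cutoff", "n_rbf",
    "n_torsion_harmonics", "n_length_rbf", "init_seed"
  )])
  model <- make_model(config, task = ser$task)
  model$encoder_weights <- json_to_weights(ser$encoder_weights)
  model$head <- json_to_weights(ser$head)
  if (length(ser$scaler) > 0L) {
    model$scaler <- list(
      center = as.numeric(unlist(ser$scaler$center)),
      scale = as.numeric(unlist(ser$scaler$scale))
    )
  }
  model$log <- ser$log
  model
}
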