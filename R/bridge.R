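#' @keywords internal
"_PACKAGE"

# Batched subprocess bridge to RDKit. All cheminformatics primitives (SMILES
# parsing/canonicalization, srETKDGv3 distance-geometry embedding, SDF I/O)
# are delegated to RDKit; the bridge exchanges JSON files with a bundled
# Python script. Results are memoised per session keyed on the request, so
# repeated parses/embeddings of the same molecule cost one subprocess call.

.reorglam_cache <- new.env(parent = emptyenv())

bridge_script <- function() {
  path <- system.file("python", "rdkit_bridge.py", package = "reorglam")
  if (!nzchar(path)) {
    stop("rdkit_bridge.py not found; is the package installed correctly?")
  }
  path
}

python_binary <- function() {
  Sys.getenv("REORGLAM_PYTHON", unset = "python")
}

#' Low-level call into the RDKit bridge
#'
#' @param op Bridge operation (`"parse"`, `"embed"`, `"read_sdf"`, `"write_sdf"`).
#' @param items List of request items; see `inst/python/rdkit_bridge.py`.
#' @return List of per-item results. Items that failed inside RDKit are
#'   returned as `list(error = <message>)`; callers decide whether to raise.
#' @keywords internal
rdkit_call <- function(op, items) {
  if (length(items) == 0L) {
    return(list())
  }
  req <- tempfile(fileext = ".json")
  resp <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, resp)), add = TRUE)
  jsonlite::write_json(
    list(op = op, items = items),
    req,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  status <- system2(python_binary(), c(bridge_script(), req, resp),
    stdout = FALSE, stderr = ""
  )
  if (!identical(status, 0L) || !file.exists(resp)) {
    stop("RDKit bridge call failed (op = ", op, ", exit status ", status, ")")
  }
  out <- jsonlite::read_json(resp, simplifyVector = FALSE)
  if (!isTRUE(out$ok)) {
    stop("RDKit bridge error: ", out$error)
  }
  out$results
}

cache_get <- function(key) {
  if (exists(key, envir = .reorglam_cache, inherits = FALSE)) {
    get(key, envir = .reorglam_cache, inherits = FALSE)
  } else {
    NULL
  }
}

cache_set <- function(key, value) {
  assign(key, value, envir = .reorglam_cache)
  value
}

#' Clear the session-level RDKit memoisation cache
#'
#' Forces subsequent parses/embeddings to go back through the bridge;
#' useful when verifying cross-process determinism.
#' @export
clear_bridge_cache <- function() {
  rm(list = ls(envir = .reorglam_cache), envir = .reorglam_cache)
  invisible(NULL)
}
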