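# Structure and label I/O: SDF (V2000, via RDKit), XYZ, and the labels CSV.

LABEL_COLUMNS <- c("molecule_id", "vertical_ip_eV", "vertical_ea_eV", "lambda_eV")

#' Write molecule/conformer pairs to SDF or XYZ
#'
#' SDF records carry the bond table, per-atom formal charges and a
#' `charge_state` property holding the redox tag; XYZ records carry the
#' canonical SMILES, redox tag and provenance on the comment line so the
#' molecular graph survives a round trip. Coordinates are preserved to
#' 1e-4 Angstrom in both formats.
#'
#' @param records List of `list(mol = <molecule_record>, conformer = <conformer>)`.
#' @param path Output file path.
#' @param format `"sdf"` or `"xyz"`.
#' @return `path` invisibly.
#' @export
write_structures <- function(records, path, format = c("sdf", "xyz")) {
  format <- match.arg(format)
  stopifnot(is.list(records))
  if (format == "sdf") {
    items <- lapply(records, function(r) {
      list(
        id = r$mol$id,
        charge = r$mol$charge,
        atoms = lapply(seq_len(nrow(r$mol$atoms)), function(k) {
          list(
            element = r$mol$atoms$element[[k]],
            formal_charge = r$mol$atoms$formal_charge[[k]]
          )
        }),
        bonds = lapply(seq_len(nrow(r$mol$bonds)), function(k) {
          list(
            i = r$mol$bonds$i[[k]], j = r$mol$bonds$j[[k]],
            order = r$mol$bonds$order[[k]]
          )
        }),
        coords = lapply(seq_len(nrow(r$conformer$coords)), function(k) {
          as.numeric(r$conformer$coords[k, ])
        })
      )
    })
    res <- rdkit_call("write_sdf", list(list(path = path, molecules = items)))
    if (!is.null(res[[1L]]$error)) stop("SDF write failed: ", res[[1L]]$error)
  } else {
    lines <- unlist(lapply(records, function(r) {
      n <- nrow(r$conformer$coords)
      comment <- sprintf(
        "id=%s charge=%d provenance=%s smiles=%s",
        r$mol$id, r$mol$charge, r$conformer$provenance, r$mol$smiles
      )
      c(
        as.character(n), comment,
        sprintf(
          "%-2s %14.6f %14.6f %14.6f",
          r$mol$atoms$element,
          r$conformer$coords[, 1], r$conformer$coords[, 2], r$conformer$coords[, 3]
        )
      )
    }))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read molecule/conformer pairs from SDF or XYZ
#'
#' @param path Input file.
#' @param format `"sdf"` or `"xyz"`.
#' @param provenance Provenance tag to assign when the file does not state one.
#' @return List of `list(mol, conformer)` pairs. An empty file yields an
#'   empty list with a warning.
#' @export
read_structures <- function(path, format = c("sdf", "xyz"),
                            provenance = "distance_geometry") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty structure file: ", path)
    return(list())
  }
  if (format == "sdf") {
    res <- rdkit_call("read_sdf", list(list(path = path)))
    if (!is.null(res[[1L]]$error)) stop("SDF read failed: ", res[[1L]]$error)
    lapply(res[[1L]]$molecules, function(r) {
      tab <- parsed_to_tables(r)
      mol <- new_molecule_record(r$id, tab$smiles, r$charge, tab$atoms, tab$bonds)
      coords <- do.call(rbind, lapply(r$coords, as.numeric))
      list(mol = mol, conformer = new_conformer(r$id, coords, provenance, 0L))
    })
  } else {
    read_xyz(path, provenance)
  }
}

read_xyz <- function(path, provenance) {
  lines <- readLines(path)
  out <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[[pos]]))) {
      pos <- pos + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[[pos]])))
    if (is.na(n) || pos + 1L + n > length(lines) + 0L) {
      stop("malformed XYZ record at line ", pos, " of ", path)
    }
    comment <- lines[[pos + 1L]]
    body <- lines[(pos + 2L):(pos + 1L + n)]
    fields <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(fields, length, integer(1)) < 4L)
    if (length(bad) > 0L) {
      stop("malformed XYZ atom line ", pos + 1L + bad[[1L]], " of ", path)
    }
    elements <- vapply(fields, `[[`, character(1), 1L)
    coords <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    meta <- xyz_comment_fields(comment)
    id <- if (!is.null(meta$id)) meta$id else paste0("mol", length(out) + 1L)
    charge <- if (!is.null(meta$charge)) as.integer(meta$charge) else 0L
    prov <- if (!is.null(meta$provenance)) meta$provenance else provenance
    mol <- xyz_molecule(meta$smiles, id, charge, elements, pos, path)
    out[[length(out) + 1L]] <- list(
      mol = mol,
      conformer = new_conformer(id, coords, prov, 0L)
    )
    pos <- pos + 2L + n
  }
  out
}

xyz_comment_fields <- function(comment) {
  tokens <- strsplit(trimws(comment), "[[:space:]]+")[[1L]]
  kv <- tokens[grepl("=", tokens, fixed = TRUE)]
  parts <- strsplit(kv, "=", fixed = TRUE)
  stats::setNames(
    lapply(parts, function(p) paste(p[-1L], collapse = "=")),
    vapply(parts, `[[`, character(1), 1L)
  )
}

xyz_molecule <- function(smiles, id, charge, elements, line, path) {
  if (!is.null(smiles)) {
    mol <- parse_smiles(smiles, id = id, charge = charge)
    if (!identical(mol$atoms$element, elements)) {
      stop(
        "XYZ record at line ", line, " of ", path,
        ": element sequence does not match its SMILES annotation"
      )
    }
    return(mol)
  }
  # Bare XYZ: no connectivity available; return an atoms-only record.
  warning("XYZ record '", id, "' has no SMILES annotation; bond table empty")
  structure(
    list(
      id = id, smiles = NA_character_, charge = charge,
      atoms = data.frame(
        element = elements, formal_charge = 0L,
        aromatic = FALSE, in_ring = FALSE, stringsAsFactors = FALSE
      ),
      bonds = data.frame(
        i = integer(), j = integer(), order = character(),
        in_ring = logical(), conjugated = logical(), stringsAsFactors = FALSE
      ),
      n_heavy = sum(elements != "H")
    ),
    class = "molecule_record"
  )
}

#' Read a label table
#'
#' Expects a UTF-8 CSV whose header is drawn from `molecule_id`,
#' `vertical_ip_eV`, `vertical_ea_eV`, `lambda_eV` (all energies in eV).
#' When all three energy columns are present every row must satisfy
#' `lambda_eV = vertical_ip_eV - vertical_ea_eV` to within 1e-9 eV; rows
#' violating the identity are rejected.
#'
#' @param path CSV file path.
#' @param strict If `TRUE` (default) inconsistent rows raise an error; if
#'   `FALSE` they are dropped with a warning report.
#' @param tol Identity tolerance in eV.
#' @return A data.frame with the validated rows (class `label_table`).
#' @export
read_labels <- function(path, strict = TRUE, tol = 1e-9) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_label_table(tab, strict = strict, tol = tol)
}

#' Validate a label table already in memory
#' @inheritParams read_labels
#' @param tab A data.frame of labels.
#' @export
validate_label_table <- function(tab, strict = TRUE, tol = 1e-9) {
  unknown <- setdiff(names(tab), LABEL_COLUMNS)
  if (length(unknown) > 0L) {
    stop("unexpected label column(s): ", paste(unknown, collapse = ", "))
  }
  if (!"molecule_id" %in% names(tab)) stop("label table needs a molecule_id column")
  has_all <- all(c("vertical_ip_eV", "vertical_ea_eV", "lambda_eV") %in% names(tab))
  if (has_all && nrow(tab) > 0L) {
    resid <- abs(tab$lambda_eV - (tab$vertical_ip_eV - tab$vertical_ea_eV))
    bad <- which(resid > tol)
    if (length(bad) > 0L) {
      report <- paste0(
        tab$molecule_id[bad], " (|lambda - (IP - EA)| = ",
        format(resid[bad], digits = 3), " eV)"
      )
      msg <- paste0(
        length(bad), " label row(s) violate lambda = IP - EA: ",
        paste(utils::head(report, 5L), collapse = "; ")
      )
      if (strict) stop(msg)
      warning(msg, "; rows dropped")
      tab <- tab[-bad, , drop = FALSE]
    }
  }
  if ("lambda_eV" %in% names(tab) && any(tab$lambda_eV < 0)) {
    warning("label table contains negative lambda values (physically inconsistent)")
  }
  class(tab) <- c("label_table", "data.frame")
  tab
}

#' Write a label table
#' @param tab A label data.frame.
#' @param path Output CSV path.
#' @export
write_labels <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
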