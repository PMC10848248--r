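# Molecule and conformer containers.
#
# A molecule_record is the chemical graph with explicit hydrogens plus a
# redox-state tag (charge 0 = neutral, +1 = radical cation). A conformer is
# one 3D realization of that graph, tagged with the provenance of the method
# that produced it. Both are plain S3 lists so they serialize cleanly.

PROVENANCE_LEVELS <- c("distance_geometry", "semiempirical", "dft", "synthetic")

new_molecule_record <- function(id, smiles, charge, atoms, bonds) {
  rec <- structure(
    list(
      id = as.character(id),
      smiles = smiles,
      charge = as.integer(charge),
      atoms = atoms,
      bonds = bonds,
      n_heavy = sum(atoms$element != "H")
    ),
    class = "molecule_record"
  )
  validate_molecule_record(rec)
}

validate_molecule_record <- function(rec) {
  n <- nrow(rec$atoms)
  b <- rec$bonds
  if (n < 1L) stop("molecule '", rec$id, "' has no atoms")
  if (nrow(b) > 0L) {
    if (any(b$i < 1L | b$i > n | b$j < 1L | b$j > n)) {
      stop("molecule '", rec$id, "': bond atom index out of range")
    }
    if (any(b$i == b$j)) stop("molecule '", rec$id, "': self-bond")
  }
  if (n > 1L) {
    g <- igraph::graph_from_edgelist(cbind(b$i, b$j), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    if (!igraph::is_connected(g)) {
      stop("molecule '", rec$id, "': disconnected graph")
    }
  }
  rec
}

#' Parse a SMILES string into a molecule record
#'
#' Hydrogens are made explicit and the canonical (heavy-atom) SMILES is
#' stored. Parsing and canonicalization are delegated to RDKit.
#'
#' @param s A SMILES string.
#' @param id Molecule identifier carried through the pipeline.
#' @param charge Redox-state tag: 0 for the neutral molecule, +1 for the
#'   radical cation. The tag does not alter connectivity; cation conformers
#'   are embedded from the neutral connectivity (distance geometry has no
#'   charge awareness).
#' @return A `molecule_record` with fields `id`, `smiles`, `charge`, `atoms`
#'   (element, formal_charge, aromatic, in_ring), `bonds` (i, j, order in
#'   {"1","2","3","ar"}, in_ring, conjugated) and `n_heavy`.
#' @examples
#' \dontrun{
#' mol <- parse_smiles("CC(=O)N", "acetamide")
#' mol$n_heavy
#' }
#' @export
parse_smiles <- function(s, id = s, charge = 0L) {
  out <- parse_smiles_batch(s, ids = id, charges = charge)
  out[[1L]]
}

#' Parse many SMILES strings in one bridge call
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Identifiers, recycled against `smiles`.
#' @param charges Integer redox tags, recycled against `smiles`.
#' @return List of `molecule_record` objects.
#' @export
parse_smiles_batch <- function(smiles, ids = smiles, charges = 0L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  ids <- rep_len(as.character(ids), length(smiles))
  charges <- rep_len(as.integer(charges), length(smiles))
  keys <- paste0("parse\r", smiles)
  need <- which(vapply(keys, function(k) is.null(cache_get(k)), logical(1)))
  if (length(need) > 0L) {
    items <- lapply(unique(smiles[need]), function(s) list(id = s, smiles = s))
    res <- rdkit_call("parse", items)
    for (k in seq_along(items)) {
      r <- res[[k]]
      if (!is.null(r$error)) {
        stop("SMILES parse error for '", items[[k]]$smiles, "': ", r$error)
      }
      cache_set(paste0("parse\r", items[[k]]$smiles), parsed_to_tables(r))
    }
  }
  lapply(seq_along(smiles), function(k) {
    tab <- cache_get(keys[[k]])
    new_molecule_record(ids[[k]], tab$smiles, charges[[k]], tab$atoms, tab$bonds)
  })
}

parsed_to_tables <- function(r) {
  atoms <- data.frame(
    element = vapply(r$atoms, function(a) a$element, character(1)),
    formal_charge = vapply(r$atoms, function(a) as.integer(a$formal_charge), integer(1)),
    aromatic = vapply(r$atoms, function(a) isTRUE(a$aromatic), logical(1)),
    in_ring = vapply(r$atoms, function(a) isTRUE(a$in_ring), logical(1)),
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    i = vapply(r$bonds, function(b) as.integer(b$i), integer(1)),
    j = vapply(r$bonds, function(b) as.integer(b$j), integer(1)),
    order = vapply(r$bonds, function(b) as.character(b$order), character(1)),
    in_ring = vapply(r$bonds, function(b) isTRUE(b$in_ring), logical(1)),
    conjugated = vapply(r$bonds, function(b) isTRUE(b$conjugated), logical(1)),
    stringsAsFactors = FALSE
  )
  list(smiles = r$smiles, atoms = atoms, bonds = bonds)
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(
    "<molecule_record> ", x$id, "  ", x$smiles,
    "  charge ", x$charge,
    "  (", nrow(x$atoms), " atoms, ", x$n_heavy, " heavy)\n",
    sep = ""
  )
  invisible(x)
}

new_conformer <- function(molecule_id, coords, provenance, seed, energy_eV = NULL) {
  provenance <- match.arg(provenance, PROVENANCE_LEVELS)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  conf <- structure(
    list(
      molecule_id = as.character(molecule_id),
      coords = coords,
      provenance = provenance,
      seed = as.integer(seed),
      energy_eV = energy_eV
    ),
    class = "conformer"
  )
  if (!all(is.finite(conf$coords))) {
    stop("conformer for '", molecule_id, "' has non-finite coordinates")
  }
  if (ncol(conf$coords) != 3L) stop("coords must be an n x 3 matrix")
  conf
}

#' @export
print.conformer <- function(x, ...) {
  cat(
    "<conformer> ", x$molecule_id, "  ", nrow(x$coords), " atoms, provenance ",
    x$provenance, ", seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

min_pairwise_distance <- function(coords) {
  if (nrow(coords) < 2L) {
    return(Inf)
  }
  min(stats::dist(coords))
}

#' Geometric sanity check for a conformer
#'
#' Verifies that no two atoms clash (minimum pairwise distance > 0.5 A) and
#' that every bonded pair sits at a chemically plausible distance
#' (0.7 - 2.0 A).
#'
#' @param mol The `molecule_record` the conformer realizes.
#' @param conformer A `conformer`.
#' @return `TRUE` invisibly; errors describe the violation.
#' @export
check_conformer_sanity <- function(mol, conformer) {
  if (nrow(conformer$coords) != nrow(mol$atoms)) {
    stop("conformer/molecule atom count mismatch for '", mol$id, "'")
  }
  if (min_pairwise_distance(conformer$coords) <= 0.5) {
    stop("atom clash (< 0.5 A) in conformer of '", mol$id, "'")
  }
  if (nrow(mol$bonds) > 0L) {
    d <- sqrt(rowSums((conformer$coords[mol$bonds$i, , drop = FALSE] -
      conformer$coords[mol$bonds$j, , drop = FALSE])^2))
    if (any(d < 0.7 | d > 2.0)) {
      stop("bonded distance outside [0.7, 2.0] A in conformer of '", mol$id, "'")
    }
  }
  invisible(TRUE)
}

#' Embed distance-geometry conformers
#'
#' Generates `n` 3D conformers with RDKit's srETKDGv3 algorithm (the ETKDG
#' version-3 parameter set with small-ring torsion terms), with no subsequent
#' geometry optimization — these are deliberately cheap geometries. The
#' embedding is deterministic for a fixed (molecule, n, seed); on failure the
#' seed is re-drawn as seed + 1000 k for up to 5 retries before erroring.
#'
#' @param mol A `molecule_record`.
#' @param n Number of conformers (>= 1).
#' @param seed Integer random seed for the distance-geometry embedding.
#' @return List of `n` `conformer` objects with provenance
#'   `"distance_geometry"`; atom order matches `mol$atoms`.
#' @export
embed_conformers <- function(mol, n = 1L, seed = 1L) {
  stopifnot(inherits(mol, "molecule_record"), n >= 1L)
  out <- embed_conformers_batch(list(mol), n = n, seed = seed)
  out[[1L]]
}

#' Embed conformers for many molecules in one bridge call
#'
#' @param mols List of `molecule_record` objects.
#' @param n Conformers per molecule.
#' @param seed Base seed; molecule k uses `seed + k - 1` so ensembles are
#'   decorrelated across molecules but reproducible.
#' @return List (per molecule) of lists of `conformer` objects.
#' @export
embed_conformers_batch <- function(mols, n = 1L, seed = 1L) {
  stopifnot(length(mols) >= 1L, n >= 1L)
  seeds <- as.integer(seed) + seq_along(mols) - 1L
  keys <- vapply(seq_along(mols), function(k) {
    paste0("embed\r", mols[[k]]$smiles, "\r", n, "\r", seeds[[k]])
  }, character(1))
  need <- which(vapply(keys, function(k) is.null(cache_get(k)), logical(1)))
  if (length(need) > 0L) {
    items <- lapply(unname(need), function(k) {
      list(id = mols[[k]]$id, smiles = mols[[k]]$smiles, n = n, seed = seeds[[k]])
    })
    res <- rdkit_call("embed", items)
    for (p in seq_along(need)) {
      r <- res[[p]]
      k <- need[[p]]
      if (!is.null(r$error)) {
        stop("conformer embedding failed for molecule '", mols[[k]]$id, "': ", r$error)
      }
      coords <- lapply(r$coords, function(cs) {
        do.call(rbind, lapply(cs, function(xyz) as.numeric(xyz)))
      })
      cache_set(keys[[k]], list(coords = coords, seed = as.integer(r$seed)))
    }
  }
  lapply(seq_along(mols), function(k) {
    hit <- cache_get(keys[[k]])
    lapply(hit$coords, function(cm) {
      conf <- new_conformer(mols[[k]]$id, cm, "distance_geometry", hit$seed)
      check_conformer_sanity(mols[[k]], conf)
      conf
    })
  })
}
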