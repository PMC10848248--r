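# Featurization: attributed 2D graph, internal coordinates (bond lengths,
# bend angles, torsions grouped per rotatable bond), and the bond-rotation
# operator that the invariance contract is tested against.

ELEMENT_VOCAB <- c("H", "C", "N", "O", "F", "other")
BOND_ORDER_VOCAB <- c("1", "2", "3", "ar")
FEATURIZATION_VERSION <- "reorglam-feat-1"

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[[k]]
    j <- mol$bonds$j[[k]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

heavy_degree <- function(mol) {
  heavy <- mol$atoms$element != "H"
  deg <- integer(nrow(mol$atoms))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[[k]]
    j <- mol$bonds$j[[k]]
    if (heavy[[j]]) deg[[i]] <- deg[[i]] + 1L
    if (heavy[[i]]) deg[[j]] <- deg[[j]] + 1L
  }
  deg
}

#' Build the attributed molecular graph
#'
#' Node features: element one-hot over {H, C, N, O, F, other}, degree, formal
#' charge, aromatic flag, ring flag. Edge features (per directed edge): bond
#' order one-hot over {single, double, triple, aromatic}, ring flag,
#' conjugation flag. Every bond appears as two directed edges.
#'
#' @param mol A `molecule_record`.
#' @return A `molecular_graph`: `node_features` (n x 10), `edges` (src, dst),
#'   `edge_features` (2m x 6), plus bookkeeping fields.
#' @export
build_graph <- function(mol) {
  stopifnot(inherits(mol, "molecule_record"))
  n <- nrow(mol$atoms)
  el <- mol$atoms$element
  el_idx <- match(el, ELEMENT_VOCAB)
  unknown <- is.na(el_idx)
  if (any(unknown)) {
    warning(
      "element(s) outside vocabulary mapped to 'other': ",
      paste(unique(el[unknown]), collapse = ", ")
    )
    el_idx[unknown] <- match("other", ELEMENT_VOCAB)
  }
  onehot <- matrix(0, n, length(ELEMENT_VOCAB))
  onehot[cbind(seq_len(n), el_idx)] <- 1
  deg <- tabulate(c(mol$bonds$i, mol$bonds$j), nbins = n)
  node_features <- cbind(
    onehot, deg, mol$atoms$formal_charge,
    as.numeric(mol$atoms$aromatic), as.numeric(mol$atoms$in_ring)
  )
  colnames(node_features) <- c(ELEMENT_VOCAB, "degree", "formal_charge", "aromatic", "ring")

  m <- nrow(mol$bonds)
  src <- c(mol$bonds$i, mol$bonds$j)
  dst <- c(mol$bonds$j, mol$bonds$i)
  ord <- match(mol$bonds$order, BOND_ORDER_VOCAB)
  if (anyNA(ord)) stop("unknown bond order: ", paste(unique(mol$bonds$order), collapse = ", "))
  ord_onehot <- matrix(0, m, length(BOND_ORDER_VOCAB))
  if (m > 0L) ord_onehot[cbind(seq_len(m), ord)] <- 1
  ef_half <- cbind(ord_onehot, as.numeric(mol$bonds$in_ring), as.numeric(mol$bonds$conjugated))
  edge_features <- rbind(ef_half, ef_half)
  colnames(edge_features) <- c(paste0("order", BOND_ORDER_VOCAB), "ring", "conjugated")

  structure(
    list(
      molecule_id = mol$id,
      node_features = node_features,
      edges = data.frame(src = src, dst = dst),
      edge_features = edge_features,
      n_atoms = n,
      version = FEATURIZATION_VERSION
    ),
    class = "molecular_graph"
  )
}

#' Rotatable bonds of a molecule
#'
#' A bond is rotatable when it is a single, non-ring bond and both endpoint
#' atoms are heavy with heavy-atom degree >= 2 (hydrogens never make a bond
#' terminal or rotatable).
#'
#' @param mol A `molecule_record`.
#' @return data.frame with columns `i`, `j` (`i < j`).
#' @export
rotatable_bonds <- function(mol) {
  heavy <- mol$atoms$element != "H"
  hdeg <- heavy_degree(mol)
  b <- mol$bonds
  keep <- b$order == "1" & !b$in_ring &
    heavy[b$i] & heavy[b$j] & hdeg[b$i] >= 2L & hdeg[b$j] >= 2L
  out <- b[keep, c("i", "j"), drop = FALSE]
  swap <- out$i > out$j
  tmp <- out$i[swap]
  out$i[swap] <- out$j[swap]
  out$j[swap] <- tmp
  rownames(out) <- NULL
  out
}

bend_angle <- function(p1, p2, p3, eps = 1e-6) {
  v1 <- p1 - p2
  v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  if (cosang > 1 - 1e-12 || cosang < -1 + 1e-12) {
    warning("collinear atom triple; bend angle clamped")
    cosang <- max(min(cosang, 1 - 1e-12), -1 + 1e-12)
  }
  ang <- acos(cosang)
  min(max(ang, eps), pi - eps)
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Signed dihedral angle of four points (IUPAC convention), radians in (-pi, pi]
#' @param p1,p2,p3,p4 Length-3 coordinate vectors along the 1-4 path.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Extract internal coordinates from a conformer
#'
#' Bond lengths for every bond, bend angles for every bonded triple, and
#' dihedral angles for every 1-4 atom path through each rotatable bond,
#' grouped per bond. Torsions use the IUPAC sign convention, radians in
#' (-pi, pi].
#'
#' @param mol A `molecule_record`.
#' @param conformer A matching `conformer`.
#' @param include_hydrogen_torsions Include 1-4 paths that start or end at a
#'   hydrogen in the torsion groups (default `TRUE`).
#' @return An `internal_coords` object: `bond_lengths` (i, j, length_A),
#'   `bend_angles` (i, j, k, angle_rad), and `torsion_groups`, a named list
#'   keyed `"i-j"` with fields `paths` (m x 4) and `angles` (length m).
#' @export
extract_internal_coords <- function(mol, conformer, include_hydrogen_torsions = TRUE) {
  X <- conformer$coords
  if (nrow(X) != nrow(mol$atoms)) {
    stop("conformer does not match molecule '", mol$id, "' (atom count)")
  }
  b <- mol$bonds
  lengths <- if (nrow(b) > 0L) {
    sqrt(rowSums((X[b$i, , drop = FALSE] - X[b$j, , drop = FALSE])^2))
  } else {
    numeric()
  }
  bond_lengths <- data.frame(i = b$i, j = b$j, length_A = lengths)

  adj <- adjacency_list(mol)
  ai <- integer()
  aj <- integer()
  ak <- integer()
  for (j in seq_len(nrow(mol$atoms))) {
    nb <- adj[[j]]
    if (length(nb) >= 2L) {
      pairs <- utils::combn(nb, 2L)
      ai <- c(ai, pairs[1L, ])
      aj <- c(aj, rep(j, ncol(pairs)))
      ak <- c(ak, pairs[2L, ])
    }
  }
  angles <- vapply(seq_along(aj), function(t) {
    bend_angle(X[ai[[t]], ], X[aj[[t]], ], X[ak[[t]], ])
  }, numeric(1))
  bend_angles <- data.frame(i = ai, j = aj, k = ak, angle_rad = angles)

  rb <- rotatable_bonds(mol)
  heavy <- mol$atoms$element != "H"
  torsion_groups <- list()
  for (r in seq_len(nrow(rb))) {
    bi <- rb$i[[r]]
    bj <- rb$j[[r]]
    a_side <- setdiff(adj[[bi]], bj)
    d_side <- setdiff(adj[[bj]], bi)
    if (!include_hydrogen_torsions) {
      a_side <- a_side[heavy[a_side]]
      d_side <- d_side[heavy[d_side]]
    }
    if (length(a_side) == 0L || length(d_side) == 0L) next
    paths <- as.matrix(expand.grid(a = a_side, d = d_side))
    paths <- cbind(paths[, "a"], bi, bj, paths[, "d"])
    psi <- vapply(seq_len(nrow(paths)), function(t) {
      dihedral_angle(X[paths[t, 1], ], X[paths[t, 2], ], X[paths[t, 3], ], X[paths[t, 4], ])
    }, numeric(1))
    torsion_groups[[paste0(bi, "-", bj)]] <- list(paths = unname(paths), angles = psi)
  }

  structure(
    list(
      molecule_id = mol$id,
      bond_lengths = bond_lengths,
      bend_angles = bend_angles,
      torsion_groups = torsion_groups,
      version = FEATURIZATION_VERSION
    ),
    class = "internal_coords"
  )
}

#' Rotate one side of a rotatable bond
#'
#' Rigidly rotates the smaller side of the bond (ties broken toward the side
#' containing the lower minimum atom index) by `delta` radians about the bond
#' axis. All torsions in the bond's group shift by a common signed delta
#' (mod 2 pi); every bond length and bend angle is unchanged.
#'
#' @param conformer A `conformer`.
#' @param mol The matching `molecule_record`.
#' @param bond Length-2 integer vector (atom indices of a rotatable bond).
#' @param delta Rotation in radians.
#' @return A new `conformer` with rotated coordinates.
#' @export
rotate_bond <- function(conformer, mol, bond, delta) {
  bond <- sort(as.integer(bond))
  rb <- rotatable_bonds(mol)
  if (!any(rb$i == bond[[1L]] & rb$j == bond[[2L]])) {
    stop(
      "bond ", bond[[1L]], "-", bond[[2L]], " of molecule '", mol$id,
      "' is not rotatable"
    )
  }
  n <- nrow(mol$atoms)
  keep <- !(mol$bonds$i == bond[[1L]] & mol$bonds$j == bond[[2L]] |
    mol$bonds$i == bond[[2L]] & mol$bonds$j == bond[[1L]])
  g <- igraph::graph_from_edgelist(
    cbind(mol$bonds$i[keep], mol$bonds$j[keep]),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  side1 <- which(comp == comp[[bond[[1L]]]])
  side2 <- which(comp == comp[[bond[[2L]]]])
  if (length(side1) < length(side2) ||
    (length(side1) == length(side2) && min(side1) < min(side2))) {
    moving <- side1
    pivot <- bond[[1L]]
    anchor <- bond[[2L]]
  } else {
    moving <- side2
    pivot <- bond[[2L]]
    anchor <- bond[[1L]]
  }
  moving <- setdiff(moving, pivot)
  X <- conformer$coords
  axis <- X[pivot, ] - X[anchor, ]
  axis <- axis / sqrt(sum(axis^2))
  origin <- X[pivot, ]
  cosd <- cos(delta)
  sind <- sin(delta)
  for (a in moving) {
    v <- X[a, ] - origin
    X[a, ] <- origin + v * cosd + cross3(axis, v) * sind +
      axis * sum(axis * v) * (1 - cosd)
  }
  new_conformer(conformer$molecule_id, X, conformer$provenance, conformer$seed,
    energy_eV = conformer$energy_eV
  )
}

#' Radial basis expansion of a distance
#'
#' Gaussian expansion `exp(-gamma (d - mu_k)^2)` over a grid of centers, the
#' standard distance filter input for continuous-filter convolutions.
#'
#' @param d Distance(s), Angstrom, `>= 0`.
#' @param centers Numeric grid of centers `mu_k` (Angstrom).
#' @param gamma Width parameter (1/Angstrom^2).
#' @return A `length(d) x length(centers)` matrix of values in (0, 1].
#' @export
rbf_expand <- function(d, centers, gamma) {
  stopifnot(all(d >= 0), gamma >= 0)
  exp(-gamma * outer(as.numeric(d), centers, `-`)^2)
}

#' Relabel atoms by a permutation (test utility)
#'
#' @param mol A `molecule_record`.
#' @param conformer Optional matching `conformer`.
#' @param perm Integer permutation of `seq_len(n_atoms)`; atom `k` of the
#'   input becomes atom `perm[k]` of the output.
#' @return `list(mol, conformer)` with relabeled indices and reordered rows.
#' @export
permute_atoms <- function(mol, conformer = NULL, perm) {
  n <- nrow(mol$atoms)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- order(perm)
  atoms <- mol$atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  bonds$i <- perm[bonds$i]
  bonds$j <- perm[bonds$j]
  out <- structure(
    list(
      id = mol$id, smiles = mol$smiles, charge = mol$charge,
      atoms = atoms, bonds = bonds, n_heavy = mol$n_heavy
    ),
    class = "molecule_record"
  )
  conf <- NULL
  if (!is.null(conformer)) {
    conf <- new_conformer(
      conformer$molecule_id, conformer$coords[inv, , drop = FALSE],
      conformer$provenance, conformer$seed, conformer$energy_eV
    )
  }
  list(mol = out, conformer = conf)
}
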