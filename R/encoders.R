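# Three molecule-conformer encoders in distinct geometric symmetry classes,
# plus the shared scalar regression head.
#
#   bond_invariant_3d  sees bond lengths, bend angles, and per-rotatable-bond
#                      torsion statistics built ONLY from pairwise torsion
#                      differences, so it is exactly invariant when all
#                      torsions about one bond shift by a common angle.
#   distance_3d        continuous-filter convolutions over radial-basis
#                      expanded interatomic distances within a cutoff;
#                      invariant to rigid motions, sensitive to bond rotation.
#   graph_2d           message passing over the attributed 2D graph only;
#                      identical for every conformer of a molecule.
#
# Encoder weights are drawn once from the config's init_seed and then held
# fixed; the trainable component is the regression head (see train_model).
# All aggregations are sums over atoms/edges, so every encoder is invariant
# to atom-order permutation.

ENCODER_KINDS <- c("bond_invariant_3d", "distance_3d", "graph_2d")

N_NODE_FEATURES <- 10L # element one-hot (6) + degree + charge + aromatic + ring
N_EDGE_FEATURES <- 6L # order one-hot (4) + ring + conjugated
N_ANGLE_FEATURES <- 4L # per-atom bend-angle summary

#' Encoder configuration
#'
#' @param kind One of `"bond_invariant_3d"`, `"distance_3d"`, `"graph_2d"`.
#' @param hidden_dim Embedding width (positive integer).
#' @param n_layers Number of message-passing / interaction layers.
#' @param distance_cutoff Interaction cutoff in Angstrom (`distance_3d` only).
#' @param n_rbf Number of radial basis centers on `[0, cutoff]` (`distance_3d`).
#' @param n_torsion_harmonics Harmonics of the torsion-difference statistics
#'   (`bond_invariant_3d` only).
#' @param n_length_rbf Radial basis centers for bond lengths (`bond_invariant_3d`).
#' @param init_seed Seed for the (fixed) random weight draw.
#' @return An `encoder_config` list.
#' @export
make_encoder_config <- function(kind, hidden_dim = 64L, n_layers = 3L,
                                distance_cutoff = 10, n_rbf = 50L,
                                n_torsion_harmonics = 3L, n_length_rbf = 8L,
                                init_seed = 1L) {
  kind <- match.arg(kind, ENCODER_KINDS)
  stopifnot(
    hidden_dim >= 1L, n_layers >= 1L, distance_cutoff > 0,
    n_rbf >= 2L, n_torsion_harmonics >= 1L, n_length_rbf >= 2L
  )
  structure(
    list(
      kind = kind,
      hidden_dim = as.integer(hidden_dim),
      n_layers = as.integer(n_layers),
      distance_cutoff = distance_cutoff,
      n_rbf = as.integer(n_rbf),
      n_torsion_harmonics = as.integer(n_torsion_harmonics),
      n_length_rbf = as.integer(n_length_rbf),
      init_seed = as.integer(init_seed),
      version = FEATURIZATION_VERSION
    ),
    class = "encoder_config"
  )
}

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rand_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
}

node_input_dim <- function(config) {
  switch(config$kind,
    bond_invariant_3d = N_NODE_FEATURES + N_ANGLE_FEATURES,
    N_NODE_FEATURES
  )
}

edge_input_dim <- function(config) {
  switch(config$kind,
    bond_invariant_3d = N_EDGE_FEATURES + config$n_length_rbf,
    graph_2d = N_EDGE_FEATURES,
    distance_3d = NA_integer_
  )
}

#' Draw the fixed random weights for an encoder
#'
#' @param config An `encoder_config`.
#' @return A weight list; deterministic in `config$init_seed`.
#' @export
init_encoder <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  h <- config$hidden_dim
  local_seed(config$init_seed, {
    w <- list(W_in = rand_mat(node_input_dim(config), h), b_in = stats::rnorm(h, sd = 0.1))
    w$layers <- lapply(seq_len(config$n_layers), function(l) {
      layer <- list(
        W_self = rand_mat(h, h),
        W_msg = rand_mat(h, h),
        b = stats::rnorm(h, sd = 0.1)
      )
      if (config$kind == "distance_3d") {
        layer$W_pre <- rand_mat(h, h)
        layer$Wf1 <- rand_mat(config$n_rbf, h)
        layer$bf1 <- stats::rnorm(h, sd = 0.1)
        layer$Wf2 <- rand_mat(h, h)
      } else {
        layer$W_edge <- rand_mat(edge_input_dim(config), h)
        layer$b_edge <- stats::rnorm(h, sd = 0.1)
      }
      layer
    })
    if (config$kind == "bond_invariant_3d") {
      tdim <- 1L + config$n_torsion_harmonics
      w$Wt1 <- rand_mat(tdim, h)
      w$bt1 <- stats::rnorm(h, sd = 0.1)
      w$Wt2 <- rand_mat(h, h)
    }
    w$W_out <- rand_mat(h, h)
    w
  })
}

check_finite <- function(x, where) {
  if (!all(is.finite(x))) stop("non-finite activation in ", where)
  x
}

scatter_sum <- function(contrib, dst, n) {
  out <- matrix(0, n, ncol(contrib))
  if (nrow(contrib) > 0L) {
    rs <- rowsum(contrib, group = dst)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

graph_message_pass <- function(H, E, graph, weights, config) {
  n <- graph$n_atoms
  src <- graph$edges$src
  dst <- graph$edges$dst
  for (l in seq_len(config$n_layers)) {
    lw <- weights$layers[[l]]
    if (nrow(E) > 0L) {
      gate <- sigmoid(sweep(E %*% lw$W_edge, 2L, lw$b_edge, `+`))
      M <- scatter_sum(H[src, , drop = FALSE] * gate, dst, n)
    } else {
      M <- matrix(0, n, config$hidden_dim)
    }
    H <- tanh(sweep(H %*% lw$W_self + M %*% lw$W_msg, 2L, lw$b, `+`))
    check_finite(H, paste0("message-passing layer ", l))
  }
  H
}

readout <- function(H, weights) {
  as.numeric(colSums(H) %*% weights$W_out)
}

#' 2D graph encoder
#'
#' @param graph A `molecular_graph`.
#' @param params `list(config = <encoder_config>, weights = <init_encoder()>)`.
#' @return Numeric embedding of length `hidden_dim`; depends only on the
#'   graph, hence bitwise-identical for all conformers of a molecule.
#' @export
encode_2d <- function(graph, params) {
  config <- params$config
  stopifnot(config$kind == "graph_2d")
  if (ncol(graph$node_features) != N_NODE_FEATURES) {
    stop("node feature dimension mismatch: got ", ncol(graph$node_features))
  }
  H <- tanh(sweep(graph$node_features %*% params$weights$W_in, 2L, params$weights$b_in, `+`))
  H <- graph_message_pass(H, graph$edge_features, graph, params$weights, config)
  check_finite(readout(H, params$weights), "2d readout")
}

#' Distance-sensitive 3D encoder
#'
#' Continuous-filter convolutions: every atom pair within the distance
#' cutoff contributes a message weighted by a filter generated from the
#' radial-basis expansion of the interatomic distance. Pairs beyond the
#' cutoff contribute nothing. Invariant to rigid rotations/translations;
#' generically sensitive to bond rotations.
#'
#' @inheritParams encode_2d
#' @param conformer A `conformer` matching the graph's molecule.
#' @export
encode_distance <- function(graph, conformer, params) {
  config <- params$config
  stopifnot(config$kind == "distance_3d")
  n <- graph$n_atoms
  if (nrow(conformer$coords) != n) stop("conformer/graph atom count mismatch")
  D <- as.matrix(stats::dist(conformer$coords))
  pairs <- which(D > 0 & D <= config$distance_cutoff & upper.tri(D), arr.ind = TRUE)
  src <- c(pairs[, 1L], pairs[, 2L])
  dst <- c(pairs[, 2L], pairs[, 1L])
  d <- rep(D[pairs], 2L)
  centers <- seq(0, config$distance_cutoff, length.out = config$n_rbf)
  gamma <- 1 / (centers[2L] - centers[1L])^2
  R <- rbf_expand(d, centers, gamma)

  w <- params$weights
  H <- tanh(sweep(graph$node_features %*% w$W_in, 2L, w$b_in, `+`))
  for (l in seq_len(config$n_layers)) {
    lw <- w$layers[[l]]
    if (length(src) > 0L) {
      filt <- tanh(sweep(R %*% lw$Wf1, 2L, lw$bf1, `+`)) %*% lw$Wf2
      HW <- H %*% lw$W_pre
      M <- scatter_sum(HW[src, , drop = FALSE] * filt, dst, n)
    } else {
      M <- matrix(0, n, config$hidden_dim)
    }
    H <- H + tanh(sweep(M %*% lw$W_msg + H %*% lw$W_self, 2L, lw$b, `+`))
    check_finite(H, paste0("interaction block ", l))
  }
  check_finite(readout(H, w), "distance readout")
}

# Shift-invariant torsion statistics for one group of angles psi:
# s_k = ((sum cos k psi)^2 + (sum sin k psi)^2) / m^2, the mean of
# cos(k (psi_i - psi_j)) over all ordered pairs. A common shift
# psi -> psi + delta cancels in every pairwise difference.
torsion_group_stats <- function(psi, n_harmonics) {
  m <- length(psi)
  s <- vapply(seq_len(n_harmonics), function(k) {
    (sum(cos(k * psi))^2 + sum(sin(k * psi))^2) / m^2
  }, numeric(1))
  c(m, s)
}

#' Bond-rotation-invariant 3D encoder
#'
#' Consumes the molecular graph plus internal coordinates. Spatial
#' information enters only through (i) radial-basis-expanded bond lengths on
#' the edges, (ii) per-atom bend-angle summaries, and (iii) per-rotatable-bond
#' torsion statistics built from pairwise torsion differences within the
#' bond's group. Because a bond rotation shifts every torsion in one group by
#' the same angle, the embedding is exactly invariant under bond rotations
#' while remaining sensitive to bond lengths and bend angles.
#'
#' @inheritParams encode_2d
#' @param internal_coords An `internal_coords` object for the conformer.
#' @export
encode_bond_invariant <- function(graph, internal_coords, params) {
  config <- params$config
  stopifnot(config$kind == "bond_invariant_3d")
  n <- graph$n_atoms
  if (!identical(internal_coords$version, graph$version)) {
    stop("featurization version mismatch between graph and internal coordinates")
  }
  ba <- internal_coords$bend_angles
  ang_feat <- matrix(0, n, N_ANGLE_FEATURES)
  if (nrow(ba) > 0L) {
    sums <- rowsum(
      cbind(cos(ba$angle_rad), sin(ba$angle_rad), cos(2 * ba$angle_rad), 1),
      group = ba$j
    )
    ang_feat[as.integer(rownames(sums)), ] <- sums
  }
  X <- cbind(graph$node_features, ang_feat)

  if (nrow(internal_coords$bond_lengths) * 2L != nrow(graph$edge_features)) {
    stop("internal coordinates do not match graph edge count")
  }
  len <- rep(internal_coords$bond_lengths$length_A, 2L)
  centers <- seq(0.8, 2.0, length.out = config$n_length_rbf)
  gamma <- 1 / (centers[2L] - centers[1L])^2
  E <- cbind(graph$edge_features, rbf_expand(len, centers, gamma))

  w <- params$weights
  H <- tanh(sweep(X %*% w$W_in, 2L, w$b_in, `+`))
  for (key in names(internal_coords$torsion_groups)) {
    grp <- internal_coords$torsion_groups[[key]]
    stats_vec <- torsion_group_stats(grp$angles, config$n_torsion_harmonics)
    phi <- as.numeric(tanh(stats_vec %*% w$Wt1 + w$bt1) %*% w$Wt2)
    ends <- as.integer(strsplit(key, "-", fixed = TRUE)[[1L]])
    H[ends[[1L]], ] <- H[ends[[1L]], ] + phi
    H[ends[[2L]], ] <- H[ends[[2L]], ] + phi
  }
  H <- graph_message_pass(H, E, graph, w, config)
  check_finite(readout(H, w), "bond-invariant readout")
}

#' Encode a molecule-conformer record with any encoder
#'
#' Dispatches on the config's `kind`, passing the graph, conformer, or
#' internal coordinates as that symmetry class requires.
#'
#' @param params `list(config, weights)`.
#' @param graph A `molecular_graph`.
#' @param conformer Conformer (needed for `distance_3d`).
#' @param internal_coords Internal coordinates (needed for `bond_invariant_3d`).
#' @return Numeric embedding of length `hidden_dim`.
#' @export
encode <- function(params, graph, conformer = NULL, internal_coords = NULL) {
  switch(params$config$kind,
    graph_2d = encode_2d(graph, params),
    distance_3d = {
      if (is.null(conformer)) stop("distance_3d encoder needs a conformer")
      encode_distance(graph, conformer, params)
    },
    bond_invariant_3d = {
      if (is.null(internal_coords)) {
        stop("bond_invariant_3d encoder needs internal coordinates")
      }
      encode_bond_invariant(graph, internal_coords, params)
    }
  )
}

#' Initialize the shared regression head
#'
#' A 2-layer perceptron mapping an embedding to a scalar in eV. The same
#' head architecture is used for every encoder so comparisons isolate the
#' encoder symmetry class.
#'
#' @param hidden_dim Embedding width of the upstream encoder.
#' @param head_dim Hidden width of the perceptron.
#' @param init_seed Seed for the weight draw (0-initialized output layer).
#' @export
init_head <- function(hidden_dim, head_dim = 32L, init_seed = 1L) {
  local_seed(init_seed, {
    list(
      W1 = rand_mat(hidden_dim, head_dim),
      b1 = numeric(head_dim),
      w2 = numeric(head_dim),
      b2 = 0
    )
  })
}

#' Scalar prediction from an embedding
#'
#' @param embedding Numeric embedding vector (or a matrix with one embedding
#'   per row).
#' @param head_params Head weights from [init_head()].
#' @return Scalar prediction(s) in eV.
#' @export
predict_scalar <- function(embedding, head_params) {
  E <- if (is.matrix(embedding)) embedding else matrix(embedding, nrow = 1L)
  if (ncol(E) != nrow(head_params$W1)) {
    stop(
      "embedding dimension ", ncol(E), " does not match head input ",
      nrow(head_params$W1)
    )
  }
  A <- tanh(sweep(E %*% head_params$W1, 2L, head_params$b1, `+`))
  check_finite(A, "head hidden layer")
  y <- as.numeric(A %*% head_params$w2 + head_params$b2)
  check_finite(y, "head output layer")
  y
}
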