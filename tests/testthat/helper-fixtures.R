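# Shared fixtures. Molecules are parsed once per test run through a single
# bridge call; encoder params are tiny so forward passes stay cheap.

FIXTURE_SMILES <- c(
  methane = "C",
  ethane = "CC",
  butane = "CCCC",
  isobutane = "CC(C)C",
  benzene = "c1ccccc1",
  acetamide = "CC(=O)N",
  acetonitrile = "CC#N",
  hydrogen_fluoride = "F",
  ethanol = "CCO",
  propane = "CCC"
)

.fixture_env <- new.env()

fixture_mol <- function(name) {
  if (is.null(.fixture_env$mols)) {
    .fixture_env$mols <- parse_smiles_batch(
      unname(FIXTURE_SMILES),
      ids = names(FIXTURE_SMILES)
    )
    names(.fixture_env$mols) <- names(FIXTURE_SMILES)
  }
  .fixture_env$mols[[name]]
}

fixture_conformer <- function(name, n = 1L, seed = 11L) {
  embed_conformers(fixture_mol(name), n = n, seed = seed)
}

encoder_params <- function(kind, init_seed = 5L, hidden_dim = 24L, n_layers = 2L) {
  config <- make_encoder_config(kind,
    hidden_dim = hidden_dim, n_layers = n_layers,
    init_seed = init_seed
  )
  list(config = config, weights = init_encoder(config))
}

# A small pool of generated molecules that all contain a rotatable bond,
# shared by invariance property tests.
fixture_rotatable_pool <- function(n = 20L) {
  if (is.null(.fixture_env$pool) || length(.fixture_env$pool) < n) {
    mols <- gen_molecules(make_fixture_spec(4L * n, seed = 77L))
    keep <- vapply(mols, function(m) nrow(rotatable_bonds(m)) > 0L, logical(1))
    .fixture_env$pool <- mols[keep]
  }
  .fixture_env$pool[seq_len(n)]
}

# Ideal staggered ethane built from closed-form tetrahedral geometry:
# C-C along x, C-H 1.09 A, H-C-C angle acos(-1/3), azimuths 60/180/300 deg
# on one carbon and 0/120/240 on the other.
ideal_staggered_ethane <- function(mol) {
  stopifnot(mol$n_heavy == 2L)
  coords <- matrix(0, nrow(mol$atoms), 3L)
  carbons <- which(mol$atoms$element == "C")
  coords[carbons[2L], ] <- c(1.54, 0, 0)
  adj <- lapply(seq_len(nrow(mol$atoms)), function(a) {
    c(mol$bonds$j[mol$bonds$i == a], mol$bonds$i[mol$bonds$j == a])
  })
  azimuths <- list(c(60, 180, 300) * pi / 180, c(0, 120, 240) * pi / 180)
  for (ci in 1:2) {
    c_atom <- carbons[[ci]]
    hs <- setdiff(adj[[c_atom]], carbons)
    sign_x <- if (ci == 1L) -1 else 1
    for (t in seq_along(hs)) {
      phi <- azimuths[[ci]][[t]]
      dir <- c(sign_x / 3, sqrt(8) / 3 * cos(phi), sqrt(8) / 3 * sin(phi))
      coords[hs[[t]], ] <- coords[c_atom, ] + 1.09 * dir
    }
  }
  new_conformer(mol$id, coords, "synthetic", 0L)
}

random_quadruples <- function(n, seed) {
  set.seed(seed)
  energy_quadruple(
    e_neutral_at_neutral = stats::runif(n, -100, 100),
    e_neutral_at_cation = stats::runif(n, -100, 100),
    e_cation_at_neutral = stats::runif(n, -100, 100),
    e_cation_at_cation = stats::runif(n, -100, 100)
  )
}

# Constant-output model: zero head weights, fixed bias.
constant_model <- function(value, kind = "graph_2d", task = "lambda_direct") {
  model <- make_model(make_encoder_config(kind, hidden_dim = 8L, init_seed = 1L),
    task = task,
    head_dim = 4L
  )
  model$head$W1[] <- 0
  model$head$w2[] <- 0
  model$head$b2 <- value
  model
}
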