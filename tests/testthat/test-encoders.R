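# Encoder symmetry classes, the regression head, and checkpointing.

embed_with <- function(params, mol, conf) {
  g <- build_graph(mol)
  ic <- if (params$config$kind == "bond_invariant_3d") {
    extract_internal_coords(mol, conf)
  } else {
    NULL
  }
  encode(params, g, conformer = conf, internal_coords = ic)
}

test_that("the bond-invariant encoder ignores bond rotations but not angles", {
  mol <- fixture_mol("butane")
  conf <- fixture_conformer("butane", seed = 13L)[[1L]]
  rb <- rotatable_bonds(mol)
  bond <- c(rb$i[[1L]], rb$j[[1L]])
  params <- encoder_params("bond_invariant_3d")
  e0 <- embed_with(params, mol, conf)
  e_rot <- embed_with(params, mol, rotate_bond(conf, mol, bond, pi / 2))
  expect_lt(max(abs(e0 - e_rot)), 1e-5)

  # perturbing a bend angle by 5 degrees must move the embedding
  coords <- conf$coords
  h <- which(mol$atoms$element == "H")[1L]
  parent <- c(mol$bonds$j[mol$bonds$i == h], mol$bonds$i[mol$bonds$j == h])[1L]
  v <- coords[h, ] - coords[parent, ]
  axis <- c(0, 0, 1)
  ang <- 5 * pi / 180
  coords[h, ] <- coords[parent, ] + v * cos(ang) +
    c(axis[2] * v[3] - axis[3] * v[2], axis[3] * v[1] - axis[1] * v[3], axis[1] * v[2] - axis[2] * v[1]) * sin(ang) +
    axis * sum(axis * v) * (1 - cos(ang))
  bent <- new_conformer(mol$id, coords, conf$provenance, conf$seed)
  e_bent <- embed_with(params, mol, bent)
  expect_gt(max(abs(e0 - e_bent)), 1e-5)
})

test_that("the distance encoder is rigid-motion invariant yet torsion sensitive", {
  mol <- fixture_mol("butane")
  conf <- fixture_conformer("butane", seed = 13L)[[1L]]
  params <- encoder_params("distance_3d")
  e0 <- embed_with(params, mol, conf)

  # rigid rotation + translation
  set.seed(4)
  qr_res <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_res)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  moved <- new_conformer(
    mol$id, conf$coords %*% R + matrix(c(3, -2, 7), nrow(conf$coords), 3, byrow = TRUE),
    conf$provenance, conf$seed
  )
  expect_lt(max(abs(e0 - embed_with(params, mol, moved))), 1e-5)

  # bond rotation moves the embedding in nearly all random initializations
  rb <- rotatable_bonds(mol)
  bond <- c(rb$i[[1L]], rb$j[[1L]])
  rot <- rotate_bond(conf, mol, bond, pi / 2)
  shifts <- vapply(1:40, function(s) {
    p <- encoder_params("distance_3d", init_seed = s)
    max(abs(embed_with(p, mol, conf) - embed_with(p, mol, rot)))
  }, numeric(1))
  expect_gte(mean(shifts > 1e-4), 0.95)
})

test_that("atom pairs beyond the distance cutoff contribute nothing", {
  mol <- fixture_mol("hydrogen_fluoride")
  g <- build_graph(mol)
  params <- encoder_params("distance_3d")
  far1 <- new_conformer(mol$id, rbind(c(0, 0, 0), c(12, 0, 0)), "synthetic", 0L)
  far2 <- new_conformer(mol$id, rbind(c(0, 0, 0), c(55, 0, 0)), "synthetic", 0L)
  near <- new_conformer(mol$id, rbind(c(0, 0, 0), c(0.95, 0, 0)), "synthetic", 0L)
  expect_equal(
    encode(params, g, conformer = far1),
    encode(params, g, conformer = far2)
  )
  expect_false(isTRUE(all.equal(
    encode(params, g, conformer = far1),
    encode(params, g, conformer = near)
  )))
})

test_that("the 2D encoder is conformer-constant and isomer-sensitive", {
  mol <- fixture_mol("butane")
  g <- build_graph(mol)
  params <- encoder_params("graph_2d")
  expect_identical(encode_2d(g, params), encode_2d(g, params))
  # graph-only input: any two conformers give bitwise-equal embeddings
  expect_identical(
    encode(params, g, conformer = fixture_conformer("butane", seed = 1L)[[1L]]),
    encode(params, g, conformer = fixture_conformer("butane", seed = 2L)[[1L]])
  )
  g_iso <- build_graph(fixture_mol("isobutane"))
  expect_false(isTRUE(all.equal(encode_2d(g, params), encode_2d(g_iso, params))))
})

test_that("all encoders are invariant to atom relabeling", {
  set.seed(77)
  mol <- fixture_mol("ethanol")
  conf <- fixture_conformer("ethanol", seed = 5L)[[1L]]
  perm <- sample(nrow(mol$atoms))
  p_out <- permute_atoms(mol, conf, perm)
  for (kind in c("bond_invariant_3d", "distance_3d", "graph_2d")) {
    params <- encoder_params(kind)
    e1 <- embed_with(params, mol, conf)
    e2 <- embed_with(params, p_out$mol, p_out$conformer)
    expect_lt(max(abs(e1 - e2)), 1e-5)
  }
})

test_that("forward passes are finite on generated molecules at default config", {
  for (mol in fixture_rotatable_pool(6L)) {
    conf <- embed_conformers(mol, n = 1L, seed = 3L)[[1L]]
    for (kind in c("bond_invariant_3d", "distance_3d", "graph_2d")) {
      e <- embed_with(encoder_params(kind), mol, conf)
      expect_true(all(is.finite(e)))
    }
  }
})

test_that("predict_scalar matches its closed form", {
  head <- list(W1 = matrix(0, 4, 3), b1 = c(0, 0, 0), w2 = c(1, 2, 3), b2 = 0.5)
  expect_equal(predict_scalar(rep(0, 4), head), 0.5) # zero head path
  head$W1 <- diag(1, 4, 3)
  e <- c(0.3, -0.2, 0.1, 9)
  expect_equal(
    predict_scalar(e, head),
    sum(tanh(e[1:3]) * c(1, 2, 3)) + 0.5
  )
  expect_identical(predict_scalar(e, head), predict_scalar(e, head))
  expect_error(predict_scalar(c(1, 2), head), "dimension")
})

test_that("model checkpoints round-trip and refuse version mismatches", {
  mol <- fixture_mol("ethanol")
  conf <- fixture_conformer("ethanol", seed = 5L)[[1L]]
  model <- make_model(
    make_encoder_config("bond_invariant_3d", hidden_dim = 16L, init_seed = 9L),
    task = "lambda_direct", head_dim = 8L
  )
  rec <- make_record(mol, conf, target = 1.0)
  pred <- predict_records(model, list(rec))
  path <- withr::local_tempfile(fileext = ".ckpt.json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(predict_records(back, list(rec)), pred, tolerance = 1e-12)

  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  ser$featurization_version <- "reorglam-feat-0"
  bad <- withr::local_tempfile(fileext = ".ckpt.json")
  jsonlite::write_json(ser, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(bad), "version")
})
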