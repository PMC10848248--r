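# SMILES parsing, conformer embedding, and structure/label I/O.

test_that("parse_smiles resolves hydrogens and records the chemical graph", {
  methane <- fixture_mol("methane")
  expect_equal(methane$n_heavy, 1L)
  expect_equal(sum(methane$atoms$element == "H"), 4L)
  expect_equal(nrow(methane$bonds), 4L)

  benzene <- fixture_mol("benzene")
  expect_equal(benzene$n_heavy, 6L)
  ring_ar <- benzene$bonds[benzene$bonds$order == "ar", ]
  expect_equal(nrow(ring_ar), 6L)
  expect_true(all(ring_ar$in_ring))
  expect_true(all(benzene$atoms$aromatic[benzene$atoms$element == "C"]))

  # acetamide: C2H5NO, exactly one double bond (C=O); cross-checked against
  # an independent SMILES parser.
  acetamide <- fixture_mol("acetamide")
  expect_equal(acetamide$n_heavy, 4L)
  expect_equal(nrow(acetamide$atoms), 9L)
  dbl <- acetamide$bonds[acetamide$bonds$order == "2", ]
  expect_equal(nrow(dbl), 1L)
  expect_setequal(acetamide$atoms$element[c(dbl$i, dbl$j)], c("C", "O"))
})

test_that("parse_smiles errors name the offending string", {
  expect_error(parse_smiles("not-a-molecule"), "not-a-molecule")
})

test_that("cation records keep neutral connectivity with the redox tag", {
  neutral <- parse_smiles("CCO", "m1", charge = 0L)
  cation <- parse_smiles("CCO", "m1_cat", charge = 1L)
  expect_equal(cation$charge, 1L)
  expect_identical(cation$bonds, neutral$bonds)
})

test_that("embedded methane has realistic C-H bond lengths", {
  mol <- fixture_mol("methane")
  conf <- fixture_conformer("methane")[[1L]]
  d <- sqrt(rowSums((conf$coords[mol$bonds$i, ] - conf$coords[mol$bonds$j, ])^2))
  expect_true(all(d >= 1.0 & d <= 1.2))
  expect_identical(conf$provenance, "distance_geometry")
})

test_that("conformer embedding is deterministic for a fixed seed", {
  mol <- fixture_mol("ethane")
  a <- embed_conformers(mol, n = 5L, seed = 42L)
  clear_bridge_cache()
  b <- embed_conformers(mol, n = 5L, seed = 42L)
  for (k in seq_len(5L)) {
    expect_identical(a[[k]]$coords, b[[k]]$coords)
  }
})

test_that("an embedded ensemble explores the central torsion of butane", {
  mol <- fixture_mol("butane")
  confs <- fixture_conformer("butane", n = 5L, seed = 3L)
  rb <- rotatable_bonds(mol)
  key <- paste0(rb$i[[1L]], "-", rb$j[[1L]])
  # representative heavy-atom dihedral per conformer
  central <- vapply(confs, function(conf) {
    ic <- extract_internal_coords(mol, conf, include_hydrogen_torsions = FALSE)
    ic$torsion_groups[[key]]$angles[[1L]]
  }, numeric(1))
  gaps <- abs(outer(central, central, `-`))
  gaps <- pmin(gaps, 2 * pi - gaps)
  expect_gt(max(gaps), 10 * pi / 180)
})

test_that("every embedded conformer passes clash and bonded-distance checks", {
  for (name in c("butane", "benzene", "ethanol", "acetamide")) {
    mol <- fixture_mol(name)
    for (conf in fixture_conformer(name, n = 3L, seed = 9L)) {
      expect_true(check_conformer_sanity(mol, conf))
    }
  }
})

test_that("SDF round trip preserves atoms, coordinates, and the charge tag", {
  mols <- list(fixture_mol("ethanol"), fixture_mol("acetamide"), fixture_mol("benzene"))
  confs <- lapply(list("ethanol", "acetamide", "benzene"), function(n) {
    fixture_conformer(n, seed = 2L)[[1L]]
  })
  records <- Map(function(m, c) list(mol = m, conformer = c), mols, confs)
  records[[1L]]$mol$charge <- 1L # cation state survives the round trip
  path <- withr::local_tempfile(fileext = ".sdf")
  write_structures(records, path, format = "sdf")
  back <- read_structures(path, format = "sdf")
  expect_length(back, 3L)
  for (k in seq_along(back)) {
    expect_identical(back[[k]]$mol$atoms$element, records[[k]]$mol$atoms$element)
    expect_lt(
      max(abs(back[[k]]$conformer$coords - records[[k]]$conformer$coords)), 1e-4
    )
  }
  expect_equal(back[[1L]]$mol$charge, 1L)
  expect_equal(back[[2L]]$mol$charge, 0L)
})

test_that("XYZ round trip preserves element sequences and coordinates", {
  names <- c("ethanol", "butane", "acetonitrile")
  records <- lapply(names, function(n) {
    list(mol = fixture_mol(n), conformer = fixture_conformer(n, seed = 4L)[[1L]])
  })
  path <- withr::local_tempfile(fileext = ".xyz")
  write_structures(records, path, format = "xyz")
  back <- read_structures(path, format = "xyz")
  expect_length(back, 3L)
  for (k in seq_along(back)) {
    expect_identical(back[[k]]$mol$atoms$element, records[[k]]$mol$atoms$element)
    expect_lt(
      max(abs(back[[k]]$conformer$coords - records[[k]]$conformer$coords)), 1e-4
    )
  }
})

test_that("empty structure files yield an empty list with a warning", {
  path <- withr::local_tempfile(fileext = ".xyz")
  file.create(path)
  expect_warning(out <- read_structures(path, format = "xyz"), "empty")
  expect_length(out, 0L)
})

test_that("label tables enforce the lambda = IP - EA identity per row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "molecule_id,vertical_ip_eV,vertical_ea_eV,lambda_eV",
    "m1,7.0,5.0,2.0",
    "m2,7.0,5.0,1.0"
  ), path)
  expect_error(read_labels(path), "m2")
  expect_warning(tab <- read_labels(path, strict = FALSE), "m2")
  expect_equal(tab$molecule_id, "m1")

  ok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "molecule_id,vertical_ip_eV,vertical_ea_eV,lambda_eV",
    "m1,7.0,5.0,2.0"
  ), ok)
  tab <- read_labels(ok)
  expect_equal(tab$lambda_eV, 2.0)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("molecule_id,vertical_ip_eV,vertical_ea_eV,lambda_eV", empty)
  expect_equal(nrow(read_labels(empty)), 0L)
})

test_that("label round trip is lossless", {
  tab <- data.frame(
    molecule_id = c("a", "b"),
    vertical_ip_eV = c(9.125, 8.5),
    vertical_ea_eV = c(7.025, 8.1),
    lambda_eV = c(2.1, 0.4)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(validate_label_table(tab), path)
  back <- read_labels(path)
  expect_equal(as.data.frame(back), tab)
})
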