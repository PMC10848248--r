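# Graph featurization, internal coordinates, and the bond-rotation operator.

test_that("build_graph encodes ring, aromaticity and bond-order features", {
  g <- build_graph(fixture_mol("benzene"))
  carbons <- which(fixture_mol("benzene")$atoms$element == "C")
  expect_true(all(g$node_features[carbons, "aromatic"] == 1))
  expect_true(all(g$node_features[carbons, "ring"] == 1))

  gm <- build_graph(fixture_mol("methane"))
  expect_equal(gm$n_atoms, 5L)
  expect_equal(nrow(gm$edges), 8L) # 4 bonds, both directions
  expect_true(all(gm$node_features[, "ring"] == 0))

  gn <- build_graph(fixture_mol("acetonitrile"))
  expect_equal(sum(gn$edge_features[, "order3"]), 2L) # one triple bond x 2 directions
})

test_that("every edge appears in both directions", {
  for (name in c("benzene", "butane", "acetamide")) {
    g <- build_graph(fixture_mol(name))
    fwd <- paste(g$edges$src, g$edges$dst)
    rev <- paste(g$edges$dst, g$edges$src)
    expect_setequal(fwd, rev)
  }
})

test_that("graph featurization commutes with atom relabeling", {
  set.seed(31)
  for (name in c("butane", "acetamide", "benzene")) {
    mol <- fixture_mol(name)
    g <- build_graph(mol)
    perm <- sample(nrow(mol$atoms))
    gp <- build_graph(permute_atoms(mol, perm = perm)$mol)
    # node k of the original is node perm[k] of the permuted graph
    expect_equal(gp$node_features[perm, ], g$node_features, ignore_attr = TRUE)
    key <- function(gg) sort(paste(gg$edges$src, gg$edges$dst))
    expect_identical(
      sort(paste(perm[g$edges$src], perm[g$edges$dst])),
      key(gp)
    )
  }
})

test_that("ideal staggered ethane has torsions at +/-60 and 180 degrees", {
  mol <- fixture_mol("ethane")
  conf <- ideal_staggered_ethane(mol)
  ic <- extract_internal_coords(mol, conf)
  # H-C-C-H paths through the C-C bond; the bond is not "rotatable" by the
  # heavy-degree rule, so measure the dihedrals directly.
  carbons <- which(mol$atoms$element == "C")
  hs1 <- setdiff(c(
    mol$bonds$j[mol$bonds$i == carbons[1]],
    mol$bonds$i[mol$bonds$j == carbons[1]]
  ), carbons)
  hs2 <- setdiff(c(
    mol$bonds$j[mol$bonds$i == carbons[2]],
    mol$bonds$i[mol$bonds$j == carbons[2]]
  ), carbons)
  angles <- c()
  for (a in hs1) {
    for (d in hs2) {
      angles <- c(angles, dihedral_angle(
        conf$coords[a, ], conf$coords[carbons[1], ],
        conf$coords[carbons[2], ], conf$coords[d, ]
      ))
    }
  }
  deg <- angles * 180 / pi
  nearest <- vapply(deg, function(x) min(abs(x - c(-60, 60, 180, -180))), numeric(1))
  expect_true(all(nearest < 1))
  # and the ideal bond lengths round-trip through the extractor
  len <- ic$bond_lengths$length_A
  expect_true(all(pmin(abs(len - 1.09), abs(len - 1.54)) < 1e-8))
})

test_that("degenerate topologies yield empty coordinate sets", {
  hf <- fixture_mol("hydrogen_fluoride")
  ic <- extract_internal_coords(hf, fixture_conformer("hydrogen_fluoride")[[1L]])
  expect_equal(nrow(ic$bend_angles), 0L)
  expect_length(ic$torsion_groups, 0L)

  benzene_ic <- extract_internal_coords(
    fixture_mol("benzene"),
    fixture_conformer("benzene")[[1L]]
  )
  expect_length(benzene_ic$torsion_groups, 0L) # all ring bonds
})

test_that("rotatable bonds require single, acyclic, non-terminal heavy bonds", {
  expect_equal(nrow(rotatable_bonds(fixture_mol("butane"))), 1L)
  expect_equal(nrow(rotatable_bonds(fixture_mol("ethane"))), 0L)
  expect_equal(nrow(rotatable_bonds(fixture_mol("benzene"))), 0L)
  expect_equal(nrow(rotatable_bonds(fixture_mol("acetonitrile"))), 0L)
  # ethanol's C-O bond is terminal under the heavy-degree rule (O carries
  # only hydrogens besides the carbon), so nothing is rotatable
  expect_equal(nrow(rotatable_bonds(fixture_mol("ethanol"))), 0L)
})

test_that("rotate_bond shifts exactly one torsion group by the rotation angle", {
  mol <- fixture_mol("butane")
  conf <- fixture_conformer("butane", seed = 8L)[[1L]]
  rb <- rotatable_bonds(mol)
  bond <- c(rb$i[[1L]], rb$j[[1L]])
  key <- paste0(bond[[1L]], "-", bond[[2L]])
  ic <- extract_internal_coords(mol, conf)

  # identity and periodicity
  expect_equal(rotate_bond(conf, mol, bond, 0)$coords, conf$coords)
  full <- extract_internal_coords(mol, rotate_bond(conf, mol, bond, 2 * pi))
  wrap <- function(x) atan2(sin(x), cos(x))
  expect_lt(
    max(abs(wrap(full$torsion_groups[[key]]$angles - ic$torsion_groups[[key]]$angles))),
    1e-8
  )

  delta <- pi / 3
  rot <- rotate_bond(conf, mol, bond, delta)
  ic2 <- extract_internal_coords(mol, rot)
  shifts <- wrap(ic2$torsion_groups[[key]]$angles - ic$torsion_groups[[key]]$angles)
  expect_lt(max(abs(abs(shifts) - delta)), 1e-8) # common magnitude delta
  expect_lt(max(shifts) - min(shifts), 1e-8) # same sign for the whole group
  expect_lt(max(abs(ic2$bond_lengths$length_A - ic$bond_lengths$length_A)), 1e-8)
  expect_lt(max(abs(ic2$bend_angles$angle_rad - ic$bend_angles$angle_rad)), 1e-8)
})

test_that("rotating a bond leaves every other torsion group untouched", {
  set.seed(19)
  wrap <- function(x) atan2(sin(x), cos(x))
  for (mol in fixture_rotatable_pool(8L)) {
    conf <- embed_conformers(mol, n = 1L, seed = 21L)[[1L]]
    ic <- extract_internal_coords(mol, conf)
    rb <- rotatable_bonds(mol)
    r <- sample(nrow(rb), 1L)
    bond <- c(rb$i[[r]], rb$j[[r]])
    key <- paste0(bond[[1L]], "-", bond[[2L]])
    delta <- stats::runif(1, -pi, pi)
    ic2 <- extract_internal_coords(mol, rotate_bond(conf, mol, bond, delta))
    for (other in setdiff(names(ic$torsion_groups), key)) {
      expect_lt(
        max(abs(wrap(ic2$torsion_groups[[other]]$angles -
          ic$torsion_groups[[other]]$angles))),
        1e-8
      )
    }
    shifts <- wrap(ic2$torsion_groups[[key]]$angles - ic$torsion_groups[[key]]$angles)
    expect_lt(max(abs(abs(shifts) - abs(wrap(delta)))), 1e-8)
  }
})

test_that("rotate_bond refuses non-rotatable bonds", {
  mol <- fixture_mol("benzene")
  conf <- fixture_conformer("benzene")[[1L]]
  ring_bond <- c(mol$bonds$i[[1L]], mol$bonds$j[[1L]])
  expect_error(rotate_bond(conf, mol, ring_bond, 0.5), "not rotatable")
})

test_that("rbf_expand matches its closed form", {
  centers <- seq(0, 10, length.out = 11)
  v <- rbf_expand(3, centers, gamma = 2)
  expect_equal(v[1, 4], 1) # d on a center
  expect_true(all(v > 0 & v <= 1))
  mid <- rbf_expand(3.5, centers, gamma = 2)
  expect_equal(mid[1, 4], mid[1, 5]) # symmetric between adjacent centers
  expect_equal(as.numeric(rbf_expand(c(1, 7), centers, gamma = 0)),
    rep(1, 22),
    tolerance = 1e-12
  ) # gamma -> 0 limit
})
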