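test_that("mass fractions match hand sums on small molecules", {
  methane <- chain_molecule("C")
  expect_equal(o_composition(methane), 0)

  water <- molecule_graph("water", data.frame(element = "O"),
                          data.frame(i = integer(0), j = integer(0),
                                     order = integer(0), aromatic = logical(0)))
  # O / (O + 2 H) from the packaged IUPAC masses
  expect_equal(o_composition(water), 100 * 15.999 / (15.999 + 2 * 1.008),
               tolerance = 1e-12)

  ethanol <- chain_molecule(c("C", "C", "O"))
  m <- atomic_masses()
  expect_equal(o_composition(ethanol),
               100 * m[["O"]] / (2 * m[["C"]] + m[["O"]] + 6 * m[["H"]]),
               tolerance = 1e-12)
  expect_equal(unname(o_composition(ethanol)), 34.73, tolerance = 1e-3)
})

test_that("mass fractions are reorder-invariant and sum to 100 percent", {
  mol <- chain_molecule(c("C", "O", "N", "C", "S"))
  perm <- c(3, 1, 5, 2, 4)
  remap <- match(seq_len(5), perm)
  mol2 <- molecule_graph("perm",
    atoms = mol$atoms[perm, , drop = FALSE],
    bonds = transform(mol$bonds, i = remap[i], j = remap[j]))
  expect_equal(o_composition(mol), o_composition(mol2))
  elems <- names(element_counts(mol))
  total <- sum(vapply(elems, function(e) mass_fraction(mol, e), numeric(1)))
  expect_equal(total, 100, tolerance = 1e-10)
})

test_that("unknown elements are reported by name", {
  mol <- chain_molecule(c("C", "Xx"))
  expect_error(o_composition(mol), "Xx")
})

test_that("ring bond count matches known ring systems and an igraph bridge oracle", {
  expect_equal(ring_bond_count(chain_molecule(rep("C", 6))), 0)
  expect_equal(ring_bond_count(ring_molecule(rep("C", 6))), 6)
  expect_equal(ring_bond_count(naphthalene_graph()), 11)

  for (seed in 1:12) {
    mol <- random_molecule(n_atoms = sample(4:12, 1), n_extra = sample(0:4, 1),
                           seed = seed)
    g <- igraph::graph_from_edgelist(cbind(mol$bonds$i, mol$bonds$j),
                                     directed = FALSE)
    bridges <- igraph::bridges(g)
    expect_equal(ring_bond_count(mol), nrow(mol$bonds) - length(bridges),
                 info = paste("seed", seed))
  }
})

test_that("sssr size equals the circuit rank on random graphs", {
  for (seed in 13:24) {
    mol <- random_molecule(n_atoms = sample(4:12, 1), n_extra = sample(0:4, 1),
                           seed = seed)
    g <- igraph::graph_from_edgelist(cbind(mol$bonds$i, mol$bonds$j),
                                     directed = FALSE)
    rank <- nrow(mol$bonds) - nrow(mol$atoms) +
      igraph::count_components(g)
    expect_length(sssr(mol), rank)
  }
})

test_that("aliphatic ring count distinguishes aromatic from saturated rings", {
  benzene_flagged <- ring_molecule(rep("C", 6), orders = 1L, aromatic = TRUE)
  expect_equal(aliphatic_ring_count(benzene_flagged), 0)
  # kekulized benzene without flags: perceived aromatic by alternation
  benzene_kekule <- ring_molecule(rep("C", 6), orders = c(1L, 2L))
  expect_equal(aliphatic_ring_count(benzene_kekule), 0)
  cyclohexane <- ring_molecule(rep("C", 6))
  expect_equal(aliphatic_ring_count(cyclohexane), 1)
  pyrrolidine <- ring_molecule(c("N", rep("C", 4)))
  expect_equal(aliphatic_ring_count(pyrrolidine), 1)
  # tetralin-like: one aromatic + one saturated fused ring
  half <- naphthalene_graph(aromatic = c(rep(TRUE, 6), rep(FALSE, 5)))
  expect_equal(aliphatic_ring_count(half), 1)
  expect_equal(aliphatic_ring_count(chain_molecule(rep("C", 4))), 0)
})

test_that("projection of a single sphere is orientation-invariant", {
  one <- molecule_graph("atom", data.frame(element = "C", x = 0, y = 0, z = 0),
                        data.frame(i = integer(0), j = integer(0),
                                   order = integer(0), aromatic = logical(0)))
  s <- projection_settings(radii = c(C = 1.5), n_orientations = 24,
                           grid_resolution = 0.02)
  area <- projection_areas(one, s)
  expect_equal(unname(area["min"]), pi * 1.5^2, tolerance = 0.01)
  expect_equal(unname(area["max"]), pi * 1.5^2, tolerance = 0.01)
  expect_equal(unname(area["min"]), unname(area["max"]), tolerance = 1e-6)

  # two coincident atoms are a single disk
  two <- molecule_graph("coincident",
    data.frame(element = c("C", "C"), x = 0, y = 0, z = 0),
    data.frame(i = integer(0), j = integer(0), order = integer(0),
               aromatic = logical(0)))
  area2 <- projection_areas(two, s)
  expect_equal(unname(area2["max"]), pi * 1.5^2, tolerance = 0.01)
})

test_that("two tangent spheres bracket between one disk and two, per closed form", {
  dumbbell <- molecule_graph("dumbbell",
    data.frame(element = c("C", "C"), x = 0, y = 0, z = c(0, 2)),
    data.frame(i = 1, j = 2, order = 1L, aromatic = FALSE))
  s <- projection_settings(radii = c(C = 1.0), n_orientations = 64,
                           grid_resolution = 0.02)
  area <- projection_areas(dumbbell, s)
  # axial view (z pole is always sampled): one disk; side view: two tangent
  expect_equal(unname(area["min"]), pi, tolerance = 0.01 * pi)
  expect_equal(unname(area["max"]), union_two_disks(1, 1, 2),
               tolerance = 0.01 * 2 * pi)
  expect_lte(area["min"], area["max"])
})

test_that("grid integration converges to the closed-form union area", {
  for (d in c(0.7, 1.3, 2.5)) {
    got <- qsardpp:::union_disk_area(px = c(0, d), py = c(0, 0),
                                     r = c(1, 1), h = 0.02)
    want <- union_two_disks(1, 1, d)
    expect_equal(got, want, tolerance = 0.01 * want)
  }
})

test_that("more orientations never loosen the projection bracket", {
  set.seed(99)
  blob <- molecule_graph("blob",
    data.frame(element = rep("C", 5), x = rnorm(5), y = rnorm(5),
               z = rnorm(5)),
    data.frame(i = integer(0), j = integer(0), order = integer(0),
               aromatic = logical(0)))
  coarse <- projection_areas(blob, projection_settings(n_orientations = 16,
                                                       grid_resolution = 0.05))
  fine <- projection_areas(blob, projection_settings(n_orientations = 32,
                                                     grid_resolution = 0.05))
  expect_lte(fine["min"], coarse["min"])
  expect_gte(fine["max"], coarse["max"])
})

test_that("projection areas demand coordinates", {
  expect_error(projection_areas(chain_molecule(c("C", "C"))), "3D")
})

test_that("the descriptor table assembles per-molecule values and pKa passthrough", {
  water_path <- write_mol_file(mol_block("water", water_atoms, water_bonds))
  methane <- molecule_graph("methane", data.frame(element = "C"),
                            data.frame(i = integer(0), j = integer(0),
                                       order = integer(0), aromatic = logical(0)))
  mols <- list(read_mol(water_path), methane)
  tab <- compute_descriptor_table(mols, c("OComposition", "RingBondCount"))
  expect_equal(n_samples(tab), 2)
  expect_equal(tab$sample_ids, c("water", "methane"))
  expect_equal(unname(tab$values[, "OComposition"]),
               c(100 * 15.999 / (15.999 + 2 * 1.008), 0), tolerance = 1e-10)
  expect_equal(unname(tab$values[, "RingBondCount"]), c(0, 0))

  empty <- compute_descriptor_table(list(), c("OComposition"))
  expect_equal(n_samples(empty), 0)
  expect_equal(feature_names(empty), "OComposition")

  pka <- feature_table(matrix(c(7.4, 9.1), 2, dimnames = list(NULL, "BasicpKa")),
                       c("water", "methane"))
  tab2 <- compute_descriptor_table(mols, c("BasicpKa"), pka_table = pka)
  expect_equal(unname(tab2$values[, "BasicpKa"]), c(7.4, 9.1))

  expect_error(compute_descriptor_table(mols, "BasicpKa"), "pka_table")
  expect_error(compute_descriptor_table(mols, "Nonexistent"), "available")
})
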