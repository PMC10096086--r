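test_that("molecular weight sums standard atomic weights", {
  single <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0))
  expect_equal(molecular_weight(single), 12.011)
  # independent sum for C10H8
  expect_equal(molecular_weight(build_cata_pah("0,0;1,0")),
               10 * 12.011 + 8 * 1.008)
  expect_error(molecular_weight(molecule(data.frame(element = character(),
                                                    x = numeric(),
                                                    y = numeric(),
                                                    z = numeric()))),
               "empty")
  unknown <- molecule(data.frame(element = "Xx", x = 0, y = 0, z = 0))
  expect_error(molecular_weight(unknown), "Xx")
})

test_that("circuit counts match exhaustive subset enumeration", {
  benz <- build_cata_pah("0,0")
  rd <- ring_descriptors(benz)
  expect_equal(rd$nCIR, 1L)
  expect_equal(rd$nR10, 0L)
  expect_equal(rd$nCIR, length(oracle_circuit_sizes(benz)))

  naph <- build_cata_pah("0,0;1,0")
  rd <- ring_descriptors(naph)
  sizes <- oracle_circuit_sizes(naph)
  expect_equal(rd$nCIR, 3L)
  expect_equal(rd$nR10, 1L)
  expect_equal(rd$nCIR, length(sizes))
  expect_equal(rd$nR10, sum(sizes == 10L))

  anth <- build_cata_pah("0,0;1,0;2,0")
  rd <- ring_descriptors(anth)
  sizes <- oracle_circuit_sizes(anth)
  expect_equal(rd$nCIR, length(sizes))
  expect_equal(rd$nR10, sum(sizes == 10L))

  chain <- molecule(data.frame(element = rep("C", 4), x = 1.4 * (0:3),
                               y = 0, z = 0),
                    data.frame(i = 1:3, j = 2:4))
  rd <- ring_descriptors(chain)
  expect_equal(rd$nCIR, 0L)
  expect_equal(rd$nR10, 0L)
})

test_that("nCIR dominates the cyclomatic number and nR10", {
  for (cells in c("0,0;1,0", "0,0;1,0;1,-1", "0,0;1,0;0,1;1,-1")) {
    m <- build_cata_pah(cells)
    rd <- ring_descriptors(m)
    heavy <- sum(m$atoms$element == "C")
    cc_bonds <- sum(m$atoms$element[m$bonds$i] == "C" &
                      m$atoms$element[m$bonds$j] == "C")
    expect_gte(rd$nCIR, cc_bonds - heavy + 1L)  # connected skeleton
    expect_lte(rd$nR10, rd$nCIR)
  }
})

test_that("RDF matches its closed forms and the brute-force pair loop", {
  pair <- molecule(data.frame(element = c("C", "C"), x = c(0, 3), y = 0, z = 0))
  expect_equal(rdf_descriptor(pair, 30), 1.0)

  benz <- build_cata_pah("0,0")
  expect_lt(rdf_descriptor(benz, 150), 1e-6)

  naph <- build_cata_pah("0,0;1,0")
  expect_equal(rdf_descriptor(naph, 30, weighting = "m"),
               oracle_rdf(naph, 3.0, "m"), tolerance = 1e-12)
  expect_gte(rdf_descriptor(naph, 45), 0)

  # mass weighting equals unweighted on a pure-carbon frame
  frame <- molecule(naph$atoms[naph$atoms$element == "C", ])
  expect_equal(rdf_descriptor(frame, 50, "m"), rdf_descriptor(frame, 50, "u"))

  expect_error(rdf_descriptor(naph, 31), "invalid")
  lone <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0))
  expect_warning(v <- rdf_descriptor(lone, 30), "fewer than 2")
  expect_equal(v, 0)
})

test_that("MoRSE matches its closed forms and the brute-force pair loop", {
  tri <- molecule(data.frame(element = rep("C", 3), x = c(0, 1, 2), y = 0, z = 0))
  # signal 1 maps to s = 0: kernel 1 for every pair
  expect_equal(morse_descriptor(tri, 1), 3)

  pair <- molecule(data.frame(element = c("C", "C"), x = c(0, 1.7), y = 0, z = 0))
  s <- 6  # signal 7 under the default convention
  expect_equal(morse_descriptor(pair, 7), sin(s * 1.7) / (s * 1.7))
  expect_equal(morse_descriptor(pair, 7, convention = "signal"),
               sin(7 * 1.7) / (7 * 1.7))

  benz <- build_cata_pah("0,0")
  expect_equal(morse_descriptor(benz, 7), oracle_morse(benz, 6),
               tolerance = 1e-12)
  expect_error(morse_descriptor(benz, 0), "1..32")
})

test_that("RDF and MoRSE are invariant to rotation, translation, reordering", {
  for (seed in 1:5) {
    mol <- random_cloud(12, seed)
    moved <- rotate_translate(mol, seed + 100)
    expect_equal(rdf_descriptor(moved, 40, "m"), rdf_descriptor(mol, 40, "m"),
                 tolerance = 1e-9)
    expect_equal(morse_descriptor(moved, 9, "m"), morse_descriptor(mol, 9, "m"),
                 tolerance = 1e-9)
    set.seed(seed)
    perm <- sample(n_atoms(mol))
    shuffled <- molecule(mol$atoms[perm, ])
    expect_equal(rdf_descriptor(shuffled, 40, "m"), rdf_descriptor(mol, 40, "m"),
                 tolerance = 1e-12)
    expect_equal(morse_descriptor(shuffled, 9, "m"), morse_descriptor(mol, 9, "m"),
                 tolerance = 1e-12)
  }
})

test_that("descriptor tables are per-cell reproducible and deterministic", {
  mols <- lattice_pah_set()
  specs <- c("MW", "nCIR", "nR10", "RDF030m", "RDF090u", "Mor07u")
  tab <- compute_descriptor_table(mols, specs)
  expect_equal(dim(tab), c(16L, 7L))
  expect_false(anyNA(tab))

  # MW strictly increases with carbon count
  ncarb <- vapply(mols, function(m) sum(m$atoms$element == "C"), 0L)
  ord <- order(ncarb)
  distinct <- diff(ncarb[ord]) > 0
  expect_true(all(diff(tab$MW[ord])[distinct] > 0))

  # spot-check cells against the standalone operations
  expect_equal(tab$RDF030m[2], rdf_descriptor(mols[[2]], 30, "m"))
  expect_equal(tab$Mor07u[5], morse_descriptor(mols[[5]], 7, "u"))
  expect_equal(tab$nCIR[1], 1)

  dup <- compute_descriptor_table(list(a = mols[[3]], b = mols[[3]]), specs)
  expect_equal(as.numeric(dup[1, -1]), as.numeric(dup[2, -1]))

  expect_error(compute_descriptor_table(mols, c("MW", "bogus")), "unrecognized")
  expect_error(compute_descriptor_table(mols, c("MW", "MW")), "duplicate")
})
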