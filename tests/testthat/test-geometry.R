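test_that("XYZ files parse and round-trip", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water-ish", "O 0.0 0.0 0.0", "H 0.96 0.0 0.0",
               "H -0.24 0.93 0.0"), path)
  mol <- read_xyz(path)
  expect_equal(n_atoms(mol), 3L)
  expect_equal(mol$atoms$element, c("O", "H", "H"))
  expect_equal(nrow(mol$bonds), 0L)

  out <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(mol, out)
  back <- read_xyz(out)
  expect_equal(back$atoms$element, mol$atoms$element)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(mol$atoms[, c("x", "y", "z")]), tolerance = 1e-6)
})

test_that("XYZ contract violations raise parse errors", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "short", "C 0 0 0", "C 1 0 0", "C 2 0 0", "C 3 0 0"), path)
  expect_error(read_xyz(path), "declared 5")

  writeLines(c("2", "bad coord", "C 0 0 0", "C one 0 0"), path)
  expect_error(read_xyz(path), "non-numeric")
})

test_that("SDF V2000 records parse with atoms and bonds", {
  path <- withr::local_tempfile(fileext = ".sdf")
  hdr <- c("benzene", "  qsrr", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 6L, 6L)
  ang <- pi / 3 * (0:5)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   1.4 * cos(ang), 1.4 * sin(ang), 0, "C")
  bonds <- sprintf("%3d%3d%3d  0  0  0  0", 1:6, c(2:6, 1L), 1L)
  writeLines(c(hdr, counts, atoms, bonds, "M  END", "$$$$"), path)
  mol <- read_sdf(path)
  expect_equal(n_atoms(mol), 6L)
  expect_equal(nrow(mol$bonds), 6L)
  expect_equal(mol$name, "benzene")

  # bond referencing a nonexistent atom
  bad_bonds <- sprintf("%3d%3d%3d  0  0  0  0", c(1L, 1L), c(2L, 9L), 1L)
  writeLines(c(hdr, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 6L, 2L),
               atoms, bad_bonds, "M  END"), path)
  expect_error(read_sdf(path), "outside")

  # single atom, no bond block
  writeLines(c("methane-core", "", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 1L, 0L),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0", 0, 0, 0, "C"),
               "M  END"), path)
  one <- read_sdf(path)
  expect_equal(n_atoms(one), 1L)
  expect_equal(nrow(one$bonds), 0L)
})

test_that("lattice builder reproduces benzene, naphthalene, anthracene counts", {
  b <- build_cata_pah("0,0")
  expect_equal(sum(b$atoms$element == "C"), 6L)
  expect_equal(sum(b$atoms$element == "H"), 6L)

  n <- build_cata_pah("0,0;1,0")
  expect_equal(sum(n$atoms$element == "C"), 10L)
  expect_equal(sum(n$atoms$element == "H"), 8L)
  cc <- n$bonds[n$atoms$element[n$bonds$i] == "C" &
                  n$atoms$element[n$bonds$j] == "C", ]
  expect_equal(nrow(cc), 11L)

  a <- build_cata_pah("0,0;1,0;2,0")
  expect_equal(sum(a$atoms$element == "C"), 14L)
  expect_equal(sum(a$atoms$element == "H"), 10L)

  expect_error(build_cata_pah("0,0;3,0"), "disconnected")
})

test_that("lattice geometry is exact: bond lengths, neighbour counts, planarity", {
  mol <- build_cata_pah("0,0;1,0;1,-1;2,-1", name = "chrysene-like")
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  el <- mol$atoms$element
  expect_true(all(mol$atoms$z == 0))
  cdeg <- integer(sum(el == "C"))
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    len <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (el[i] == "C" && el[j] == "C") {
      expect_equal(len, 1.40, tolerance = 1e-9)
      cdeg[i] <- cdeg[i] + 1L; cdeg[j] <- cdeg[j] + 1L
    } else {
      expect_equal(len, 1.09, tolerance = 1e-9)
    }
  }
  expect_true(all(cdeg %in% c(2L, 3L)))
})

test_that("bond perception follows distance cutoffs and ignores atom order", {
  two <- molecule(data.frame(element = c("C", "C"), x = c(0, 1.4), y = 0, z = 0))
  expect_equal(nrow(perceive_bonds(two)$bonds), 1L)
  far <- molecule(data.frame(element = c("C", "C"), x = c(0, 3.0), y = 0, z = 0))
  expect_equal(nrow(perceive_bonds(far)$bonds), 0L)

  benz <- build_cata_pah("0,0")
  bare <- molecule(benz$atoms, NULL, "benzene")
  perc <- perceive_bonds(bare)
  el <- perc$atoms$element
  kinds <- paste(pmin(el[perc$bonds$i], el[perc$bonds$j]),
                 pmax(el[perc$bonds$i], el[perc$bonds$j]), sep = "-")
  expect_equal(sum(kinds == "C-C"), 6L)
  expect_equal(sum(kinds == "C-H"), 6L)

  # reorder atoms: same bonds up to index relabelling
  set.seed(4)
  perm <- sample(n_atoms(bare))
  shuffled <- molecule(bare$atoms[perm, ], NULL, "benzene-shuffled")
  perc2 <- perceive_bonds(shuffled)
  canon <- function(m, map) {
    sort(apply(cbind(map[m$bonds$i], map[m$bonds$j]), 1L,
               function(p) paste(sort(p), collapse = "-")))
  }
  expect_equal(canon(perc2, perm), canon(perc, seq_len(n_atoms(bare))))
})
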