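# SDF / SMILES input-output and conformer generation.

min_v2000 <- function(title = "tiny") {
  c(title, "", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.2345    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "M  END",
    "$$$$")
}

test_that("a minimal V2000 record reads as one molecule with one conformer", {
  tf <- tempfile(fileext = ".sdf")
  writeLines(min_v2000(), tf)
  recs <- read_sdf(tf)
  expect_length(recs, 1)
  mol <- recs[[1]]$molecule
  expect_equal(nrow(mol$atoms), 3)
  expect_equal(mol$atoms$element, c("C", "C", "O"))
  expect_length(mol$conformers, 1)
  expect_equal(mol$conformers[[1]][3, 2], 1.2345)
  expect_equal(recs[[1]]$record_index, 0)
})

test_that("an empty SDF file reads as an empty library", {
  tf <- tempfile(fileext = ".sdf")
  writeLines(character(0), tf)
  expect_length(read_sdf(tf), 0)
})

test_that("truncated records are skipped with a warning, or fatal when strict", {
  tf <- tempfile(fileext = ".sdf")
  good <- function(i) min_v2000(paste0("mol", i))
  broken <- c("bad", "", "", "  5  4  0  0  0  0999 V2000",
              "    0.0000    0.0000", "$$$$")
  writeLines(c(good(1), good(2), broken, good(4), good(5)), tf)
  expect_warning(recs <- read_sdf(tf), "malformed")
  expect_length(recs, 4)
  expect_equal(vapply(recs, function(r) r$molecule$id, ""),
               c("mol1", "mol2", "mol4", "mol5"))
  expect_error(read_sdf(tf, strict = TRUE), "malformed")
})

test_that("SDF round trip preserves counts and coordinates to 4 decimals", {
  tf <- tempfile(fileext = ".sdf")
  writeLines(min_v2000(), tf)
  recs <- read_sdf(tf)
  out <- tempfile(fileext = ".sdf")
  write_sdf(recs, out)
  back <- read_sdf(out)
  expect_length(back, 1)
  expect_equal(nrow(back[[1]]$molecule$atoms), 3)
  expect_equal(nrow(back[[1]]$molecule$bonds), 2)
  expect_equal(back[[1]]$molecule$conformers[[1]],
               recs[[1]]$molecule$conformers[[1]], tolerance = 1e-4)
  # richer case: embedded phenol with hydrogens
  ph <- embedded_mol("c1ccccc1O", "phenol")
  write_sdf(list(ph), out)
  back <- read_sdf(out)
  expect_equal(back[[1]]$molecule$conformers[[1]], ph$conformers[[1]],
               tolerance = 1e-4)
  expect_equal(nrow(back[[1]]$molecule$bonds), nrow(ph$bonds))
})

test_that("a multi-conformer molecule round-trips as consecutive records", {
  mol <- embedded_mol("CCCCO", "butanol")
  mol <- generate_conformers(mol, max_conformers = 3, seed = 5)
  out <- tempfile(fileext = ".sdf")
  write_sdf(list(mol), out)
  n_recs <- sum(grepl("^\\$\\$\\$\\$", readLines(out)))
  expect_equal(n_recs, length(mol$conformers))
  back <- read_sdf(out)
  expect_length(back, 1)   # regrouped into one molecule
  expect_length(back[[1]]$molecule$conformers, length(mol$conformers))
  expect_equal(back[[1]]$molecule$structure_key, mol$structure_key)
})

test_that("writing an empty library yields a valid empty file", {
  out <- tempfile(fileext = ".sdf")
  write_sdf(list(), out)
  expect_true(file.exists(out))
  expect_length(read_sdf(out), 0)
})

test_that("SMILES tables parse with warnings for bad lines and duplicates", {
  tf <- tempfile()
  writeLines(c("smiles id", "CCO ethanol", "c1ccccc1 benzene"), tf)
  recs <- read_smiles_table(tf)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$molecule$id, "ethanol")
  expect_equal(sum(recs[[1]]$molecule$atoms$element != "H"), 3)
  expect_length(recs[[1]]$molecule$conformers, 0)

  writeLines(c("not_a_smiles x"), tf)
  expect_warning(recs <- read_smiles_table(tf), "unparsable")
  expect_length(recs, 0)

  writeLines(c("CCO a", "CCC a"), tf)
  expect_warning(recs <- read_smiles_table(tf), "duplicate")
  expect_length(recs, 2)
})

test_that("structure keys are invariant to atom order and retain stereo", {
  tf <- tempfile()
  writeLines(c("OCC eth1", "CCO eth2", "C(C)O eth3"), tf)
  recs <- read_smiles_table(tf)
  keys <- vapply(recs, function(r) r$molecule$structure_key, "")
  expect_length(unique(keys), 1)
  # enantiomers must have distinct keys
  writeLines(c("C[C@H](N)C(=O)O l_ala", "C[C@@H](N)C(=O)O d_ala"), tf)
  recs <- read_smiles_table(tf)
  expect_false(recs[[1]]$molecule$structure_key ==
                 recs[[2]]$molecule$structure_key)
})

test_that("conformer generation is seed-deterministic and clash-free", {
  mol <- embedded_mol("CCCCCO", "pentanol")
  a <- generate_conformers(mol, max_conformers = 10, seed = 7)
  b <- generate_conformers(mol, max_conformers = 10, seed = 7)
  expect_identical(a$conformers, b$conformers)
  expect_gte(length(a$conformers), 1)
  expect_lte(length(a$conformers), 10)
  for (cf in a$conformers) {
    d <- as.matrix(dist(cf))
    diag(d) <- Inf
    expect_gte(min(d), 0.8)
  }
  # ethanol capped at one conformer
  eth <- embedded_mol("CCO", "ethanol")
  expect_length(generate_conformers(eth, max_conformers = 1,
                                    seed = 7)$conformers, 1)
  # cyclohexane: rigid ring, between 1 and 10 conformers
  cyc <- embedded_mol("C1CCCCC1", "cyclohexane")
  n <- length(generate_conformers(cyc, max_conformers = 10,
                                  seed = 1)$conformers)
  expect_gte(n, 1)
  expect_lte(n, 10)
})

test_that("molecules without a parsable structure refuse to embed", {
  mol <- molecule("broken", data.frame(element = "C", charge = 0,
                                       aromatic = FALSE),
                  data.frame(a1 = integer(0), a2 = integer(0),
                             order = integer(0)))
  expect_error(generate_conformers(mol, 1, 1), "broken")
})
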