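# Feature perception: placements, directions, rule boundaries,
# equivariance, and the documented SMARTS of the default rule table.

test_that("benzene yields one ring feature with a true plane normal plus one hydrophobic", {
  mol <- embedded_mol("c1ccccc1", "benzene")
  fs <- perceive_features(mol)
  expect_equal(sum(fs$features$kind == "AI"), 1)
  expect_equal(sum(fs$features$kind == "HC"), 1)
  expect_equal(nrow(fs$features), 2)
  ai <- fs$features[fs$features$kind == "AI", ]
  ring <- ai$atoms[[1]]
  X <- mol$conformers[[1]][ring, ]
  centroid <- colMeans(X)
  expect_equal(as.numeric(ai[, c("x", "y", "z")]), centroid,
               tolerance = 1e-8)
  normal <- as.numeric(ai[, c("dx", "dy", "dz")])
  offsets <- sweep(X, 2, centroid) %*% normal
  expect_lt(max(abs(offsets)), 0.1)
  hc <- fs$features[fs$features$kind == "HC", ]
  expect_equal(sort(hc$atoms[[1]]), sort(ring))
})

test_that("phenol carries donor and acceptor on the hydroxyl oxygen", {
  mol <- embedded_mol("c1ccccc1O", "phenol")
  fs <- perceive_features(mol)
  counts <- table(fs$features$kind)
  expect_equal(counts[["HBD"]], 1L)
  expect_equal(counts[["HBA"]], 1L)
  expect_equal(counts[["AI"]], 1L)
  expect_equal(counts[["HC"]], 1L)
  o_idx <- which(mol$atoms$element == "O")
  expect_equal(fs$features$atoms[[which(fs$features$kind == "HBD")]], o_idx)
  expect_equal(fs$features$atoms[[which(fs$features$kind == "HBA")]], o_idx)
  # donor direction points along the O-H bond
  hbd <- fs$features[fs$features$kind == "HBD", ]
  h_idx <- which(mol$atoms$element == "H" &
                   vapply(seq_len(nrow(mol$atoms)), function(a)
                     any(mol$bonds$a1 == a & mol$bonds$a2 == o_idx |
                         mol$bonds$a2 == a & mol$bonds$a1 == o_idx),
                     logical(1)))
  oh <- mol$conformers[[1]][h_idx, ] - mol$conformers[[1]][o_idx, ]
  ca <- sum(oh * as.numeric(hbd[, c("dx", "dy", "dz")])) / sqrt(sum(oh^2))
  expect_lt(acos(min(1, ca)), 1e-6)
  # the hydrophobic cluster excludes the oxygen-bearing carbon
  hc <- fs$features[fs$features$kind == "HC", ]
  expect_length(hc$atoms[[1]], 5)
})

test_that("rule boundaries: methane bare, pyridine accepts, pyrrole donates, nitro and amide are excluded", {
  expect_equal(nrow(perceive_features(embedded_mol("C", "methane"))$features), 0)
  pyr <- perceive_features(embedded_mol("c1ccncc1", "pyridine"))$features
  expect_equal(sum(pyr$kind == "HBA"), 1)
  expect_equal(sum(pyr$kind == "HBD"), 0)
  expect_equal(sum(pyr$kind == "AI"), 1)
  pyl <- perceive_features(embedded_mol("c1cc[nH]c1", "pyrrole"))$features
  expect_equal(sum(pyl$kind == "HBD"), 1)
  expect_equal(sum(pyl$kind == "HBA"), 0)   # pyrrole-type N keeps its pair
  expect_equal(sum(pyl$kind == "AI"), 1)
  nitro <- perceive_features(embedded_mol("C[N+](=O)[O-]", "nitromethane"))$features
  expect_equal(sum(nitro$kind == "HBA"), 0)
  amide <- perceive_features(embedded_mol("CC(=O)NC", "nmethylacetamide"))$features
  # amide N is a donor but not an acceptor; carbonyl O accepts
  expect_equal(sum(amide$kind == "HBD"), 1)
  expect_equal(sum(amide$kind == "HBA"), 1)
})

test_that("features move rigidly with the conformer (equivariance)", {
  mol <- embedded_mol("c1ccccc1O", "phenol")
  fs0 <- perceive_features(mol)
  set.seed(31)
  for (k in 1:5) {
    R <- rand_rotation(); tr <- stats::runif(3, -10, 10)
    mol2 <- mol
    mol2$conformers[[1]] <- sweep(mol$conformers[[1]] %*% t(R), 2, tr, `+`)
    fs2 <- perceive_features(mol2)
    expect_equal(fs2$features$kind, fs0$features$kind)
    P0 <- unname(as.matrix(fs0$features[, c("x", "y", "z")]))
    P2 <- unname(as.matrix(fs2$features[, c("x", "y", "z")]))
    expect_equal(P2, sweep(P0 %*% t(R), 2, tr, `+`), tolerance = 1e-8)
    for (i in seq_len(nrow(P0))) {
      d0 <- as.numeric(fs0$features[i, c("dx", "dy", "dz")])
      d2 <- as.numeric(fs2$features[i, c("dx", "dy", "dz")])
      if (anyNA(d0)) { expect_true(anyNA(d2)); next }
      rd <- as.numeric(R %*% d0)
      # ring normals are axial: sign is arbitrary
      err <- min(sqrt(sum((d2 - rd)^2)), sqrt(sum((d2 + rd)^2)))
      expect_lt(err, 1e-8)
    }
  }
})

test_that("feature census is independent of atom ordering", {
  # same connectivity entered with different atom orders
  tf <- tempfile()
  writeLines(c("Oc1ccccc1 phenolA", "c1ccc(O)cc1 phenolB"), tf)
  recs <- read_smiles_table(tf)
  ms <- lapply(recs, function(r) generate_conformers(r$molecule, 1, seed = 2))
  tab <- lapply(ms, function(m) table(perceive_features(m)$features$kind))
  expect_equal(sort(names(tab[[1]])), sort(names(tab[[2]])))
  expect_equal(as.integer(tab[[1]][sort(names(tab[[1]]))]),
               as.integer(tab[[2]][sort(names(tab[[2]]))]))
})

test_that("missing conformers and empty rule tables are errors", {
  tf <- tempfile()
  writeLines("CCO ethanol", tf)
  mol <- read_smiles_table(tf)[[1]]$molecule   # zero conformers
  expect_error(perceive_features(mol), "no conformer")
  emb <- embedded_mol("CCO", "ethanol")
  expect_error(perceive_features(emb, rules = NULL), "empty")
})

test_that("documented SMARTS patterns are valid and match their probes", {
  rules <- default_perception_rules()
  probes <- list(
    HBD = list(pos = "c1ccccc1O", neg = "CCOC"),      # phenol vs ether
    HBA = list(pos = "c1ccncc1", neg = "C[N+](=O)[O-]"), # pyridine vs nitro
    AI  = list(pos = "c1ccccc1", neg = "C1CCCCC1"),   # benzene vs cyclohexane
    HC  = list(pos = "CCCC",     neg = "O"))
  count_matches <- function(smiles, smarts) {
    sdf <- ChemmineOB::convertFormat("SMI", "SDF",
                                     paste0(smiles, "\tprobe\n"))
    sum(unlist(ChemmineOB::forEachMol("SDF", sdf, function(m)
      ChemmineOB::smartsSearch_OB(list(m), smarts, uniqueMatches = TRUE))))
  }
  for (kind in names(probes)) {
    pats <- rules$smarts[rules$kind == kind]
    pos <- sum(vapply(pats, function(p)
      count_matches(probes[[kind]]$pos, p), numeric(1)))
    neg <- sum(vapply(pats, function(p)
      count_matches(probes[[kind]]$neg, p), numeric(1)))
    expect_gt(pos, 0, label = paste(kind, "positive probe"))
    expect_equal(neg, 0, label = paste(kind, "negative probe"))
  }
})
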