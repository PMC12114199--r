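# Model schema, fixtures, quality flags, ligand-based merging.

test_that("the exemplar fixture loads with the documented census", {
  col <- exemplar_collection()
  expect_length(col$models, 8)
  census <- function(id, kinds) as.integer(
    table(factor(col$models[[id]]$features$kind, levels = kinds)))
  m <- col$models[["JAK1_SB1"]]
  expect_equal(census("JAK1_SB1", c("HBD", "HBA", "HC")), c(1L, 1L, 2L))
  expect_equal(nrow(m$xvols), 66)
  expect_equal(m$features$anchor[m$features$kind == "HBD"], "Glu957")
  expect_equal(m$features$anchor[m$features$kind == "HBA"], "Leu959")
  lb <- col$models[["JAK1_LB1"]]
  expect_equal(census("JAK1_LB1", c("HBA", "AI")), c(3L, 2L))
  expect_equal(nrow(lb$xvols), 47)
  expect_equal(nrow(col$models[["TYK2_SB1"]]$features), 6)
  expect_equal(nrow(col$models[["TYK2_LB1"]]$xvols), 35)
})

test_that("summarize_collection counts per target and origin", {
  col <- exemplar_collection()
  s <- summarize_collection(col)
  expect_equal(s$target, c("JAK1", "JAK2", "JAK3", "TYK2"))
  expect_equal(s$n_models, rep(2L, 4))
  expect_equal(s$n_structure_based, rep(1L, 4))
  expect_equal(s$n_ligand_based, rep(1L, 4))
  expect_equal(nrow(summarize_collection(model_collection())), 0)
  # duplicating a model under a new id increments its target's count
  dup <- col$models[["JAK1_SB1"]]
  dup$id <- "JAK1_SB1_copy"
  col2 <- model_collection(c(col$models, list(dup)))
  expect_equal(summarize_collection(col2)$n_models[1], 3L)
})

test_that("invalid model files abort with the offending field path", {
  tf <- tempfile(fileext = ".json")
  doc <- list(schema = "pharmscreen-model/1", models = list(list(
    id = "bad", target = "JAK1",
    origin = list(type = "structure_based", pdb_id = "XXXX",
                  resolution = 2.0),
    max_omitted = 0,
    features = list(list(kind = "XYZ", center = c(0, 0, 0), radius = 1.5)),
    xvols = list())))
  jsonlite::write_json(doc, tf, auto_unbox = TRUE)
  expect_error(load_models(tf), "features\\[1\\].kind")
  doc$models[[1]]$features[[1]]$kind <- "HBD"
  doc$models[[1]]$features[[1]]$radius <- -1
  jsonlite::write_json(doc, tf, auto_unbox = TRUE)
  expect_error(load_models(tf), "radius")
  # duplicate ids rejected
  doc$models[[1]]$features[[1]]$radius <- 1.5
  doc$models <- list(doc$models[[1]], doc$models[[1]])
  jsonlite::write_json(doc, tf, auto_unbox = TRUE)
  expect_error(load_models(tf), "duplicate")
})

test_that("serialization round trip is the identity", {
  col <- exemplar_collection()
  tf <- tempfile(fileext = ".json")
  save_models(col, tf)
  back <- load_models(tf)
  expect_equal(back, col)
  # high-precision coordinates survive exactly
  P <- matrix(c(0.123456, -2.654321, 3.111111,
                2, 0, 0, 0, 2, 0), 3, 3, byrow = TRUE)
  m <- toy_model(c("HBD", "HBA", "HC"), P, id = "prec", target = "JAK2")
  save_models(model_collection(list(m)), tf)
  expect_identical(load_models(tf)$models[["prec"]]$features$x[1], 0.123456)
  # empty collection round-trips
  save_models(model_collection(), tf)
  expect_length(load_models(tf)$models, 0)
})

test_that("quality flags fire on the documented boundaries", {
  P4 <- matrix(stats::runif(12, -4, 4), 4, 3)
  P3 <- P4[1:3, ]
  sb <- function(P, res) {
    feats <- data.frame(kind = rep("HC", nrow(P)), x = P[, 1], y = P[, 2],
                        z = P[, 3], radius = 1.5, stringsAsFactors = FALSE)
    pharmacophore_model("m", "JAK1",
                        list(type = "structure_based", pdb_id = "X",
                             resolution = res), feats)
  }
  expect_equal(check_model_quality(sb(P3, 2.0)), "too_few_features")
  expect_equal(check_model_quality(sb(P4, 3.2)), "low_resolution")
  expect_equal(check_model_quality(sb(P4, 3.0)), "low_resolution")  # >= 3
  expect_length(check_model_quality(sb(P4, 2.9)), 0)
  for (m in exemplar_collection()$models)
    expect_length(check_model_quality(m), 0)
})

test_that("merging two identical feature sets reproduces the input features", {
  set.seed(5)
  P <- matrix(stats::runif(12, -4, 4), 4, 3)
  fs <- toy_fs(c("HBD", "HBA", "HC", "AI"), P, id = "a")
  model <- build_ligand_based_model(list(fs, fs), merge_radius = 1.0,
                                    min_fraction = 1.0)
  expect_equal(nrow(model$features), 4)
  got <- as.matrix(model$features[order(model$features$x), c("x", "y", "z")])
  expect_equal(unname(got), unname(P[order(P[, 1]), ]), tolerance = 1e-12)
  expect_equal(model$origin$type, "ligand_based")
})

test_that("a shared acceptor pair merges at its midpoint", {
  a <- toy_fs("HBA", matrix(c(0, 0, 0), 1, 3), id = "a")
  b <- toy_fs("HBA", matrix(c(0.8, 0, 0), 1, 3), id = "b")
  model <- build_ligand_based_model(list(a, b), merge_radius = 1.0,
                                    min_fraction = 1.0)
  expect_equal(nrow(model$features), 1)
  expect_equal(as.numeric(model$features[1, c("x", "y", "z")]),
               c(0.4, 0, 0))
})

test_that("min_fraction excludes under-represented clusters", {
  a <- toy_fs(c("HBD", "HC"), matrix(c(0, 0, 0, 5, 0, 0), 2, 3,
                                     byrow = TRUE), id = "a")
  b <- toy_fs(c("HBD", "HC"), matrix(c(0.2, 0, 0, 5.1, 0, 0), 2, 3,
                                     byrow = TRUE), id = "b")
  c_ <- toy_fs("HC", matrix(c(5, 0.1, 0), 1, 3), id = "c")
  # HBD appears in 2 of 3 sets: below 0.7, above 0.5
  m1 <- build_ligand_based_model(list(a, b, c_), merge_radius = 1.0,
                                 min_fraction = 0.7)
  expect_false("HBD" %in% m1$features$kind)
  m2 <- build_ligand_based_model(list(a, b, c_), merge_radius = 1.0,
                                 min_fraction = 0.5)
  expect_true("HBD" %in% m2$features$kind)
  # input order never matters
  m3 <- build_ligand_based_model(list(c_, b, a), merge_radius = 1.0,
                                 min_fraction = 0.7)
  expect_equal(m3$features[, c("kind", "x", "y", "z")],
               m1$features[, c("kind", "x", "y", "z")])
})

test_that("degenerate merge inputs are rejected", {
  a <- toy_fs("HBA", matrix(0, 1, 3), id = "a")
  expect_error(build_ligand_based_model(list(a)), "at least two")
  far <- toy_fs("HBD", matrix(c(50, 0, 0), 1, 3), id = "b")
  expect_error(build_ligand_based_model(list(a, far), merge_radius = 1,
                                        min_fraction = 1.0),
               "no consensus")
})
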