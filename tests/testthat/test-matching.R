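# Geometric matching: self-match, invariance, clash semantics, pruning
# correctness against the exhaustive oracle.

test_that("a model built from a ligand's own features self-matches with score 1", {
  set.seed(42)
  for (kinds in list(c("HBD", "HBA", "HC", "AI"),
                     c("HC", "HC", "HC"),
                     c("HBA", "HBA", "AI", "HC", "HBD"))) {
    P <- matrix(stats::runif(length(kinds) * 3, -5, 5), ncol = 3)
    model <- toy_model(kinds, P)
    res <- match_feature_set(model, self_fs(model))
    expect_true(res$matched)
    expect_equal(res$score, 1, tolerance = 1e-12)
    expect_true(all(res$residuals < 1e-9))
    expect_false(res$clash)
  }
})

test_that("match outcome is invariant under rigid motions of the ligand", {
  set.seed(7)
  P <- matrix(stats::runif(12, -4, 4), 4, 3)
  dirs <- t(replicate(4, rand_unit()))
  model <- toy_model(c("HBD", "HBA", "HC", "AI"), P, dirs = dirs)
  fs0 <- self_fs(model)
  base <- match_feature_set(model, fs0)
  expect_true(base$matched)
  for (k in 1:50) {
    R <- rand_rotation(); tr <- stats::runif(3, -50, 50)
    res <- match_feature_set(model, move_fs(fs0, R, tr))
    expect_true(res$matched)
    expect_equal(res$score, base$score, tolerance = 1e-6)
    # recovered transform inverts the motion
    expect_equal(res$rotation %*% R, diag(3), tolerance = 1e-6)
  }
})

test_that("an exclusion volume on a ligand atom position forces a clash", {
  set.seed(11)
  P <- matrix(stats::runif(12, -4, 4), 4, 3)
  model0 <- toy_model(c("HBD", "HBA", "HC", "HC"), P)
  fs <- self_fs(model0)
  # xvol centred on the first ligand heavy atom (model frame)
  xv <- data.frame(x = P[1, 1], y = P[1, 2], z = P[1, 3], radius = 1.0)
  model1 <- toy_model(c("HBD", "HBA", "HC", "HC"), P, xvols = xv)
  res <- match_feature_set(model1, fs)
  expect_false(res$matched)
  expect_true(res$clash)
  # and without the xvol it matches
  expect_true(match_feature_set(model0, fs)$matched)
})

test_that("clash_check uses strict interiors", {
  xv <- data.frame(x = 0, y = 0, z = 0, radius = 1)
  on_surface <- matrix(c(1, 0, 0), 1, 3)
  at_center <- matrix(0, 1, 3)
  expect_false(clash_check(on_surface, xv))
  expect_true(clash_check(at_center, xv))
  expect_false(clash_check(at_center, empty_xvols()))
})

test_that("pruned search agrees with the exhaustive oracle on random instances", {
  n_match <- 0
  for (seed in 1:120) {
    inst <- make_random_instance(seed)
    got <- match_feature_set(inst$model, inst$fs)
    want <- oracle_match(inst$model, inst$fs)
    expect_identical(got$matched, want$matched, label = paste("seed", seed))
    if (want$matched) {
      n_match <- n_match + 1
      expect_equal(got$score, want$score, tolerance = 1e-9,
                   label = paste("seed", seed))
    }
  }
  # the instance generator must exercise both outcomes
  expect_gt(n_match, 20)
  expect_lt(n_match, 120)
})

test_that("oracle agreement holds with omitted features allowed", {
  for (seed in 201:230) {
    inst <- make_random_instance(seed)
    model <- inst$model
    model$max_omitted <- 1L
    got <- match_feature_set(model, inst$fs)
    want <- oracle_match(model, inst$fs)
    expect_identical(got$matched, want$matched, label = paste("seed", seed))
    if (want$matched)
      expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("enlarging radii never unmatches; adding an xvol never matches", {
  for (seed in 301:330) {
    inst <- make_random_instance(seed)
    res <- match_feature_set(inst$model, inst$fs)
    grown <- inst$model
    grown$features$radius <- grown$features$radius * 2
    res2 <- match_feature_set(grown, inst$fs)
    if (res$matched) expect_true(res2$matched)
    if (!res2$matched) expect_false(res$matched)
  }
})

test_that("fewer than three matchable features never match", {
  P <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  model <- toy_model(c("HBD", "HBA"), P)
  res <- match_feature_set(model, self_fs(model))
  expect_false(res$matched)
  # empty feature set
  fs <- toy_fs(character(0), matrix(0, 0, 3))
  P3 <- matrix(stats::runif(9), 3, 3)
  expect_false(match_feature_set(toy_model(c("HC", "HC", "HC"), P3), fs)$matched)
})

test_that("direction cones reject misaligned donors", {
  P <- matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0, 3, 3, 0), 4, 3, byrow = TRUE)
  dirs <- matrix(NA_real_, 4, 3)
  dirs[1, ] <- c(0, 0, 1)
  model <- toy_model(c("HBD", "HBA", "HC", "HC"), P, dirs = dirs,
                     angle_tol = 30)
  fs_ok <- self_fs(model)
  expect_true(match_feature_set(model, fs_ok)$matched)
  # tilt the ligand donor direction 40 degrees: outside the 30 degree cone
  tilt <- c(sin(40 * pi / 180), 0, cos(40 * pi / 180))
  fs_bad <- toy_fs(model$features$kind, P,
                   dirs = rbind(tilt, matrix(NA_real_, 3, 3)))
  expect_false(match_feature_set(model, fs_bad)$matched)
  # a ligand feature without direction is not direction-checked
  fs_none <- toy_fs(model$features$kind, P)
  expect_true(match_feature_set(model, fs_none)$matched)
})

test_that("three collinear features accept only when both axial solutions pass", {
  P <- matrix(c(0, 0, 0, 2.5, 0, 0, 5, 0, 0), 3, 3, byrow = TRUE)
  model <- toy_model(c("HBD", "HBA", "HC"), P)
  fs <- self_fs(model)
  expect_true(match_feature_set(model, fs)$matched)
  # an on-axis xvol centred on an on-axis ligand atom clashes in every
  # member of the axial solution family, so the match must be rejected
  xv <- data.frame(x = 2.5, y = 0, z = 0, radius = 1.0)
  model_xv <- toy_model(c("HBD", "HBA", "HC"), P, xvols = xv)
  expect_false(match_feature_set(model_xv, fs)$matched)
})

test_that("screen_molecule picks the best conformer deterministically", {
  mol <- embedded_mol("CCCCO", "butanol")
  mol4 <- generate_conformers(mol, max_conformers = 4, seed = 3)
  # model from the features of the LAST conformer
  ci <- length(mol4$conformers)
  fs <- perceive_features(mol4, ci)
  ff <- fs$features
  model <- toy_model(ff$kind, as.matrix(ff[, c("x", "y", "z")]), radius = 0.4,
                     id = "self", target = "other")
  res <- screen_molecule(model, mol4)
  expect_true(res$matched)
  expect_equal(res$conformer, ci)
  expect_error(screen_molecule(model, molecule("x", mol4$atoms, mol4$bonds)),
               "no conformers")
})
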