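# One-off authoring script for the synthetic exemplar model fixture.
# Feature/Xvol census follows the published figure captions; geometry is
# generated here (seeded) and frozen into inst/extdata.
suppressMessages(library(pharmscreen))

author_model <- function(id, target, origin, kinds, anchors, n_xvol, seed) {
  set.seed(seed)
  n <- length(kinds)
  # feature layout: random points, pairwise >= 2.5 A, inside a 5 A sphere
  pts <- matrix(0, 0, 3)
  while (nrow(pts) < n) {
    p <- runif(3, -5, 5)
    if (sqrt(sum(p^2)) > 5) next
    if (nrow(pts) && min(sqrt(rowSums(sweep(pts, 2, p)^2))) < 2.5) next
    pts <- rbind(pts, p)
  }
  dirs <- t(apply(matrix(rnorm(3 * n), n, 3), 1, function(v) v / sqrt(sum(v^2))))
  has_dir <- kinds %in% c("HBD", "HBA", "AI")
  feats <- data.frame(kind = kinds, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      radius = 1.5,
                      dx = ifelse(has_dir, dirs[, 1], NA_real_),
                      dy = ifelse(has_dir, dirs[, 2], NA_real_),
                      dz = ifelse(has_dir, dirs[, 3], NA_real_),
                      angle_tol = ifelse(has_dir, 34, NA_real_),
                      anchor = anchors, stringsAsFactors = FALSE)
  # xvols: shell around the feature cloud, never within 2.6 A of a feature
  # center (so atoms inside a 1.5 A tolerance sphere stay clear of the
  # 1.0 A xvol radius), pairwise >= 1.2 A apart
  xv <- matrix(0, 0, 3)
  while (nrow(xv) < n_xvol) {
    base <- pts[sample(n, 1), ]
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    p <- base + u * runif(1, 2.6, 7)
    if (min(sqrt(rowSums(sweep(pts, 2, p)^2))) < 2.6) next
    if (nrow(xv) && min(sqrt(rowSums(sweep(xv, 2, p)^2))) < 1.2) next
    xv <- rbind(xv, p)
  }
  xvols <- data.frame(x = round(xv[, 1], 3), y = round(xv[, 2], 3),
                      z = round(xv[, 3], 3), radius = 1.0)
  feats[, c("x", "y", "z")] <- round(feats[, c("x", "y", "z")], 3)
  feats[, c("dx", "dy", "dz")] <- round(feats[, c("dx", "dy", "dz")], 6)
  pharmacophore_model(id, target, origin, feats, xvols, max_omitted = 0,
                      metadata = list(synthetic = TRUE,
                                      note = "authored exemplar; census per published captions, geometry synthetic"))
}

models <- list(
  author_model("JAK1_SB1", "JAK1",
               list(type = "structure_based", pdb_id = "5HX8", resolution = 2.2),
               c("HBD", "HBA", "HC", "HC"),
               c("Glu957", "Leu959", NA, NA), 66, 101),
  author_model("JAK1_LB1", "JAK1",
               list(type = "ligand_based",
                    training_ids = c("compound_2", "compound_3", "compound_4")),
               c("HBA", "HBA", "HBA", "AI", "AI"),
               rep(NA_character_, 5), 47, 102),
  author_model("JAK2_SB1", "JAK2",
               list(type = "structure_based", pdb_id = "6VNB", resolution = 2.4),
               c("HBD", "HBA", "HC", "HC"),
               c("Leu932", "Glu930", NA, NA), 9, 103),
  author_model("JAK2_LB1", "JAK2",
               list(type = "ligand_based",
                    training_ids = c("compound_7", "compound_8", "compound_9",
                                     "compound_10")),
               c("HBD", "HBA", "HBA", "AI", "AI"),
               rep(NA_character_, 5), 9, 104),
  author_model("JAK3_SB1", "JAK3",
               list(type = "structure_based", pdb_id = "4Z16", resolution = 1.9),
               c("HBD", "HBA", "HC", "HC", "HC"),
               c("Leu905", NA, NA, NA, NA), 20, 105),
  author_model("JAK3_LB1", "JAK3",
               list(type = "ligand_based",
                    training_ids = c("compound_12", "compound_13")),
               c("HBA", "AI", "AI", "HC", "HC"),
               rep(NA_character_, 5), 29, 106),
  author_model("TYK2_SB1", "TYK2",
               list(type = "structure_based", pdb_id = "6VNS", resolution = 2.5),
               c("HBD", "HBA", "HBA", "HBA", "HC", "HC"),
               c("Val981", NA, "Ser985", "Ser985", NA, NA), 26, 107),
  author_model("TYK2_LB1", "TYK2",
               list(type = "ligand_based",
                    training_ids = c("compound_15", "compound_16")),
               c("HBD", "HBA", "HBA", "HC", "AI"),
               rep(NA_character_, 5), 35, 108))

dir.create("inst/extdata/models", recursive = TRUE, showWarnings = FALSE)
save_models(model_collection(models),
            "inst/extdata/models/jak_exemplar_models.synthetic.json")

# sanity: reload, self-match every model against its own layout
col <- load_models("inst/extdata/models/jak_exemplar_models.synthetic.json")
for (m in col$models) {
  fs <- pharmscreen:::model_as_feature_set(m, "self")
  r <- match_feature_set(m, fs)
  cat(m$id, nrow(m$features), "feat", nrow(m$xvols), "xvol | self-match:",
      r$matched, "score", round(r$score, 3), "\n")
  stopifnot(r$matched, abs(r$score - 1) < 1e-9)
  # and a decoy must fail
  d <- make_decoy_featureset(m, "displace_one", seed = 9)
  stopifnot(!match_feature_set(m, d)$matched)
}
cat("fixture OK, size:",
    file.size("inst/extdata/models/jak_exemplar_models.synthetic.json"), "bytes\n")
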