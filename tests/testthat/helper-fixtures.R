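# Shared fixture builders.  Everything is constructed in code; the only
# file fixture is the shipped exemplar model JSON.

# Quick model from a kind vector and a position matrix.
toy_model <- function(kinds, P, radius = 1.5, dirs = NULL, xvols = NULL,
                      id = "toy", target = "other", max_omitted = 0,
                      angle_tol = 34) {
  n <- length(kinds)
  feats <- data.frame(kind = kinds, x = P[, 1], y = P[, 2], z = P[, 3],
                      radius = radius,
                      dx = NA_real_, dy = NA_real_, dz = NA_real_,
                      angle_tol = NA_real_, anchor = NA_character_,
                      stringsAsFactors = FALSE)
  if (!is.null(dirs)) {
    has <- !is.na(dirs[, 1])
    feats$dx[has] <- dirs[has, 1]
    feats$dy[has] <- dirs[has, 2]
    feats$dz[has] <- dirs[has, 3]
    feats$angle_tol[has] <- angle_tol
  }
  pharmacophore_model(id, target,
                      list(type = "ligand_based", training_ids = character(0)),
                      feats,
                      xvols = if (is.null(xvols)) empty_xvols() else xvols,
                      max_omitted = max_omitted)
}

# Feature set from a kind vector and a position matrix.
toy_fs <- function(kinds, P, dirs = NULL, id = "lig", coords = P) {
  na <- rep(NA_real_, length(kinds))
  df <- data.frame(kind = kinds, x = P[, 1], y = P[, 2], z = P[, 3],
                   dx = na, dy = na, dz = na,
                   stringsAsFactors = FALSE)
  if (!is.null(dirs)) {
    has <- !is.na(dirs[, 1])
    df$dx[has] <- dirs[has, 1]
    df$dy[has] <- dirs[has, 2]
    df$dz[has] <- dirs[has, 3]
  }
  df$atoms <- I(as.list(seq_len(nrow(df))))
  feature_set(id, 1L, df, coords = coords)
}

# Model feature layout as a feature set in the model's own frame.
self_fs <- function(model, id = "self") {
  ff <- model$features
  toy_fs(ff$kind, as.matrix(ff[, c("x", "y", "z")]),
         dirs = as.matrix(ff[, c("dx", "dy", "dz")]), id = id)
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

rand_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Rigidly move a feature set (positions, directions, coords).
move_fs <- function(fs, R, t) {
  df <- fs$features
  P <- as.matrix(df[, c("x", "y", "z")])
  df[, c("x", "y", "z")] <- sweep(P %*% t(R), 2, t, `+`)
  for (k in seq_len(nrow(df))) {
    if (is.na(df$dx[k])) next
    d <- as.numeric(R %*% c(df$dx[k], df$dy[k], df$dz[k]))
    df[k, c("dx", "dy", "dz")] <- as.list(d / sqrt(sum(d^2)))
  }
  coords <- if (!is.null(fs$coords))
    sweep(fs$coords %*% t(R), 2, t, `+`) else NULL
  feature_set(fs$molecule_id, fs$conformer, df, coords = coords)
}

# Memoised embedded molecules (Open Babel 3D) for perception tests.
.mol_cache <- new.env(parent = emptyenv())
embedded_mol <- function(smiles, id) {
  key <- paste0(id, "|", smiles)
  if (!is.null(.mol_cache[[key]])) return(.mol_cache[[key]])
  tf <- tempfile(fileext = ".smi")
  writeLines(paste(smiles, id, sep = "\t"), tf)
  rec <- read_smiles_table(tf)[[1]]
  mol <- generate_conformers(rec$molecule, max_conformers = 1, seed = 1)
  .mol_cache[[key]] <- mol
  mol
}

exemplar_collection <- function() load_models(exemplar_model_path())

# Random matching instance: model with 3-5 features, ligand carrying a
# perturbed copy of the layout plus distractors (<= 8 ligand features).
make_random_instance <- function(seed) {
  set.seed(seed)
  nm <- sample(3:5, 1)
  kinds <- sample(c("HBD", "HBA", "HC", "AI"), nm, replace = TRUE)
  P <- matrix(stats::runif(nm * 3, -4, 4), nm, 3)
  while (min(dist(P)) < 2) P <- matrix(stats::runif(nm * 3, -4, 4), nm, 3)
  model <- toy_model(kinds, P, radius = 1.5)
  R <- rand_rotation(); tr <- stats::runif(3, -10, 10)
  Lp <- sweep(P %*% t(R), 2, tr, `+`) +
    matrix(stats::rnorm(nm * 3, 0, stats::runif(1, 0, 1.2)), nm, 3)
  n_extra <- sample(0:(8 - nm), 1)
  Le <- matrix(stats::runif(n_extra * 3, -8, 8), n_extra, 3)
  ke <- sample(c("HBD", "HBA", "HC", "AI"), n_extra, replace = TRUE)
  fs <- toy_fs(c(kinds, ke), rbind(Lp, Le))
  list(model = model, fs = fs)
}
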