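# Pharmacophore model representation, JSON (de)serialization, quality
# flags, and ligand-based construction by feature merging.
#
# A model is a set of typed tolerance spheres (optionally directed, with a
# cone half-angle) plus exclusion volumes approximating receptor bulk.
# Residue anchors ("Glu957" and the like) are annotation only and never
# influence matching.

.feature_kinds <- c("HBD", "HBA", "HC", "AI")
.targets <- c("JAK1", "JAK2", "JAK3", "TYK2", "other")
.schema_id <- "pharmscreen-model/1"

#' Construct a pharmacophore model
#'
#' @param id model identifier, unique within a collection.
#' @param target one of `"JAK1"`, `"JAK2"`, `"JAK3"`, `"TYK2"`, `"other"`.
#' @param origin list: either `list(type = "structure_based", pdb_id =,
#'   resolution =)` or `list(type = "ligand_based", training_ids =)`.
#' @param features data.frame with columns `kind`, `x`, `y`, `z`,
#'   `radius`, `dx`, `dy`, `dz` (unit direction or `NA`), `angle_tol`
#'   (degrees, `NA` when undirected), `anchor` (residue label or `NA`).
#' @param xvols data.frame with columns `x`, `y`, `z`, `radius`
#'   (may have zero rows).
#' @param max_omitted number of model features allowed to go unmatched.
#' @param metadata free-form named list.
#' @return Object of class `pharm_model`.
#' @export
pharmacophore_model <- function(id, target, origin, features,
                                xvols = empty_xvols(), max_omitted = 0L,
                                metadata = list()) {
  features <- as.data.frame(features)
  xvols <- as.data.frame(xvols)
  if (nrow(features) < 1) stop("model ", id, ": needs at least one feature")
  if (!target %in% .targets) stop("model ", id, ": unknown target ", target)
  if (!origin$type %in% c("structure_based", "ligand_based"))
    stop("model ", id, ": unknown origin type ", origin$type)
  for (col in c("dx", "dy", "dz", "angle_tol"))
    if (is.null(features[[col]])) features[[col]] <- NA_real_
  if (is.null(features$anchor)) features$anchor <- NA_character_
  for (k in seq_len(nrow(features))) {
    f <- features[k, ]
    path <- sprintf("model %s feature %d", id, k)
    if (!f$kind %in% .feature_kinds)
      stop(path, ": unknown feature kind '", f$kind, "'")
    if (!is.finite(f$radius) || f$radius <= 0)
      stop(path, ": non-positive radius")
    if (!is.na(f$angle_tol) && is.na(f$dx))
      stop(path, ": angle_tol given without direction")
    if (!is.na(f$dx)) {
      d <- c(f$dx, f$dy, f$dz)
      n <- vnorm(d)
      if (n < 1e-9) stop(path, ": zero-length direction")
      features[k, c("dx", "dy", "dz")] <- as.list(d / n)
    }
  }
  if (nrow(xvols) && any(!is.finite(xvols$radius) | xvols$radius <= 0))
    stop("model ", id, ": exclusion volume with non-positive radius")
  if (max_omitted < 0 || max_omitted >= nrow(features))
    stop("model ", id, ": max_omitted must be in [0, feature count)")
  structure(list(id = as.character(id), target = target, origin = origin,
                 features = features, xvols = xvols,
                 max_omitted = as.integer(max_omitted),
                 metadata = metadata),
            class = "pharm_model")
}

#' @export
print.pharm_model <- function(x, ...) {
  cat(sprintf("<pharm_model %s (%s, %s): %s + %d Xvol(s)>\n",
              x$id, x$target, x$origin$type,
              paste(x$features$kind, collapse = " "), nrow(x$xvols)))
  invisible(x)
}

#' @rdname pharmacophore_model
#' @export
empty_xvols <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             radius = numeric(0))
}

feature_centers <- function(model) {
  as.matrix(model$features[, c("x", "y", "z")])
}

#' Group models into a collection
#'
#' @param models list of [pharmacophore_model()] objects; ids must be
#'   globally unique.
#' @return Object of class `model_collection` (a named list of models).
#' @export
model_collection <- function(models = list()) {
  ids <- vapply(models, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate model id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(models) <- ids
  structure(list(models = models), class = "model_collection")
}

#' @export
print.model_collection <- function(x, ...) {
  cat(sprintf("<model_collection: %d model(s)>\n", length(x$models)))
  invisible(x)
}

## ---- JSON serialization ----------------------------------------------

#' Load a model collection from JSON
#'
#' Reads the documented schema
#' `{schema: "pharmscreen-model/1", models: [...]}` and enforces all model
#' invariants; violations abort with the offending field path.
#'
#' @param path JSON file path.
#' @return A [model_collection()].
#' @export
load_models <- function(path) {
  if (!file.exists(path)) stop("cannot read model file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, .schema_id))
    stop(path, ": unsupported schema '", doc$schema %||% "<missing>", "'")
  models <- lapply(seq_along(doc$models), function(i) {
    m <- doc$models[[i]]
    where <- sprintf("%s: models[%d]", path, i)
    if (is.null(m$id)) stop(where, ".id missing")
    feats <- lapply(seq_along(m$features), function(j) {
      f <- m$features[[j]]
      if (is.null(f$kind) || !f$kind %in% .feature_kinds)
        stop(where, sprintf(".features[%d].kind invalid ('%s')",
                            j, f$kind %||% ""))
      if (is.null(f$radius) || f$radius <= 0)
        stop(where, sprintf(".features[%d].radius must be > 0", j))
      dir <- f$direction
      data.frame(kind = f$kind,
                 x = f$center[[1]], y = f$center[[2]], z = f$center[[3]],
                 radius = f$radius,
                 dx = if (is.null(dir)) NA_real_ else dir[[1]],
                 dy = if (is.null(dir)) NA_real_ else dir[[2]],
                 dz = if (is.null(dir)) NA_real_ else dir[[3]],
                 angle_tol = f$angle_tol %||% NA_real_,
                 anchor = f$anchor %||% NA_character_,
                 stringsAsFactors = FALSE)
    })
    xv <- lapply(seq_along(m$xvols), function(j) {
      v <- m$xvols[[j]]
      if (is.null(v$radius) || v$radius <= 0)
        stop(where, sprintf(".xvols[%d].radius must be > 0", j))
      data.frame(x = v$center[[1]], y = v$center[[2]], z = v$center[[3]],
                 radius = v$radius)
    })
    origin <- list(type = m$origin$type %||% "")
    if (identical(origin$type, "structure_based")) {
      origin$pdb_id <- m$origin$pdb_id %||% NA_character_
      origin$resolution <- m$origin$resolution %||% NA_real_
    } else {
      origin$training_ids <- as.character(unlist(m$origin$training_ids))
    }
    pharmacophore_model(
      id = m$id, target = m$target %||% "other", origin = origin,
      features = do.call(rbind, feats),
      xvols = if (length(xv)) do.call(rbind, xv) else empty_xvols(),
      max_omitted = m$max_omitted %||% 0L,
      metadata = m$metadata %||% list())
  })
  model_collection(models)
}

#' Save a model collection to JSON
#'
#' Inverse of [load_models()]: `load_models(save_models(x))` reproduces
#' the collection field for field (coordinates at full double precision).
#'
#' @param collection a [model_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_models <- function(collection, path) {
  stopifnot(inherits(collection, "model_collection"))
  models <- lapply(collection$models, function(m) {
    feats <- lapply(seq_len(nrow(m$features)), function(k) {
      f <- m$features[k, ]
      out <- list(kind = f$kind, center = c(f$x, f$y, f$z),
                  radius = f$radius)
      if (!is.na(f$dx)) {
        out$direction <- c(f$dx, f$dy, f$dz)
        if (!is.na(f$angle_tol)) out$angle_tol <- f$angle_tol
      }
      if (!is.na(f$anchor)) out$anchor <- f$anchor
      out
    })
    xv <- lapply(seq_len(nrow(m$xvols)), function(k) {
      v <- m$xvols[k, ]
      list(center = c(v$x, v$y, v$z), radius = v$radius)
    })
    list(id = m$id, target = m$target, origin = m$origin,
         max_omitted = m$max_omitted, features = feats, xvols = xv,
         metadata = m$metadata)
  })
  jsonlite::write_json(list(schema = .schema_id, models = unname(models)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

## ---- quality flags ----------------------------------------------------

#' Quality-check a pharmacophore model
#'
#' Flags models that would have been discarded during model selection:
#' `too_few_features` when a model has three or fewer features, and
#' `low_resolution` when a structure-based model derives from a crystal
#' structure at 3 A resolution or worse.
#'
#' @param model a [pharmacophore_model()].
#' @return Character vector of flags (possibly empty).
#' @export
check_model_quality <- function(model) {
  flags <- character(0)
  if (nrow(model$features) <= 3) flags <- c(flags, "too_few_features")
  if (identical(model$origin$type, "structure_based")) {
    res <- model$origin$resolution
    if (!is.null(res) && !is.na(res) && res >= 3)
      flags <- c(flags, "low_resolution")
  }
  flags
}

## ---- ligand-based construction ----------------------------------------

#' Build a ligand-based model by merging aligned feature sets
#'
#' Features of identical kind across pre-aligned ligands are single-linkage
#' clustered at `merge_radius`; clusters represented in at least
#' `min_fraction` of the ligands become model features at the cluster
#' centroid.  A merged feature carries a direction only when every member
#' has one (normalized mean, members sign-aligned to the first for axial
#' AI normals).
#'
#' @param feature_sets list of two or more [feature_set()]s in a common
#'   frame.
#' @param merge_radius single-linkage cut distance (A).
#' @param min_fraction minimum fraction of ligands a cluster must cover.
#' @param id,target identity of the resulting model.
#' @param radius tolerance sphere radius assigned to merged features (A).
#' @param angle_tol cone half-angle assigned to directed merged features.
#' @return A ligand-based [pharmacophore_model()].
#' @export
build_ligand_based_model <- function(feature_sets, merge_radius = 1.5,
                                     min_fraction = 0.5, id = "LB1",
                                     target = "other", radius = 1.5,
                                     angle_tol = 34) {
  if (length(feature_sets) < 2)
    stop("need at least two aligned feature sets")
  stopifnot(merge_radius > 0, min_fraction > 0, min_fraction <= 1)
  n_lig <- length(feature_sets)
  rows <- list()
  for (kind in .feature_kinds) {
    pts <- list(); dirs <- list(); lig <- integer(0)
    for (s in seq_len(n_lig)) {
      ff <- feature_sets[[s]]$features
      sel <- which(ff$kind == kind)
      for (k in sel) {
        pts <- c(pts, list(c(ff$x[k], ff$y[k], ff$z[k])))
        dirs <- c(dirs, list(if (is.na(ff$dx[k])) NULL
                             else c(ff$dx[k], ff$dy[k], ff$dz[k])))
        lig <- c(lig, s)
      }
    }
    if (length(pts) == 0) next
    P <- do.call(rbind, pts)
    cl <- if (nrow(P) == 1) 1L else
      stats::cutree(stats::hclust(stats::dist(P), method = "single"),
                    h = merge_radius)
    for (g in unique(cl)) {
      members <- which(cl == g)
      frac <- length(unique(lig[members])) / n_lig
      if (frac < min_fraction) next
      centroid <- colMeans(P[members, , drop = FALSE])
      dir <- NULL
      member_dirs <- dirs[members]
      if (all(!vapply(member_dirs, is.null, logical(1)))) {
        ref <- member_dirs[[1]]
        acc <- ref
        for (d in member_dirs[-1]) {
          if (kind == "AI" && sum(d * ref) < 0) d <- -d
          acc <- acc + d
        }
        dir <- unitize(acc)
      }
      rows <- c(rows, list(data.frame(
        kind = kind, x = centroid[1], y = centroid[2], z = centroid[3],
        radius = radius,
        dx = if (is.null(dir)) NA_real_ else dir[1],
        dy = if (is.null(dir)) NA_real_ else dir[2],
        dz = if (is.null(dir)) NA_real_ else dir[3],
        angle_tol = if (is.null(dir)) NA_real_ else angle_tol,
        anchor = NA_character_, stringsAsFactors = FALSE)))
    }
  }
  if (length(rows) == 0) stop("no consensus features")
  pharmacophore_model(
    id = id, target = target,
    origin = list(type = "ligand_based",
                  training_ids = vapply(feature_sets, `[[`, "",
                                        "molecule_id")),
    features = do.call(rbind, rows))
}

## ---- collection summary ------------------------------------------------

#' Summarize a model collection
#'
#' @param collection a [model_collection()].
#' @return data.frame with one row per target present (plus an `all` row):
#'   model counts split by structure-based / ligand-based origin.
#' @export
summarize_collection <- function(collection) {
  stopifnot(inherits(collection, "model_collection"))
  tg <- vapply(collection$models, `[[`, "", "target")
  sb <- vapply(collection$models, function(m)
    identical(m$origin$type, "structure_based"), logical(1))
  targets <- .targets[.targets %in% tg]
  out <- data.frame(
    target = targets,
    n_models = vapply(targets, function(t) sum(tg == t), integer(1)),
    n_structure_based = vapply(targets, function(t) sum(tg == t & sb),
                               integer(1)),
    n_ligand_based = vapply(targets, function(t) sum(tg == t & !sb),
                            integer(1)),
    row.names = NULL)
  out
}

#' Path to the synthetic exemplar model fixtures
#'
#' Eight synthetic exemplar models (one structure-based and one
#' ligand-based per kinase) whose feature and exclusion-volume census
#' follows the published figure captions; the geometries are authored for
#' this package and exercise the schema and pipeline, they are not a
#' replication of any published model's coordinates.
#'
#' @return File path of the shipped JSON fixture.
#' @export
exemplar_model_path <- function() {
  system.file("extdata", "models", "jak_exemplar_models.synthetic.json",
              package = "pharmscreen", mustWork = TRUE)
}
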