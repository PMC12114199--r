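# Library screening with union-of-models hit semantics.
#
# A compound is a hit for a target when at least one of that target's
# models matches any of its conformers; this union reading is what lets a
# single overall hit count stand for a set of 8-10 models per kinase.

screen_result_row <- function(molecule_id, target, results) {
  matched_ids <- vapply(results[vapply(results, `[[`, FALSE, "matched")],
                        `[[`, "", "model_id")
  scores <- vapply(results, `[[`, 0, "score")
  best <- which.max(scores)
  data.frame(molecule_id = molecule_id, target = target,
             matched = length(matched_ids) > 0,
             model_ids = paste(matched_ids, collapse = ","),
             best_score = scores[best],
             conformer = results[[best]]$conformer,
             stringsAsFactors = FALSE)
}

screen_core <- function(collection, items, match_one) {
  stopifnot(inherits(collection, "model_collection"))
  targets <- sort(unique(vapply(collection$models, `[[`, "", "target")))
  rows <- list()
  for (item in items) {
    for (tg in targets) {
      models <- Filter(function(m) m$target == tg, collection$models)
      results <- lapply(models, function(m) match_one(m, item))
      rows <- c(rows, list(screen_result_row(attr(results, "id") %||%
                                               results[[1]]$molecule_id,
                                             tg, results)))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_id = character(0), target = character(0),
               matched = logical(0), model_ids = character(0),
               best_score = numeric(0), conformer = integer(0))
  out <- out[order(out$molecule_id, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Screen a molecule library against a model collection
#'
#' Runs [screen_molecule()] for every molecule against every model,
#' one row per (molecule, target) with union-of-models hit semantics.
#' Molecules without conformers are collected as per-molecule errors and
#' reported at the end; the run continues.
#'
#' @param collection a [model_collection()].
#' @param records library records from [read_sdf()] / [read_smiles_table()],
#'   or a list of [molecule()]s.
#' @param params a [screen_params()].
#' @return data.frame of class `screen_result` with columns `molecule_id`,
#'   `target`, `matched`, `model_ids` (comma-joined matching models),
#'   `best_score`, `conformer`.  Failed molecules are recorded in the
#'   `errors` attribute.
#' @export
screen_library <- function(collection, records, params = screen_params()) {
  mols <- lapply(records, function(r) if (inherits(r, "pharm_mol")) r
                                      else r$molecule)
  errors <- character(0)
  ok <- vapply(mols, function(m) length(m$conformers) > 0, logical(1))
  if (any(!ok)) {
    errors <- vapply(mols[!ok], `[[`, "", "id")
    warning(length(errors), " molecule(s) without conformers skipped: ",
            paste(errors, collapse = ", "))
    mols <- mols[ok]
  }
  out <- screen_core(collection, mols,
                     function(m, mol) screen_molecule(m, mol, params))
  attr(out, "errors") <- errors
  out
}

#' Screen a library of pre-computed feature sets
#'
#' Feature-set-level variant of [screen_library()], used by the synthetic
#' benchmarks: each [feature_set()] stands for one single-conformer
#' compound, bypassing chemistry and perception.
#'
#' @param collection a [model_collection()].
#' @param feature_sets list of [feature_set()]s.
#' @param params a [screen_params()].
#' @return A `screen_result` data.frame (see [screen_library()]).
#' @export
screen_feature_library <- function(collection, feature_sets,
                                   params = screen_params()) {
  screen_core(collection, feature_sets,
              function(m, fs) match_feature_set(m, fs, params = params))
}

#' Extract hits from a screen result
#'
#' @param screen a `screen_result`.
#' @return The matched rows only.
#' @export
screen_hits <- function(screen) {
  out <- screen[screen$matched, , drop = FALSE]
  rownames(out) <- NULL
  out
}

normalize_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Cross-reference hits against an identifier list
#'
#' Flags each unique hit molecule as present or absent in a reference
#' identifier list (e.g. compounds qualitatively detected in a human
#' metabolome inventory).  Matching uses structure keys first and
#' normalized names (lower-cased, punctuation stripped) as fallback; the
#' reference list is deduplicated on load.
#'
#' @param hits a `screen_result` (typically [screen_hits()] output).
#' @param reference_ids character vector of structure keys or names.
#' @param structure_keys optional named character vector mapping
#'   `molecule_id` to structure key.
#' @return `hits` with an `in_reference` column; summary counts in the
#'   `summary` attribute.
#' @export
cross_reference <- function(hits, reference_ids, structure_keys = NULL) {
  reference_ids <- unique(as.character(reference_ids))
  ref_norm <- normalize_name(reference_ids)
  present <- vapply(hits$molecule_id, function(id) {
    key <- if (!is.null(structure_keys)) structure_keys[[id]] else NULL
    (!is.null(key) && !is.na(key) && key %in% reference_ids) ||
      normalize_name(id) %in% ref_norm
  }, logical(1))
  hits$in_reference <- unname(present)
  uniq <- !duplicated(hits$molecule_id)
  attr(hits, "summary") <- c(n_unique_hits = sum(uniq),
                             n_in_reference = sum(present[uniq]))
  hits
}

#' Per-target and overall unique hit counts
#'
#' @param screen a `screen_result`.
#' @return List with `per_target` (named counts of unique hit molecules
#'   per target) and `overall` (size of the cross-target union, each
#'   compound counted once).
#' @export
hit_census <- function(screen) {
  hits <- screen_hits(screen)
  per_target <- tapply(hits$molecule_id, hits$target,
                       function(x) length(unique(x)))
  list(per_target = per_target,
       overall = length(unique(hits$molecule_id)))
}
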