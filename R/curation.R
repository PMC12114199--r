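# Activity-threshold dataset curation.
#
# Actives are compounds with IC50 <= 1000 nM against the given kinase;
# inactives need IC50 > 40,000 nM (JAK1) or > 50,000 nM (JAK2/JAK3/TYK2);
# everything in between is excluded as intermediate.  Decoys — presumed
# inactives with active-like physicochemical properties — are attached
# separately and never overlap the measured sets.

.inactive_floor <- c(JAK1 = 40000, JAK2 = 50000, JAK3 = 50000, TYK2 = 50000)
.active_ceiling <- 1000

#' Build an activity record table
#'
#' @param compound_id character vector of compound identifiers.
#' @param target kinase (recycled): `"JAK1"`, `"JAK2"`, `"JAK3"`, `"TYK2"`.
#' @param ic50_nM positive IC50 values in nM.
#' @param source free-text provenance (recycled).
#' @return data.frame of activity records.
#' @export
activity_records <- function(compound_id, target, ic50_nM,
                             source = "unspecified") {
  n <- length(compound_id)
  df <- data.frame(compound_id = as.character(compound_id),
                   target = rep_len(as.character(target), n),
                   ic50_nM = as.numeric(ic50_nM),
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  bad <- !df$target %in% names(.inactive_floor)
  if (any(bad)) stop("unknown target(s): ",
                     paste(unique(df$target[bad]), collapse = ", "))
  bad <- !is.finite(df$ic50_nM) | df$ic50_nM <= 0
  if (any(bad)) stop("non-positive IC50 for record(s): ",
                     paste(df$compound_id[bad], collapse = ", "))
  df
}

#' Labeled dataset container
#'
#' @param target kinase the dataset belongs to.
#' @param actives,inactives,decoys character vectors of compound ids.
#' @param excluded data.frame with columns `compound_id`, `reason`.
#' @return Object of class `labeled_dataset`.  The four id sets are
#'   pairwise disjoint by construction.
#' @export
labeled_dataset <- function(target, actives = character(0),
                            inactives = character(0),
                            decoys = character(0),
                            excluded = data.frame(compound_id = character(0),
                                                  reason = character(0))) {
  sets <- list(actives, inactives, decoys, excluded$compound_id)
  all_ids <- unlist(sets)
  if (anyDuplicated(all_ids))
    stop("dataset sets are not disjoint: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  structure(list(target = target, actives = actives, inactives = inactives,
                 decoys = decoys, excluded = excluded),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset %s: %d active / %d inactive / %d decoy / %d excluded>\n",
              x$target, length(x$actives), length(x$inactives),
              length(x$decoys), nrow(x$excluded)))
  invisible(x)
}

#' Label a per-target activity table
#'
#' Applies the activity thresholds: active iff IC50 <= 1000 nM; inactive
#' iff IC50 > 40,000 nM (JAK1) or > 50,000 nM (JAK2, JAK3, TYK2); the
#' intermediate range is excluded.  Multiple measurements for one
#' compound are reconciled by their geometric mean before thresholding.
#'
#' @param records data.frame from [activity_records()], all for `target`.
#' @param target kinase.
#' @return A [labeled_dataset()] (decoys empty; see [attach_decoys()]).
#' @export
label_dataset <- function(records, target) {
  stopifnot(target %in% names(.inactive_floor))
  records <- activity_records(records$compound_id, records$target,
                              records$ic50_nM, records$source)
  if (any(records$target != target))
    stop("record(s) for a different target than ", target, ": ",
         paste(unique(records$compound_id[records$target != target]),
               collapse = ", "))
  # geometric-mean aggregation of repeated measurements; the relative
  # tolerance keeps exact boundary values (e.g. 1000 nM measured twice)
  # on the boundary despite log/exp round-off
  ic50 <- exp(tapply(log(records$ic50_nM), records$compound_id, mean))
  ids <- names(ic50)
  floor_ <- .inactive_floor[[target]]
  eps <- 1e-9
  lab <- ifelse(ic50 <= .active_ceiling * (1 + eps), "active",
                ifelse(ic50 > floor_ * (1 + eps), "inactive",
                       "intermediate"))
  labeled_dataset(
    target = target,
    actives = sort(ids[lab == "active"]),
    inactives = sort(ids[lab == "inactive"]),
    excluded = data.frame(
      compound_id = sort(ids[lab == "intermediate"]),
      reason = rep("intermediate", sum(lab == "intermediate")),
      stringsAsFactors = FALSE))
}

#' Attach decoys to a labeled dataset
#'
#' @param ds a [labeled_dataset()].
#' @param decoy_ids compound ids, disjoint from actives and inactives
#'   (overlap aborts, listing the offending ids).
#' @return The dataset with decoys appended.
#' @export
attach_decoys <- function(ds, decoy_ids) {
  stopifnot(inherits(ds, "labeled_dataset"))
  decoy_ids <- unique(as.character(decoy_ids))
  clash <- intersect(decoy_ids, c(ds$actives, ds$inactives))
  if (length(clash))
    stop("decoy id(s) overlap measured compounds: ",
         paste(clash, collapse = ", "))
  labeled_dataset(ds$target, ds$actives, ds$inactives,
                  c(ds$decoys, decoy_ids), ds$excluded)
}
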