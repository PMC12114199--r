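# Decoy-aware enrichment validation: confusion counts, the screening
# performance statistics, ROC/AUC, and the enrichment-factor model filter.
#
# Definitions (per screened dataset of nAC actives, nIA inactives and nDC
# decoys, with TP actives retrieved and FP = inactive + decoy hits):
#   sensitivity = TP / nAC
#   YoA         = TP / (TP + FP)          (yield of actives)
#   EF          = YoA / (nAC / total)     (enrichment factor)
#   accuracy    = (TP + TN) / total
# Two specificity variants are reported because no single published
# formula reproduces all four printed values: TN / (nIA + nDC)
# ("specificity_all") and 1 - FP_inactive / nIA ("specificity_ia_only").

#' Confusion summary for one screened dataset
#'
#' @param tp actives retrieved (true positives).
#' @param fp_inactive inactives retrieved.
#' @param fp_decoy decoys retrieved.
#' @param n_ac,n_ia,n_dc dataset census: actives, inactives, decoys.
#' @return Object of class `confusion_summary` with derived fields `fn`,
#'   `fp`, `tn`.
#' @export
#' @examples
#' cs <- confusion_summary(tp = 95, fp_inactive = 0, fp_decoy = 79,
#'                         n_ac = 105, n_ia = 48, n_dc = 3263)
#' compute_metrics(cs)$ef
confusion_summary <- function(tp, fp_inactive, fp_decoy, n_ac, n_ia, n_dc) {
  vals <- c(tp = tp, fp_inactive = fp_inactive, fp_decoy = fp_decoy,
            n_ac = n_ac, n_ia = n_ia, n_dc = n_dc)
  stopifnot(all(vals >= 0), all(vals == round(vals)))
  if (tp > n_ac) stop("tp exceeds the number of actives")
  if (fp_inactive > n_ia) stop("fp_inactive exceeds the number of inactives")
  if (fp_decoy > n_dc) stop("fp_decoy exceeds the number of decoys")
  fp <- fp_inactive + fp_decoy
  structure(list(tp = tp, fp_inactive = fp_inactive, fp_decoy = fp_decoy,
                 n_ac = n_ac, n_ia = n_ia, n_dc = n_dc,
                 fn = n_ac - tp, fp = fp, tn = n_ia + n_dc - fp),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion: TP %d FP %d (IA %d + DC %d) TN %d FN %d | nAC %d nIA %d nDC %d>\n",
              x$tp, x$fp, x$fp_inactive, x$fp_decoy, x$tn, x$fn,
              x$n_ac, x$n_ia, x$n_dc))
  invisible(x)
}

#' Confusion counts from a screen result and a labeled dataset
#'
#' Applies union-of-models hit semantics: a compound counts as retrieved
#' when any model of the dataset's target matched it.  Excluded compounds
#' are ignored; hit ids absent from the dataset raise a warning and are
#' dropped from the counts.
#'
#' @param screen a `screen_result` (or its [screen_hits()] subset).
#' @param ds a [labeled_dataset()].
#' @return A [confusion_summary()].
#' @export
confusion_from_screen <- function(screen, ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  rows <- screen[screen$matched & screen$target == ds$target, , drop = FALSE]
  hit_ids <- unique(rows$molecule_id)
  known <- c(ds$actives, ds$inactives, ds$decoys, ds$excluded$compound_id)
  unknown <- setdiff(hit_ids, known)
  if (length(unknown)) {
    warning(length(unknown), " hit id(s) not in the dataset ignored: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    hit_ids <- setdiff(hit_ids, unknown)
  }
  confusion_summary(
    tp = length(intersect(hit_ids, ds$actives)),
    fp_inactive = length(intersect(hit_ids, ds$inactives)),
    fp_decoy = length(intersect(hit_ids, ds$decoys)),
    n_ac = length(ds$actives), n_ia = length(ds$inactives),
    n_dc = length(ds$decoys))
}

#' Screening performance statistics
#'
#' Computes sensitivity, both specificity variants, accuracy, yield of
#' actives (YoA) and enrichment factor (EF) from a confusion summary.
#' With zero total hits YoA and EF are undefined and reported as `NA`
#' with `undefined_hits = TRUE`.
#'
#' @param cs a [confusion_summary()] with `n_ac >= 1`.
#' @return List of class `metrics_report`.
#' @export
compute_metrics <- function(cs) {
  stopifnot(inherits(cs, "confusion_summary"), cs$n_ac >= 1)
  total <- cs$n_ac + cs$n_ia + cs$n_dc
  stopifnot(total >= 1)
  hits <- cs$tp + cs$fp
  yoa <- if (hits > 0) cs$tp / hits else NA_real_
  ef <- if (hits > 0) yoa / (cs$n_ac / total) else NA_real_
  structure(list(
    sensitivity = cs$tp / cs$n_ac,
    specificity_all = if (cs$n_ia + cs$n_dc > 0)
      cs$tn / (cs$n_ia + cs$n_dc) else NA_real_,
    specificity_ia_only = if (cs$n_ia > 0)
      1 - cs$fp_inactive / cs$n_ia else NA_real_,
    accuracy = (cs$tp + cs$tn) / total,
    yoa = yoa, ef = ef,
    undefined_hits = hits == 0, total = total),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics: sens %.2f acc %.2f YoA %s EF %s>\n",
              x$sensitivity, x$accuracy,
              if (is.na(x$yoa)) "NA" else sprintf("%.2f", x$yoa),
              if (is.na(x$ef)) "NA" else sprintf("%.2f", x$ef)))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Ranks compounds by descending score; tied scores enter together.  The
#' curve starts at (0,0) and ends at (1,1); AUC is the trapezoid-rule
#' area, which equals the Mann-Whitney statistic with ties counted 1/2.
#'
#' @param score numeric ranking scores.
#' @param truth logical (or 0/1): `TRUE` for actives.
#' @return List of class `roc_data`: `points` (data.frame `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_auc <- function(score, truth) {
  truth <- as.logical(truth)
  stopifnot(length(score) == length(truth), !anyNA(score), !anyNA(truth))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs at least one positive and one negative")
  ord <- order(-score)
  s <- score[ord]
  y <- truth[ord]
  # group ties: one curve point per distinct threshold
  last_of_group <- c(diff(s) != 0, TRUE)
  tpr <- c(0, cumsum(y)[last_of_group] / n_pos)
  fpr <- c(0, cumsum(!y)[last_of_group] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_data")
}

#' @export
print.roc_data <- function(x, ...) {
  cat(sprintf("<roc: %d points, AUC %.3f>\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Drop models below the enrichment-factor cutoff
#'
#' A model is retained iff its EF is defined and at least `threshold`
#' (strict `<` drops).  Models with zero hits have undefined EF and are
#' dropped with reason `"no hits"`.
#'
#' @param per_model named list of [confusion_summary()] objects.
#' @param threshold EF cutoff (default 4).
#' @return List with `retained` (character ids) and `dropped`
#'   (data.frame `id`, `ef`, `reason`).
#' @export
filter_models_by_ef <- function(per_model, threshold = 4) {
  ids <- names(per_model)
  stopifnot(!is.null(ids), all(nzchar(ids)))
  ef <- vapply(per_model, function(cs) compute_metrics(cs)$ef, numeric(1))
  undef <- is.na(ef)
  drop <- undef | ef < threshold
  list(retained = ids[!drop],
       dropped = data.frame(id = ids[drop], ef = ef[drop],
                            reason = ifelse(undef[drop], "no hits",
                                            "ef below threshold"),
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Published benchmark census for the four kinases
#'
#' The overall per-kinase dataset sizes and combined-model hit counts of
#' the reference evaluation (one column block per kinase: retrieved
#' actives, retrieved inactives, retrieved decoys, and the active /
#' inactive / decoy census of the screened database).  These counts are
#' the input for reproducing the reported accuracy, yield of actives and
#' enrichment factors via [compute_metrics()].
#'
#' @return data.frame with one row per kinase.
#' @export
#' @examples
#' cc <- jak_validation_counts()
#' cs <- confusion_summary(cc$tp[1], cc$fp_inactive[1], cc$fp_decoy[1],
#'                         cc$n_ac[1], cc$n_ia[1], cc$n_dc[1])
#' round(compute_metrics(cs)$ef, 2)
jak_validation_counts <- function() {
  data.frame(
    target = c("JAK1", "JAK2", "JAK3", "TYK2"),
    n_models = c(8L, 10L, 10L, 9L),
    tp = c(95L, 167L, 116L, 68L),
    fp_inactive = c(0L, 15L, 2L, 40L),
    fp_decoy = c(79L, 75L, 292L, 136L),
    n_ac = c(105L, 185L, 129L, 75L),
    n_ia = c(48L, 49L, 42L, 61L),
    n_dc = c(3263L, 2840L, 4499L, 3050L),
    stringsAsFactors = FALSE)
}
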