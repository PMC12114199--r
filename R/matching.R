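# Geometric pharmacophore matching.
#
# A conformer satisfies a model when an injective, kind-compatible
# assignment of model features to perceived ligand features exists whose
# least-squares rigid superposition puts every matched ligand feature
# inside its model feature's tolerance sphere, keeps every direction pair
# within the cone half-angle, and leaves no heavy atom strictly inside an
# exclusion volume.  The search enumerates assignments with a
# pairwise-distance pruning rule; correctness against exhaustive
# enumeration is part of the test suite.

#' Exclusion-volume clash check
#'
#' @param coords n x 3 matrix of (transformed) heavy-atom positions.
#' @param xvols exclusion volume data.frame (`x`, `y`, `z`, `radius`).
#' @return `TRUE` iff any point lies strictly inside any sphere (a point
#'   exactly on the surface does not clash).
#' @export
clash_check <- function(coords, xvols) {
  if (is.null(xvols) || nrow(xvols) == 0 || is.null(coords) ||
      nrow(coords) == 0) return(FALSE)
  centers <- as.matrix(xvols[, c("x", "y", "z")])
  for (k in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(coords, 2, centers[k, ])^2)
    if (any(d2 < xvols$radius[k]^2 - 1e-12)) return(TRUE)
  }
  FALSE
}

# Evaluate one complete assignment.  `assign` is an integer vector over
# model features (NA = omitted).  Returns NULL if the rigid fit is
# underdetermined, otherwise acceptance status, residuals, transform and
# score.  For exactly three collinear features the one-parameter rotation
# family about the feature axis leaves residuals unchanged but moves the
# rest of the molecule; both ends of that family (the Kabsch solution and
# its half-turn about the axis) must then pass the direction and clash
# checks.
evaluate_assignment <- function(model, fs, coords, assign, params) {
  sel <- which(!is.na(assign))
  if (length(sel) < 3) return(NULL)
  M <- feature_centers(model)[sel, , drop = FALSE]
  ffs <- fs$features
  L <- as.matrix(ffs[assign[sel], c("x", "y", "z"), drop = FALSE])
  fit <- kabsch_fit(L, M)
  radii <- model$features$radius[sel]
  transforms <- list(fit)
  if (length(sel) == 3 && (is_collinear(M, 1e-9) || is_collinear(L, 1e-9))) {
    axis <- M[3, ] - M[1, ]
    if (vnorm(axis) > 1e-9) {
      R2 <- rotation_about_axis(axis, pi) %*% fit$R
      # keep the fitted centroid correspondence
      t2 <- as.numeric(colMeans(M) - R2 %*% colMeans(L))
      transforms <- c(transforms, list(list(R = R2, t = t2)))
    }
  }
  best <- NULL
  for (tr in transforms) {
    Lt <- apply_rigid(L, tr$R, tr$t)
    residuals <- sqrt(rowSums((Lt - M)^2))
    score <- mean(pmax(0, 1 - residuals / radii))
    ok <- all(residuals <= radii + 1e-9)
    if (ok) {
      for (i in seq_along(sel)) {
        mf <- model$features[sel[i], ]
        lf <- ffs[assign[sel[i]], ]
        if (!is.na(mf$dx) && !is.na(lf$dx)) {
          ang <- angle_deg(as.numeric(tr$R %*% c(lf$dx, lf$dy, lf$dz)),
                           c(mf$dx, mf$dy, mf$dz),
                           axial = identical(mf$kind, "AI"))
          tol <- if (is.na(mf$angle_tol)) params$angle_tol else mf$angle_tol
          if (ang > tol + 1e-9) { ok <- FALSE; break }
        }
      }
    }
    clash <- FALSE
    if (ok && !is.null(coords) && nrow(model$xvols) > 0) {
      clash <- clash_check(apply_rigid(coords, tr$R, tr$t), model$xvols)
      if (clash) ok <- FALSE
    }
    cand <- list(ok = ok, clash = clash, score = score,
                 residuals = residuals, R = tr$R, t = tr$t)
    if (is.null(best)) best <- cand
    if (length(transforms) > 1) {
      # collinear case: accept only if every branch accepts
      if (!cand$ok) { best$ok <- FALSE; best$clash <- best$clash || cand$clash }
    }
  }
  best
}

#' Match a feature set against a pharmacophore model
#'
#' Enumerates injective kind-compatible assignments of at least
#' `feature_count - max_omitted` model features to ligand features,
#' pruning pairs whose intra-set distances are incompatible
#' (`|d_model(i,j) - d_ligand(a,b)| > radius_i + radius_j`).  Each
#' surviving assignment is scored by least-squares rigid superposition;
#' the best acceptable assignment (highest mean `1 - residual/radius`,
#' ties broken by lexicographically smallest correspondence) is returned.
#' When nothing is acceptable the best-scoring failed attempt is reported
#' with `matched = FALSE`.
#'
#' @param model a [pharmacophore_model()].
#' @param fs a [feature_set()].
#' @param coords heavy-atom coordinates for the exclusion-volume check;
#'   defaults to the coordinates stored in `fs`.
#' @param params a [screen_params()].
#' @return A list of class `match_result`: `matched`, `model_id`,
#'   `molecule_id`, `conformer`, `correspondence` (model feature ->
#'   ligand feature index, `NA` = omitted), `rotation`, `translation`,
#'   `residuals`, `clash`, `score`.
#' @export
match_feature_set <- function(model, fs, coords = fs$coords,
                              params = screen_params()) {
  stopifnot(inherits(model, "pharm_model"), inherits(fs, "feature_set"))
  nm <- nrow(model$features)
  ffs <- fs$features
  nl <- nrow(ffs)
  max_omit <- params$max_omitted %||% model$max_omitted
  need <- nm - max_omit

  empty <- list(matched = FALSE, model_id = model$id,
                molecule_id = fs$molecule_id, conformer = fs$conformer,
                correspondence = rep(NA_integer_, nm), rotation = NULL,
                translation = NULL, residuals = NULL, clash = FALSE,
                score = 0)
  class(empty) <- "match_result"
  if (nl == 0) return(empty)

  M <- feature_centers(model)
  L <- as.matrix(ffs[, c("x", "y", "z"), drop = FALSE])
  dM <- as.matrix(stats::dist(M))
  dL <- as.matrix(stats::dist(L))
  radii <- model$features$radius
  compat <- lapply(seq_len(nm), function(i) which(ffs$kind == model$features$kind[i]))

  state <- new.env(parent = emptyenv())
  state$best <- NULL          # best accepted
  state$best_fail <- empty    # best failed attempt

  consider <- function(assign) {
    ev <- evaluate_assignment(model, fs, coords, assign, params)
    if (is.null(ev)) return(invisible())
    res <- list(matched = ev$ok, model_id = model$id,
                molecule_id = fs$molecule_id, conformer = fs$conformer,
                correspondence = assign, rotation = ev$R,
                translation = ev$t, residuals = ev$residuals,
                clash = ev$clash, score = ev$score)
    class(res) <- "match_result"
    if (ev$ok) {
      if (is.null(state$best) || ev$score > state$best$score + 1e-12)
        state$best <- res
    } else {
      if (ev$score > state$best_fail$score + 1e-12) state$best_fail <- res
    }
    invisible()
  }

  # Depth-first over model features in order; ligand candidates in
  # ascending index, omission tried last, so the first assignment reaching
  # a given score is the lexicographically smallest.
  recurse <- function(i, assign, used, omitted) {
    if (i > nm) {
      if (sum(!is.na(assign)) >= max(need, 3L)) consider(assign)
      return(invisible())
    }
    for (a in compat[[i]]) {
      if (used[a]) next
      ok <- TRUE
      for (j in which(!is.na(assign))) {
        if (abs(dM[i, j] - dL[a, assign[j]]) > radii[i] + radii[j] + 1e-9) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      assign[i] <- a
      used[a] <- TRUE
      recurse(i + 1L, assign, used, omitted)
      used[a] <- FALSE
      assign[i] <- NA_integer_
    }
    if (omitted < max_omit) recurse(i + 1L, assign, used, omitted + 1L)
    invisible()
  }
  recurse(1L, rep(NA_integer_, nm), rep(FALSE, nl), 0L)

  if (!is.null(state$best)) state$best else state$best_fail
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match %s ~ %s[%d]: %s, score %.3f%s>\n",
              x$molecule_id, x$model_id, x$conformer,
              if (x$matched) "MATCH" else "no match", x$score,
              if (x$clash) ", clash" else ""))
  invisible(x)
}

#' Screen one molecule against a model
#'
#' Perceives features on every conformer and returns the best
#' [match_feature_set()] result across conformers (highest score among
#' matches, else highest failed score; ties broken by lowest conformer
#' index).
#'
#' @param model a [pharmacophore_model()].
#' @param mol a [molecule()] with at least one conformer.
#' @param params a [screen_params()].
#' @param rules perception rule table.
#' @return A `match_result`.
#' @export
screen_molecule <- function(model, mol, params = screen_params(),
                            rules = default_perception_rules()) {
  stopifnot(inherits(mol, "pharm_mol"))
  if (length(mol$conformers) == 0)
    stop("molecule ", mol$id,
         " has no conformers; run generate_conformers() first")
  best <- NULL
  for (ci in seq_along(mol$conformers)) {
    fs <- perceive_features(mol, ci, rules)
    res <- match_feature_set(model, fs, params = params)
    if (is.null(best)) { best <- res; next }
    if (res$matched > best$matched ||
        (res$matched == best$matched && res$score > best$score + 1e-12))
      best <- res
  }
  best
}
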