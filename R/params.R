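#' Screening run configuration
#'
#' Central bundle of the tunable tolerances used across model building,
#' matching and validation.  Defaults mirror common pharmacophore-tool
#' settings: 1.5 A feature tolerance spheres, 1.0 A exclusion-volume radii,
#' a 34 degree cone half-angle for direction checks, all model features
#' required (`max_omitted = 0` unless the model says otherwise), 200
#' conformers for training compounds and 400 for screening libraries, and
#' an enrichment-factor cutoff of 4 below which a model is discarded.
#'
#' @param feature_radius default tolerance sphere radius (A) for model
#'   features that do not carry their own.
#' @param xvol_radius default exclusion volume radius (A).
#' @param angle_tol default cone half-angle (degrees) for direction checks
#'   when a directed model feature carries none.
#' @param max_omitted if non-`NULL`, overrides each model's own
#'   `max_omitted` (number of model features that may go unmatched).
#' @param max_conformers_training,max_conformers_screening conformer
#'   ensemble caps for training and screening libraries.
#' @param ef_threshold enrichment-factor cutoff for [filter_models_by_ef()].
#' @param seed global seed; stage seeds are derived via [derive_seed()].
#' @return A list of class `screen_params`.
#' @export
#' @examples
#' p <- screen_params(angle_tol = 30)
#' p$feature_radius
screen_params <- function(feature_radius = 1.5,
                          xvol_radius = 1.0,
                          angle_tol = 34,
                          max_omitted = NULL,
                          max_conformers_training = 200,
                          max_conformers_screening = 400,
                          ef_threshold = 4,
                          seed = 1L) {
  stopifnot(feature_radius > 0, xvol_radius > 0, angle_tol > 0,
            ef_threshold >= 0)
  structure(list(feature_radius = feature_radius,
                 xvol_radius = xvol_radius,
                 angle_tol = angle_tol,
                 max_omitted = max_omitted,
                 max_conformers_training = max_conformers_training,
                 max_conformers_screening = max_conformers_screening,
                 ef_threshold = ef_threshold,
                 seed = as.integer(seed)),
            class = "screen_params")
}
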