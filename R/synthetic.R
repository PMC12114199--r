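# Synthetic benchmark generation.
#
# Benchmarks are feature-set-level: a planted active is the model's own
# feature layout re-expressed in a random rigid frame with isotropic
# Gaussian positional jitter; a decoy is built to violate at least one
# model constraint and is verified to fail the matcher at generation
# time.  Dummy heavy atoms sit on the feature positions so the
# exclusion-volume check stays live.  This isolates the matching and
# validation stages from chemistry; the perception-to-match path is
# covered separately by small real-molecule fixtures in the test suite.

#' Benchmark specification
#'
#' @param model_id id of the model the benchmark is planted against.
#' @param n_actives,n_decoys library composition (`n_actives + n_decoys
#'   >= 1`).
#' @param jitter_sd isotropic positional noise (A) applied to planted
#'   actives.
#' @param decoy_mode `"shuffle_kind"` (permute feature kinds),
#'   `"displace_one"` (move one feature by more than twice its radius) or
#'   `"random_points"` (uniform points in the model bounding box).
#' @param seed integer seed; the benchmark is byte-identical for equal
#'   seeds.
#' @return List of class `benchmark_spec`.
#' @export
benchmark_spec <- function(model_id, n_actives, n_decoys, jitter_sd = 0,
                           decoy_mode = c("displace_one", "shuffle_kind",
                                          "random_points"),
                           seed = 1L) {
  decoy_mode <- match.arg(decoy_mode)
  stopifnot(n_actives >= 0, n_decoys >= 0, n_actives + n_decoys >= 1,
            jitter_sd >= 0)
  structure(list(model_id = model_id, n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys), jitter_sd = jitter_sd,
                 decoy_mode = decoy_mode, seed = as.integer(seed)),
            class = "benchmark_spec")
}

# Feature set laid out exactly like the model, in the model frame.
model_as_feature_set <- function(model, molecule_id) {
  ff <- model$features
  df <- data.frame(kind = ff$kind, x = ff$x, y = ff$y, z = ff$z,
                   dx = ff$dx, dy = ff$dy, dz = ff$dz,
                   stringsAsFactors = FALSE)
  df$atoms <- I(as.list(seq_len(nrow(df))))
  feature_set(molecule_id, 1L, df, coords = as.matrix(df[, c("x", "y", "z")]))
}

# Re-express a feature set in a random rigid frame, optionally jittering
# positions (isotropic Gaussian, sd in A) and directions (rotation about
# a random axis, angle ~ N(0, 5 deg)).  Consumes the active RNG stream.
perturb_feature_set <- function(fs, jitter_sd = 0, direction_sd_deg = 5) {
  R <- random_rotation()
  t <- stats::runif(3, -20, 20)
  df <- fs$features
  P <- as.matrix(df[, c("x", "y", "z")])
  P <- apply_rigid(P, R, t)
  if (jitter_sd > 0)
    P <- P + matrix(stats::rnorm(length(P), 0, jitter_sd), ncol = 3)
  df[, c("x", "y", "z")] <- P
  for (k in seq_len(nrow(df))) {
    if (is.na(df$dx[k])) next
    d <- as.numeric(R %*% c(df$dx[k], df$dy[k], df$dz[k]))
    if (direction_sd_deg > 0) {
      ax <- stats::rnorm(3)
      ang <- stats::rnorm(1, 0, direction_sd_deg) * pi / 180
      d <- as.numeric(rotation_about_axis(ax, ang) %*% d)
    }
    df[k, c("dx", "dy", "dz")] <- as.list(d / vnorm(d))
  }
  feature_set(fs$molecule_id, fs$conformer, df,
              coords = as.matrix(df[, c("x", "y", "z")]))
}

#' Construct one constraint-violating decoy feature set
#'
#' Builds a feature set from the model layout, breaks it per `mode`, and
#' verifies that [match_feature_set()] rejects it at the given tolerances;
#' on an accidental match the construction is retried (fresh derived
#' seed) up to `max_retries` times.  A model whose features all share one
#' kind cannot be broken by `shuffle_kind`; that mode then falls back to
#' `displace_one` with a warning.
#'
#' @param model a [pharmacophore_model()].
#' @param mode decoy mode (see [benchmark_spec()]).
#' @param seed integer seed.
#' @param params matching tolerances used for verification.
#' @param max_retries bound on regeneration attempts.
#' @return A [feature_set()] that fails the matcher.
#' @export
make_decoy_featureset <- function(model, mode = "displace_one", seed = 1L,
                                  params = screen_params(),
                                  max_retries = 20L) {
  stopifnot(inherits(model, "pharm_model"))
  if (mode == "shuffle_kind" && length(unique(model$features$kind)) == 1L) {
    warning("all model features share one kind; falling back to displace_one")
    mode <- "displace_one"
  }
  for (attempt in seq_len(max_retries)) {
    fs <- with_seed(derive_seed(seed, paste0("decoy", attempt)), {
      base <- model_as_feature_set(model, "decoy")
      df <- base$features
      if (mode == "shuffle_kind") {
        repeat {
          perm <- sample(nrow(df))
          if (!identical(df$kind[perm], df$kind)) break
        }
        df$kind <- df$kind[perm]
      } else if (mode == "displace_one") {
        k <- sample(nrow(df), 1)
        r <- model$features$radius[k]
        dir <- unitize(stats::rnorm(3))
        shift <- stats::runif(1, 2 * r + 0.5, 3 * r + 0.5)
        df[k, c("x", "y", "z")] <-
          as.list(as.numeric(df[k, c("x", "y", "z")]) + dir * shift)
      } else { # random_points
        P <- feature_centers(model)
        lo <- apply(P, 2, min) - 2
        hi <- apply(P, 2, max) + 2
        for (k in seq_len(nrow(df)))
          df[k, c("x", "y", "z")] <- as.list(stats::runif(3, lo, hi))
      }
      fs <- feature_set("decoy", 1L, df,
                        coords = as.matrix(df[, c("x", "y", "z")]))
      perturb_feature_set(fs, 0, 0)
    })
    if (!match_feature_set(model, fs, params = params)$matched) return(fs)
  }
  stop("model ", model$id, " is unfalsifiable at these tolerances: ",
       "could not construct a failing decoy in ", max_retries, " attempts")
}

#' Generate a planted benchmark library
#'
#' Actives realize the model's feature layout in random rigid frames with
#' Gaussian positional jitter; decoys violate at least one constraint
#' (verified against the matcher at generation time).  Equal seeds give
#' byte-identical libraries.
#'
#' @param model a [pharmacophore_model()].
#' @param spec a [benchmark_spec()].
#' @param params matching tolerances used for decoy verification.
#' @return List with `feature_sets` (the library) and `labels`
#'   (data.frame `molecule_id`, `truth`).
#' @export
make_planted_benchmark <- function(model, spec, params = screen_params()) {
  stopifnot(inherits(model, "pharm_model"), inherits(spec, "benchmark_spec"))
  sets <- list()
  labels <- list()
  if (spec$n_actives > 0) {
    actives <- with_seed(derive_seed(spec$seed, "actives"), {
      lapply(seq_len(spec$n_actives), function(i) {
        fs <- model_as_feature_set(model, sprintf("act_%04d", i))
        perturb_feature_set(fs, spec$jitter_sd)
      })
    })
    sets <- c(sets, actives)
    labels <- c(labels, list(data.frame(
      molecule_id = sprintf("act_%04d", seq_len(spec$n_actives)),
      truth = TRUE, stringsAsFactors = FALSE)))
  }
  if (spec$n_decoys > 0) {
    decoys <- lapply(seq_len(spec$n_decoys), function(j) {
      fs <- make_decoy_featureset(model, spec$decoy_mode,
                                  seed = derive_seed(spec$seed,
                                                     paste0("dc", j)),
                                  params = params)
      fs$molecule_id <- sprintf("dec_%04d", j)
      fs
    })
    sets <- c(sets, decoys)
    labels <- c(labels, list(data.frame(
      molecule_id = sprintf("dec_%04d", seq_len(spec$n_decoys)),
      truth = FALSE, stringsAsFactors = FALSE)))
  }
  list(feature_sets = sets, labels = do.call(rbind, labels))
}

#' Generate synthetic activity records
#'
#' IC50 values are sampled log-uniformly inside the three bands the
#' activity thresholds define for the target (active: up to 1000 nM;
#' intermediate: up to the target's inactive floor; inactive: above it),
#' so [label_dataset()] recovers exactly the requested band counts.
#'
#' @param target kinase.
#' @param n_active,n_intermediate,n_inactive band counts.
#' @param seed integer seed.
#' @return data.frame of [activity_records()].
#' @export
make_activity_records <- function(target, n_active, n_intermediate,
                                  n_inactive, seed = 1L) {
  stopifnot(target %in% names(.inactive_floor),
            n_active >= 0, n_intermediate >= 0, n_inactive >= 0)
  floor_ <- .inactive_floor[[target]]
  with_seed(derive_seed(seed, "activity"), {
    logu <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))
    ic50 <- c(logu(n_active, 0.1, .active_ceiling),
              logu(n_intermediate, .active_ceiling * 1.001, floor_),
              logu(n_inactive, floor_ * 1.001, 1e7))
    n <- n_active + n_intermediate + n_inactive
    if (n == 0) return(activity_records(character(0), character(0),
                                        numeric(0))[0, ])
    activity_records(sprintf("%s_cmpd_%04d", target, seq_len(n)),
                     target, ic50, source = "synthetic")
  })
}
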