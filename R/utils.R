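# Small geometry and RNG helpers shared across modules.

#' Derive a stage-local random seed from a global seed
#'
#' Every stochastic stage of the pipeline (conformer generation, benchmark
#' simulation, decoy construction) takes its own seed.  Deriving those from a
#' single global seed with a stable hash keeps stages independently
#' reproducible: rerunning one stage does not disturb another.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(42, "conformers")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) return(NULL)
  v / n
}

# Angle in degrees between two vectors; axial = TRUE ignores orientation
# (used for aromatic ring normals, which have no preferred sign).
angle_deg <- function(a, b, axial = FALSE) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  if (axial) ca <- abs(ca)
  ca <- max(-1, min(1, ca))
  acos(ca) * 180 / pi
}

# Rotation matrix about `axis` by `theta` radians (Rodrigues).
rotation_about_axis <- function(axis, theta) {
  u <- unitize(axis)
  if (is.null(u)) stop("zero-length rotation axis")
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Uniform random proper rotation (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  Q <- Q %*% d
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Least-squares rigid superposition (Kabsch): returns R, t such that
# R %*% p + t best fits q over paired rows of P and Q.  Proper rotations
# only -- reflections would invert chirality.
kabsch_fit <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cq - R %*% cp), singular = s$d)
}

apply_rigid <- function(coords, R, t) {
  sweep(coords %*% t(R), 2, t, `+`)
}

# Are the rows of X collinear (within tol of a line)?
is_collinear <- function(X, tol = 1e-6) {
  if (nrow(X) < 3) return(TRUE)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)$d
  sv[2] < tol * max(sv[1], 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
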