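# Independent matching oracle: exhaustive enumeration of every injective
# kind-compatible assignment (no pruning) with a quaternion-based rigid
# fit (Horn's closed form), sharing no code with the package's Kabsch
# search path.  Used to certify the pruned search on small instances.

horn_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  A <- sweep(P, 2, cp); B <- sweep(Q, 2, cq)
  S <- t(A) %*% B
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  list(R = R, t = as.numeric(cq - R %*% cp))
}

# Returns list(matched, score): best accepted assignment over exhaustive
# enumeration, or matched = FALSE when none is acceptable.
oracle_match <- function(model, fs, coords = fs$coords,
                         params = screen_params()) {
  mf <- model$features
  lf <- fs$features
  nm <- nrow(mf); nl <- nrow(lf)
  max_omit <- params$max_omitted
  if (is.null(max_omit)) max_omit <- model$max_omitted
  need <- max(nm - max_omit, 3L)
  M <- as.matrix(mf[, c("x", "y", "z")])
  L <- as.matrix(lf[, c("x", "y", "z")])
  best <- list(matched = FALSE, score = 0)

  eval_assign <- function(sel, lig) {
    fit <- horn_fit(L[lig, , drop = FALSE], M[sel, , drop = FALSE])
    Lt <- sweep(L[lig, , drop = FALSE] %*% t(fit$R), 2, fit$t, `+`)
    res <- sqrt(rowSums((Lt - M[sel, , drop = FALSE])^2))
    if (any(res > mf$radius[sel] + 1e-9)) return(NULL)
    for (i in seq_along(sel)) {
      f <- mf[sel[i], ]; g <- lf[lig[i], ]
      if (!is.na(f$dx) && !is.na(g$dx)) {
        dl <- as.numeric(fit$R %*% c(g$dx, g$dy, g$dz))
        dm <- c(f$dx, f$dy, f$dz)
        ca <- sum(dl * dm) / sqrt(sum(dl^2) * sum(dm^2))
        if (identical(f$kind, "AI")) ca <- abs(ca)
        ang <- acos(max(-1, min(1, ca))) * 180 / pi
        tol <- if (is.na(f$angle_tol)) params$angle_tol else f$angle_tol
        if (ang > tol + 1e-9) return(NULL)
      }
    }
    if (!is.null(coords) && nrow(model$xvols) > 0) {
      Ct <- sweep(coords %*% t(fit$R), 2, fit$t, `+`)
      for (k in seq_len(nrow(model$xvols))) {
        ctr <- as.numeric(model$xvols[k, c("x", "y", "z")])
        if (any(rowSums(sweep(Ct, 2, ctr)^2) <
                model$xvols$radius[k]^2 - 1e-12)) return(NULL)
      }
    }
    mean(pmax(0, 1 - res / mf$radius[sel]))
  }

  search <- function(sel, lig, i) {
    if (i > length(sel)) {
      sc <- eval_assign(sel, lig)
      if (!is.null(sc) && (!best$matched || sc > best$score))
        best <<- list(matched = TRUE, score = sc)
      return(invisible())
    }
    for (a in seq_len(nl)) {
      if (a %in% lig) next
      if (lf$kind[a] != mf$kind[sel[i]]) next
      search(sel, c(lig, a), i + 1)
    }
  }

  sizes <- if (nm >= need) seq(nm, need, by = -1) else integer(0)
  for (size in sizes) {
    if (size > nl || size < 3) next
    subs <- utils::combn(nm, size, simplify = FALSE)
    for (sel in subs) search(sel, integer(0), 1)
  }
  best
}
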