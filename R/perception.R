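# Pharmacophoric feature perception on a single conformer.
#
# Four feature kinds are perceived: hydrogen-bond donors (HBD) and
# acceptors (HBA), hydrophobic contacts (HC) and aromatic-ring features
# (AI).  The rule table documents each rule's intent with an equivalent
# SMARTS pattern, but placement works directly on the annotated molecular
# graph so that feature positions and directions come out of the stored
# conformer coordinates.

#' Feature set container
#'
#' Typed pharmacophoric points perceived on one conformer, plus the
#' heavy-atom coordinates of that conformer (used by the matcher for
#' exclusion-volume checks).  `features` has one row per feature with
#' columns `kind`, `x`, `y`, `z`, `dx`, `dy`, `dz` (unit direction, `NA`
#' when the feature carries none) and a list column `atoms` of supporting
#' atom indices.
#'
#' @param molecule_id molecule identifier.
#' @param conformer conformer index.
#' @param features feature data.frame (see above).
#' @param coords heavy-atom n x 3 coordinate matrix in the same frame.
#' @return Object of class `feature_set`.
#' @export
feature_set <- function(molecule_id, conformer, features, coords = NULL) {
  stopifnot(is.data.frame(features))
  if (nrow(features)) {
    dir <- as.matrix(features[, c("dx", "dy", "dz")])
    has <- !is.na(dir[, 1])
    if (any(has)) {
      nn <- sqrt(rowSums(dir[has, , drop = FALSE]^2))
      stopifnot(all(abs(nn - 1) < 1e-9))
    }
  }
  structure(list(molecule_id = as.character(molecule_id),
                 conformer = as.integer(conformer),
                 features = features, coords = coords),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set %s[%d]: %s>\n", x$molecule_id, x$conformer,
              paste(x$features$kind, collapse = " ")))
  invisible(x)
}

#' Default perception rule table
#'
#' One row per rule with the feature kind, a human-readable description,
#' and the equivalent SMARTS pattern.  Donors are N-H / O-H (one feature
#' per donor heavy atom); acceptors are N or O with an available lone
#' pair, excluding amide nitrogens, nitro oxygens, pyrrole-type aromatic
#' nitrogens and positively charged atoms; aromatic features sit on 5- and
#' 6-membered aromatic rings; hydrophobic features on connected clusters
#' of at least `hc_min_cluster` low-polarity atoms (C, S, halogens, none
#' bonded to N or O).
#'
#' @param hc_min_cluster minimum cluster size for a hydrophobic feature.
#' @return data.frame with columns `kind`, `description`, `smarts`,
#'   plus the attribute `hc_min_cluster`.
#' @export
default_perception_rules <- function(hc_min_cluster = 3L) {
  rules <- data.frame(
    kind = c("HBD", "HBD", "HBA", "HBA", "AI", "HC"),
    description = c(
      "N-H donor", "O-H donor",
      "N acceptor (not amide, not pyrrole-type, not cationic)",
      "O acceptor (not nitro)",
      "5/6-membered aromatic ring",
      "lipophilic atom cluster (C,S,F,Cl,Br,I not bonded to N/O)"),
    smarts = c(
      "[#7!H0]", "[#8!H0]",
      "[#7;!$([NX3][CX3]=[OX1]);!$([nH]);!$([#7+])]",
      "[#8;!$([OX1]~[NX3](~[OX1]))&!$([#8+])]",
      "[a;r5,r6]",
      "[#6,#16,#9,#17,#35,#53;!$([*]~[#7,#8])]"),
    stringsAsFactors = FALSE)
  attr(rules, "hc_min_cluster") <- as.integer(hc_min_cluster)
  rules
}

# standard valences used to infer implicit hydrogen counts
.std_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                  Cl = 1, Br = 1, I = 1)

implicit_h_counts <- function(mol) {
  n <- n_atoms(mol)
  bs <- rep(0, n)
  for (k in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[k]
    if (o == 4) o <- 1.5          # aromatic bond order convention
    bs[mol$bonds$a1[k]] <- bs[mol$bonds$a1[k]] + o
    bs[mol$bonds$a2[k]] <- bs[mol$bonds$a2[k]] + o
  }
  val <- unname(.std_valence[mol$atoms$element])
  val[is.na(val)] <- 0
  # charge raises the N valence (ammonium) and lowers the O valence (oxide)
  val <- val + ifelse(mol$atoms$element == "N", mol$atoms$charge, 0)
  val <- val - ifelse(mol$atoms$element == "O" & mol$atoms$charge < 0, 1, 0)
  pmax(0, round(val - bs))
}

least_squares_normal <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  svd(Xc)$v[, 3]
}

#' Perceive pharmacophoric features on one conformer
#'
#' Places HBD features on donor heavy atoms (direction along the mean
#' explicit-hydrogen vector, omitted when hydrogens are implicit), HBA
#' features on acceptor heavy atoms (direction along the lone-pair
#' bisector approximation, i.e. opposite the mean bond vector), AI
#' features at aromatic ring centroids with the least-squares plane
#' normal, and HC features at the centroids of maximal qualifying
#' lipophilic clusters.  Output order is deterministic: by kind
#' (HBD, HBA, HC, AI), then by lowest supporting atom index.
#'
#' @param mol a [molecule()].
#' @param conformer_index conformer to use.
#' @param rules rule table from [default_perception_rules()].
#' @return A [feature_set()].
#' @export
perceive_features <- function(mol, conformer_index = 1L,
                              rules = default_perception_rules()) {
  stopifnot(inherits(mol, "pharm_mol"))
  if (conformer_index < 1 || conformer_index > length(mol$conformers))
    stop("molecule ", mol$id, " has no conformer ", conformer_index)
  if (is.null(rules) || nrow(rules) == 0) stop("empty perception rule table")
  cf <- mol$conformers[[conformer_index]]
  el <- mol$atoms$element
  nb <- graph_neighbors(mol$bonds, n_atoms(mol))
  implh <- implicit_h_counts(mol)
  hc_min <- attr(rules, "hc_min_cluster") %||% 3L

  feats <- list()
  add <- function(kind, pos, dir, atoms) {
    if (!is.null(dir)) dir <- unitize(dir)
    feats[[length(feats) + 1L]] <<- list(kind = kind, pos = pos,
                                         dir = dir, atoms = atoms)
  }

  has_double_to_O <- function(a) {
    any(vapply(seq_len(nrow(mol$bonds)), function(k) {
      b <- mol$bonds[k, ]
      b$order == 2 && ((b$a1 == a && el[b$a2] == "O") ||
                       (b$a2 == a && el[b$a1] == "O"))
    }, logical(1)))
  }

  for (a in seq_len(n_atoms(mol))) {
    if (!(el[a] %in% c("N", "O"))) next
    h_nb <- nb[[a]][el[nb[[a]]] == "H"]
    n_h <- length(h_nb) + implh[a]
    heavy_nb <- nb[[a]][el[nb[[a]]] != "H"]

    ## --- donor
    if (n_h > 0) {
      dir <- NULL
      if (length(h_nb) > 0) {
        vs <- lapply(h_nb, function(h) unitize(cf[h, ] - cf[a, ]))
        dir <- Reduce(`+`, vs)
      }
      add("HBD", cf[a, ], dir, a)
    }

    ## --- acceptor
    acc <- FALSE
    if (el[a] == "O") {
      # exclude nitro oxygens (O on an N that carries another O)
      nitro <- any(vapply(heavy_nb, function(b) {
        el[b] == "N" && sum(el[nb[[b]]] == "O") >= 2
      }, logical(1)))
      acc <- !nitro && mol$atoms$charge[a] <= 0
    } else if (el[a] == "N") {
      amide <- any(vapply(heavy_nb, function(b) {
        el[b] == "C" && has_double_to_O(b)
      }, logical(1)))
      pyrrole_type <- mol$atoms$aromatic[a] && n_h > 0
      # a nitrogen with 4 connections (counting implicit H) has no lone pair
      saturated <- (length(nb[[a]]) + implh[a]) >= 4
      acc <- !amide && !pyrrole_type && !saturated && mol$atoms$charge[a] <= 0
    }
    if (acc) {
      all_nb <- nb[[a]]
      dir <- NULL
      if (length(all_nb) > 0) {
        vs <- lapply(all_nb, function(b) unitize(cf[b, ] - cf[a, ]))
        s <- Reduce(`+`, vs)
        if (!is.null(unitize(s))) dir <- -s
      }
      add("HBA", cf[a, ], dir, a)
    }
  }

  ## --- aromatic rings
  for (r in mol$rings) {
    if (!(length(r) %in% c(5L, 6L))) next
    if (!all(mol$atoms$aromatic[r])) next
    X <- cf[r, , drop = FALSE]
    centroid <- colMeans(X)
    add("AI", centroid, least_squares_normal(X), sort(r))
  }

  ## --- hydrophobic clusters
  lipophilic <- el %in% c("C", "S", "F", "Cl", "Br", "I") &
    !vapply(seq_len(n_atoms(mol)), function(a) {
      any(el[nb[[a]]] %in% c("N", "O"))
    }, logical(1))
  seen <- rep(FALSE, n_atoms(mol))
  for (a in which(lipophilic)) {
    if (seen[a]) next
    comp <- integer(0)
    queue <- a
    seen[a] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      for (v in nb[[u]]) if (lipophilic[v] && !seen[v]) {
        seen[v] <- TRUE; queue <- c(queue, v)
      }
    }
    if (length(comp) >= hc_min) {
      add("HC", colMeans(cf[sort(comp), , drop = FALSE]), NULL, sort(comp))
    }
  }

  ## --- assemble in deterministic order
  kind_rank <- c(HBD = 1, HBA = 2, HC = 3, AI = 4)
  if (length(feats)) {
    ord <- order(kind_rank[vapply(feats, `[[`, "", "kind")],
                 vapply(feats, function(f) min(f$atoms), numeric(1)))
    feats <- feats[ord]
  }
  df <- data.frame(
    kind = vapply(feats, `[[`, "", "kind"),
    x = vapply(feats, function(f) f$pos[1], numeric(1)),
    y = vapply(feats, function(f) f$pos[2], numeric(1)),
    z = vapply(feats, function(f) f$pos[3], numeric(1)),
    dx = vapply(feats, function(f) (f$dir %||% NA_real_)[1], numeric(1)),
    dy = vapply(feats, function(f) if (is.null(f$dir)) NA_real_ else f$dir[2],
                numeric(1)),
    dz = vapply(feats, function(f) if (is.null(f$dir)) NA_real_ else f$dir[3],
                numeric(1)),
    stringsAsFactors = FALSE)
  df$atoms <- I(lapply(feats, `[[`, "atoms"))
  feature_set(mol$id, conformer_index, df,
              coords = heavy_coords(mol, conformer_index))
}
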