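# Molecule container and SDF / SMILES input-output.
#
# Parsing and format conversion are delegated to ChemmineR (SDF records)
# and ChemmineOB / Open Babel (SMILES, canonicalization, InChIKey, 3D
# embedding); this file only adapts them to the package's `pharm_mol`
# container, which groups consecutive SDF records with identical titles
# and connectivity into one molecule with a conformer ensemble.

#' Molecule container
#'
#' Lightweight container for one small molecule: atoms (element, formal
#' charge, aromatic flag), bonds, zero or more 3D conformers (n x 3
#' matrices, Angstrom), plus a canonical `structure_key` (InChIKey when
#' derivable, canonical SMILES otherwise) that is invariant under atom
#' reordering.
#'
#' @param id molecule identifier.
#' @param atoms data.frame with columns `element`, `charge`, `aromatic`.
#' @param bonds data.frame with columns `a1`, `a2`, `order`.
#' @param conformers list of n x 3 coordinate matrices.
#' @param name optional display name.
#' @param smiles canonical SMILES, if known.
#' @param structure_key canonical structure identifier.
#' @param rings list of integer vectors (atom indices of rings of size <= 6).
#' @return Object of class `pharm_mol`.
#' @export
molecule <- function(id, atoms, bonds, conformers = list(), name = id,
                     smiles = NA_character_, structure_key = NA_character_,
                     rings = list()) {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("element", "charge", "aromatic") %in% names(atoms)))
  if (nrow(bonds)) {
    stopifnot(all(c("a1", "a2", "order") %in% names(bonds)),
              all(bonds$a1 >= 1), all(bonds$a2 >= 1),
              all(bonds$a1 <= nrow(atoms)), all(bonds$a2 <= nrow(atoms)))
  }
  for (cf in conformers) {
    stopifnot(is.matrix(cf), nrow(cf) == nrow(atoms), ncol(cf) == 3)
  }
  structure(list(id = as.character(id), name = as.character(name),
                 atoms = atoms, bonds = bonds, conformers = conformers,
                 smiles = smiles, structure_key = structure_key,
                 rings = rings),
            class = "pharm_mol")
}

#' @export
print.pharm_mol <- function(x, ...) {
  cat(sprintf("<pharm_mol %s: %d atoms, %d bonds, %d conformer(s)>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), length(x$conformers)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

heavy_atom_indices <- function(mol) which(mol$atoms$element != "H")

# Heavy-atom coordinates of one conformer.
heavy_coords <- function(mol, conformer_index = 1L) {
  cf <- mol$conformers[[conformer_index]]
  cf[heavy_atom_indices(mol), , drop = FALSE]
}

## ---- internal: Open Babel bridge -------------------------------------

ob_convert <- function(from, to, input) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, input)),
    error = function(e) "")
  out
}

# Open Babel CLI conversion (the in-process bindings drop stereo
# descriptors on some paths; the CLI perceives and keeps them).
ob_cli <- function(in_format, out_format, text) {
  f <- tempfile(fileext = paste0(".", tolower(in_format)))
  on.exit(unlink(f))
  writeLines(text, f)
  out <- tryCatch(
    suppressWarnings(system2("obabel",
                             c(paste0("-i", tolower(in_format)), f,
                               paste0("-o", tolower(out_format))),
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) character(0))
  out[nzchar(trimws(out))]
}

first_token <- function(x) {
  if (length(x) == 0 || is.na(x[1])) return("")
  tok <- strsplit(trimws(x[1]), "[\t ]")[[1]]
  if (length(tok) == 0) "" else tok[1]
}

structure_key_from <- function(format, input) {
  key <- first_token(ob_cli(format, "inchikey", input))
  if (!nzchar(key)) key <- first_token(ob_cli(format, "can", input))
  if (!nzchar(key)) NA_character_ else key
}

## ---- internal: SDF record -> pharm_mol -------------------------------

# Old-style molfile charge codes (field 6 of the atom line).
.mol_charge_codes <- c(`1` = 3, `2` = 2, `3` = 1, `5` = -1, `6` = -2, `7` = -3)

sdf_record_to_parts <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  chg_col <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  charge <- unname(.mol_charge_codes[as.character(chg_col)])
  charge[is.na(charge)] <- 0
  atoms <- data.frame(element = elements, charge = charge,
                      aromatic = FALSE, stringsAsFactors = FALSE)
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  coords <- unname(ab[, 1:3, drop = FALSE])
  has3d <- any(abs(coords) > 1e-8)
  name <- ChemmineR::header(sdf)[["Molecule_Name"]]
  list(atoms = atoms, bonds = bonds,
       coords = if (has3d) coords else NULL,
       name = if (is.null(name) || is.na(name)) "" else name)
}

# Ring perception (ChemmineR ring finder) + aromaticity flags.  A 5- or
# 6-ring is flagged aromatic by a Hueckel-style electron count: every ring
# atom must contribute to the pi system (a double bond, or a lone pair on
# N/O/S), and the contributed electrons must total 4n+2.
perceive_rings <- function(sdf, atoms, bonds) {
  n <- nrow(atoms)
  ring_idx <- list()
  if (n >= 3 && nrow(bonds) >= 3) {
    rr <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = 6, type = "all",
                                        arom = FALSE)),
      error = function(e) list())
    ring_idx <- lapply(rr, function(r) as.integer(sub("^.*_", "", r)))
    ring_idx <- ring_idx[lengths(ring_idx) >= 3]
  }
  aromatic <- rep(FALSE, n)
  has_double <- rep(FALSE, n)
  if (nrow(bonds)) {
    dd <- bonds[bonds$order == 2, , drop = FALSE]
    has_double[c(dd$a1, dd$a2)] <- TRUE
    # Input files written with aromatic bond order 4 count as well.
    aa <- bonds[bonds$order == 4, , drop = FALSE]
    has_double[c(aa$a1, aa$a2)] <- TRUE
  }
  arom_rings <- list()
  for (r in ring_idx) {
    if (!(length(r) %in% c(5L, 6L))) next
    el <- atoms$element[r]
    pi_e <- integer(length(r))
    ok <- TRUE
    for (k in seq_along(r)) {
      if (has_double[r[k]]) {
        pi_e[k] <- 1L
      } else if (el[k] %in% c("N", "O", "S")) {
        pi_e[k] <- 2L            # pyrrole/furan/thiophene-type lone pair
      } else {
        ok <- FALSE
        break
      }
    }
    if (ok && sum(pi_e) %% 4 == 2) {
      aromatic[r] <- TRUE
      arom_rings <- c(arom_rings, list(r))
    }
  }
  list(rings = ring_idx, aromatic = aromatic)
}

# "M  CHG" property lines (pairs of atom index, charge) override the
# old-style atom-line charge column.
parse_chg_lines <- function(sdf_text, n_atoms) {
  charge <- rep(0, n_atoms)
  lines <- grep("^M  CHG", strsplit(sdf_text, "\n")[[1]], value = TRUE)
  for (l in lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "[ ]+")[[1]])
    n <- f[1]
    for (k in seq_len(n)) {
      idx <- f[2 * k]
      if (!is.na(idx) && idx >= 1 && idx <= n_atoms)
        charge[idx] <- f[2 * k + 1]
    }
  }
  charge
}

# Fallback for bondless records (single atoms), which ChemmineR's SDF
# reader rejects: fixed-width V2000 atom-line parse, no ring perception
# needed.
parse_bondless_record <- function(rec_lines) {
  counts <- rec_lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || nb != 0 || na < 1) return(NULL)
  if (length(rec_lines) < 4 + na) return(NULL)
  atom_lines <- rec_lines[5:(4 + na)]
  coords <- t(vapply(atom_lines, function(l) {
    c(as.numeric(substr(l, 1, 10)), as.numeric(substr(l, 11, 20)),
      as.numeric(substr(l, 21, 30)))
  }, numeric(3)))
  if (anyNA(coords)) return(NULL)
  dimnames(coords) <- NULL
  elements <- trimws(substr(atom_lines, 32, 34))
  if (any(!nzchar(elements))) return(NULL)
  list(atoms = data.frame(element = elements, charge = 0, aromatic = FALSE,
                          stringsAsFactors = FALSE),
       bonds = data.frame(a1 = integer(0), a2 = integer(0),
                          order = integer(0)),
       coords = if (any(abs(coords) > 1e-8)) coords else NULL,
       name = trimws(rec_lines[1]))
}

# `recs`: list of raw records, each list(sdf = SDF-or-NULL, parts, text).
sdf_records_to_molecule <- function(recs, id, sdf_text = NULL) {
  parts <- recs[[1]]$parts
  atoms <- parts$atoms
  bonds <- parts$bonds
  if (!is.null(sdf_text) && grepl("M  CHG", sdf_text, fixed = TRUE))
    atoms$charge <- parse_chg_lines(sdf_text, nrow(atoms))
  ringinfo <- if (!is.null(recs[[1]]$sdf)) {
    perceive_rings(recs[[1]]$sdf, atoms, bonds)
  } else list(rings = list(), aromatic = rep(FALSE, nrow(atoms)))
  atoms$aromatic <- ringinfo$aromatic
  conformers <- list()
  for (rec in recs) {
    if (!is.null(rec$parts$coords))
      conformers <- c(conformers, list(rec$parts$coords))
  }
  key <- if (!is.null(sdf_text)) structure_key_from("SDF", sdf_text)
         else NA_character_
  smi <- if (!is.null(sdf_text)) {
    s <- first_token(ob_cli("SDF", "can", sdf_text))
    if (nzchar(s)) s else NA_character_
  } else NA_character_
  molecule(id = id, atoms = atoms, bonds = bonds, conformers = conformers,
           name = if (nzchar(parts$name)) parts$name else id,
           smiles = smi, structure_key = key, rings = ringinfo$rings)
}

## ---- read_sdf ---------------------------------------------------------

#' Read an SDF library
#'
#' Reads an MDL SDF file (V2000 or V3000 records) into library records.
#' Consecutive records sharing the same title and connectivity are grouped
#' into a single molecule carrying a conformer ensemble.  Records whose
#' coordinates are all zero contribute no conformer.  Malformed records are
#' skipped with a warning, or abort the read when `strict = TRUE`.
#'
#' @param path SDF file path.
#' @param strict abort on the first malformed record instead of skipping.
#' @return List of library records, each a list with elements `molecule`
#'   (a [molecule()]), `source`, and `record_index` (0-based index of the
#'   first SDF record of the molecule).
#' @export
read_sdf <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read SDF file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) return(list())
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1) + 1L)
  if (length(ends) == 0L || max(ends) < length(lines)) {
    # trailing record without terminator
    starts <- c(starts, if (length(ends)) max(ends) + 1L else 1L)
    ends <- c(ends, length(lines))
    starts <- unique(starts)
  }
  raw <- list()   # per parsed record: list(sdf, text, title)
  n_bad <- 0L
  for (k in seq_along(starts)) {
    rec_lines <- lines[starts[k]:ends[k]]
    if (!any(nzchar(trimws(rec_lines)))) next
    rec <- tryCatch({
      sset <- suppressWarnings(
        ChemmineR::read.SDFset(ChemmineR::read.SDFstr(rec_lines)))
      if (length(sset) != 1L || !ChemmineR::validSDF(sset)) stop("invalid")
      list(sdf = sset[[1]], parts = sdf_record_to_parts(sset[[1]]),
           text = paste(c(rec_lines, ""), collapse = "\n"),
           title = trimws(rec_lines[1]))
    }, error = function(e) NULL)
    if (is.null(rec)) {
      parts <- tryCatch(parse_bondless_record(rec_lines),
                        error = function(e) NULL)
      if (!is.null(parts))
        rec <- list(sdf = NULL, parts = parts,
                    text = paste(c(rec_lines, ""), collapse = "\n"),
                    title = trimws(rec_lines[1]))
    }
    if (is.null(rec)) {
      if (strict) stop("malformed SDF record ", k, " in ", path)
      n_bad <- n_bad + 1L
      next
    }
    raw <- c(raw, list(rec))
  }
  if (n_bad > 0L)
    warning(n_bad, " malformed SDF record(s) skipped in ", path)
  # group consecutive records with identical title + connectivity
  records <- list()
  i <- 1L
  rec_index <- 0L
  while (i <= length(raw)) {
    j <- i
    p_i <- raw[[i]]$parts
    while (j < length(raw) &&
           identical(raw[[j + 1L]]$title, raw[[i]]$title) &&
           nzchar(raw[[i]]$title)) {
      p_j <- raw[[j + 1L]]$parts
      if (!identical(p_i$atoms$element, p_j$atoms$element) ||
          !identical(p_i$bonds, p_j$bonds)) break
      j <- j + 1L
    }
    id <- if (nzchar(raw[[i]]$title)) raw[[i]]$title
          else sprintf("mol_%03d", rec_index + 1L)
    mol <- sdf_records_to_molecule(raw[i:j], id, sdf_text = raw[[i]]$text)
    records <- c(records, list(list(molecule = mol, source = path,
                                    record_index = rec_index)))
    rec_index <- rec_index + 1L
    i <- j + 1L
  }
  records
}

## ---- write_sdf --------------------------------------------------------

.ab_colnames <- c("C1", "C2", "C3", paste0("C", 5:16))

molecule_to_sdf_objects <- function(mol) {
  n <- n_atoms(mol)
  confs <- mol$conformers
  if (length(confs) == 0L) confs <- list(matrix(0, n, 3))
  lapply(confs, function(cf) {
    ab <- cbind(cf, matrix(0, n, 12))
    rownames(ab) <- paste(mol$atoms$element, seq_len(n), sep = "_")
    colnames(ab) <- .ab_colnames
    nb <- nrow(mol$bonds)
    bb <- cbind(as.matrix(mol$bonds[, c("a1", "a2", "order")]),
                matrix(0, nb, 4))
    colnames(bb) <- paste0("C", 1:7)
    rownames(bb) <- seq_len(max(nb, 0))
    h <- c(Molecule_Name = mol$id, Source = "pharmscreen", Comment = "",
           Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                 n, nb))
    methods::new("SDF", header = h, atomblock = ab, bondblock = bb,
                 datablock = character(0))
  })
}

#' Write library records to an SDF file
#'
#' Writes MDL V2000 records; a molecule with several conformers is emitted
#' as consecutive records sharing its id, which [read_sdf()] regroups.
#' Coordinates survive a round trip to at least 4 decimal places.
#'
#' @param records list of library records (as returned by [read_sdf()]) or
#'   of bare [molecule()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(records, path) {
  mols <- lapply(records, function(r) if (inherits(r, "pharm_mol")) r
                                      else r$molecule)
  if (length(mols) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  sdfs <- do.call(c, lapply(mols, molecule_to_sdf_objects))
  ids <- unlist(lapply(mols, function(m) rep(m$id, max(1L, length(m$conformers)))))
  sset <- methods::new("SDFset", SDF = sdfs, ID = ids)
  ChemmineR::write.SDF(sset, file = path)
  invisible(path)
}

## ---- read_smiles_table ------------------------------------------------

#' Read a SMILES table
#'
#' Reads a whitespace/tab-separated table with columns `smiles` and `id`
#' (header optional, detected by a literal `smiles` in the first field).
#' Molecules carry no conformers; stereo descriptors are retained in the
#' structure key.  Unparsable SMILES are skipped with a warning.
#'
#' @param path file path.
#' @return List of library records (see [read_sdf()]).
#' @export
read_smiles_table <- function(path) {
  if (!file.exists(path)) stop("cannot read SMILES table: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^smiles\\b", tolower(lines[1]))) {
    lines <- lines[-1]
  }
  records <- list()
  ids_seen <- character(0)
  n_bad <- 0L
  n_dup <- 0L
  for (k in seq_along(lines)) {
    fields <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    smi <- fields[1]
    id <- if (length(fields) >= 2) fields[2] else sprintf("smi_%03d", k)
    sdf_text <- ob_convert("SMI", "SDF", paste0(smi, "\t", id, "\n"))
    sdf_lines <- strsplit(sdf_text, "\n")[[1]]
    rec <- tryCatch({
      s <- suppressWarnings(
        ChemmineR::read.SDFset(ChemmineR::read.SDFstr(sdf_lines)))
      if (length(s) != 1L || !ChemmineR::validSDF(s) ||
          nrow(ChemmineR::atomblock(s[[1]])) == 0L) stop("bad")
      list(sdf = s[[1]], parts = sdf_record_to_parts(s[[1]]))
    }, error = function(e) NULL)
    if (is.null(rec)) {
      parts <- tryCatch(parse_bondless_record(sdf_lines),
                        error = function(e) NULL)
      if (!is.null(parts)) rec <- list(sdf = NULL, parts = parts)
    }
    if (is.null(rec)) {
      n_bad <- n_bad + 1L
      next
    }
    mol <- sdf_records_to_molecule(list(rec), id)
    mol$conformers <- list()
    # keep the input SMILES (stereo included) for downstream embedding
    mol$smiles <- smi
    mol$structure_key <- structure_key_from("SMI", paste0(smi, "\n"))
    if (id %in% ids_seen) n_dup <- n_dup + 1L
    ids_seen <- c(ids_seen, id)
    records <- c(records, list(list(molecule = mol, source = path,
                                    record_index = length(records))))
  }
  if (n_bad > 0L) warning(n_bad, " unparsable SMILES line(s) skipped in ", path)
  if (n_dup > 0L) warning(n_dup, " duplicate id(s) in ", path, " (all kept)")
  records
}

## ---- conformer generation --------------------------------------------

graph_neighbors <- function(bonds, n) {
  nb <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a1[k]; b <- bonds$a2[k]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

# Atoms reachable from `from` without crossing the bond (from, cut).
component_beyond <- function(nb, from, cut) {
  seen <- rep(FALSE, length(nb))
  seen[cut] <- TRUE
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    for (b in nb[[a]]) if (!seen[b]) { seen[b] <- TRUE; queue <- c(queue, b) }
  }
  seen[cut] <- FALSE
  which(seen)
}

#' Generate a deterministic conformer ensemble
#'
#' Embeds up to `max_conformers` 3D conformers with RDKit's ETKDG
#' distance-geometry algorithm (explicit hydrogens added, MMFF cleanup,
#' RMSD-based pruning), run through the bundled Python helper with a
#' fixed random seed: identical seeds give bitwise-identical coordinates.
#' Embedded geometries are energy-reasonable; no atom pair comes closer
#' than 0.8 A.
#'
#' @param mol a [molecule()] with valence-consistent connectivity (a SMILES
#'   is required, as produced by [read_smiles_table()] or [read_sdf()]).
#' @param max_conformers ensemble cap (>= 1).
#' @param seed integer seed.
#' @param rmsd_dedup heavy-atom RMSD (A) below which two candidate
#'   conformers are considered duplicates and pruned.
#' @return The molecule with explicit hydrogens and `1..max_conformers`
#'   conformers.
#' @export
generate_conformers <- function(mol, max_conformers = 200, seed = 1L,
                                rmsd_dedup = 0.5) {
  stopifnot(inherits(mol, "pharm_mol"), max_conformers >= 1)
  smi <- mol$smiles
  if (is.na(smi) || !nzchar(smi))
    stop("molecule ", mol$id, " has no SMILES; cannot embed")
  recs <- embed_smiles_table(data.frame(smiles = smi, id = mol$id),
                             max_conformers = max_conformers, seed = seed,
                             rmsd_dedup = rmsd_dedup)
  if (length(recs) == 0L) stop("cannot embed molecule ", mol$id)
  emb <- recs[[1]]$molecule
  emb$name <- mol$name
  if (!is.na(mol$structure_key)) emb$structure_key <- mol$structure_key
  emb
}

# Batch embedding through the bundled RDKit helper; returns library
# records like read_sdf().  Molecules that fail to embed are dropped
# (ids recorded in the "failed" attribute).
embed_smiles_table <- function(table, max_conformers = 200, seed = 1L,
                               rmsd_dedup = 0.5) {
  script <- system.file("python", "embed_conformers.py",
                        package = "pharmscreen", mustWork = TRUE)
  smi_file <- tempfile(fileext = ".smi")
  sdf_file <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(smi_file, sdf_file)))
  writeLines(paste(table$smiles, table$id, sep = "\t"), smi_file)
  err <- suppressWarnings(system2(
    "python", c(script, "--smi", smi_file, "--out", sdf_file,
                "--max-confs", max_conformers, "--seed", seed,
                "--prune-rms", rmsd_dedup),
    stdout = FALSE, stderr = TRUE))
  status <- attr(err, "status") %||% 0L
  if (status != 0L)
    stop("conformer embedding failed: ", paste(err, collapse = " "))
  failed <- sub("^EMBED_FAIL ", "", grep("^EMBED_FAIL ", err, value = TRUE))
  recs <- if (file.exists(sdf_file)) read_sdf(sdf_file) else list()
  attr(recs, "failed") <- failed
  recs
}
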