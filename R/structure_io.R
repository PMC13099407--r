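# Structure input/output and atom selection.
#
# An "atom table" is a plain data.frame with one row per atom and columns
#   serial, atom_name, alt_loc, res_name, chain_id, res_seq, insert,
#   x, y, z, occ, b, element
# plus an attribute `model_id`. An "ensemble" (class gdv_ensemble) is a list
# of atom tables sharing an identical atom roster. PDB parsing and writing is
# delegated to bio3d; this layer adds model handling, heavy-atom selection
# and shape descriptors.

ATOM_COLS <- c("serial", "atom_name", "alt_loc", "res_name", "chain_id",
               "res_seq", "insert", "x", "y", "z", "occ", "b", "element")

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Construct an atom table
#'
#' Validates and assembles the per-atom data.frame used throughout the
#' package. Coordinates must be finite; occupancies, when present, must lie
#' in \[0, 1\].
#'
#' @param df data.frame holding the atom columns (see Details).
#' @param model_id integer model number the table belongs to.
#' @return The validated data.frame with attribute `model_id`.
#' @export
atom_table <- function(df, model_id = 1L) {
  missing_cols <- setdiff(ATOM_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)
  df <- df[, c(ATOM_COLS, setdiff(names(df), ATOM_COLS))]
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("non-finite coordinates in atom table")
  occ <- df$occ[!is.na(df$occ)]
  if (length(occ) > 0 && (min(occ) < 0 || max(occ) > 1))
    stop("occupancy outside [0, 1]")
  rownames(df) <- NULL
  attr(df, "model_id") <- as.integer(model_id)
  df
}

coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# Residue identity of each atom, as a factor in order of first appearance.
residue_ids <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$insert, sep = "|")
  factor(key, levels = unique(key))
}

#' Read a structural model (or all models) from a PDB file
#'
#' @param path path to a PDB file (ATOM/HETATM/MODEL/ENDMDL records).
#' @param model integer model number, or `"all"` to return every model of a
#'   multi-model (e.g. NMR) file as an ensemble.
#' @return An atom table, or for `model = "all"` an object of class
#'   `gdv_ensemble`: a list of atom tables with a shared atom roster.
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("unparseable PDB file '", path, "': ",
                             conditionMessage(e))
  )
  n_models <- nrow(pdb$xyz)
  tab_for <- function(k) {
    xyz <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    atom_table(data.frame(
      serial = pdb$atom$eleno,
      atom_name = pdb$atom$elety,
      alt_loc = ifelse(is.na(pdb$atom$alt), "", pdb$atom$alt),
      res_name = pdb$atom$resid,
      chain_id = ifelse(is.na(pdb$atom$chain), "", pdb$atom$chain),
      res_seq = pdb$atom$resno,
      insert = ifelse(is.na(pdb$atom$insert), "", pdb$atom$insert),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = pdb$atom$o,
      b = pdb$atom$b,
      element = element_of(pdb$atom),
      type = pdb$atom$type,
      stringsAsFactors = FALSE
    )[, c(ATOM_COLS, "type")], model_id = k)
  }
  if (identical(model, "all")) {
    ens <- lapply(seq_len(n_models), tab_for)
    class(ens) <- "gdv_ensemble"
    return(ens)
  }
  model <- as.integer(model)
  if (model < 1 || model > n_models)
    stop("model ", model, " not found (file has ", n_models, " model(s))")
  tab_for(model)
}

# Best-effort element symbol: trust the element column when present,
# otherwise strip digits from the atom name (PDB v2 style).
element_of <- function(atom_df) {
  ele <- atom_df$elesy
  if (is.null(ele)) ele <- rep(NA_character_, nrow(atom_df))
  guess <- sub("^[0-9]*([A-Za-z]).*$", "\\1", trimws(atom_df$elety))
  # two-letter special case for common hetero elements is irrelevant for
  # protein heavy atoms; H/D detection is what matters here
  ifelse(is.na(ele) | ele == "", toupper(guess), toupper(ele))
}

#' Restrict an atom table to protein heavy atoms
#'
#' Keeps ATOM records of the twenty standard amino acids, drops hydrogens
#' and deuteriums, waters and hetero compounds, and resolves alternate
#' locations by keeping the highest-occupancy conformer (ties go to the
#' first encountered). Idempotent.
#'
#' @param atoms atom table (from [read_structure()] or a generator).
#' @return The filtered atom table, original ordering preserved.
#' @export
filter_protein_heavy <- function(atoms) {
  keep <- atoms$res_name %in% STANDARD_AA &
    !(atoms$element %in% c("H", "D"))
  if (!is.null(atoms$type)) keep <- keep & atoms$type == "ATOM"
  out <- atoms[keep, , drop = FALSE]
  if (nrow(out) > 0) {
    key <- paste(out$chain_id, out$res_seq, out$insert, out$atom_name, sep = "|")
    occ <- ifelse(is.na(out$occ), 1, out$occ)
    ord <- order(key, -occ, seq_len(nrow(out)))
    dup <- duplicated(key[ord])
    keep2 <- logical(nrow(out))
    keep2[ord[!dup]] <- TRUE
    out <- out[keep2, , drop = FALSE]
  }
  if (nrow(out) == 0)
    stop("no protein heavy atoms left after filtering")
  rownames(out) <- NULL
  attr(out, "model_id") <- attr(atoms, "model_id")
  out
}

#' Write per-atom values into the B-factor column of a PDB file
#'
#' The standard channel for storing a per-atom score: each value is written
#' into the B-factor field (width 6, two decimals), clamped to the
#' representable range \[-99.99, 999.99\].
#'
#' @param atoms atom table whose coordinates and identities are written.
#' @param values numeric vector, one value per atom.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_predictions <- function(atoms, values, path) {
  if (length(values) != nrow(atoms))
    stop("length of values (", length(values), ") does not match atom count (",
         nrow(atoms), ")")
  b <- pmin(pmax(as.numeric(values), -99.99), 999.99)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords(atoms))),
    type = rep("ATOM", nrow(atoms)),
    eleno = atoms$serial,
    elety = atoms$atom_name,
    resid = atoms$res_name,
    chain = atoms$chain_id,
    resno = atoms$res_seq,
    insert = ifelse(atoms$insert == "", NA, atoms$insert),
    o = ifelse(is.na(atoms$occ), 1, atoms$occ),
    b = b,
    elesy = atoms$element
  )
  invisible(path)
}

#' Radius of gyration
#'
#' Unweighted root-mean-square distance of the atoms from their centroid.
#'
#' @param atoms atom table with at least one atom.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(atoms) {
  if (nrow(atoms) < 1) stop("empty atom table")
  xyz <- coords(atoms)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Globularity filter
#'
#' A chain is considered globular when its radius of gyration is below
#' N^0.6 with N the number of distinct residues; a companion length flag
#' reports whether N exceeds 50 residues. Elongated, rod-like chains fail
#' the radius criterion because their gyration radius grows linearly with
#' length.
#'
#' @param atoms atom table carrying residue identities.
#' @return List with elements `globular` (logical), `rg`, `n_res`,
#'   `threshold` (= N^0.6) and `long_enough` (N > 50).
#' @export
globularity_check <- function(atoms) {
  rg <- radius_of_gyration(atoms)
  n_res <- nlevels(residue_ids(atoms))
  thr <- n_res^0.6
  list(globular = rg < thr, rg = rg, n_res = n_res, threshold = thr,
       long_enough = n_res > 50)
}
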