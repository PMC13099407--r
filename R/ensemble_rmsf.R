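# Reference fluctuations from multi-model ensembles (NMR-style): rigid-body
# superposition onto an iteratively refined mean structure, per-atom RMSF
# across conformers, and representative-conformer selection.

ensemble_coords <- function(ens) lapply(ens, coords)

check_roster <- function(ens) {
  if (!is.list(ens) || length(ens) < 1) stop("empty ensemble")
  ref <- ens[[1]]
  key <- function(a) paste(a$chain_id, a$res_seq, a$insert, a$atom_name)
  k0 <- key(ref)
  for (i in seq_along(ens)) {
    if (nrow(ens[[i]]) != nrow(ref) || !identical(key(ens[[i]]), k0))
      stop("ensemble models do not share an identical atom roster (model ",
           i, ")")
  }
  invisible(TRUE)
}

# Optimal proper rotation (Kabsch): returns P aligned onto Q, both n x 3,
# least-squares on the masked rows. Reflections are never applied.
kabsch_align <- function(P, Q, mask) {
  cp <- colMeans(P[mask, , drop = FALSE])
  cq <- colMeans(Q[mask, , drop = FALSE])
  A <- sweep(P[mask, , drop = FALSE], 2, cp)
  B <- sweep(Q[mask, , drop = FALSE], 2, cq)
  H <- crossprod(A, B) # t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sweep(sweep(P, 2, cp) %*% R, 2, cq, "+")
}

#' Superpose an ensemble onto its mean structure
#'
#' Each model is rigid-body superposed (least squares, proper rotations
#' only) onto the mean coordinate structure, which is refined iteratively:
#' superpose, re-average, repeat until the mean moves by less than 1e-6
#' Angstrom (at most 10 rounds). The default superposition mask is the
#' alpha carbons; pass `mask = NULL` to use every atom.
#'
#' @param ens `gdv_ensemble` (list of roster-identical atom tables),
#'   at least two models.
#' @param mask logical vector over atoms used for the superposition;
#'   default alpha carbons.
#' @return Object of class `aligned_ensemble`: list with `models` (list of
#'   n x 3 coordinate matrices), `mean_xyz`, `rmsd` (per-model RMSD to the
#'   mean over the mask), `mask`, and `atoms` (the shared atom table).
#' @export
superpose_ensemble <- function(ens, mask = NULL) {
  check_roster(ens)
  if (length(ens) < 2) stop("need at least two models to superpose")
  atoms <- ens[[1]]
  if (is.null(mask)) mask <- atoms$atom_name == "CA"
  if (!any(mask)) mask <- rep(TRUE, nrow(atoms))
  xyz <- ensemble_coords(ens)
  mean_xyz <- xyz[[1]]
  for (iter in seq_len(10)) {
    xyz <- lapply(xyz, kabsch_align, Q = mean_xyz, mask = mask)
    new_mean <- Reduce(`+`, xyz) / length(xyz)
    shift <- max(sqrt(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < 1e-6) break
  }
  rmsd <- vapply(xyz, function(m) {
    sqrt(mean(rowSums((m[mask, , drop = FALSE] -
                         mean_xyz[mask, , drop = FALSE])^2)))
  }, numeric(1))
  structure(list(models = xyz, mean_xyz = mean_xyz, rmsd = rmsd,
                 mask = mask, atoms = atoms),
            class = "aligned_ensemble")
}

#' Per-atom RMSF across an aligned ensemble
#'
#' For each atom, the square root of the mean squared displacement from
#' that atom's mean position over the models.
#'
#' @param aligned an `aligned_ensemble` with at least two models.
#' @return Raw [rmsf_profile()] in Angstrom.
#' @export
rmsf_from_ensemble <- function(aligned) {
  xyz <- aligned$models
  if (length(xyz) < 2) stop("need at least two models for an RMSF")
  mean_pos <- Reduce(`+`, xyz) / length(xyz)
  msd <- Reduce(`+`, lapply(xyz, function(m) rowSums((m - mean_pos)^2))) /
    length(xyz)
  rmsf_profile(sqrt(msd), normalized = FALSE)
}

#' Representative conformer of an ensemble
#'
#' The model with the minimum alpha-carbon RMSD to the mean coordinate
#' structure; ties go to the lowest model index.
#'
#' @param aligned an `aligned_ensemble`.
#' @return Integer model index.
#' @export
representative_model <- function(aligned) {
  ca <- aligned$atoms$atom_name == "CA"
  if (!any(ca)) ca <- rep(TRUE, nrow(aligned$atoms))
  rmsd_ca <- vapply(aligned$models, function(m) {
    sqrt(mean(rowSums((m[ca, , drop = FALSE] -
                         aligned$mean_xyz[ca, , drop = FALSE])^2)))
  }, numeric(1))
  which.min(rmsd_ca)
}
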