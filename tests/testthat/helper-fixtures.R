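# Small named graphs and structure helpers shared across test files.

# nodes I=1, J=2, H=3, F=4; the closed neighborhood of I in the
# ten-node example: edges I-J, I-H, I-F and J-H
worked_example_graph <- function() {
  contact_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3)))
}

path_graph <- function(n) {
  contact_graph(n, cbind(seq_len(n - 1), seq_len(n - 1) + 1))
}

complete_graph <- function(n) contact_graph(n, t(combn(n, 2)))

star_graph <- function(n_leaves) {
  contact_graph(n_leaves + 1, cbind(1, 1 + seq_len(n_leaves)))
}

# bare atom table from coordinates, one single-atom residue per row
point_atoms <- function(xyz, atom_name = "CA") {
  n <- nrow(xyz)
  atom_table(data.frame(
    serial = seq_len(n), atom_name = atom_name, alt_loc = "",
    res_name = "GLY", chain_id = "A", res_seq = seq_len(n), insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
    element = "C", stringsAsFactors = FALSE
  ))
}

random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

transform_atoms <- function(atoms, R, shift) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% R
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# multi-model PDB from a list of atom tables (shared roster)
write_multimodel_pdb <- function(models, path) {
  lines <- character(0)
  for (i in seq_along(models)) {
    tmp <- tempfile(fileext = ".pdb")
    write_predictions(models[[i]], models[[i]]$b, tmp)
    atom_lines <- grep("^ATOM", readLines(tmp), value = TRUE)
    unlink(tmp)
    lines <- c(lines, sprintf("MODEL     %4d", i), atom_lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# brute-force edge list by checking all pairs
all_pairs_edges <- function(atoms, cutoff) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
}

# independent triangle count via the adjacency-matrix trace
count_triangles <- function(g) {
  A <- matrix(0, g$n_nodes, g$n_nodes)
  A[g$edges] <- 1
  A[g$edges[, c(2, 1), drop = FALSE]] <- 1
  round(sum(diag(A %*% A %*% A)) / 6)
}

make_rigid_copies <- function(base, n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    transform_atoms(base, random_rotation(), rnorm(3, sd = 20)))
}

edge_key <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  sort(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
}
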