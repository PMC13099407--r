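# Atomic contact graphs and spatial partition plans.
#
# A contact graph (class "contact_graph") is a simple undirected graph over
# 1-based node indices: list(n_nodes, edges) where `edges` is a 2-column
# integer matrix with edges[, 1] < edges[, 2], no duplicates, no self-loops.

#' Construct a contact graph object
#'
#' @param n_nodes number of nodes.
#' @param edges two-column integer matrix of node index pairs (1-based).
#' @return Object of class `contact_graph`.
#' @export
contact_graph <- function(n_nodes, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1) || any(edges > n_nodes))
      stop("edge endpoint outside [1, n_nodes]")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    flip <- edges[, 1] > edges[, 2]
    edges[flip, ] <- edges[flip, c(2, 1)]
    if (anyDuplicated(paste(edges[, 1], edges[, 2])))
      stop("duplicate edges are not allowed")
  }
  structure(list(n_nodes = as.integer(n_nodes), edges = edges),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("Contact graph:", x$n_nodes, "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Build the atomic contact graph
#'
#' Nodes are atoms; an edge joins every atom pair whose Euclidean distance is
#' strictly below the cutoff. The neighbour search uses a cell list, so peak
#' memory scales with the number of contacts rather than with the full
#' N x N distance matrix.
#'
#' @param atoms atom table (at least two atoms).
#' @param cutoff contact distance cutoff in Angstrom (default 7).
#' @return A `contact_graph` over the atom indices (file order).
#' @export
build_contact_graph <- function(atoms, cutoff = 7.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (nrow(atoms) < 2) stop("need at least two atoms to build a graph")
  pairs <- .neighbor_pairs_cpp(coords(atoms), cutoff)
  contact_graph(nrow(atoms), pairs)
}

#' Plan index-contiguous partitions with spatial environments
#'
#' Splits the structure into cores of consecutive whole residues
#' (`chunk_size` residues each; the last core may be smaller). The
#' environment of a core consists of all atoms of residues outside it that
#' have any atom within `surround_radius` of any core alpha-carbon, so each
#' core's subgraph reproduces the local topology of the full graph.
#'
#' @param atoms atom table carrying residue identities.
#' @param chunk_size core size in residues (default 100).
#' @param surround_radius environment radius in Angstrom (default 15; use
#'   3 x cutoff = 21 for results identical to the all-at-once computation).
#' @return Object of class `partition_plan`: a list of parts, each with
#'   `core_atoms` and `env_atoms` (atom indices), plus the parameters.
#' @export
plan_partitions <- function(atoms, chunk_size = 100L, surround_radius = 15.0) {
  if (chunk_size < 1) stop("chunk_size must be at least 1 residue")
  res <- residue_ids(atoms)
  n_res <- nlevels(res)
  res_idx <- as.integer(res)
  starts <- seq(1L, n_res, by = as.integer(chunk_size))
  xyz <- coords(atoms)
  is_ca <- atoms$atom_name == "CA"
  parts <- lapply(starts, function(s) {
    core_res <- s:min(s + chunk_size - 1L, n_res)
    in_core <- res_idx %in% core_res
    core_atoms <- which(in_core)
    ca_core <- core_atoms[is_ca[core_atoms]]
    anchors <- if (length(ca_core) > 0) ca_core else core_atoms
    near <- .any_within_cpp(xyz, xyz[anchors, , drop = FALSE], surround_radius)
    env_res <- setdiff(unique(res_idx[near]), core_res)
    env_atoms <- which(res_idx %in% env_res)
    list(core_atoms = core_atoms, env_atoms = env_atoms)
  })
  structure(list(parts = parts, chunk_size = as.integer(chunk_size),
                 surround_radius = surround_radius, n_res = n_res),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  sizes <- vapply(x$parts, function(p) length(p$core_atoms), integer(1))
  cat("Partition plan:", length(x$parts), "part(s) over", x$n_res,
      "residues (chunk", x$chunk_size, "residues, surround",
      x$surround_radius, "A)\n")
  cat("  core atom counts:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Contact graph of one core-plus-environment part
#'
#' @param atoms full atom table.
#' @param part one element of a [plan_partitions()] plan.
#' @param cutoff contact cutoff in Angstrom.
#' @return List with `graph` (a `contact_graph` over the part's atoms, in
#'   original atom order), `atom_index` (original indices of the subgraph
#'   nodes) and `core_mask` (logical, TRUE for core nodes).
#' @export
extract_subgraph <- function(atoms, part, cutoff = 7.0) {
  idx <- sort(unique(c(part$core_atoms, part$env_atoms)))
  if (length(idx) == 0) stop("empty partition part")
  sub <- atoms[idx, , drop = FALSE]
  attr(sub, "model_id") <- attr(atoms, "model_id")
  g <- if (nrow(sub) >= 2) build_contact_graph(sub, cutoff)
       else contact_graph(nrow(sub), matrix(integer(0), ncol = 2))
  list(graph = g, atom_index = idx, core_mask = idx %in% part$core_atoms)
}
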