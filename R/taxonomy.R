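# Exhaustive enumeration of the graphlet orbit taxonomy.
#
# Independent of the counting code: generates every connected simple graph
# on 2-4 labelled nodes, reduces to isomorphism classes, and partitions each
# class's nodes into automorphism orbits. The canonical ordering (graphlets
# by size, then edge count, then maximum degree; orbits within a graphlet by
# node degree) reproduces the standard numbering 0-14 used by the model
# coefficients: edge 0; 3-path 1, 2; triangle 3; 4-path 4, 5; 3-star 6, 7;
# 4-cycle 8; tailed triangle 9, 10, 11; diamond 12, 13; K4 14.

graph_connected <- function(A) {
  n <- nrow(A)
  seen <- c(TRUE, rep(FALSE, n - 1))
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(apply(A[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

canonical_code <- function(A) {
  n <- nrow(A)
  codes <- apply(perms_of(n), 1, function(p) {
    paste(as.integer(A[p, p][upper.tri(A)]), collapse = "")
  })
  max(codes)
}

automorphism_orbits <- function(A) {
  n <- nrow(A)
  P <- perms_of(n)
  keep <- apply(P, 1, function(p) identical(A[p, p], A))
  auto <- P[keep, , drop = FALSE]
  # orbit label of node i: smallest node it can be mapped to
  vapply(seq_len(n), function(i) min(auto[, i]), integer(1))
}

#' Enumerate the graphlets on 2-4 nodes and their automorphism orbits
#'
#' Exhaustively generates all connected non-isomorphic simple graphs on 2, 3
#' and 4 nodes and partitions each graph's nodes into automorphism orbits.
#' There are 9 such graphlets carrying 15 orbits in total; the returned
#' numbering matches the orbit order expected by [published_model()].
#'
#' @return data.frame with one row per orbit: `orbit` (global id 0-14),
#'   `graphlet` (id 0-8), `size`, `n_edges`, `degree` (degree of the orbit's
#'   nodes within the graphlet) and `multiplicity` (number of nodes in the
#'   orbit).
#' @export
orbit_taxonomy <- function() {
  graphlets <- list()
  for (size in 2:4) {
    pairs <- t(combn(size, 2))
    np <- nrow(pairs)
    seen <- character(0)
    for (code in seq_len(2^np - 1)) {
      sel <- as.logical(intToBits(code)[seq_len(np)])
      A <- matrix(FALSE, size, size)
      A[pairs[sel, , drop = FALSE]] <- TRUE
      A <- A | t(A)
      if (!graph_connected(A)) next
      canon <- canonical_code(A)
      if (canon %in% seen) next
      seen <- c(seen, canon)
      graphlets[[length(graphlets) + 1L]] <- A
    }
  }
  size <- vapply(graphlets, nrow, integer(1))
  n_edges <- vapply(graphlets, function(A) sum(A) / 2L, numeric(1))
  max_deg <- vapply(graphlets, function(A) max(rowSums(A)), numeric(1))
  ord <- order(size, n_edges, max_deg)
  graphlets <- graphlets[ord]

  rows <- list()
  next_orbit <- 0L
  for (g in seq_along(graphlets)) {
    A <- graphlets[[g]]
    lab <- automorphism_orbits(A)
    deg <- rowSums(A)
    labs <- unique(lab)
    for (l in labs[order(deg[match(labs, lab)])]) {
      members <- which(lab == l)
      rows[[length(rows) + 1L]] <- data.frame(
        orbit = next_orbit, graphlet = g - 1L, size = nrow(A),
        n_edges = sum(A) / 2L, degree = deg[members[1]],
        multiplicity = length(members)
      )
      next_orbit <- next_orbit + 1L
    }
  }
  do.call(rbind, rows)
}
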