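expect_gdv_row <- function(gdv, node, expected_named) {
  row <- setNames(rep(0L, 15), paste0("O", 0:14))
  row[names(expected_named)] <- as.integer(expected_named)
  expect_equal(gdv[node, ], row)
}

test_that("orbit counts on named small graphs match hand enumeration", {
  for (counter in list(count_orbits, count_orbits_bruteforce)) {
    edge <- counter(contact_graph(2, rbind(c(1, 2))))
    expect_gdv_row(edge, 1, c(O0 = 1))
    expect_gdv_row(edge, 2, c(O0 = 1))

    tri <- counter(complete_graph(3))
    for (v in 1:3) expect_gdv_row(tri, v, c(O0 = 2, O3 = 1))

    p3 <- counter(path_graph(3))
    expect_gdv_row(p3, 1, c(O0 = 1, O1 = 1))
    expect_gdv_row(p3, 2, c(O0 = 2, O2 = 1))

    p4 <- counter(path_graph(4))
    expect_gdv_row(p4, 1, c(O0 = 1, O1 = 1, O4 = 1))
    expect_gdv_row(p4, 2, c(O0 = 2, O1 = 1, O2 = 1, O5 = 1))

    star <- counter(star_graph(3))
    expect_gdv_row(star, 1, c(O0 = 3, O2 = 3, O7 = 1)) # center
    expect_gdv_row(star, 2, c(O0 = 1, O1 = 2, O6 = 1)) # leaf

    k4 <- counter(complete_graph(4))
    for (v in 1:4) expect_gdv_row(k4, v, c(O0 = 3, O3 = 3, O14 = 1))

    cyc4 <- counter(contact_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))))
    for (v in 1:4) expect_gdv_row(cyc4, v, c(O0 = 2, O1 = 2, O2 = 1, O8 = 1))
  }
})

test_that("the worked-example neighborhood graph gives node I 3, 2, 1", {
  g <- worked_example_graph()
  gdv <- count_orbits(g)
  expect_equal(unname(gdv[1, c("O0", "O2", "O3")]), c(3L, 2L, 1L))
  expect_identical(gdv, count_orbits_bruteforce(g))
})

test_that("fast counter equals the brute-force oracle on random graphs", {
  set.seed(1)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    p <- sample(c(0.1, 0.3, 0.5), 1)
    g <- make_random_graph(n, p, seed = 1000 + i)
    expect_identical(count_orbits(g), count_orbits_bruteforce(g),
                     label = sprintf("graph n=%d p=%.1f seed=%d", n, p, i))
  }
})

test_that("combinatorial orbit identities hold on random graphs", {
  for (i in 1:10) {
    g <- make_random_graph(25, 0.3, seed = 2000 + i)
    gdv <- count_orbits(g)
    deg <- gdv[, "O0"]
    expect_equal(sum(deg), 2 * nrow(g$edges))
    expect_equal(sum(gdv[, "O3"]), 3 * count_triangles(g))
    expect_equal(gdv[, "O2"] + gdv[, "O3"], choose(deg, 2))
    # per node: O1 + 2*O3 = sum over neighbors of (deg - 1)
    nbr_sum <- vapply(seq_len(g$n_nodes), function(v) {
      nb <- c(g$edges[g$edges[, 1] == v, 2], g$edges[g$edges[, 2] == v, 1])
      sum(deg[nb] - 1)
    }, numeric(1))
    expect_equal(gdv[, "O1"] + 2 * gdv[, "O3"], nbr_sum)
  }
})

test_that("triangle totals agree with igraph", {
  skip_if_not_installed("igraph")
  g <- make_random_graph(40, 0.3, seed = 77)
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  # both sides equal three times the number of triangles
  expect_equal(sum(count_orbits(g)[, "O3"]),
               sum(igraph::count_triangles(ig)))
})

test_that("relabelling nodes permutes GDV rows identically", {
  g <- make_random_graph(20, 0.3, seed = 5)
  perm <- with(list(), {set.seed(8); sample(20)})
  relabelled <- contact_graph(20, cbind(perm[g$edges[, 1]],
                                        perm[g$edges[, 2]]))
  gdv <- count_orbits(g)
  gdv_rel <- count_orbits(relabelled)
  expect_equal(gdv_rel[perm, ], gdv)
})

test_that("degenerate graphs are handled", {
  empty <- contact_graph(0, matrix(integer(0), ncol = 2))
  expect_equal(dim(count_orbits(empty)), c(0, 15))
  isolated <- contact_graph(3, rbind(c(1, 2)))
  gdv <- count_orbits(isolated)
  expect_equal(unname(gdv[3, ]), rep(0L, 15))
})

test_that("orbit taxonomy enumerates 9 graphlets carrying 15 orbits", {
  tax <- orbit_taxonomy()
  expect_equal(nrow(tax), 15)
  expect_equal(length(unique(tax$graphlet)), 9)
  expect_equal(tax$orbit, 0:14)
  expect_equal(sum(tax$size == 2), 1)  # the edge
  expect_equal(sum(tax$size == 3), 3)  # 3-path ends/middle + triangle
  expect_equal(sum(tax$size == 4), 11)
  # orbit 0 is the edge end; orbit 14 the K4 node
  expect_equal(tax$n_edges[tax$orbit == 14], 6)
  expect_equal(tax$degree[tax$orbit == 7], 3) # star centre
})

test_that("structure-level GDV aligns rows with atoms", {
  # spacing 4: adjacent pairs within the 7 A cutoff, the ends (8 A) not
  collinear <- point_atoms(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)))
  gdv <- gdv_all_at_once(collinear, cutoff = 7)
  expect_equal(unname(gdv[2, 1:4]), c(2L, 0L, 1L, 0L))
})

test_that("by-parts equals all-at-once when one chunk covers the protein", {
  atoms <- make_helix_structure(50, seed = 21)
  expect_identical(gdv_by_parts(atoms, chunk_size = 1000),
                   gdv_all_at_once(atoms))
})

test_that("by-parts with surround 3x cutoff reproduces all-at-once exactly", {
  atoms <- make_helix_structure(300, seed = 22)
  expect_identical(gdv_by_parts(atoms, chunk_size = 60, surround_radius = 21),
                   gdv_all_at_once(atoms))
})

test_that("independent clusters decompose exactly", {
  c1 <- gdvflex:::make_cloud_structure(10, seed = 31)
  c2 <- gdvflex:::make_cloud_structure(10, seed = 32)
  c2$x <- c2$x + 60
  c2$res_seq <- c2$res_seq + 10
  both <- atom_table(rbind(c1, c2))
  combined <- gdv_by_parts(both, chunk_size = 10, surround_radius = 12)
  expect_equal(combined[seq_len(nrow(c1)), ], gdv_all_at_once(c1))
  expect_equal(combined[nrow(c1) + seq_len(nrow(c2)), ], gdv_all_at_once(c2))
})

test_that("GDV export writes the canonical tab-separated layout", {
  gdv <- count_orbits(worked_example_graph())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gdv(gdv, path)
  back <- as.matrix(read.delim(path))
  expect_equal(colnames(back), paste0("O", 0:14))
  expect_equal(unname(back), unname(gdv))
})
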