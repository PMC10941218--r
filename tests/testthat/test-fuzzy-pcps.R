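test_that("linear similarity kernel follows 1 - d/dmax", {
  d <- patristic_distances(toy_tree())
  s <- phylo_similarity(d)
  expect_equal(s["A", "B"], 0.5)
  expect_equal(s["A", "C"], 0)
  expect_equal(s["B", "C"], 0)
  expect_equal(diag(s), stats::setNames(rep(1, 3), c("A", "B", "C")))

  two <- patristic_distances(read_newick("(A:1,B:1);"))
  s2 <- phylo_similarity(two)
  expect_equal(s2["A", "B"], 0)

  # star tree: all off-diagonal similarities equal
  star <- patristic_distances(set_unit_branch_lengths(read_newick("(A,B,C,D);")))
  ss <- phylo_similarity(star)
  expect_equal(length(unique(ss[upper.tri(ss)])), 1)

  expect_error(phylo_similarity(matrix(0, 2, 2)), "zero")
})

test_that("membership matrix column-standardizes the similarity", {
  s <- phylo_similarity(patristic_distances(toy_tree()))
  q <- fuzzy_membership(s)
  # column A of the toy: (1, 0.5, 0) / 1.5
  expect_equal(unname(q[, "A"]), c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(unname(colSums(q)), rep(1, 3), tolerance = 1e-12)
  # diagonal is each column's maximum
  expect_true(all(diag(q) >= apply(q, 2, max) - 1e-15))

  # identity similarity (star tree) gives identity membership
  star <- phylo_similarity(
    patristic_distances(set_unit_branch_lengths(read_newick("(A,B,C);"))))
  expect_equal(unname(fuzzy_membership(star)), diag(3))
})

test_that("composition rows mix memberships of the present species", {
  q <- fuzzy_membership(phylo_similarity(patristic_distances(toy_tree())))
  pres <- matrix(c(1, 1, 0,   # cell 1: A, B
                   0, 0, 1),  # cell 2: C
                 2, 3, byrow = TRUE,
                 dimnames = list(1:2, c("A", "B", "C")))
  p <- phylo_composition(pres, q)
  # hand arithmetic: row 1 = (Q[A,] + Q[B,]) renormalized
  raw1 <- q["A", ] + q["B", ]
  expect_equal(p[1, ], raw1 / sum(raw1), tolerance = 1e-12)
  expect_equal(unname(rowSums(p)), c(1, 1), tolerance = 1e-12)

  # identity membership: uniform row over all present species
  id_q <- diag(3); dimnames(id_q) <- list(c("A", "B", "C"), c("A", "B", "C"))
  all_pres <- matrix(1, 1, 3, dimnames = list(1, c("A", "B", "C")))
  expect_equal(unname(phylo_composition(all_pres, id_q)[1, ]), rep(1 / 3, 3))
  one_pres <- matrix(c(0, 1, 0), 1, 3, dimnames = list(1, c("A", "B", "C")))
  expect_equal(unname(phylo_composition(one_pres, id_q)[1, ]), c(0, 1, 0))

  # misaligned species order is refused
  bad <- pres[, c(2, 1, 3)]
  expect_error(phylo_composition(bad, q), "align")
})

test_that("single-species cells reduce the composition to membership rows", {
  q <- fuzzy_membership(phylo_similarity(patristic_distances(toy_tree())))
  pres <- diag(3)
  dimnames(pres) <- list(1:3, c("A", "B", "C"))
  p <- phylo_composition(pres, q)
  expect_equal(unname(p), unname(sweep(q, 1, rowSums(q), "/")),
               tolerance = 1e-12)
})

test_that("sqrt Bray-Curtis hits its closed-form toy values", {
  x <- rbind(a = c(0.5, 0.5, 0), b = c(0, 0.5, 0.5), c = c(0.5, 0.5, 0))
  d <- sqrt_bray_curtis(x)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], sqrt(0.5), tolerance = 1e-12)
  disj <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(sqrt_bray_curtis(disj)["a", "b"], 1)
})

test_that("PCoA reconstructs distances and matches cmdscale", {
  set.seed(5)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- seq_len(8)
  ord <- pcps(d)
  rec <- as.matrix(dist(ord$axes))
  expect_lt(max(abs(rec - d)), 1e-8)

  ref <- stats::cmdscale(d, k = 3, eig = TRUE)
  expect_equal(sort(ord$eigenvalues[1:3], decreasing = TRUE),
               sort(ref$eig[1:3], decreasing = TRUE), tolerance = 1e-8)

  # 3 equidistant points: two equal eigenvalues, unit pairwise distances
  d3 <- matrix(1, 3, 3) - diag(3)
  rownames(d3) <- colnames(d3) <- 1:3
  o3 <- pcps(d3)
  expect_equal(o3$eigenvalues[1], o3$eigenvalues[2], tolerance = 1e-10)
  expect_equal(as.vector(as.matrix(dist(o3$axes))[upper.tri(d3)]),
               rep(1, 3), tolerance = 1e-10)

  # collinear configuration: a single positive eigenvalue recovers the line
  line <- as.matrix(dist(c(0, 1, 3, 6)))
  rownames(line) <- colnames(line) <- 1:4
  ol <- pcps(line)
  expect_equal(length(ol$eigenvalues), 1)
  expect_equal(as.matrix(dist(ol$axes)), line, ignore_attr = TRUE,
               tolerance = 1e-10)

  # fully degenerate input errors
  zero <- matrix(0, 3, 3); rownames(zero) <- colnames(zero) <- 1:3
  expect_error(pcps(zero), "degenerate")
})

test_that("axis selection is strictly greater than the threshold", {
  # 2-D configuration with relative variances exactly (0.95, 0.05)
  a <- sqrt(0.95); b <- sqrt(0.05)
  pts <- rbind(c(-a, 0), c(a, 0), c(0, -b), c(0, b))
  d <- as.matrix(dist(pts)); rownames(d) <- colnames(d) <- 1:4
  ord <- pcps(d, var_threshold = 0.05)
  expect_equal(ord$relative_variance[2], 0.05, tolerance = 1e-12)
  # strictness probed at the exact computed value: an axis sitting exactly
  # on the threshold is NOT selected, one epsilon below the threshold is
  rv2 <- ord$relative_variance[2]
  expect_equal(pcps(d, var_threshold = rv2)$selected, 1L)
  expect_equal(pcps(d, var_threshold = rv2 - 1e-9)$selected, c(1L, 2L))

  b2 <- sqrt(0.06)
  pts2 <- rbind(c(-a, 0), c(a, 0), c(0, -b2), c(0, b2))
  d2 <- as.matrix(dist(pts2)); rownames(d2) <- colnames(d2) <- 1:4
  expect_equal(pcps(d2, var_threshold = 0.05)$selected, c(1L, 2L))
})

test_that("membership columns and composition rows are exact simplexes", {
  for (seed in 1:10) {
    tg <- random_tree_grid(n_species = 5 + seed, n_cells = 8 + seed, seed)
    d <- patristic_distances(tg$tree)
    q <- fuzzy_membership(phylo_similarity(d))
    p <- phylo_composition(tg$grid, q)
    expect_lt(max(abs(colSums(q) - 1)), 1e-12)
    expect_lt(max(abs(rowSums(p) - 1)), 1e-12)
    expect_true(all(q >= 0 & q <= 1))
    expect_true(all(p >= 0 & p <= 1))
  }
})
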