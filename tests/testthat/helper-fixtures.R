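# Shared fixtures: toy trees, random grids, and the standard
# classification pipeline used across test files.

toy_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# random nonnegative composition-like matrix with unit row sums
random_fuzzy_rows <- function(n_cells, n_species, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_cells * n_species), n_cells, n_species)
  rownames(m) <- seq_len(n_cells)
  sweep(m, 1, rowSums(m), "/")
}

# random tree + random occupancy grid sharing the tree's species
random_tree_grid <- function(n_species, n_cells, seed) {
  tree <- simulate_tree(n_species, seed = seed)
  set.seed(seed + 1)
  repeat {
    pres <- matrix(rbinom(n_cells * n_species, 1, 0.3), n_cells, n_species,
                   dimnames = list(seq_len(n_cells), tree$tip.label))
    if (all(rowSums(pres) > 0) && all(colSums(pres) > 0)) break
  }
  list(tree = tree, grid = occurrence_grid(pres))
}

# composition matrix straight from a synthetic truth
composition_of <- function(truth) {
  g <- drop_empty_cells(truth$grid)
  g <- suppressMessages(align_to_tree(g, truth$tree))
  d <- patristic_distances(truth$tree)[g$species, g$species]
  phylo_composition(g, fuzzy_membership(phylo_similarity(d)))
}

# full recovery run on a synthetic truth; returns classification + truth
recover_regions <- function(truth, seed) {
  p <- composition_of(truth)
  r <- classify_evoregions(p, seed = seed)
  list(regions = r, truth = truth$true_cell_region[r$cell_ids])
}

# gaussian blobs at given centers
gaussian_blobs <- function(centers, n_per, sd, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(stats::rnorm(n_per, centers[i, 1], sd),
          stats::rnorm(n_per, centers[i, 2], sd))
  }))
}

# independent brute-force Mk likelihood: sum over all internal-state
# assignments (trees small enough to enumerate)
enumerate_mk_loglik <- function(tree, tip_states, rate, states) {
  k <- length(states)
  ntip <- length(tree$tip.label)
  n_int <- tree$Nnode
  Pm <- function(t) {
    e <- exp(-k * rate * t / (k - 1))
    m <- matrix((1 - e) / k, k, k)
    diag(m) <- 1 / k + (k - 1) * e / k
    m
  }
  tip_idx <- match(tip_states[tree$tip.label], states)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  lik <- 0
  for (ci in seq_len(nrow(combos))) {
    ns <- c(tip_idx, combos[ci, ])
    pr <- 1 / k
    for (ei in seq_len(nrow(tree$edge))) {
      pr <- pr * Pm(tree$edge.length[ei])[ns[tree$edge[ei, 1]],
                                          ns[tree$edge[ei, 2]]]
    }
    lik <- lik + pr
  }
  log(lik)
}

# simulate tip states forward along the tree under the ER model
# (independent of the pruning/simmap code path)
simulate_tip_states <- function(tree, rate, k, seed) {
  set.seed(seed)
  Pm <- function(t) {
    e <- exp(-k * rate * t / (k - 1))
    m <- matrix((1 - e) / k, k, k)
    diag(m) <- 1 / k + (k - 1) * e / k
    m
  }
  ntip <- length(tree$tip.label)
  ns <- integer(ntip + tree$Nnode)
  ns[ntip + 1] <- sample.int(k, 1)
  edges <- rev(seq_len(nrow(tree$edge)))
  po <- stats::reorder(tree, "postorder")
  for (i in rev(seq_len(nrow(po$edge)))) {
    P <- Pm(po$edge.length[i])
    ns[po$edge[i, 2]] <- sample.int(k, 1, prob = P[ns[po$edge[i, 1]], ])
  }
  stats::setNames(LETTERS[ns[seq_len(ntip)]], tree$tip.label)
}
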