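test_that("pruning matches the two-state closed form and the rate->0 limit", {
  tr <- read_newick("(A:1,B:1);")
  # k = 2, rate q each way: P(same) = (1 + exp(-2qt))/2
  for (q in c(0.2, 0.7, 1.5)) {
    psame <- (1 + exp(-2 * q)) / 2
    pdiff <- (1 - exp(-2 * q)) / 2
    ll_same <- log(0.5 * psame^2 + 0.5 * pdiff^2)
    ll_diff <- log(psame * pdiff)
    expect_equal(mk_loglik(tr, c(A = "x", B = "x"), q,
                           states = c("x", "y")), ll_same,
                 tolerance = 1e-10)
    expect_equal(mk_loglik(tr, c(A = "x", B = "y"), q), ll_diff,
                 tolerance = 1e-10)
  }
  # rate -> 0 with equal tip states: likelihood -> 1/k
  expect_equal(mk_loglik(tr, c(A = "x", B = "x"), 1e-9,
                         states = c("x", "y", "z")), log(1 / 3),
               tolerance = 1e-6)
})

test_that("pruning equals brute-force enumeration on 4-tip 3-state toys", {
  states <- c("x", "y", "z")
  trees <- list(
    read_newick("((A:1,B:1):1,(C:1,D:1):1);"),
    read_newick("((A:0.4,B:1.3):0.6,(C:2,D:0.2):1.1);"),
    read_newick("(((A:1,B:1):1,C:2):1,D:3);")
  )
  tips <- list(c(A = "x", B = "y", C = "x", D = "z"),
               c(A = "x", B = "x", C = "y", D = "y"),
               c(A = "z", B = "z", C = "z", D = "x"))
  for (tr in trees) for (ts in tips) for (rate in c(0.3, 1.1)) {
    expect_equal(mk_loglik(tr, ts, rate, states = states),
                 enumerate_mk_loglik(tr, ts, rate, states),
                 tolerance = 1e-10)
  }
})

test_that("the ML rate is recovered from forward simulations", {
  # depth 8 so a single character undergoes enough changes for its rate
  # to be identifiable from one realization
  tree <- simulate_tree(64, seed = 100)
  tree$edge.length <- tree$edge.length * 8
  hits <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    ts <- simulate_tip_states(tree, rate = 0.5, k = 3, seed = 200 + i)
    if (length(unique(ts)) < 2) next
    fit <- fit_mk_rate(tree, ts, states = LETTERS[1:3])
    if (abs(fit - 0.5) <= 0.25) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * n_rep)
})

test_that("degenerate and two-tip rate fits behave as documented", {
  tr <- read_newick("(A:1,B:1);")
  expect_warning(r0 <- fit_mk_rate(tr, c(A = "x", B = "x"),
                                   states = c("x", "y")), "lower bound")
  expect_equal(r0, 1e-6)

  # two different tips: the likelihood (1 - exp(-4qt))/4 rises
  # monotonically with the rate (a single unresolved difference cannot
  # bound it), so the bounded fit pins at the top of the search interval
  # (numerically the likelihood plateaus at 1/4 once exp(-4q) underflows,
  # so the optimizer stops anywhere on the plateau)
  fit <- fit_mk_rate(tr, c(A = "x", B = "y"))
  expect_gt(fit, 5)
  expect_lte(fit, 1e3)
  ll <- function(r) mk_loglik(tr, c(A = "x", B = "y"), r)
  expect_gt(ll(fit), ll(0.1))
  expect_equal(ll(fit), log(1 / 4), tolerance = 1e-3)
})

test_that("stochastic maps are seeded, consistent and endpoint-matching", {
  tr <- ultrametrize_extend(set_unit_branch_lengths(
    read_newick("(((A,B),C),(D,E));")))
  ts <- c(A = "r", B = "r", C = "g", D = "g", E = "b")
  sm1 <- mk_simmap(tr, ts, rate = 0.8, n_maps = 25, seed = 4)
  sm2 <- mk_simmap(tr, ts, rate = 0.8, n_maps = 25, seed = 4)
  expect_identical(sm1$maps, sm2$maps)
  expect_identical(sm1$node_posteriors, sm2$node_posteriors)

  for (m in seq_along(sm1$maps)) {
    for (ei in seq_along(sm1$maps[[m]])) {
      h <- sm1$maps[[m]][[ei]]
      expect_true(all(h$lengths > 0))
      expect_equal(sum(h$lengths), sm1$edge_length[ei], tolerance = 1e-9)
      par <- sm1$edge[ei, 1]; ch <- sm1$edge[ei, 2]
      expect_equal(h$states[1], sm1$node_states[m, par])
      expect_equal(h$states[length(h$states)], sm1$node_states[m, ch])
      # contiguous segmentation: consecutive states always differ
      if (length(h$states) > 1) {
        expect_true(all(h$states[-1] != h$states[-length(h$states)]))
      }
    }
  }
  # node posteriors are frequencies: rows sum to 1
  expect_equal(unname(rowSums(sm1$node_posteriors)),
               rep(1, nrow(sm1$node_posteriors)))
})

test_that("a near-zero rate keeps a single-state clade's ancestor fixed", {
  tr <- ultrametrize_extend(set_unit_branch_lengths(
    read_newick("(((A,B),C),(D,E));")))
  ts <- c(A = "r", B = "r", C = "r", D = "b", E = "b")
  sm <- mk_simmap(tr, ts, rate = 1e-4, n_maps = 200, seed = 1)
  node_ab <- ape::getMRCA(tr, c("A", "B"))
  expect_gte(sm$node_posteriors[as.character(node_ab), "r"], 0.99)
})

test_that("map frequencies converge to the exact marginal posteriors", {
  tr <- ultrametrize_extend(set_unit_branch_lengths(
    read_newick("(((A,B),(C,D)),(E,F));")))
  ts <- c(A = "r", B = "g", C = "g", D = "g", E = "b", F = "r")
  rate <- 0.9
  n_maps <- 600
  marg <- mk_marginal(tr, ts, rate)
  sm <- mk_simmap(tr, ts, rate = rate, n_maps = n_maps, seed = 11)
  se <- sqrt(marg * (1 - marg) / n_maps)
  expect_true(all(abs(sm$node_posteriors - marg) <= 3 * se + 1e-9))
})

test_that("expected changes per map increase with the rate", {
  tr <- ultrametrize_extend(set_unit_branch_lengths(
    read_newick("(((A,B),C),(D,E));")))
  ts <- c(A = "r", B = "g", C = "r", D = "b", E = "b")
  means <- vapply(c(0.2, 0.6, 1.2, 2.5), function(rate) {
    mean(mk_simmap(tr, ts, rate = rate, n_maps = 300, seed = 5)$n_changes)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("tips without states are pruned with a message", {
  tr <- toy_tree()
  ts <- c(A = "x", B = "y")
  expect_message(pr <- prune_to_states(tr, ts), "pruning 1 tips")
  expect_setequal(pr$tip.label, c("A", "B"))
})
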