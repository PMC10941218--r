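# Equal-rates Mk machinery: pruning likelihood, ML rate, marginal
# ancestral states, and stochastic character mapping. `rate` is the total
# rate of leaving a state, so the off-diagonal rate between any ordered
# state pair is rate / (k - 1).

# ER transition probability matrix over k states for elapsed time t
.mk_P <- function(rate, k, t) {
  e <- exp(-k * rate * t / (k - 1))
  same <- 1 / k + (k - 1) / k * e
  diff <- 1 / k - e / k
  m <- matrix(diff, k, k)
  diag(m) <- same
  m
}

.mk_check <- function(tree, tip_states, states) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  if (sum(tree$edge.length) <= 0) stop("zero-length tree", call. = FALSE)
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss) > 0) {
    stop("tips without a state: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tip_states <- tip_states[tree$tip.label]
  if (is.null(states)) states <- sort(unique(unname(as.character(tip_states))))
  if (!all(tip_states %in% states)) stop("tip state outside state set",
                                         call. = FALSE)
  if (length(states) < 2) stop("need at least 2 states", call. = FALSE)
  list(tip_states = as.character(tip_states), states = states)
}

# Felsenstein pruning pass: conditional likelihoods of the data below
# each node given its state, with running log rescaling.
.mk_down <- function(tree, tip_states, states, rate) {
  k <- length(states)
  ntip <- length(tree$tip.label)
  L <- matrix(1, ntip + tree$Nnode, k)
  L[seq_len(ntip), ] <- 0
  L[cbind(seq_len(ntip), match(tip_states, states))] <- 1
  po <- stats::reorder(tree, "postorder")
  logscale <- 0
  msg <- vector("list", nrow(po$edge))  # P_e %*% L[child] per edge
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1]; ch <- po$edge[i, 2]
    P <- .mk_P(rate, k, po$edge.length[i])
    m <- as.vector(P %*% L[ch, ])
    msg[[i]] <- m
    L[par, ] <- L[par, ] * m
    mx <- max(L[par, ])
    if (mx > 0 && mx < 1e-200) {
      # defer rescale until the row is complete enough; simple guard
      L[par, ] <- L[par, ] / mx
      logscale <- logscale + log(mx)
    }
  }
  root <- ntip + 1L
  mx <- max(L[root, ])
  list(L = L, logscale = logscale, po = po, root = root, k = k,
       loglik = log(sum(L[root, ] / k)) + logscale, msg = msg)
}

#' Mk-model log-likelihood of a discrete character
#'
#' Felsenstein pruning under the equal-rates (ER) Mk model with a uniform
#' root prior: every transition between distinct states occurs at rate
#' `rate / (k - 1)`, so `rate` is the total rate of leaving any state.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param tip_states Named character vector, one state per tip (evoregion
#'   labels and possibly `"WIDESPREAD"`).
#' @param rate Positive total transition rate.
#' @param states Optional state set (default: sorted unique tip states);
#'   supply explicitly when some state is absent from the tips.
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, rate, states = NULL) {
  stopifnot(rate > 0)
  chk <- .mk_check(tree, tip_states, states)
  .mk_down(tree, chk$tip_states, chk$states, rate)$loglik
}

#' Maximum-likelihood ER transition rate
#'
#' Bounded one-dimensional optimisation of [mk_loglik()] on the log-rate
#' scale over `interval` (default `[1e-6, 1e3]`), tolerance 1e-8. When
#' all tips share one state the rate is pinned to the lower bound with a
#' warning.
#'
#' @inheritParams mk_loglik
#' @param interval Rate search bounds.
#' @return Fitted rate (scalar).
#' @export
fit_mk_rate <- function(tree, tip_states, states = NULL,
                        interval = c(1e-6, 1e3)) {
  chk <- .mk_check(tree, tip_states, states)
  if (length(unique(chk$tip_states)) < 2) {
    warning("all tip states identical; rate pinned to the lower bound")
    return(interval[1])
  }
  opt <- stats::optimize(
    function(lr) mk_loglik(tree, tip_states, exp(lr), states = chk$states),
    interval = log(interval), maximum = TRUE, tol = 1e-8
  )
  exp(opt$maximum)
}

#' Marginal ancestral state posteriors under the ER Mk model
#'
#' Exact marginal posterior probability of each state at every internal
#' node, from a down (pruning) pass combined with an up pass carrying the
#' information outside each subtree; uniform root prior.
#'
#' @inheritParams mk_loglik
#' @return Matrix internal nodes x states (rownames are ape node numbers,
#'   root first); each row sums to 1.
#' @export
mk_marginal <- function(tree, tip_states, rate, states = NULL) {
  stopifnot(rate > 0)
  chk <- .mk_check(tree, tip_states, states)
  dn <- .mk_down(tree, chk$tip_states, chk$states, rate)
  k <- dn$k
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  po <- dn$po
  ne <- nrow(po$edge)
  G <- matrix(0, ntip + nn, k)
  G[dn$root, ] <- 1 / k
  edges_of_parent <- split(seq_len(ne), po$edge[, 1])
  for (i in rev(seq_len(ne))) {  # reverse postorder: parents before children
    par <- po$edge[i, 1]; ch <- po$edge[i, 2]
    E <- G[par, ]
    for (j in edges_of_parent[[as.character(par)]]) {
      if (j != i) E <- E * dn$msg[[j]]
    }
    P <- .mk_P(rate, k, po$edge.length[i])
    g <- as.vector(crossprod(P, E))
    G[ch, ] <- g / sum(g)
  }
  marg <- G * dn$L
  marg <- marg / rowSums(marg)
  nodes <- ntip + seq_len(nn)
  out <- marg[nodes, , drop = FALSE]
  dimnames(out) <- list(nodes, chk$states)
  out
}

# One edge history conditional on endpoint states: rejection sampling of
# the ER chain capped at `max_tries`, then uniformization. For the ER
# model the uniformized jump chain has zero self-transition probability,
# so every sampled jump is a real state change.
.mk_edge_history <- function(a, b, t, rate, k, max_tries = 1000) {
  if (t <= 0) {
    return(list(states = a, lengths = 0))
  }
  for (try in seq_len(max_tries)) {
    s <- a
    jumps_t <- numeric(0)
    jumps_s <- integer(0)
    tau <- stats::rexp(1, rate)
    while (tau < t) {
      cand <- seq_len(k)[-s]
      s <- if (length(cand) == 1) cand else sample(cand, 1)
      jumps_t <- c(jumps_t, tau)
      jumps_s <- c(jumps_s, s)
      tau <- tau + stats::rexp(1, rate)
    }
    if (s == b) {
      return(list(states = c(a, jumps_s),
                  lengths = diff(c(0, jumps_t, t))))
    }
  }
  # uniformization fallback: sample the number of (real) jumps given the
  # endpoints, then the intermediate states of the jump chain
  R <- matrix(1 / (k - 1), k, k); diag(R) <- 0
  lam <- rate * t
  nmax <- max(20, ceiling(lam + 10 * sqrt(lam) + 20))
  Rpow <- vector("list", nmax + 1)
  Rpow[[1]] <- diag(k)
  for (n in seq_len(nmax)) Rpow[[n + 1]] <- Rpow[[n]] %*% R
  pn <- vapply(0:nmax, function(n) {
    stats::dpois(n, lam) * Rpow[[n + 1]][a, b]
  }, 0)
  n_jumps <- sample(0:nmax, 1, prob = pn)
  if (n_jumps == 0) return(list(states = a, lengths = t))
  states <- integer(n_jumps + 1)
  states[1] <- a
  states[n_jumps + 1] <- b
  if (n_jumps > 1) {
    for (j in 2:n_jumps) {
      w <- R[states[j - 1], ] * Rpow[[n_jumps - j + 2]][, b]
      states[j] <- sample(seq_len(k), 1, prob = w)
    }
  }
  jumps_t <- sort(stats::runif(n_jumps, 0, t))
  list(states = states, lengths = diff(c(0, jumps_t, t)))
}

#' Stochastic character maps of evoregion history
#'
#' Samples full histories of a discrete character along the tree under
#' the ER Mk model, conditional on the tip states: node states are drawn
#' from their joint conditional distribution (root from its posterior,
#' then each child given its parent), and each edge is filled with a
#' history conditioned on its endpoints by rejection sampling with a
#' uniformization fallback. Node posteriors are the per-node state
#' frequencies across maps.
#'
#' @inheritParams mk_loglik
#' @param rate Transition rate; fitted by [fit_mk_rate()] when `NULL`.
#' @param n_maps Number of sampled maps (default 100).
#' @param seed Integer seed; identical seeds give identical maps.
#' @return An `mk_simmap` object: `node_posteriors` (internal nodes x
#'   states), `maps` (per map, a list over tree edges of
#'   `list(states, lengths)` from parent to child), `node_states`
#'   (maps x nodes sampled states), `n_changes` per map, `rate`,
#'   `states`, `edge` (the tree's edge matrix).
#' @export
mk_simmap <- function(tree, tip_states, rate = NULL, n_maps = 100, seed = 0,
                      states = NULL) {
  chk <- .mk_check(tree, tip_states, states)
  if (is.null(rate)) rate <- fit_mk_rate(tree, tip_states, states = chk$states)
  stopifnot(rate > 0, n_maps >= 1)
  set.seed(seed)
  dn <- .mk_down(tree, chk$tip_states, chk$states, rate)
  k <- dn$k
  ntip <- length(tree$tip.label)
  nnode_all <- ntip + tree$Nnode
  po <- dn$po
  ne <- nrow(po$edge)
  Pe <- lapply(seq_len(ne), function(i) .mk_P(rate, k, po$edge.length[i]))
  root_w <- dn$L[dn$root, ] / k

  node_states <- matrix(0L, n_maps, nnode_all)
  n_changes <- integer(n_maps)
  maps <- vector("list", n_maps)
  edge_order <- rev(seq_len(ne))  # preorder: parent sampled before child
  for (m in seq_len(n_maps)) {
    ns <- integer(nnode_all)
    ns[dn$root] <- sample.int(k, 1, prob = root_w)
    hist_m <- vector("list", ne)
    for (i in edge_order) {
      par <- po$edge[i, 1]; ch <- po$edge[i, 2]
      w <- Pe[[i]][ns[par], ] * dn$L[ch, ]
      ns[ch] <- sample.int(k, 1, prob = w)
    }
    for (i in seq_len(ne)) {
      h <- .mk_edge_history(ns[po$edge[i, 1]], ns[po$edge[i, 2]],
                            po$edge.length[i], rate, k)
      hist_m[[i]] <- list(states = chk$states[h$states], lengths = h$lengths)
      n_changes[m] <- n_changes[m] + length(h$lengths) - 1L
    }
    node_states[m, ] <- ns
    maps[[m]] <- hist_m
  }
  internal <- ntip + seq_len(tree$Nnode)
  postr <- t(apply(node_states[, internal, drop = FALSE], 2, function(col) {
    tabulate(col, nbins = k) / n_maps
  }))
  dimnames(postr) <- list(internal, chk$states)
  structure(
    list(node_posteriors = postr, maps = maps,
         node_states = matrix(chk$states[node_states], n_maps, nnode_all),
         n_changes = n_changes, rate = rate, states = chk$states,
         edge = po$edge, edge_length = po$edge.length, n_maps = n_maps),
    class = "mk_simmap"
  )
}

#' @export
print.mk_simmap <- function(x, ...) {
  cat("stochastic character maps:", x$n_maps, "maps over",
      length(x$states), "states; rate =", signif(x$rate, 4),
      "; mean changes per map =", round(mean(x$n_changes), 2), "\n")
  invisible(x)
}

#' Prune a tree to the tips with a known character state
#'
#' Tips absent from `tip_states` (e.g. species in the phylogeny but not
#' on the grid) are dropped, with a message listing them.
#'
#' @param tree A `phylo` tree.
#' @param tip_states Named vector of states.
#' @return The pruned tree.
#' @export
prune_to_states <- function(tree, tip_states) {
  drop <- setdiff(tree$tip.label, names(tip_states))
  if (length(drop) > 0) {
    message("pruning ", length(drop), " tips without states: ",
            paste(utils::head(drop, 10), collapse = ", "),
            if (length(drop) > 10) " ..." else "")
    tree <- ape::drop.tip(tree, drop)
  }
  tree
}
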