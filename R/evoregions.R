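#' Choose the number of clusters by the elbow rule
#'
#' Computes the best-of-restarts k-means total within-cluster sum of
#' squares for k = 1..k_max, min-max normalises both axes of the (k, WSS)
#' curve, and returns the k whose point lies farthest (perpendicular
#' distance) from the chord joining the curve's endpoints. Ties go to the
#' smaller k; a degenerate input (all rows identical) returns 1.
#'
#' @param x Numeric matrix, observations in rows.
#' @param k_max Largest k examined (default 10; capped at the number of
#'   distinct rows).
#' @param restarts Random restarts per k (default 20).
#' @param seed Integer seed.
#' @return Integer k.
#' @export
elbow_k <- function(x, k_max = 10, restarts = 20, seed = 0) {
  x <- as.matrix(x)
  stopifnot(k_max >= 2)
  m <- nrow(unique(x))
  if (m == 1) return(1L)
  k_hi <- min(k_max, m)
  wss <- numeric(k_hi)
  wss[1] <- sum(sweep(x, 2, colMeans(x))^2)
  for (k in 2:k_hi) {
    wss[k] <- kmeans_wss(x, k, restarts = restarts, seed = seed)
  }
  wss <- cummin(wss)  # guard against restart noise; WSS is nonincreasing
  if (k_hi < 3 || wss[1] - wss[k_hi] <= 0) {
    return(if (wss[1] <= 0) 1L else k_hi)
  }
  kk <- (seq_len(k_hi) - 1) / (k_hi - 1)
  ww <- (wss - wss[k_hi]) / (wss[1] - wss[k_hi])
  # distance from (kk, ww) to the chord (0,1)-(1,0)
  dist <- abs(kk + ww - 1) / sqrt(2)
  as.integer(which.max(dist))  # which.max takes the first (smallest k) tie
}

# best-of-restarts k-means WSS (internal)
kmeans_wss <- function(x, k, restarts = 20, seed = 0) {
  set.seed(seed + 1000L * k)
  stats::kmeans(x, centers = k, nstart = restarts,
                iter.max = 100)$tot.withinss
}

#' Seeded best-of-restarts k-means partition
#'
#' @param x Numeric matrix, observations in rows.
#' @param k Number of clusters.
#' @param restarts Random restarts (default 20; the lowest-WSS run wins).
#' @param seed Integer seed; identical seeds give identical labels.
#' @return Integer cluster labels named by rownames of `x`.
#' @export
kmeans_cluster <- function(x, k, restarts = 20, seed = 0) {
  x <- as.matrix(x)
  stopifnot(k >= 1)
  m <- nrow(unique(x))
  if (k > m) stop("k exceeds the number of distinct rows", call. = FALSE)
  if (k == 1) {
    lab <- rep(1L, nrow(x))
    names(lab) <- rownames(x)
    return(lab)
  }
  set.seed(seed + 1000L * k)
  fit <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100)
  lab <- fit$cluster
  names(lab) <- rownames(x)
  lab
}

#' Refine a clustering by discriminant analysis of principal components
#'
#' PCA-reduces the ordination scores, fits a linear (shared-covariance
#' Gaussian) discriminant on the initial cluster labels, and returns each
#' cell's posterior probability over groups together with the argmax
#' label. Groups are renamed A, B, ... by descending assigned cell count.
#' The number of retained components defaults to the smallest number
#' explaining at least 90 percent of variance, capped at one third of the
#' number of cells. A singular pooled within-group covariance is ridged
#' by 1e-8 on the diagonal with a warning.
#'
#' @param x Numeric matrix of ordination scores, cells in rows.
#' @param initial_labels Cluster labels (coercible to factor) per row.
#' @param n_pca Number of principal components to keep, or `NULL` for the
#'   default rule.
#' @return An `evoregions` object: `cell_ids`, `labels` (letters, named by
#'   cell), `k`, `posterior` (cells x groups, rows sum to 1), `n_pca`.
#' @export
dapc_assign <- function(x, initial_labels, n_pca = NULL) {
  x <- as.matrix(x)
  grp <- factor(initial_labels)
  stopifnot(nrow(x) == length(grp), nlevels(grp) >= 2)
  if (any(table(grp) < 2)) {
    warning("groups with fewer than 2 members; discriminant may be unstable")
  }
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (is.null(n_pca)) {
    relvar <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
    n_pca <- which(relvar >= 0.9)[1]
    n_pca <- min(n_pca, max(1L, floor(nrow(x) / 3)))
  }
  n_pca <- min(n_pca, ncol(pca$x))
  s <- pca$x[, seq_len(n_pca), drop = FALSE]

  n <- nrow(s); G <- nlevels(grp); p <- ncol(s)
  mu <- matrix(0, G, p)
  W <- matrix(0, p, p)
  for (gi in seq_len(G)) {
    rows <- s[grp == levels(grp)[gi], , drop = FALSE]
    mu[gi, ] <- colMeans(rows)
    cc <- sweep(rows, 2, mu[gi, ])
    W <- W + crossprod(cc)
  }
  W <- W / max(n - G, 1)
  Winv <- tryCatch(
    solve(W),
    error = function(e) {
      warning("singular within-group covariance; adding 1e-8 ridge")
      solve(W + diag(1e-8, p))
    }
  )
  prior <- as.numeric(table(grp)) / n
  # log posterior up to a constant: log pi_g - Mahalanobis/2
  ll <- matrix(0, n, G)
  for (gi in seq_len(G)) {
    cc <- sweep(s, 2, mu[gi, ])
    ll[, gi] <- log(prior[gi]) - 0.5 * rowSums((cc %*% Winv) * cc)
  }
  ll <- ll - apply(ll, 1, max)
  post <- exp(ll)
  post <- post / rowSums(post)

  hard <- max.col(post, ties.method = "first")
  counts <- tabulate(hard, nbins = G)
  # rename by descending cell count; ties broken by the lexicographically
  # smallest member cell id so labelling is invariant to row order
  first_cell <- vapply(seq_len(G), function(gi) {
    cells <- rownames(x)[hard == gi]
    if (length(cells) == 0) "" else min(cells)
  }, "")
  ord <- order(-counts, first_cell)
  post <- post[, ord, drop = FALSE]
  colnames(post) <- LETTERS[seq_len(G)]
  rownames(post) <- rownames(x)
  labels <- colnames(post)[max.col(post, ties.method = "first")]
  names(labels) <- rownames(x)
  structure(
    list(cell_ids = rownames(x), labels = labels, k = G, posterior = post,
         n_pca = n_pca, provenance = list()),
    class = "evoregions"
  )
}

#' Classify grid cells into evoregions
#'
#' Full classification pipeline on a phylogeny-weighted composition
#' matrix: square-rooted Bray-Curtis dissimilarities, PCoA with the
#' strict >`var_threshold` axis-selection rule, elbow choice of k,
#' best-of-restarts k-means, and DAPC refinement. A composition in which
#' all cells are (numerically) identical yields the degenerate single
#' evoregion without error.
#'
#' @param p Composition matrix from [phylo_composition()].
#' @param var_threshold Relative-variance cutoff for axis selection.
#' @param k_max Largest k examined by the elbow rule.
#' @param restarts k-means restarts.
#' @param seed Integer seed threaded through every stochastic stage.
#' @return An `evoregions` object; `$provenance` records k, eigenvalues,
#'   the selected axes and the seed, and `$dissimilarity` holds the
#'   cell dissimilarity matrix for downstream affiliation.
#' @export
classify_evoregions <- function(p, var_threshold = 0.05, k_max = 10,
                                restarts = 20, seed = 0) {
  p <- as.matrix(p)
  d <- sqrt_bray_curtis(p)
  if (max(d) < 1e-12) {
    labels <- rep("A", nrow(p))
    names(labels) <- rownames(p)
    post <- matrix(1, nrow(p), 1, dimnames = list(rownames(p), "A"))
    res <- structure(
      list(cell_ids = rownames(p), labels = labels, k = 1L, posterior = post,
           n_pca = 0L,
           provenance = list(k = 1L, degenerate = TRUE, seed = seed)),
      class = "evoregions"
    )
    res$dissimilarity <- d
    return(res)
  }
  ord <- pcps(d, var_threshold = var_threshold)
  sel <- ord$selected
  if (length(sel) == 0) sel <- 1L  # fall back to the leading gradient
  # standardize the retained axes so every selected turnover gradient
  # carries equal weight in the clustering
  x <- scale(ord$axes[, sel, drop = FALSE])
  k <- elbow_k(x, k_max = min(k_max, nrow(x) - 1), restarts = restarts,
               seed = seed)
  if (k == 1) {
    labels <- rep("A", nrow(p))
    names(labels) <- rownames(p)
    post <- matrix(1, nrow(p), 1, dimnames = list(rownames(p), "A"))
    res <- structure(
      list(cell_ids = rownames(p), labels = labels, k = 1L, posterior = post,
           n_pca = 0L, provenance = list()),
      class = "evoregions"
    )
  } else {
    init <- kmeans_cluster(x, k, restarts = restarts, seed = seed)
    res <- dapc_assign(x, init)
  }
  res$provenance <- list(
    k = res$k, eigenvalues = ord$eigenvalues,
    relative_variance = ord$relative_variance, selected_axes = sel,
    var_threshold = var_threshold, k_max = k_max, restarts = restarts,
    seed = seed
  )
  res$dissimilarity <- d
  res
}

#' @export
print.evoregions <- function(x, ...) {
  cat("evoregion classification:", length(x$cell_ids), "cells in", x$k,
      "evoregions\n")
  print(table(x$labels))
  invisible(x)
}

# labels as a named character vector, from an evoregions object or a
# named vector
.region_labels <- function(x) {
  if (inherits(x, "evoregions")) {
    x$labels
  } else {
    stopifnot(!is.null(names(x)))
    stats::setNames(as.character(x), names(x))
  }
}
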