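#' Phylogenetic similarity between species
#'
#' Converts a patristic distance matrix into a similarity used by the
#' fuzzy-weighting transform. The default linear kernel is
#' `s = 1 - d / max(d)`: unit self-similarity, zero for the most distant
#' pair. An exponential-decay kernel `exp(-rate * d)` is available as an
#' alternative.
#'
#' @param d Symmetric patristic distance matrix with zero diagonal.
#' @param kernel `"linear"` (default) or `"exponential"`.
#' @param rate Decay rate for the exponential kernel.
#' @return Symmetric similarity matrix with unit diagonal, entries in
#'   `[0, 1]`.
#' @export
phylo_similarity <- function(d, kernel = c("linear", "exponential"),
                             rate = 1) {
  kernel <- match.arg(kernel)
  d <- as.matrix(d)
  stopifnot(isTRUE(all.equal(d, t(d))), all(diag(d) == 0))
  if (kernel == "linear") {
    dmax <- max(d)
    if (dmax <= 0) {
      stop("all pairwise distances are zero; species are indistinguishable",
           call. = FALSE)
    }
    s <- 1 - d / dmax
  } else {
    s <- exp(-rate * d)
  }
  dimnames(s) <- dimnames(d)
  s
}

#' Fuzzy phylogenetic membership matrix (species x species)
#'
#' Standardizes a similarity matrix by its column totals so that column j
#' describes the degree of membership of every species in species j's
#' phylogenetic neighbourhood: entries are nonnegative, each column sums
#' to 1, and the diagonal entry is each column's maximum.
#'
#' @param s Similarity matrix from [phylo_similarity()].
#' @return Column-standardized membership matrix.
#' @export
fuzzy_membership <- function(s) {
  s <- as.matrix(s)
  cs <- colSums(s)
  if (any(cs <= 0)) stop("zero column sum in similarity matrix", call. = FALSE)
  sweep(s, 2, cs, "/")
}

#' Phylogeny-weighted assemblage composition (cells x species)
#'
#' Multiplies the presence/absence matrix by the fuzzy membership matrix,
#' spreading each occurrence over the phylogenetic neighbourhood of the
#' occurring species, then standardizes rows to unit sum so each row is
#' the phylogenetically weighted composition of one cell's assemblage
#' (entries in `[0, 1]`).
#'
#' @param g An `occurrence_grid` (or a bare binary cells x species matrix).
#' @param q Membership matrix from [fuzzy_membership()], species order
#'   matching the grid columns.
#' @return Row-standardized composition matrix.
#' @export
phylo_composition <- function(g, q) {
  pres <- if (inherits(g, "occurrence_grid")) g$presence else as.matrix(g)
  q <- as.matrix(q)
  if (!identical(colnames(pres), rownames(q))) {
    stop("species order of grid and membership matrix differ; ",
         "run align_to_tree() first", call. = FALSE)
  }
  raw <- pres %*% q
  rs <- rowSums(raw)
  if (any(rs <= 0)) {
    stop("empty cell rows; run drop_empty_cells() first", call. = FALSE)
  }
  sweep(raw, 1, rs, "/")
}

#' Square-rooted Bray-Curtis dissimilarities between cells
#'
#' Bray-Curtis dissimilarity of the composition rows, square-rooted
#' elementwise so that the subsequent principal coordinates analysis does
#' not produce (appreciably) negative eigenvalues.
#'
#' @param p Composition matrix from [phylo_composition()] (nonnegative
#'   rows).
#' @return Symmetric cells x cells matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
sqrt_bray_curtis <- function(p) {
  p <- as.matrix(p)
  stopifnot(all(p >= 0))
  d <- sqrt(as.matrix(vegan::vegdist(p, method = "bray")))
  dimnames(d) <- list(rownames(p), rownames(p))
  d
}

#' Principal coordinates of phylogenetic structure
#'
#' Classical scaling (PCoA) of a dissimilarity matrix: double-centering of
#' `-d^2/2`, eigendecomposition, axes scaled by the square root of their
#' eigenvalues. Axes on negative eigenvalues are dropped (with a warning
#' when any eigenvalue falls below -1e-10); relative variance is computed
#' over the retained positive eigenvalues, and the axes whose relative
#' variance strictly exceeds `var_threshold` are marked as selected.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param var_threshold Strict relative-variance cutoff for axis selection
#'   (default 0.05, i.e. more than 5 percent of explained variance).
#' @return A `pcps` object: `axes` (cells x n_positive), `eigenvalues`
#'   (positive, nonincreasing), `relative_variance`, `selected` (axis
#'   indices), `all_eigenvalues` (full spectrum including any negatives).
#' @export
pcps <- function(d, var_threshold = 0.05) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 2, isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
  d2 <- d^2
  ctr <- function(m) sweep(m, 1, rowMeans(m), "-")
  b <- -0.5 * t(ctr(t(ctr(d2))))
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -1e-10)) {
    warning(sprintf("dropping %d negative eigenvalues (most negative %.3g)",
                    sum(vals < -1e-10), min(vals)))
  }
  tol <- max(abs(vals)) * 1e-12
  pos <- which(vals > tol)
  if (length(pos) == 0) {
    stop("no positive eigenvalue: configuration is degenerate", call. = FALSE)
  }
  axes <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]),
                                                  length(pos))
  rownames(axes) <- rownames(d)
  colnames(axes) <- paste0("pcps", seq_along(pos))
  rel <- vals[pos] / sum(vals[pos])
  structure(
    list(axes = axes, eigenvalues = vals[pos], relative_variance = rel,
         selected = which(rel > var_threshold), all_eigenvalues = vals,
         var_threshold = var_threshold),
    class = "pcps"
  )
}

#' @export
print.pcps <- function(x, ...) {
  cat("PCoA of phylogenetic composition:", nrow(x$axes), "cells,",
      length(x$eigenvalues), "positive axes;",
      length(x$selected), "axes above", x$var_threshold * 100,
      "% relative variance\n")
  invisible(x)
}
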