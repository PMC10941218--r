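#' Overlap table between two regionalizations
#'
#' Cross-tabulates the labels of two regionalizations over their shared
#' cells. Weights are shared-cell counts by default, or cell areas
#' (cosine-latitude approximation) when `weight = "area"`.
#'
#' @param a,b `evoregions` objects or named label vectors (names are cell
#'   ids).
#' @param weight `"count"` (default) or `"area"`.
#' @param cell_areas Named numeric vector of cell areas, required for
#'   `weight = "area"`.
#' @return An `overlap_table`: `weights` (regions of `a` x regions of
#'   `b`), `total`, `n_shared`, `dropped_a`, `dropped_b`.
#' @export
build_overlap <- function(a, b, weight = c("count", "area"),
                          cell_areas = NULL) {
  weight <- match.arg(weight)
  la <- .region_labels(a)
  lb <- .region_labels(b)
  shared <- intersect(names(la), names(lb))
  if (length(shared) == 0) stop("no shared cells", call. = FALSE)
  w <- if (weight == "count") {
    rep(1, length(shared))
  } else {
    stopifnot(!is.null(cell_areas), all(shared %in% names(cell_areas)))
    as.numeric(cell_areas[shared])
  }
  fa <- factor(la[shared])
  fb <- factor(lb[shared])
  weights <- matrix(0, nlevels(fa), nlevels(fb),
                    dimnames = list(levels(fa), levels(fb)))
  for (i in seq_along(shared)) {
    weights[fa[i], fb[i]] <- weights[fa[i], fb[i]] + w[i]
  }
  structure(
    list(weights = weights, total = sum(weights), n_shared = length(shared),
         dropped_a = length(la) - length(shared),
         dropped_b = length(lb) - length(shared)),
    class = "overlap_table"
  )
}

#' V-measure congruence between two regionalizations
#'
#' Entropy-based association between the row and column partitions of an
#' overlap table, in natural logarithms. Homogeneity is
#' `1 - H(rows | cols) / H(rows)` (1 when the row partition carries no
#' entropy), completeness is the transpose, and V is their harmonic mean
#' (0 when both are 0). V is invariant to label permutations and to
#' swapping the two maps; swapping exchanges homogeneity and
#' completeness.
#'
#' @param o An `overlap_table` from [build_overlap()].
#' @return A `v_measure` object: `v`, `homogeneity`, `completeness`,
#'   `overlap`.
#' @export
v_measure <- function(o) {
  stopifnot(inherits(o, "overlap_table"))
  if (o$total <= 0) stop("zero total weight", call. = FALSE)
  p <- o$weights / o$total
  pr <- rowSums(p)
  pc <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  HR <- ent(pr)
  HC <- ent(pc)
  cond <- function(p, marg_cols) {
    # H(rows | cols): -sum_ij p_ij log(p_ij / p_.j)
    tot <- 0
    for (j in seq_along(marg_cols)) {
      col <- p[, j]
      col <- col[col > 0]
      if (length(col) > 0) tot <- tot - sum(col * log(col / marg_cols[j]))
    }
    tot
  }
  HRgZ <- cond(p, pc)
  HZgR <- cond(t(p), pr)
  h <- if (HR == 0) 1 else 1 - HRgZ / HR
  cm <- if (HC == 0) 1 else 1 - HZgR / HC
  v <- if (h + cm == 0) 0 else 2 * h * cm / (h + cm)
  structure(list(v = v, homogeneity = h, completeness = cm, overlap = o),
            class = "v_measure")
}

#' @export
print.v_measure <- function(x, ...) {
  cat(sprintf("V-measure = %.3f (homogeneity %.3f, completeness %.3f) over %d shared cells\n",
              x$v, x$homogeneity, x$completeness, x$overlap$n_shared))
  invisible(x)
}
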