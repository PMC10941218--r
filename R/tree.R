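#' Read a single Newick tree
#'
#' Parses a Newick string (or file) into an [ape::phylo] object. Quoted
#' labels are accepted and square-bracket comments are stripped before
#' parsing. Branch lengths are optional; when the string carries none the
#' returned tree has no `edge.length` component (lengths are absent, not
#' zero).
#'
#' @param text Newick string (must end in `;`). Ignored when `file` is given.
#' @param file Path to a file holding one Newick tree.
#' @return A rooted `phylo` tree.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- gsub("\\[[^]]*\\]", "", text)  # strip comments
  .check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick string", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate tip names: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  tree
}

# Cheap structural validation so errors carry a character offset; quoted
# labels containing parentheses are not supported by this pre-check.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  last_open <- NA_integer_
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      depth <- depth + 1L
      last_open <- i
    } else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("Newick parse error at character %d: unmatched ')'", i),
             call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop(sprintf("Newick parse error at character %d: unclosed '('", last_open),
         call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop(sprintf("Newick parse error at character %d: missing ';'",
                 nchar(text)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Assign unit length to every branch
#'
#' Used when a topology (e.g. a supertree assembled from taxonomy) carries
#' no meaningful branch-length information: every edge, terminal or
#' internal, is set to 1. Idempotent.
#'
#' @param tree A `phylo` tree.
#' @return The tree with all edge lengths equal to 1.
#' @export
set_unit_branch_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Make a tree ultrametric by extending terminal branches
#'
#' Each terminal edge is lengthened by (maximum tip depth - tip depth) so
#' that every tip reaches the depth of the deepest tip. Internal edges are
#' untouched; a tree that is already ultrametric is returned unchanged.
#'
#' @param tree A `phylo` tree with all edge lengths present and >= 0.
#' @return An ultrametric `phylo` tree.
#' @export
ultrametrize_extend <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; assign lengths first", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  tip_depth <- depth[seq_len(ntip)]
  term_edge <- match(seq_len(ntip), tree$edge[, 2])
  tree$edge.length[term_edge] <-
    tree$edge.length[term_edge] + (max(tip_depth) - tip_depth)
  tree
}

#' Resolve polytomies into random binary ladders
#'
#' Multifurcations are replaced by randomly ordered ladders of binary
#' nodes (via [ape::multi2di]); the inserted internal edges receive a
#' small strictly positive length `epsilon` so downstream distance and
#' likelihood machinery never sees zero-length edges. Every clade of the
#' original tree remains a clade of the resolved tree, and total tip
#' depths change by at most `epsilon` times the largest polytomy size.
#'
#' @param tree A rooted `phylo` tree.
#' @param seed Integer seed controlling the random resolution (default 0).
#' @param epsilon Length given to inserted edges (default 1e-6, negligible
#'   against unit branches yet strictly positive).
#' @return A binary `phylo` tree.
#' @export
resolve_polytomies <- function(tree, seed = 0, epsilon = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::is.binary(tree)) return(tree)
  set.seed(seed)
  res <- ape::multi2di(tree, random = TRUE)
  if (!is.null(res$edge.length)) {
    # edges created by the resolution come out with length 0; any
    # pre-existing zero-length internal edge is raised too
    ntip <- length(res$tip.label)
    zero_internal <- res$edge[, 2] > ntip & res$edge.length == 0
    res$edge.length[zero_internal] <- epsilon
  }
  res
}

#' Pairwise patristic distances between tips
#'
#' Sum of branch lengths along the path between every pair of tips. For an
#' ultrametric tree this equals twice the depth below the pair's most
#' recent common ancestor.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Symmetric species x species matrix, zero diagonal, rows and
#'   columns in `tree$tip.label` order.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  d <- as.matrix(stats::cophenetic(tree))
  d[tree$tip.label, tree$tip.label]
}

#' Standard tree preprocessing for regionalization
#'
#' Convenience composite: unit branch lengths (optional), terminal-edge
#' ultrametrization, and random polytomy resolution, in that order. The
#' steps are also exported individually so either order of unit-length
#' assignment and ultrametrization can be run explicitly.
#'
#' @param tree A `phylo` tree.
#' @param unit_lengths Replace all branch lengths by 1 first?
#' @param ultrametrize Extend terminal edges to a common depth?
#' @param resolve Resolve polytomies to binary?
#' @param seed Seed for the polytomy resolution.
#' @return A processed `phylo` tree.
#' @export
prepare_tree <- function(tree, unit_lengths = TRUE, ultrametrize = TRUE,
                         resolve = TRUE, seed = 0) {
  if (unit_lengths) tree <- set_unit_branch_lengths(tree)
  if (resolve) tree <- resolve_polytomies(tree, seed = seed)
  if (ultrametrize) tree <- ultrametrize_extend(tree)
  tree
}
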