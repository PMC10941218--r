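#' Per-cell affiliation with its evoregion
#'
#' Affiliation of a cell is 1 minus the mean dissimilarity between that
#' cell and all other cells of the same evoregion, so high affiliation
#' means low phylogenetic turnover within the region. A cell that is the
#' sole member of its evoregion has affiliation 1 (no peers). Cells whose
#' affiliation falls strictly below the within-region quantile
#' (`transition_quantile`, default the lower quartile) are flagged as
#' transition candidates.
#'
#' @param d Cell dissimilarity matrix (the square-rooted Bray-Curtis
#'   matrix used for the ordination; entries in `[0, 1]`).
#' @param regions An `evoregions` object or named label vector.
#' @param transition_quantile Within-region quantile below which a cell is
#'   flagged (default 0.25).
#' @return An `evoregion_affiliation` object whose `$table` holds
#'   `cell_id`, `evoregion`, `affiliation`, `transition`.
#' @export
cell_affiliation <- function(d, regions, transition_quantile = 0.25) {
  labels <- .region_labels(regions)
  d <- as.matrix(d)
  cells <- names(labels)
  stopifnot(all(cells %in% rownames(d)))
  d <- d[cells, cells, drop = FALSE]
  n <- length(cells)
  aff <- numeric(n)
  for (i in seq_len(n)) {
    mates <- which(labels == labels[i])
    mates <- mates[mates != i]
    aff[i] <- if (length(mates) == 0) 1 else 1 - mean(d[i, mates])
  }
  flag <- logical(n)
  for (g in unique(labels)) {
    idx <- which(labels == g)
    q <- stats::quantile(aff[idx], transition_quantile, names = FALSE)
    flag[idx] <- aff[idx] < q
  }
  structure(
    list(table = data.frame(cell_id = cells, evoregion = unname(labels),
                            affiliation = aff, transition = flag,
                            stringsAsFactors = FALSE),
         transition_quantile = transition_quantile),
    class = "evoregion_affiliation"
  )
}

#' @export
print.evoregion_affiliation <- function(x, ...) {
  cat("cell affiliations:", nrow(x$table), "cells;",
      sum(x$table$transition), "transition-flagged\n")
  invisible(x)
}

# neighbours under 4-adjacency, keyed by cell_id; meta has cell_id,row,col
.grid_neighbours <- function(meta) {
  key <- paste(meta$row, meta$col)
  idx <- stats::setNames(seq_len(nrow(meta)), key)
  lapply(seq_len(nrow(meta)), function(i) {
    nb <- c(paste(meta$row[i] - 1, meta$col[i]),
            paste(meta$row[i] + 1, meta$col[i]),
            paste(meta$row[i], meta$col[i] - 1),
            paste(meta$row[i], meta$col[i] + 1))
    unname(idx[nb[nb %in% names(idx)]])
  })
}

#' Evolutionary transition zones
#'
#' Connected components (4-neighbour adjacency on the grid) of
#' transition-flagged cells. By default a flagged cell enters a zone only
#' if it is also adjacent to a cell of a different evoregion, so zones sit
#' at region boundaries; set `require_border = FALSE` to keep all flagged
#' cells. Each component is annotated with the evoregion labels of its
#' member cells and their neighbours.
#'
#' @param affiliation An `evoregion_affiliation` from [cell_affiliation()].
#' @param grid The `occurrence_grid` providing cell geometry (`cell_meta`
#'   with `row` and `col`).
#' @param require_border Restrict zones to cells bordering another
#'   evoregion (default TRUE)?
#' @return A list of zones, each `list(cells, labels, size)`, ordered by
#'   decreasing size; class `transition_zones`.
#' @export
transition_zones <- function(affiliation, grid, require_border = TRUE) {
  stopifnot(inherits(affiliation, "evoregion_affiliation"))
  tab <- affiliation$table
  meta <- if (inherits(grid, "occurrence_grid")) grid$cell_meta else grid
  stopifnot(!is.null(meta), all(c("row", "col") %in% names(meta)))
  meta <- meta[match(tab$cell_id, as.character(meta$cell_id)), , drop = FALSE]
  nbs <- .grid_neighbours(meta)
  cand <- which(tab$transition)
  if (require_border) {
    borders <- vapply(seq_len(nrow(tab)), function(i) {
      any(tab$evoregion[nbs[[i]]] != tab$evoregion[i])
    }, TRUE)
    cand <- cand[borders[cand]]
  }
  if (length(cand) == 0) {
    return(structure(list(), class = "transition_zones"))
  }
  in_cand <- seq_len(nrow(tab)) %in% cand
  edges <- do.call(rbind, lapply(cand, function(i) {
    nb <- nbs[[i]][in_cand[nbs[[i]]]]
    if (length(nb) == 0) NULL else cbind(i, nb)
  }))
  gr <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = character(0), to = character(0))
        else data.frame(from = as.character(edges[, 1]),
                        to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(cand))
  )
  comp <- igraph::components(gr)
  zones <- lapply(seq_len(comp$no), function(ci) {
    members <- as.integer(names(comp$membership)[comp$membership == ci])
    around <- unique(unlist(nbs[members]))
    list(cells = tab$cell_id[members],
         labels = sort(unique(tab$evoregion[c(members, around)])),
         size = length(members))
  })
  zones <- zones[order(vapply(zones, `[[`, 0L, "size"), decreasing = TRUE)]
  structure(zones, class = "transition_zones")
}

#' @export
print.transition_zones <- function(x, ...) {
  cat("transition zones:", length(x), "component(s)\n")
  for (i in seq_along(x)) {
    cat(sprintf("  zone %d: %d cells, borders %s\n", i, x[[i]]$size,
                paste(x[[i]]$labels, collapse = "/")))
  }
  invisible(x)
}

#' Associate species with evoregions
#'
#' A species is assigned to the evoregion holding at least `threshold`
#' (default 60 percent, inclusive) of its occupied cells; otherwise it is
#' classed as `WIDESPREAD`. When two regions tie for the species' modal
#' share, the species is widespread.
#'
#' @param g An `occurrence_grid`.
#' @param regions An `evoregions` object or named label vector over the
#'   same cells.
#' @param threshold Minimum modal share for assignment (default 0.60).
#' @return A data frame with `species`, `assignment` (evoregion label or
#'   `"WIDESPREAD"`), `fraction` (modal share), `n_cells`.
#' @export
species_association <- function(g, regions, threshold = 0.60) {
  pres <- if (inherits(g, "occurrence_grid")) g$presence else as.matrix(g)
  labels <- .region_labels(regions)
  stopifnot(all(rownames(pres) %in% names(labels)))
  labels <- labels[rownames(pres)]
  out <- lapply(colnames(pres), function(sp) {
    occ <- labels[pres[, sp] > 0]
    if (length(occ) == 0) stop("species with zero occupied cells: ", sp,
                               call. = FALSE)
    counts <- table(occ)
    frac <- max(counts) / length(occ)
    modal <- names(counts)[counts == max(counts)]
    assign <- if (length(modal) > 1 || frac < threshold) "WIDESPREAD"
              else modal
    data.frame(species = sp, assignment = assign, fraction = frac,
               n_cells = length(occ), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
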