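#' Define an equal-angle grid
#'
#' Tiles a longitude/latitude rectangle with square cells of
#' `cell_size` degrees. Cells are numbered row-major from the north-west
#' corner and are half-open (`[lon, lon + size)` by `[lat - size, lat)`),
#' so a point on a shared border belongs to exactly one cell. Cell areas
#' are reported in relative units of `degree^2 * cos(mid latitude)`.
#'
#' @param lon_range Length-2 numeric, western and eastern bounds.
#' @param lat_range Length-2 numeric, southern and northern bounds.
#' @param cell_size Cell side in degrees (default 2).
#' @return A `grid_spec` object with a `cells` data frame
#'   (cell_id, row, col, lon_min, lon_max, lat_min, lat_max, area).
#' @export
grid_spec <- function(lon_range = c(-180, 180), lat_range = c(-90, 90),
                      cell_size = 2) {
  stopifnot(cell_size > 0, lon_range[2] > lon_range[1],
            lat_range[2] > lat_range[1])
  n_cols <- as.integer(round(diff(lon_range) / cell_size))
  n_rows <- as.integer(round(diff(lat_range) / cell_size))
  stopifnot(n_cols >= 1, n_rows >= 1)
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  lat_max <- lat_range[2] - (row - 1) * cell_size
  lon_min <- lon_range[1] + (col - 1) * cell_size
  cells <- data.frame(
    cell_id = (row - 1L) * n_cols + col,
    row = row, col = col,
    lon_min = lon_min, lon_max = lon_min + cell_size,
    lat_min = lat_max - cell_size, lat_max = lat_max
  )
  cells$area <- cell_size^2 *
    cos((cells$lat_min + cells$lat_max) / 2 * pi / 180)
  structure(
    list(cell_size = cell_size, lon_range = lon_range, lat_range = lat_range,
         n_rows = n_rows, n_cols = n_cols, cells = cells),
    class = "grid_spec"
  )
}

#' Build an occurrence grid from a presence/absence matrix
#'
#' @param presence Binary matrix, cells in rows (rownames = cell ids) and
#'   species in columns (colnames = species names).
#' @param grid Optional [grid_spec()] providing cell geometry.
#' @param cell_meta Optional data frame with at least `cell_id`, `row`,
#'   `col`; derived from `grid` when omitted.
#' @return An `occurrence_grid` object.
#' @export
occurrence_grid <- function(presence, grid = NULL, cell_meta = NULL) {
  presence <- as.matrix(presence)
  if (is.null(rownames(presence)) || is.null(colnames(presence))) {
    stop("presence matrix needs cell-id rownames and species colnames",
         call. = FALSE)
  }
  if (!all(presence %in% c(0, 1))) {
    stop("presence matrix must be binary 0/1", call. = FALSE)
  }
  storage.mode(presence) <- "double"
  if (is.null(cell_meta) && !is.null(grid)) {
    idx <- match(as.integer(rownames(presence)), grid$cells$cell_id)
    if (anyNA(idx)) stop("presence rownames not found in grid", call. = FALSE)
    cell_meta <- grid$cells[idx, , drop = FALSE]
  }
  structure(
    list(presence = presence, species = colnames(presence),
         cell_ids = rownames(presence), grid = grid, cell_meta = cell_meta),
    class = "occurrence_grid"
  )
}

#' @export
print.occurrence_grid <- function(x, ...) {
  cat("occurrence grid:", nrow(x$presence), "cells x",
      ncol(x$presence), "species;",
      sum(x$presence), "presences\n")
  invisible(x)
}

# ---- polygon rasterization ---------------------------------------------

# Sutherland-Hodgman clip of a ring against an axis-aligned rectangle.
# `ring` is a 2-column matrix (lon, lat); returns the clipped ring.
.clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  clip <- function(pts, inside, cross) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- vector("list", 2L * n)
    j <- 0L
    prev <- pts[n, ]
    prev_in <- inside(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) { j <- j + 1L; out[[j]] <- cross(prev, cur) }
        j <- j + 1L; out[[j]] <- cur
      } else if (prev_in) {
        j <- j + 1L; out[[j]] <- cross(prev, cur)
      }
      prev <- cur
      prev_in <- cur_in
    }
    if (j == 0L) matrix(numeric(0), 0, 2) else do.call(rbind, out[seq_len(j)])
  }
  cross_x <- function(a) function(p, q) {
    t <- (a - p[1]) / (q[1] - p[1])
    c(a, p[2] + t * (q[2] - p[2]))
  }
  cross_y <- function(a) function(p, q) {
    t <- (a - p[2]) / (q[2] - p[2])
    c(p[1] + t * (q[1] - p[1]), a)
  }
  ring <- clip(ring, function(p) p[1] >= xmin, cross_x(xmin))
  ring <- clip(ring, function(p) p[1] <= xmax, cross_x(xmax))
  ring <- clip(ring, function(p) p[2] >= ymin, cross_y(ymin))
  ring <- clip(ring, function(p) p[2] <= ymax, cross_y(ymax))
  ring
}

.shoelace_area <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Rasterize species range polygons onto a grid
#'
#' A species is recorded present in a cell when its range covers at least
#' `min_coverage` of the cell's area (`>=` at the boundary). The coverage
#' ratio within a single cell is computed planimetrically in degrees: the
#' cosine-latitude area factor is effectively constant inside one cell and
#' cancels between numerator and denominator.
#'
#' @param polygons Named list (one entry per species) of rings; each ring
#'   a 2-column lon/lat matrix. Holes are not supported.
#' @param grid A [grid_spec()].
#' @param min_coverage Minimum covered fraction of a cell (default 0.125).
#' @return An `occurrence_grid` over all grid cells (use
#'   [drop_empty_cells()] to discard empty ones). Species with an empty
#'   polygon set are dropped with a warning.
#' @export
rasterize_ranges <- function(polygons, grid, min_coverage = 0.125) {
  stopifnot(inherits(grid, "grid_spec"),
            min_coverage > 0, min_coverage <= 1)
  if (is.null(names(polygons)) || any(names(polygons) == "")) {
    stop("polygons must be a named list (one name per species)",
         call. = FALSE)
  }
  empty <- vapply(polygons, function(p) length(p) == 0 ||
                    all(vapply(p, nrow, 0L) < 3), TRUE)
  if (any(empty)) {
    warning("dropping species with empty polygon set: ",
            paste(names(polygons)[empty], collapse = ", "))
    polygons <- polygons[!empty]
  }
  if (length(polygons) == 0) stop("no species with valid polygons",
                                  call. = FALSE)
  cells <- grid$cells
  cell_area_deg <- grid$cell_size^2
  presence <- matrix(0, nrow(cells), length(polygons),
                     dimnames = list(cells$cell_id, names(polygons)))
  for (s in seq_along(polygons)) {
    rings <- polygons[[s]]
    bb <- apply(do.call(rbind, rings), 2, range)
    cand <- which(cells$lon_max > bb[1, 1] & cells$lon_min < bb[2, 1] &
                    cells$lat_max > bb[1, 2] & cells$lat_min < bb[2, 2])
    for (ci in cand) {
      a <- 0
      for (ring in rings) {
        clipped <- .clip_ring_rect(ring, cells$lon_min[ci], cells$lon_max[ci],
                                   cells$lat_min[ci], cells$lat_max[ci])
        a <- a + .shoelace_area(clipped)
      }
      if (min(a / cell_area_deg, 1) >= min_coverage) presence[ci, s] <- 1
    }
  }
  occurrence_grid(presence, grid = grid)
}

#' Read species range polygons from a GeoJSON FeatureCollection
#'
#' Each feature must carry a `species` property and a Polygon or
#' MultiPolygon geometry; only outer rings are used.
#'
#' @param path Path to a GeoJSON file.
#' @return Named list of rings suitable for [rasterize_ranges()].
#' @export
read_ranges_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a FeatureCollection", call. = FALSE)
  out <- list()
  for (f in gj$features) {
    sp <- f$properties$species
    if (is.null(sp)) stop("feature without 'species' property", call. = FALSE)
    geom <- f$geometry
    ring_of <- function(coords) {
      do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
    }
    rings <- switch(
      geom$type,
      Polygon = list(ring_of(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(p) ring_of(p[[1]])),
      stop("unsupported geometry type: ", geom$type)
    )
    out[[sp]] <- c(out[[sp]], rings)
  }
  out
}

#' Drop grid cells without any species
#'
#' @param g An `occurrence_grid`.
#' @return The grid restricted to occupied cells; cell ids are retained.
#' @export
drop_empty_cells <- function(g) {
  stopifnot(inherits(g, "occurrence_grid"))
  keep <- rowSums(g$presence) > 0
  if (!any(keep)) stop("empty occurrence matrix", call. = FALSE)
  g$presence <- g$presence[keep, , drop = FALSE]
  g$cell_ids <- g$cell_ids[keep]
  if (!is.null(g$cell_meta)) g$cell_meta <- g$cell_meta[keep, , drop = FALSE]
  g
}

# species with no occupied cell (can arise after cell filtering)
.drop_empty_species <- function(g) {
  keep <- colSums(g$presence) > 0
  g$presence <- g$presence[, keep, drop = FALSE]
  g$species <- g$species[keep]
  g
}

#' Align grid species with a phylogeny's tips
#'
#' Restricts the grid to species present among the tree tips and reorders
#' its columns to tip order; the counts of names dropped on each side are
#' reported as a message.
#'
#' @param g An `occurrence_grid`.
#' @param tree A `phylo` tree.
#' @return The aligned `occurrence_grid`.
#' @export
align_to_tree <- function(g, tree) {
  stopifnot(inherits(g, "occurrence_grid"), inherits(tree, "phylo"))
  common <- intersect(tree$tip.label, g$species)
  if (length(common) == 0) {
    stop("no species shared between grid and tree", call. = FALSE)
  }
  dropped_grid <- length(setdiff(g$species, common))
  dropped_tree <- length(setdiff(tree$tip.label, common))
  if (dropped_grid + dropped_tree > 0) {
    message("align_to_tree: dropped ", dropped_grid, " grid species and ",
            dropped_tree, " tree tips not shared")
  }
  g$presence <- g$presence[, common, drop = FALSE]
  g$species <- common
  g
}

#' Write / read an occurrence grid as CSV
#'
#' Layout: `cell_id`, `row`, `col`, then one 0/1 column per species.
#'
#' @param g An `occurrence_grid`.
#' @param path Output path.
#' @return `write_grid_csv` returns `path` invisibly; `read_grid_csv`
#'   returns an `occurrence_grid` (without full grid geometry).
#' @export
write_grid_csv <- function(g, path) {
  meta <- if (!is.null(g$cell_meta)) {
    g$cell_meta[, c("cell_id", "row", "col")]
  } else {
    data.frame(cell_id = g$cell_ids, row = NA, col = NA)
  }
  utils::write.csv(cbind(meta, as.data.frame(g$presence)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  pres <- as.matrix(df[, setdiff(names(df), c("cell_id", "row", "col")),
                       drop = FALSE])
  rownames(pres) <- df$cell_id
  occurrence_grid(pres, cell_meta = df[, c("cell_id", "row", "col")])
}
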