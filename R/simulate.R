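#' Scenario configuration for the synthetic fauna generator
#'
#' Defines the study conditions emulated by [simulate_regional_fauna()]:
#' a grid tiled into contiguous rectangular latent regions, a clade-
#' structured species pool whose clades diversify within those regions,
#' contiguous species ranges mostly inside their clade's region, and a
#' fraction of widespread species that ignore region boundaries.
#'
#' @param n_regions Number of latent regions (default 4).
#' @param grid_nrow,grid_ncol Grid dimensions (default 12 x 12).
#' @param n_species Species pool size (default 120).
#' @param range_size_mean Mean range size in cells (default 30, i.e.
#'   a typical species occupies most of its ~36-cell region, emulating
#'   the broad-ranged continental faunas the method is applied to).
#' @param spillover_prob Probability that a range-growth step leaves the
#'   species' region (default 0.1); non-widespread species always keep at
#'   least 60 percent of their cells inside their region.
#' @param widespread_frac Fraction of species grown without regard to
#'   region boundaries and labelled `WIDESPREAD` in the truth
#'   (default 0.1).
#' @param seed Integer seed (default 7).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_regions = 4, grid_nrow = 12, grid_ncol = 12,
                            n_species = 120, range_size_mean = 30,
                            spillover_prob = 0.1, widespread_frac = 0.1,
                            seed = 7) {
  stopifnot(n_regions >= 1, n_regions <= grid_nrow * grid_ncol,
            n_species >= 3, range_size_mean >= 1,
            spillover_prob >= 0, spillover_prob <= 1,
            widespread_frac >= 0, widespread_frac <= 1)
  structure(
    list(n_regions = n_regions, grid_nrow = grid_nrow,
         grid_ncol = grid_ncol, n_species = n_species,
         range_size_mean = range_size_mean, spillover_prob = spillover_prob,
         widespread_frac = widespread_frac, seed = seed),
    class = "scenario_config"
  )
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Yule tree with `n_species` tips, rescaled to unit root-to-tip depth;
#' tips are labelled `sp001`, `sp002`, ... Deterministic per seed.
#'
#' @param n_species Number of tips (>= 3).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` tree of depth 1.
#' @export
simulate_tree <- function(n_species, seed = 0) {
  stopifnot(n_species >= 3)
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

# rectangular block tiling of an nrow x ncol grid into n_regions blocks;
# returns an integer matrix plus the block layout as attributes
.region_block_map <- function(nrow, ncol, n_regions) {
  nb_rows <- max(1L, floor(sqrt(n_regions)))
  nb_cols <- ceiling(n_regions / nb_rows)
  map <- matrix(0L, nrow, ncol)
  # distribute regions over a nb_rows x nb_cols block lattice (last band
  # may hold fewer blocks)
  region <- 0L
  row_breaks <- round(seq(0, nrow, length.out = nb_rows + 1))
  for (br in seq_len(nb_rows)) {
    blocks_here <- min(nb_cols, n_regions - region)
    col_breaks <- round(seq(0, ncol, length.out = blocks_here + 1))
    for (bc in seq_len(blocks_here)) {
      region <- region + 1L
      map[(row_breaks[br] + 1):row_breaks[br + 1],
          (col_breaks[bc] + 1):col_breaks[bc + 1]] <- region
    }
  }
  attr(map, "nb_rows") <- nb_rows
  attr(map, "nb_cols") <- nb_cols
  map
}

# cut an ultrametric binary tree into exactly n_clades monophyletic tip
# groups: the number of lineages crossing depth t is 1 + #{internal nodes
# shallower than t}, so cut between the (n-1)-th and n-th shallowest
# internal node depths
.cut_clades <- function(tree, n_clades) {
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  int_depth <- sort(depth[(ntip + 1):(ntip + tree$Nnode)])
  n_clades <- min(n_clades, ntip)
  cut <- if (n_clades <= 1) {
    -1
  } else if (n_clades > tree$Nnode) {
    max(int_depth) + 1e-9
  } else {
    (int_depth[n_clades - 1] + int_depth[n_clades]) / 2
  }
  # clade roots: nodes deeper than the cut whose parent is shallower
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  clade <- integer(ntip)
  is_root_of_clade <- function(v) {
    depth[v] > cut && (v == root || depth[parent[v]] <= cut)
  }
  clade_roots <- Filter(is_root_of_clade, seq_len(ntip + tree$Nnode))
  desc_tips <- function(v) {
    if (v <= ntip) return(v)
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    unlist(lapply(kids, desc_tips))
  }
  for (i in seq_along(clade_roots)) {
    clade[desc_tips(clade_roots[i])] <- i
  }
  stats::setNames(clade, tree$tip.label)
}

# contiguous blob grown by frontier sampling under 4-adjacency.
# region_mask: logical matrix of "inside" cells; max_out caps accepted
# outside cells so the 60 percent containment rule holds by construction.
.grow_blob <- function(region_mask, start, size, spillover, max_out) {
  nrow <- nrow(region_mask); ncol <- ncol(region_mask)
  id <- function(r, c) (r - 1L) * ncol + c
  rc <- function(i) c((i - 1L) %/% ncol + 1L, (i - 1L) %% ncol + 1L)
  inside <- as.vector(t(region_mask))  # cell-id order (row-major)
  blob <- start
  n_out <- if (inside[start]) 0L else 1L
  while (length(blob) < size) {
    nb <- unique(unlist(lapply(blob, function(i) {
      p <- rc(i)
      c(if (p[1] > 1) id(p[1] - 1, p[2]),
        if (p[1] < nrow) id(p[1] + 1, p[2]),
        if (p[2] > 1) id(p[1], p[2] - 1),
        if (p[2] < ncol) id(p[1], p[2] + 1))
    })))
    nb <- setdiff(nb, blob)
    if (length(nb) == 0) break
    nb_in <- nb[inside[nb]]
    nb_out <- nb[!inside[nb]]
    go_out <- length(nb_out) > 0 && n_out < max_out &&
      stats::runif(1) < spillover
    pick_from <- if (go_out) nb_out else nb_in
    if (length(pick_from) == 0) {
      # trapped frontier: fall back to the other side, but never leave the
      # region when spillover is impossible or the quota is exhausted
      pick_from <- if (go_out) nb_in else {
        if (spillover > 0 && n_out < max_out) nb_out else integer(0)
      }
    }
    if (length(pick_from) == 0) break
    cell <- if (length(pick_from) == 1) pick_from else sample(pick_from, 1)
    blob <- c(blob, cell)
    if (!inside[cell]) n_out <- n_out + 1L
  }
  blob
}

# core generator shared by simulate_regional_fauna and the paired
# host/parasite scenario (which injects a shifted region map)
.simulate_fauna <- function(cfg, region_map = NULL) {
  set.seed(cfg$seed)
  tree <- simulate_tree(cfg$n_species, seed = cfg$seed)
  set.seed(cfg$seed + 1L)
  if (is.null(region_map)) {
    region_map <- .region_block_map(cfg$grid_nrow, cfg$grid_ncol,
                                    cfg$n_regions)
  }
  nrow <- nrow(region_map); ncol <- ncol(region_map)
  # several ancestral lineages per region (the evoregion concept allows
  # "one or several ancestors"): cut into ~3 clades per region and assign
  # clades, largest first, to the least-loaded region so every region
  # holds a comparable share of the species pool
  clade <- .cut_clades(tree, min(3L * cfg$n_regions, cfg$n_species))
  n_clades <- max(clade)
  sizes <- tabulate(clade, nbins = n_clades)
  clade_region <- integer(n_clades)
  load <- numeric(cfg$n_regions)
  for (i in order(sizes, decreasing = TRUE)) {
    r <- which.min(load)
    clade_region[i] <- r
    load[r] <- load[r] + sizes[i]
  }
  species <- tree$tip.label
  n_wide <- round(cfg$widespread_frac * cfg$n_species)
  wide <- sample(species, n_wide)
  region_of <- clade_region[clade[species]]
  names(region_of) <- species

  all_mask <- matrix(TRUE, nrow, ncol)
  presence <- matrix(0, nrow * ncol, cfg$n_species,
                     dimnames = list(seq_len(nrow * ncol), species))
  true_sp <- character(cfg$n_species)
  names(true_sp) <- species
  for (sp in species) {
    widespread <- sp %in% wide
    reg <- region_of[[sp]]
    mask <- if (widespread) all_mask else region_map == reg
    size <- min(1 + stats::rpois(1, max(cfg$range_size_mean - 1, 0)),
                sum(all_mask))
    max_out <- if (widespread) .Machine$integer.max
               else max(size - ceiling(0.6 * size), 0L)
    start_cells <- which(as.vector(t(mask)))
    start <- if (length(start_cells) == 1) start_cells
             else sample(start_cells, 1)
    blob <- .grow_blob(mask, start, size, cfg$spillover_prob, max_out)
    presence[blob, sp] <- 1
    true_sp[sp] <- if (widespread) "WIDESPREAD" else LETTERS[reg]
  }
  grid <- grid_spec(lon_range = c(0, 2 * ncol),
                    lat_range = c(0, 2 * nrow), cell_size = 2)
  g <- occurrence_grid(presence, grid = grid)
  true_cells <- stats::setNames(LETTERS[as.vector(t(region_map))],
                                seq_len(nrow * ncol))
  structure(
    list(tree = tree, grid = g, true_cell_region = true_cells,
         true_species_region = true_sp, region_map = region_map,
         config = cfg),
    class = "synthetic_truth"
  )
}

#' Simulate a fauna with known regional structure
#'
#' Tiles the grid into `n_regions` contiguous rectangular latent regions,
#' partitions the Yule tree's tips into exactly `n_regions` clades by
#' cutting at the appropriate depth, binds each clade to a region, and
#' grows every species' range as a contiguous random blob from a random
#' cell of its region. Growth steps leave the region with probability
#' `spillover_prob`, capped so each non-widespread species keeps at least
#' 60 percent of its cells inside its region; a `widespread_frac` of
#' species grow blobs ignoring boundaries and are labelled `WIDESPREAD`.
#'
#' @param cfg A [scenario_config()].
#' @return A `synthetic_truth` object: `tree`, `grid`
#'   (an `occurrence_grid`), `true_cell_region`, `true_species_region`,
#'   `region_map`, `config`.
#' @export
simulate_regional_fauna <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  .simulate_fauna(cfg)
}

#' Simulate a host/parasite fauna pair with tunable spatial congruence
#'
#' The host fauna comes from [simulate_regional_fauna()]. The parasite
#' fauna shares the grid but its latent region boundaries are shifted
#' cyclically by `round((1 - congruence_level) * half-block)` cells in
#' both grid axes, so at `congruence_level = 1` the two latent geometries
#' coincide and at 0 their blocks are maximally offset (a surrogate for
#' dispersal and host switching decoupling the two regionalizations).
#'
#' @param cfg A [scenario_config()] (the parasite fauna uses
#'   `cfg$seed + 10000`).
#' @param congruence_level Fraction in `[0, 1]`.
#' @return List with elements `host` and `parasite`, both
#'   `synthetic_truth`.
#' @export
simulate_host_parasite_pair <- function(cfg, congruence_level = 1) {
  stopifnot(inherits(cfg, "scenario_config"),
            congruence_level >= 0, congruence_level <= 1)
  host <- simulate_regional_fauna(cfg)
  map <- host$region_map
  block_h <- nrow(map) / attr(map, "nb_rows")
  block_w <- ncol(map) / attr(map, "nb_cols")
  half <- floor(min(block_h, block_w) / 2)
  s <- round((1 - congruence_level) * half)
  shift <- function(m, by_r, by_c) {
    m[((seq_len(nrow(m)) - 1 - by_r) %% nrow(m)) + 1,
      ((seq_len(ncol(m)) - 1 - by_c) %% ncol(m)) + 1]
  }
  pmap <- shift(map, s, s)
  attributes(pmap) <- attributes(map)
  pcfg <- cfg
  pcfg$seed <- cfg$seed + 10000L
  parasite <- .simulate_fauna(pcfg, region_map = pmap)
  list(host = host, parasite = parasite)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic fauna:", x$config$n_species, "species,",
      x$config$n_regions, "latent regions on a",
      x$config$grid_nrow, "x", x$config$grid_ncol, "grid\n")
  invisible(x)
}
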