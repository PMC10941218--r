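#' Run the full two-taxon evoregion study
#'
#' End-to-end driver over two taxa sharing a grid (e.g. parasites and
#' their hosts): per taxon it aligns grid and tree, builds the fuzzy
#' membership and composition matrices, classifies evoregions, computes
#' affiliations, transition zones and species associations, and (when
#' `n_maps > 0`) reconstructs ancestral evoregions by stochastic
#' character mapping; jointly it reports the V-measure congruence of the
#' two regionalizations in both orientations. Every stochastic stage
#' consumes a seed derived from `seed`, so two runs with equal inputs are
#' identical.
#'
#' @param taxa Named list of two (or more) `list(tree =, grid =)` pairs.
#' @param var_threshold PCPS axis-selection cutoff (default 0.05).
#' @param k_max Largest k for the elbow rule (default 10).
#' @param restarts k-means restarts (default 20).
#' @param association_threshold Species association rule (default 0.60).
#' @param transition_quantile Affiliation quantile flagging transition
#'   cells (default 0.25).
#' @param n_maps Stochastic maps per taxon (default 100; 0 skips the
#'   ancestral reconstruction).
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, per-taxon CSV tables
#'   and a JSON report are written into it.
#' @return An `evoregion_study` list: one entry per taxon
#'   (`regions`, `affiliation`, `zones`, `association`, `ancestral`) plus
#'   `congruence` (both orientations) and `seeds`.
#' @export
run_full_study <- function(taxa, var_threshold = 0.05, k_max = 10,
                           restarts = 20, association_threshold = 0.60,
                           transition_quantile = 0.25, n_maps = 100,
                           seed = 0, out_dir = NULL) {
  stopifnot(is.list(taxa), length(taxa) >= 1, !is.null(names(taxa)))
  results <- list()
  seeds <- list()
  for (ti in seq_along(taxa)) {
    nm <- names(taxa)[ti]
    tree <- taxa[[ti]]$tree
    grid <- taxa[[ti]]$grid
    stopifnot(inherits(tree, "phylo"), inherits(grid, "occurrence_grid"))
    taxon_seed <- seed + 100L * ti
    seeds[[nm]] <- taxon_seed

    grid <- drop_empty_cells(grid)
    grid <- align_to_tree(grid, tree)
    grid <- .drop_empty_species(grid)
    d_sp <- patristic_distances(tree)[grid$species, grid$species]
    q <- fuzzy_membership(phylo_similarity(d_sp))
    p <- phylo_composition(grid, q)
    regions <- classify_evoregions(p, var_threshold = var_threshold,
                                   k_max = k_max, restarts = restarts,
                                   seed = taxon_seed)
    affil <- cell_affiliation(regions$dissimilarity, regions,
                              transition_quantile = transition_quantile)
    zones <- if (!is.null(grid$cell_meta)) {
      transition_zones(affil, grid)
    } else NULL
    assoc <- species_association(grid, regions,
                                 threshold = association_threshold)
    ancestral <- NULL
    if (n_maps > 0 && length(unique(assoc$assignment)) >= 2) {
      states <- stats::setNames(assoc$assignment, assoc$species)
      map_tree <- prune_to_states(tree, states)
      ancestral <- mk_simmap(map_tree, states, n_maps = n_maps,
                             seed = taxon_seed + 1L)
    }
    results[[nm]] <- list(grid = grid, regions = regions,
                          affiliation = affil, zones = zones,
                          association = assoc, ancestral = ancestral)
  }
  congruence <- NULL
  if (length(results) >= 2) {
    r1 <- results[[1]]$regions
    r2 <- results[[2]]$regions
    congruence <- list(
      forward = v_measure(build_overlap(r1, r2)),
      reverse = v_measure(build_overlap(r2, r1))
    )
  }
  study <- structure(
    list(taxa = results, congruence = congruence, seeds = seeds,
         params = list(var_threshold = var_threshold, k_max = k_max,
                       restarts = restarts,
                       association_threshold = association_threshold,
                       transition_quantile = transition_quantile,
                       n_maps = n_maps, seed = seed)),
    class = "evoregion_study"
  )
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' Write the tables of a study to disk
#'
#' Per taxon: `<name>_regions.csv` (cell, evoregion, posteriors),
#' `<name>_affiliation.csv`, `<name>_association.csv`, and
#' `<name>_node_posteriors.csv` when ancestral states were mapped; plus
#' `report.json` with the headline numbers.
#'
#' @param study An `evoregion_study`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$taxa)) {
    tx <- study$taxa[[nm]]
    reg <- data.frame(cell_id = tx$regions$cell_ids,
                      evoregion = unname(tx$regions$labels))
    reg <- cbind(reg, as.data.frame(tx$regions$posterior))
    utils::write.csv(reg, file.path(out_dir, paste0(nm, "_regions.csv")),
                     row.names = FALSE)
    utils::write.csv(tx$affiliation$table,
                     file.path(out_dir, paste0(nm, "_affiliation.csv")),
                     row.names = FALSE)
    utils::write.csv(tx$association,
                     file.path(out_dir, paste0(nm, "_association.csv")),
                     row.names = FALSE)
    if (!is.null(tx$ancestral)) {
      np <- tx$ancestral$node_posteriors
      utils::write.csv(
        data.frame(node = rep(rownames(np), ncol(np)),
                   state = rep(colnames(np), each = nrow(np)),
                   probability = as.vector(np)),
        file.path(out_dir, paste0(nm, "_node_posteriors.csv")),
        row.names = FALSE
      )
    }
  }
  report <- list(
    k = lapply(study$taxa, function(tx) tx$regions$k),
    n_transition_cells = lapply(study$taxa, function(tx)
      sum(tx$affiliation$table$transition)),
    n_widespread = lapply(study$taxa, function(tx)
      sum(tx$association$assignment == "WIDESPREAD")),
    seeds = study$seeds,
    params = study$params
  )
  if (!is.null(study$congruence)) {
    report$v_measure <- list(
      forward = list(v = study$congruence$forward$v,
                     homogeneity = study$congruence$forward$homogeneity,
                     completeness = study$congruence$forward$completeness),
      reverse = list(v = study$congruence$reverse$v,
                     homogeneity = study$congruence$reverse$homogeneity,
                     completeness = study$congruence$reverse$completeness)
    )
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.evoregion_study <- function(x, ...) {
  for (nm in names(x$taxa)) {
    cat(nm, ": k =", x$taxa[[nm]]$regions$k, ";",
        sum(x$taxa[[nm]]$association$assignment == "WIDESPREAD"),
        "widespread species\n")
  }
  if (!is.null(x$congruence)) print(x$congruence$forward)
  invisible(x)
}
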