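#!/usr/bin/env Rscript
# Step 3 — within-evoregion affiliation of every cell assemblage and the
# evolutionary transition zones (low-affiliation cells at region
# borders, joined into 4-neighbour components).

library(evoregions)

for (nm in c("host", "parasite")) {
  st <- readRDS(file.path("results", paste0(nm, "_classification.rds")))
  aff <- cell_affiliation(st$regions$dissimilarity, st$regions)
  utils::write.csv(aff$table,
                   file.path("results", paste0(nm, "_affiliation.csv")),
                   row.names = FALSE)
  zones <- transition_zones(aff, st$grid)
  cat(nm, "affiliation: median",
      round(stats::median(aff$table$affiliation), 3),
      "|", sum(aff$table$transition), "transition-flagged cells in",
      length(zones), "zones\n")
  for (i in seq_along(zones)) {
    cat(sprintf("  zone %d: %d cells, borders %s\n", i, zones[[i]]$size,
                paste(zones[[i]]$labels, collapse = "/")))
  }
}
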