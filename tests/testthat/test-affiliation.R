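# hand-built dissimilarity with region A (4 core cells + 2 stripe cells)
# and region B (2 cells); stripe cells sit next to B on a 2x4 grid
stripe_fixture <- function() {
  cells <- as.character(1:8)
  # grid layout (rows x cols):  1 2 3 4
  #                             5 6 7 8
  # labels: cols 1-3 -> A (col 3 is the stripe), col 4 -> B
  labels <- stats::setNames(c("A", "A", "A", "B", "A", "A", "A", "B"), cells)
  meta <- data.frame(cell_id = cells, row = rep(1:2, each = 4),
                     col = rep(1:4, 2))
  core_a <- c("1", "2", "5", "6")
  stripe <- c("3", "7")
  d <- matrix(0.9, 8, 8, dimnames = list(cells, cells))
  diag(d) <- 0
  d[core_a, core_a] <- 0.1
  d[stripe, stripe] <- 0.1
  d[core_a, stripe] <- 0.6
  d[stripe, core_a] <- 0.6
  d[c("4", "8"), c("4", "8")] <- 0.1
  diag(d) <- 0
  list(d = d, labels = labels, meta = meta, stripe = stripe,
       core_a = core_a)
}

test_that("affiliation is one minus the mean within-region dissimilarity", {
  # 3-cell evoregion with d(1,2) = 0.2, d(1,3) = 0.4 -> affiliation 0.7
  cells <- as.character(1:3)
  d <- matrix(c(0, 0.2, 0.4, 0.2, 0, 0.3, 0.4, 0.3, 0), 3, 3,
              dimnames = list(cells, cells))
  labels <- stats::setNames(rep("A", 3), cells)
  a <- cell_affiliation(d, labels)
  expect_equal(a$table$affiliation[1], 0.7)

  # identical assemblages: affiliation 1 everywhere
  dz <- matrix(0, 3, 3, dimnames = list(cells, cells))
  expect_equal(cell_affiliation(dz, labels)$table$affiliation, rep(1, 3))

  # maximally dissimilar cell: affiliation 0
  dm <- matrix(1, 3, 3, dimnames = list(cells, cells)); diag(dm) <- 0
  expect_equal(cell_affiliation(dm, labels)$table$affiliation[1], 0)

  # sole member of its region: affiliation defined as 1
  lone <- stats::setNames(c("A", "B", "B"), cells)
  expect_equal(cell_affiliation(d, lone)$table$affiliation[1], 1)
})

test_that("affiliation ignores region names and non-member cells", {
  fx <- stripe_fixture()
  a1 <- cell_affiliation(fx$d, fx$labels)
  relab <- stats::setNames(chartr("AB", "XY", fx$labels), names(fx$labels))
  a2 <- cell_affiliation(fx$d, relab)
  expect_equal(a2$table$affiliation, a1$table$affiliation)
  # perturbing dissimilarities between cells of *different* regions only
  d3 <- fx$d
  d3["1", "4"] <- d3["4", "1"] <- 0.2
  a3 <- cell_affiliation(d3, fx$labels)
  expect_equal(a3$table$affiliation, a1$table$affiliation)
})

test_that("uniform affiliations flag no transition cells", {
  cells <- as.character(1:4)
  dz <- matrix(0.3, 4, 4, dimnames = list(cells, cells)); diag(dz) <- 0
  a <- cell_affiliation(dz, stats::setNames(rep("A", 4), cells))
  expect_false(any(a$table$transition))
})

test_that("a low-affiliation stripe forms one zone bordering both regions", {
  fx <- stripe_fixture()
  a <- cell_affiliation(fx$d, fx$labels)
  flagged <- a$table$cell_id[a$table$transition]
  expect_setequal(flagged, fx$stripe)
  zones <- transition_zones(a, fx$meta)
  expect_length(zones, 1)
  expect_setequal(zones[[1]]$cells, fx$stripe)
  expect_setequal(zones[[1]]$labels, c("A", "B"))
})

test_that("an isolated flagged cell is a size-1 component", {
  fx <- stripe_fixture()
  a <- cell_affiliation(fx$d, fx$labels)
  a$table$transition <- a$table$cell_id == "3"  # only one stripe cell
  zones <- transition_zones(a, fx$meta)
  expect_length(zones, 1)
  expect_equal(zones[[1]]$size, 1)
})

test_that("species association applies the inclusive 60% rule with ties widespread", {
  cells <- as.character(1:10)
  labels <- stats::setNames(rep(c("A", "B"), each = 5), cells)
  pres <- matrix(0, 10, 4, dimnames = list(cells, c("one", "seven",
                                                    "split", "exact")))
  pres["1", "one"] <- 1                      # single cell -> A, fraction 1
  pres[c(1:4, 6:8), "seven"] <- 1            # 4 A of 7 -> widespread
  pres[c(1:5, 6:10), "split"] <- 1           # 5/5 tie -> widespread
  pres[c(1:3, 6, 7), "exact"] <- 1           # 3 of 5 = 0.6 -> A
  assoc <- species_association(pres, labels)
  rownames(assoc) <- assoc$species
  expect_equal(assoc["one", "assignment"], "A")
  expect_equal(assoc["one", "fraction"], 1)
  expect_equal(assoc["seven", "assignment"], "WIDESPREAD")
  expect_equal(assoc["seven", "fraction"], 4 / 7)
  expect_equal(assoc["split", "assignment"], "WIDESPREAD")
  expect_equal(assoc["exact", "assignment"], "A")
  expect_equal(assoc["exact", "fraction"], 0.6)

  # 8 occupied cells, 5 of them in region B: 0.625 -> B
  pres2 <- matrix(0, 10, 1, dimnames = list(cells, "b5of8"))
  pres2[c(1, 2, 3, 6, 7, 8, 9, 10), 1] <- 1
  a2 <- species_association(pres2, labels)
  expect_equal(a2$assignment, "B")
  expect_equal(a2$fraction, 0.625)
})

test_that("raising the association threshold never un-widespreads a species", {
  set.seed(8)
  cells <- as.character(1:30)
  labels <- stats::setNames(sample(LETTERS[1:3], 30, replace = TRUE), cells)
  pres <- matrix(rbinom(30 * 12, 1, 0.4), 30, 12,
                 dimnames = list(cells, paste0("s", 1:12)))
  pres[1, colSums(pres) == 0] <- 1
  prev <- NULL
  for (th in c(0.4, 0.6, 0.8, 1.0)) {
    assoc <- species_association(pres, labels, threshold = th)
    if (!is.null(prev)) {
      moved <- prev == "WIDESPREAD" & assoc$assignment != "WIDESPREAD"
      expect_false(any(moved))
    }
    prev <- assoc$assignment
  }
  # at threshold 1, widespread species = species spanning > 1 region
  assoc1 <- species_association(pres, labels, threshold = 1)
  spans <- vapply(colnames(pres), function(sp) {
    length(unique(labels[pres[, sp] > 0])) > 1
  }, TRUE)
  expect_equal(unname(assoc1$assignment == "WIDESPREAD"), unname(spans))
})
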