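st4 <- suppressMessages(species_tree("((A,B),(C,D));"))

test_that("edge species-set cache matches naive per-edge recomputation", {
  set.seed(101)
  for (rep in 1:5) {
    stn <- species_tree(ape::rtree(6))
    gt <- random_gene_tree(stn, n_genes = sample(4:12, 1))
    cache <- cache_species_sets(gt, stn)
    E <- gt$phy$edge
    for (i in seq_len(nrow(E))) {
      v <- E[i, 1]; u <- E[i, 2]
      expect_equal(which(cache$dir_set(v, u)),
                   naive_side_species(gt$phy, gt$species_idx, v, u))
      expect_equal(which(cache$dir_set(u, v)),
                   naive_side_species(gt$phy, gt$species_idx, u, v))
      # the two directions of an edge jointly cover the tree's species
      both <- cache$dir_set(v, u) | cache$dir_set(u, v)
      expect_setequal(which(both), unique(gt$species_idx))
    }
  }
})

test_that("smallest containing block is unique or absent", {
  expect_equal(smallest_containing_block(c("A", "B"), st4)$branch_id,
               which(st4$branches$block_a == "A;B"))
  # {A,C}: blocks A;B;C and A;C;D tie at size 3
  expect_null(smallest_containing_block(c("A", "C"), st4))
  # the full species set is not a block of any bipartition
  expect_null(smallest_containing_block(c("A", "B", "C", "D"), st4))
  expect_error(smallest_containing_block(c("A", "Z"), st4), "unknown")

  # agreement with exhaustive enumeration on random trees and subsets
  set.seed(7)
  for (rep in 1:10) {
    stn <- species_tree(ape::rtree(7))
    S <- sample(stn$species, sample(1:6, 1))
    got <- smallest_containing_block(S, stn)
    want <- oracle_smallest_block(S, stn)
    if (is.null(want)) {
      expect_null(got)
    } else {
      side <- got$side
      key <- if (side == "a") stn$branches$block_a[got$branch_id] else
        stn$branches$block_b[got$branch_id]
      expect_setequal(strsplit(key, ";")[[1]], want)
    }
  }
})

test_that("grandchild clades cover the block and degenerate to singletons", {
  st5 <- species_tree("((A,B),(C,D),E);")
  full <- smallest_containing_block(c("A", "B", "C", "D"), st5)
  gc <- grandchild_clades(full$branch_id, full$side, st5)
  expect_setequal(c(gc$X, gc$Y), c("A", "B", "C", "D"))
  expect_setequal(unlist(gc$gc), c("A", "B", "C", "D"))
  expect_equal(sort(lengths(gc$gc)), c(1, 1, 1, 1))

  two <- smallest_containing_block(c("A", "B"), st5)
  gc2 <- grandchild_clades(two$branch_id, two$side, st5)
  expect_setequal(unlist(gc2$gc), c("A", "B"))
  expect_equal(length(gc2$gc), 2)  # deduplicated degenerate slots

  # union property over every block of random trees
  set.seed(13)
  stn <- species_tree(ape::rtree(8))
  bp <- bipartitions(stn)
  for (j in seq_len(nrow(bp))) for (side in c("a", "b")) {
    gcj <- grandchild_clades(j, side, stn)
    key <- if (side == "a") bp$block_a[j] else bp$block_b[j]
    expect_setequal(unlist(gcj$gc), strsplit(key, ";")[[1]])
  }
})

test_that("duplication detection follows the worked four-taxon traces", {
  # a duplication of the (A,B) clade, at the (collapsed) root of the tree
  ev <- find_duplications(gene_tree("((A_1,B_1),(A_2,B_2));", st4, id = "g"),
                          st4)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$species_observed, "A;B")
  expect_equal(ev$branch_id, which(st4$branches$block_a == "A;B"))
  expect_true(ev$informative)

  # same but with an interior duplication node: still exactly one event
  ev2 <- find_duplications(
    gene_tree("(((A_1,B_1),(A_2,B_2)),(C_1,D_1));", st4, id = "g"), st4)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$species_observed, "A;B")
  expect_gt(ev2$node_id, 0)

  # one copy reduced to a single gene: grandchild presence fails
  ev3 <- find_duplications(gene_tree("((A_1,B_1),A_2);", st4, id = "g"), st4)
  expect_equal(nrow(ev3), 0)

  # species pair straddling the central branch: smallest block ties
  ev4 <- find_duplications(gene_tree("((A_1,C_1),(A_2,C_2));", st4, id = "g"),
                           st4)
  expect_equal(nrow(ev4), 0)

  # congruent single-copy tree: no overlapping species sets anywhere
  ev5 <- find_duplications(gene_tree("((A_1,B_1),(C_1,D_1));", st4, id = "g"),
                           st4)
  expect_equal(nrow(ev5), 0)
})

test_that("ambiguous nodes with tied smallest blocks yield no event", {
  # three (A,B) copies meeting at one node: all three pairs tie at size 2
  ev <- find_duplications(
    gene_tree("((A_1,B_1),(A_2,B_2),(A_3,B_3));", st4, id = "g"), st4)
  expect_equal(nrow(ev), 0)
})

test_that("detection is independent of gene-tree rooting and edge order", {
  set.seed(23)
  ds <- simulate_dataset(sim_config(n_species = 8, n_gene_trees = 30,
                                    seed = 23))
  key <- function(e) sort(paste(e$branch_id, e$dup_block, e$species_observed))
  for (gt in ds$gene_trees[1:15]) {
    ev <- find_duplications(gt, ds$st)
    if (ape::Ntip(gt$phy) < 4) next
    og <- gt$phy$tip.label[sample(ape::Ntip(gt$phy), 1)]
    rer <- ape::unroot(ape::root(gt$phy, outgroup = og))
    gt2 <- gene_tree(rer, ds$st, id = gt$id)
    expect_equal(key(find_duplications(gt2, ds$st)), key(ev))
  }
})

test_that("aggregated counts split events by block orientation", {
  st <- toy_species_tree()
  ev <- events_from_blocks(list(c("elephant", "dog"),
                                c("elephant", "dog", "bird"),
                                c("elephant", "dog", "bird")), st)
  cnt <- aggregate_counts(ev, st)
  ed <- which(st$branches$block_a == "dog;elephant" |
                st$branches$block_b == "dog;elephant")
  edb <- which(st$branches$block_a == "bird;dog;elephant" |
                 st$branches$block_b == "bird;dog;elephant")
  expect_equal(cnt$m[ed] + cnt$n[ed], 1)
  expect_equal(cnt$m[edb] + cnt$n[edb], 2)
  expect_equal(sum(cnt$m + cnt$n), 3)
  expect_equal(sum(cnt$m + cnt$n), sum(ev$informative))

  none <- aggregate_counts(ev[0, ], st)
  expect_true(all(none$m == 0 & none$n == 0))
})
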