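#' Cache the species sets either side of every gene-tree edge
#'
#' For every directed edge (v -> u) of the unrooted gene tree, the species
#' observed in the subtree hanging on u's side is precomputed with one
#' postorder and one preorder traversal, so duplication testing at each node
#' is a set lookup rather than a subtree walk.
#'
#' @param gt A [gene_tree()].
#' @param st The [species_tree()] the gene tree is bound to.
#' @return An environment-free list with the traversal cache; primarily
#'   internal, exposed for testing. `dir_set(v, u)` returns the logical
#'   species membership vector on u's side of edge \{v, u\}.
#' @export
cache_species_sets <- function(gt, st) {
  stopifnot(inherits(gt, "duproot_gene_tree"))
  .edge_cache(gt$phy, gt$species_idx, st$t)
}

#' Smallest species-tree block containing a species set
#'
#' Among all `2(2t - 3)` blocks of the species tree's bipartitions, finds the
#' unique block of minimum size containing `S`. Partial gene loss after a
#' duplication shrinks the observed species set; mapping to the smallest
#' containing block recovers the branch the event belongs to. When the
#' minimum is not unique the placement is ambiguous and nothing is returned;
#' likewise the full species set is contained in no block.
#'
#' @param S Species set: character vector of species names or logical
#'   membership vector over `st$species`.
#' @param st A [species_tree()].
#' @return A list with `branch_id`, `side` (`"a"`/`"b"`), `row` (block-matrix
#'   row) and `size`, or `NULL` when no unique smallest block exists.
#' @export
smallest_containing_block <- function(S, st) {
  if (is.character(S)) {
    idx <- match(S, st$species)
    if (anyNA(idx)) stop("unknown species: ",
                         paste(S[is.na(idx)], collapse = ", "), call. = FALSE)
    S <- seq_len(st$t) %in% idx
  }
  if (!any(S)) stop("species set must be nonempty", call. = FALSE)
  .smallest_block(S, st)
}

# logical-vector fast path used by the detector
.smallest_block <- function(S, st) {
  cnt <- as.vector(st$block01 %*% S)
  containing <- cnt == sum(S)
  if (!any(containing)) return(NULL)
  sizes <- st$block_sizes
  smin <- min(sizes[containing])
  rows <- which(containing & sizes == smin)
  if (length(rows) != 1) return(NULL)
  r <- rows[1]
  list(branch_id = (r + 1L) %/% 2L, side = if (r %% 2 == 1) "a" else "b",
       row = r, size = smin)
}

#' Child and grandchild clades of a species-tree block
#'
#' Roots the block's subtree on the node separating it from its complement
#' and reports the species sets of the two child clades `X`, `Y` and the
#' grandchild clades. When a child clade is a single leaf its grandchild
#' slots degenerate to that leaf's singleton set; the `gc` element is the
#' deduplicated list of grandchild sets actually required of a duplication
#' candidate.
#'
#' @param branch_id,side Identify the block (see [bipartitions()]).
#' @param st A [species_tree()].
#' @return List with character-vector `X`, `Y` and list `gc`.
#' @export
grandchild_clades <- function(branch_id, side = c("a", "b"), st) {
  side <- match.arg(side)
  info <- st$gc_info[[.block_row(branch_id, side)]]
  list(X = st$species[info$X], Y = st$species[info$Y],
       gc = lapply(info$gc, function(g) st$species[g]))
}

# Core test: are the two subtrees with species sets S1, S2 (rooted at nodes
# r1, r2, approached from a1, a2 respectively) a well-supported
# post-duplication copy pair? Returns NULL or a list describing the event.
# Conditions:
#   (i)   overlapping species sets,
#   (ii)  a unique smallest containing block beta,
#   (iii) every grandchild clade of beta represented in each subtree,
#   (iv)  each subtree's root children map into the two child clades of beta
#         (leaf or polytomy subtree roots fail unless beta is a degenerate
#         two-species block).
.test_copy_pair <- function(S1, r1, a1, S2, r2, a2, cache, st, tally = NULL) {
  bump <- function(reason) {
    if (!is.null(tally)) tally[[reason]] <- tally[[reason]] + 1L
    NULL
  }
  if (!any(S1 & S2)) return(bump("no_species_overlap"))    # (i)
  U <- S1 | S2
  beta <- .smallest_block(U, st)
  if (is.null(beta)) return(bump("block_tie_or_root_spanning"))  # (ii)
  info <- st$gc_info[[beta$row]]
  for (g in info$gc) {                                     # (iii)
    if (!any(S1 & g) || !any(S2 & g)) return(bump("grandchild_missing"))
  }
  degenerate <- beta$size == 2
  for (i in 1:2) {                                         # (iv)
    r <- if (i == 1) r1 else r2
    a <- if (i == 1) a1 else a2
    ch <- setdiff(cache$neighbours[[r]], a)
    if (length(ch) != 2) {                 # leaf (0) or polytomy (>2)
      if (!degenerate) return(bump("copy_root_unresolved"))
      next
    }
    A1 <- cache$dir_set(r, ch[1])
    A2 <- cache$dir_set(r, ch[2])
    ok <- (!any(A1 & !info$X) && !any(A2 & !info$Y)) ||
          (!any(A1 & !info$Y) && !any(A2 & !info$X))
    if (!ok) return(bump("local_topology_mismatch"))
  }
  list(branch_id = beta$branch_id, side = beta$side, size = beta$size,
       species_observed = U)
}

.new_tally <- function() {
  as.environment(list(no_species_overlap = 0L,
                      block_tie_or_root_spanning = 0L,
                      grandchild_missing = 0L,
                      copy_root_unresolved = 0L,
                      local_topology_mismatch = 0L,
                      polytomy_nodes_skipped = 0L,
                      ambiguous_nodes_discarded = 0L))
}

.tally_to_list <- function(tally) {
  as.list(tally)[c("no_species_overlap", "block_tie_or_root_spanning",
                   "grandchild_missing", "copy_root_unresolved",
                   "local_topology_mismatch", "polytomy_nodes_skipped",
                   "ambiguous_nodes_discarded")]
}

# Duplication node candidate at a degree-3 node v: the copies hang from two
# of its incident edges (toward u1 and u2).
.is_duplication_pair <- function(v, u1, u2, cache, st, tally = NULL) {
  .test_copy_pair(cache$dir_set(v, u1), u1, v,
                  cache$dir_set(v, u2), u2, v, cache, st, tally)
}

# Duplication node candidate collapsed onto the edge {a, b}: when the input
# gene tree was rooted at a duplication node, unrooting removes that node and
# the two copies become the two complementary sides of one edge.
.is_duplication_edge <- function(a, b, cache, st, tally = NULL) {
  .test_copy_pair(cache$dir_set(b, a), a, b,
                  cache$dir_set(a, b), b, a, cache, st, tally)
}

#' Find well-supported gene duplication events in a gene tree
#'
#' Visits every internal node of degree three in the unrooted gene tree and
#' tests each of its three unordered pairs of incident subtrees as a putative
#' post-duplication pair. Nodes of higher degree (unresolved polytomies) are
#' skipped. A node yields at most one event: if several pairs pass, the pair
#' mapping to the smallest species-tree block is kept, and a tie discards the
#' node's events entirely. In addition every edge is tested with its two
#' complementary sides as the copy pair: a duplication node at which the
#' input gene tree happened to be rooted is collapsed when the tree is
#' unrooted, and its copies then sit either side of a single edge. Such edge
#' events are reported with `node_id` equal to minus the edge index.
#'
#' Events observed in a single species ("outward" terminal duplications)
#' carry no rooting information and are flagged `informative = FALSE`.
#'
#' @param gt A [gene_tree()].
#' @param st A [species_tree()].
#' @return A data frame of events: `gene_tree_id`, `node_id`, `branch_id`,
#'   `dup_block` (`"a"`/`"b"`), `species_observed` (semicolon-joined),
#'   `n_species`, `informative`. The per-reason counts of rejected candidates
#'   (no species overlap, block tie, missing grandchild, unresolved or
#'   mismatching copy topology, polytomy, ambiguous node) are attached as
#'   attribute `"discarded"` — they make the recall behaviour explainable.
#' @export
find_duplications <- function(gt, st) {
  cache <- cache_species_sets(gt, st)
  phy <- gt$phy
  ntip <- ape::Ntip(phy)
  n_node <- ntip + phy$Nnode
  deg <- tabulate(phy$edge, nbins = n_node)
  nodes <- which(deg == 3)
  tally <- .new_tally()
  tally$polytomy_nodes_skipped <- sum(deg[(ntip + 1):n_node] > 3)

  rows <- list()
  for (v in nodes) {
    nb <- cache$neighbours[[v]]
    cand <- list()
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      ev <- .is_duplication_pair(v, nb[pair[1]], nb[pair[2]], cache, st,
                                 tally)
      if (!is.null(ev)) cand[[length(cand) + 1]] <- ev
    }
    if (length(cand) == 0) next
    sizes <- vapply(cand, `[[`, 0, "size")
    best <- which(sizes == min(sizes))
    if (length(best) != 1) {           # ambiguous node: discard
      tally$ambiguous_nodes_discarded <- tally$ambiguous_nodes_discarded + 1L
      next
    }
    rows[[length(rows) + 1]] <- .event_row(gt$id, v, cand[[best]], st)
  }

  E <- phy$edge
  for (i in seq_len(nrow(E))) {
    ev <- .is_duplication_edge(E[i, 1], E[i, 2], cache, st, tally)
    if (!is.null(ev)) rows[[length(rows) + 1]] <- .event_row(gt$id, -i, ev, st)
  }

  out <- if (length(rows) == 0) .empty_events() else do.call(rbind, rows)
  attr(out, "discarded") <- .tally_to_list(tally)
  out
}

.event_row <- function(id, node_id, ev, st) {
  data.frame(
    gene_tree_id = id,
    node_id = as.integer(node_id),
    branch_id = ev$branch_id,
    dup_block = ev$side,
    species_observed = block_key(ev$species_observed, st$species),
    n_species = sum(ev$species_observed),
    informative = sum(ev$species_observed) >= 2,
    stringsAsFactors = FALSE
  )
}

.empty_events <- function() {
  data.frame(gene_tree_id = character(), node_id = integer(),
             branch_id = integer(), dup_block = character(),
             species_observed = character(), n_species = integer(),
             informative = logical(), stringsAsFactors = FALSE)
}

#' Find duplication events across a set of gene trees
#'
#' @param gene_trees List of [gene_tree()] objects.
#' @param st A [species_tree()].
#' @return Row-bound event data frame (see [find_duplications()]); the
#'   `"discarded"` attribute holds the summed per-reason rejection counts.
#' @export
find_all_duplications <- function(gene_trees, st) {
  evs <- lapply(gene_trees, find_duplications, st = st)
  out <- do.call(rbind, c(list(.empty_events()), evs))
  rownames(out) <- NULL
  tallies <- lapply(evs, attr, "discarded")
  total <- .tally_to_list(.new_tally())
  for (tl in tallies) for (k in names(total)) total[[k]] <- total[[k]] + tl[[k]]
  attr(out, "discarded") <- total
  out
}

#' Aggregate duplication events into per-branch counts
#'
#' For each species-tree branch `i` the ordered pair `(m_i, n_i)` counts the
#' informative events whose duplicate-containing block is `block_a`
#' (orientation "left") and `block_b` (orientation "right") respectively.
#' Single-species events are excluded from both counts.
#'
#' @param events Event data frame from [find_all_duplications()].
#' @param st A [species_tree()].
#' @return Data frame `branch_id`, `m`, `n` with one row per branch.
#' @export
aggregate_counts <- function(events, st) {
  ev <- events[events$informative, , drop = FALSE]
  if (nrow(ev) > 0 &&
      (any(ev$branch_id < 1) || any(ev$branch_id > st$b))) {
    stop("events reference branches outside the species tree", call. = FALSE)
  }
  m <- tabulate(ev$branch_id[ev$dup_block == "a"], nbins = st$b)
  n <- tabulate(ev$branch_id[ev$dup_block == "b"], nbins = st$b)
  data.frame(branch_id = seq_len(st$b), m = m, n = n)
}
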