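#' Simulator configuration
#'
#' Defaults define the standard validation conditions used throughout the
#' package's tests: 12 species, 500 gene trees, an expected 0.2 duplications
#' per lineage per species-tree branch, a 0.2 per-branch per-copy loss
#' probability, and no topological noise.
#'
#' @param n_species Number of species (>= 4).
#' @param n_gene_trees Number of gene trees to simulate.
#' @param dup_rate Expected duplications per surviving lineage per
#'   species-tree branch (Poisson).
#' @param loss_prob Probability that a gene copy is lost on each branch it
#'   traverses.
#' @param nni_noise Probability that a simulated gene tree receives one
#'   random nearest-neighbour interchange after ground truth is logged; a
#'   cheap proxy for gene-tree inference error or incomplete lineage sorting.
#' @param seed Master seed; identical configurations give identical output.
#' @return A `duproot_sim_config` list.
#' @export
sim_config <- function(n_species = 12, n_gene_trees = 500, dup_rate = 0.2,
                       loss_prob = 0.2, nni_noise = 0, seed = 1) {
  stopifnot(n_species >= 4, n_gene_trees >= 1, dup_rate >= 0,
            loss_prob >= 0, loss_prob <= 1, nni_noise >= 0, nni_noise <= 1)
  structure(list(n_species = n_species, n_gene_trees = n_gene_trees,
                 dup_rate = dup_rate, loss_prob = loss_prob,
                 nni_noise = nni_noise, seed = as.integer(seed)),
            class = "duproot_sim_config")
}

#' Simulate a rooted species tree
#'
#' A pure-birth (Yule) topology with tips labelled `s1..sk`. Branch lengths
#' are generated by the birth process but ignored downstream.
#'
#' @param n_species Number of species (>= 4).
#' @param seed Integer seed.
#' @return A rooted `phylo`.
#' @export
simulate_species_tree <- function(n_species, seed = 1) {
  if (n_species < 4) stop("n_species must be >= 4", call. = FALSE)
  set.seed(seed)
  phy <- ape::rphylo(n_species, birth = 1, death = 0)
  phy$tip.label <- paste0("s", seq_len(n_species))
  phy$edge.length <- NULL
  phy
}

# Simulate one gene tree on a rooted species tree by a top-down walk. The
# lineage entering a branch is first subject to loss, then duplicates
# Pois(dup_rate) times on the branch; each duplication produces a fresh copy
# that continues independently from the bottom of the branch (further
# within-branch duplications of new copies are not modelled). Events are
# recorded with the surviving species sets of their two post-duplication
# subtrees. Assumes the RNG state is already set by the caller.
.sim_gene_tree <- function(sp, cfg) {
  ntip <- ape::Ntip(sp)
  children <- vector("list", ntip + sp$Nnode)
  for (i in seq_len(nrow(sp$edge))) {
    children[[sp$edge[i, 1]]] <- c(children[[sp$edge[i, 1]]], sp$edge[i, 2])
  }
  root <- setdiff(sp$edge[, 1], sp$edge[, 2])[1]

  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  events <- list()

  # lineage at species-tree node 'v' (bottom of the branch into v)
  continue_below <- function(v) {
    if (v <= ntip) {
      counter$k <- counter$k + 1L
      lab <- paste0(sp$tip.label[v], "_", counter$k)
      return(list(nwk = lab, sp = v))
    }
    parts <- lapply(children[[v]], descend)
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (length(parts) == 0) return(NULL)
    if (length(parts) == 1) return(parts[[1]])
    list(nwk = paste0("(", parts[[1]]$nwk, ",", parts[[2]]$nwk, ")"),
         sp = union(parts[[1]]$sp, parts[[2]]$sp))
  }

  # lineage entering the branch leading to species-tree node 'v'
  descend <- function(v) {
    if (stats::runif(1) < cfg$loss_prob) return(NULL)
    k <- stats::rpois(1, cfg$dup_rate)
    copies <- lapply(seq_len(k + 1), function(i) continue_below(v))
    # fold the copies into a pectinate subtree; event i joins copy i with
    # the chain of copies i+1 .. k+1
    sub <- copies[[k + 1]]
    if (k > 0) {
      for (i in k:1) {
        ci <- copies[[i]]
        if (!is.null(ci) && !is.null(sub)) {
          events[[length(events) + 1]] <<- list(
            sp_node = v, sp1 = ci$sp, sp2 = sub$sp)
          sub <- list(nwk = paste0("(", ci$nwk, ",", sub$nwk, ")"),
                      sp = union(ci$sp, sub$sp))
        } else if (is.null(sub)) {
          sub <- ci
        }
      }
    }
    sub
  }

  top <- lapply(children[[root]], descend)
  top <- top[!vapply(top, is.null, TRUE)]
  if (length(top) == 0 || counter$k < 2) {
    return(list(newick = NULL, events = events))
  }
  nwk <- if (length(top) == 1) top[[1]]$nwk else
    paste0("(", top[[1]]$nwk, ",", top[[2]]$nwk, ")")
  list(newick = paste0(nwk, ";"), events = events)
}

#' Simulate a duplication-loss gene-tree dataset with ground truth
#'
#' Simulates a rooted Yule species tree and a set of gene trees evolving on
#' it by duplication and loss. Each duplication surviving in both copies and
#' observed in at least two species is logged as ground truth at the branch
#' of the smallest rooted clade containing the surviving species of both
#' copies, i.e. at the clade where the event remains phylogenetically
#' observable after loss. Gene trees are emitted unrooted; optional NNI noise
#' is applied after logging. Gene trees in which fewer than two genes survive
#' are omitted (and counted in `n_omitted`).
#'
#' @param cfg A [sim_config()].
#' @return A list: `cfg`, `species_tree_rooted` (phylo), `st`
#'   ([species_tree()] of the unrooted topology), `true_root_branch` (branch
#'   id of the root branch in the unrooted tree), `gene_trees` (list of
#'   [gene_tree()]), `truth` (data frame `gene_tree_id`, `branch_id`,
#'   `dup_block`), `n_omitted`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  sp_rooted <- simulate_species_tree(cfg$n_species, cfg$seed)
  st <- species_tree(sp_rooted)

  # the root branch of the unrooted tree = the bipartition of the root split
  root <- setdiff(sp_rooted$edge[, 1], sp_rooted$edge[, 2])[1]
  kids <- sp_rooted$edge[sp_rooted$edge[, 1] == root, 2]
  clade1 <- if (kids[1] <= ape::Ntip(sp_rooted)) {
    sp_rooted$tip.label[kids[1]]
  } else {
    ape::extract.clade(sp_rooted, kids[1])$tip.label
  }
  block <- st$species %in% clade1
  tr <- .smallest_block(block, st)
  true_root_branch <- tr$branch_id

  rooted_cache <- .edge_cache(sp_rooted, seq_len(ape::Ntip(sp_rooted)),
                              ape::Ntip(sp_rooted))

  set.seed(cfg$seed)
  tree_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_gene_trees)

  gene_trees <- vector("list", cfg$n_gene_trees)
  truth_rows <- vector("list", cfg$n_gene_trees)
  n_omitted <- 0L
  rule <- mapping_rule("delimiter", delimiter = "_")
  for (i in seq_len(cfg$n_gene_trees)) {
    set.seed(tree_seeds[i])
    sim <- .sim_gene_tree(sp_rooted, cfg)
    id <- sprintf("tree_%04d", i)
    if (is.null(sim$newick)) {
      n_omitted <- n_omitted + 1L
      next
    }
    phy <- parse_newick(sim$newick, kind = "gene")
    if (cfg$nni_noise > 0 && ape::Ntip(phy) >= 4 &&
        stats::runif(1) < cfg$nni_noise) {
      phy <- phangorn::rNNI(phy, moves = 1)
    }
    gene_trees[[i]] <- gene_tree(phy, st, mapping = rule, id = id)
    truth_rows[[i]] <- .truth_events(sim$events, id, st, sp_rooted,
                                     rooted_cache)
  }
  gene_trees <- gene_trees[!vapply(gene_trees, is.null, TRUE)]
  truth <- do.call(rbind, c(list(data.frame(gene_tree_id = character(),
                                            branch_id = integer(),
                                            dup_block = character(),
                                            stringsAsFactors = FALSE)),
                            truth_rows))
  rownames(truth) <- NULL
  list(cfg = cfg, species_tree_rooted = sp_rooted, st = st,
       true_root_branch = true_root_branch, gene_trees = gene_trees,
       truth = truth, n_omitted = n_omitted)
}

# Convert raw simulated events (surviving species-tree tip ids per copy) to
# observable ground truth: both copies survive and the union of survivors
# covers >= 2 species. The event is logged at the smallest rooted clade
# containing the surviving species (found by walking down from the branch
# the event occurred on), i.e. where a loss-aware mapping of the event is
# placed; every proper rooted clade is a block of the unrooted tree, so the
# lookup of its branch is exact and unique.
.truth_events <- function(events, id, st, sp_rooted, rooted_cache) {
  ntip <- ape::Ntip(sp_rooted)
  rows <- list()
  for (ev in events) {
    u <- union(ev$sp1, ev$sp2)
    if (length(ev$sp1) == 0 || length(ev$sp2) == 0 || length(u) < 2) next
    u_log <- seq_len(ntip) %in% u
    v <- ev$sp_node
    repeat {
      ch <- rooted_cache$children[[v]]
      nxt <- ch[vapply(ch, function(c) !any(u_log & !rooted_cache$down[c, ]),
                       TRUE)]
      if (length(nxt) != 1) break
      v <- nxt
    }
    species <- sp_rooted$tip.label[rooted_cache$down[v, ]]
    beta <- .smallest_block(st$species %in% species, st)
    rows[[length(rows) + 1]] <- data.frame(
      gene_tree_id = id, branch_id = beta$branch_id, dup_block = beta$side,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Score detected events against simulator ground truth
#'
#' Events are matched with multiplicity by the key (gene tree, species-tree
#' branch, duplicate-containing block). Only informative detected events
#' enter the comparison. With no detected events precision is reported as
#' 1.0 (with a warning) by convention.
#'
#' @param found Event data frame from [find_all_duplications()].
#' @param truth Truth data frame from [simulate_dataset()].
#' @return Named numeric `precision`, `recall`.
#' @export
score_detection <- function(found, truth) {
  found <- found[found$informative, , drop = FALSE]
  key <- function(d) paste(d$gene_tree_id, d$branch_id, d$dup_block, sep = "|")
  fk <- table(key(found))
  tk <- table(key(truth))
  common <- intersect(names(fk), names(tk))
  matched <- sum(pmin(fk[common], tk[common]))
  precision <- if (nrow(found) == 0) {
    warning("no events found; precision reported as 1.0 by convention")
    1.0
  } else matched / nrow(found)
  recall <- if (nrow(truth) == 0) NA_real_ else matched / nrow(truth)
  c(precision = precision, recall = recall)
}

#' Write a simulated dataset to a directory
#'
#' Writes `species_tree.nwk` (unrooted), `species_tree_rooted.nwk` (with the
#' true root), `gene_trees/tree_NNNN.nwk`, `truth_events.tsv` and
#' `config.json`.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "gene_trees"), recursive = TRUE,
             showWarnings = FALSE)
  write_newick(dataset$st$phy, file.path(dir, "species_tree.nwk"))
  write_newick(dataset$species_tree_rooted,
               file.path(dir, "species_tree_rooted.nwk"))
  for (gt in dataset$gene_trees) {
    write_newick(gt$phy, file.path(dir, "gene_trees", paste0(gt$id, ".nwk")))
  }
  utils::write.table(dataset$truth,
                     file.path(dir, "truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$cfg
  jsonlite::write_json(
    c(unclass(cfg), list(true_root_branch = dataset$true_root_branch,
                         n_omitted = dataset$n_omitted)),
    file.path(dir, "config.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
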