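# Independent oracles used to check the optimized implementations, plus small
# fixture builders. Everything here recomputes quantities from first
# principles (component splits, exhaustive enumeration, numerical quadrature)
# and stays independent of the code paths under test.

# Species set on u's side of edge {v, u}, by brute-force component search.
naive_side_species <- function(phy, species_idx, v, u) {
  n_node <- ape::Ntip(phy) + phy$Nnode
  adj <- vector("list", n_node)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- rep(FALSE, n_node)
  seen[v] <- TRUE  # block passage through v
  stack <- u; seen[u] <- TRUE
  comp <- c()
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    comp <- c(comp, x)
    for (y in adj[[x]]) if (!seen[y]) { seen[y] <- TRUE; stack <- c(stack, y) }
  }
  sort(unique(species_idx[comp[comp <= ape::Ntip(phy)]]))
}

# All blocks of a species tree as character vectors, from the public table.
all_blocks <- function(st) {
  bp <- bipartitions(st)
  out <- list()
  for (i in seq_len(nrow(bp))) {
    out[[2 * i - 1]] <- strsplit(bp$block_a[i], ";", fixed = TRUE)[[1]]
    out[[2 * i]] <- strsplit(bp$block_b[i], ";", fixed = TRUE)[[1]]
  }
  out
}

# Exhaustive smallest containing block: returns the species vector or NULL.
oracle_smallest_block <- function(S, st) {
  blocks <- all_blocks(st)
  containing <- Filter(function(b) all(S %in% b), blocks)
  if (length(containing) == 0) return(NULL)
  sizes <- lengths(containing)
  if (sum(sizes == min(sizes)) != 1) return(NULL)
  containing[[which.min(sizes)]]
}

# Brute-force maximum-parsimony root: per candidate branch, count events whose
# duplicate block properly contains one of the candidate's blocks.
oracle_mp_scores <- function(events, st) {
  bp <- bipartitions(st)
  blocks <- all_blocks(st)
  ev <- events[events$informative, , drop = FALSE]
  ev_blocks <- lapply(seq_len(nrow(ev)), function(i) {
    blocks[[2 * ev$branch_id[i] - (ev$dup_block[i] == "a")]]
  })
  vapply(seq_len(st$b), function(j) {
    mine <- list(blocks[[2 * j - 1]], blocks[[2 * j]])
    sum(vapply(ev_blocks, function(B) {
      any(vapply(mine, function(blk)
        length(blk) < length(B) && all(blk %in% B), TRUE))
    }, TRUE))
  }, 0)
}

# Numerical quadrature of the root-orientation likelihood integral, using the
# binomially collapsed integrand Po(m; x*lam + (1-x)*a*lam) *
# Po(n; (1-x)*lam + x*a*lam).
quad_root_likelihood <- function(m, n, alpha) {
  lam <- (m + n) / (1 + alpha)
  f <- function(x) {
    stats::dpois(m, x * lam + (1 - x) * alpha * lam) *
      stats::dpois(n, (1 - x) * lam + x * alpha * lam)
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-13, abs.tol = 0)$value
}

# Direct transcription of the double-sum integrand (no binomial collapse).
quad_root_likelihood_direct <- function(m, n, alpha) {
  lam <- (m + n) / (1 + alpha)
  f <- function(xv) {
    vapply(xv, function(x) {
      acc <- 0
      for (s in 0:m) for (t in 0:n) {
        acc <- acc + stats::dpois(m - s, x * lam) *
          stats::dpois(t, x * alpha * lam) *
          stats::dpois(n - t, (1 - x) * lam) *
          stats::dpois(s, (1 - x) * alpha * lam)
      }
      acc
    }, 0)
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-13, abs.tol = 0)$value
}

# Fixture: the four-species tree of the worked example, with an event list
# built from named blocks.
toy_species_tree <- function() species_tree("((elephant,dog),(bird,fish));")

events_from_blocks <- function(block_list, st) {
  rows <- lapply(seq_along(block_list), function(i) {
    key <- paste(sort(block_list[[i]]), collapse = ";")
    j <- which(st$branches$block_a == key | st$branches$block_b == key)
    stopifnot(length(j) == 1)
    data.frame(gene_tree_id = sprintf("ev%02d", i), node_id = i,
               branch_id = j,
               dup_block = if (st$branches$block_a[j] == key) "a" else "b",
               species_observed = key,
               n_species = length(block_list[[i]]),
               informative = length(block_list[[i]]) >= 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Random gene tree over the species of st: random topology, each tip assigned
# a random species (possibly repeated).
random_gene_tree <- function(st, n_genes, id = "rand") {
  phy <- ape::rtree(n_genes)
  sp <- sample(st$species, n_genes, replace = TRUE)
  phy$tip.label <- paste0(sp, "_g", seq_len(n_genes))
  gene_tree(phy, st, id = id)
}
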