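#' Parse a Newick tree
#'
#' Parses a single Newick statement into an unrooted `phylo` object. Branch
#' lengths, internal node labels (e.g. support values) and square-bracket
#' comments (NHX annotations) are accepted and discarded: only the topology is
#' retained. A rooted (bifurcating-at-the-root) tree is unrooted by collapsing
#' the degree-2 root node.
#'
#' @param text A Newick statement terminated by `";"`.
#' @param kind `"gene"` or `"species"`. Species trees additionally log a
#'   message when a rooted input is unrooted; structural validation of species
#'   trees (binary, >= 4 taxa) happens in [species_tree()].
#' @return An unrooted `phylo` object without branch lengths or node labels.
#' @examples
#' parse_newick("((A:1,B:2)0.99:3,C:1,D:1);")
#' @export
parse_newick <- function(text, kind = c("gene", "species")) {
  kind <- match.arg(kind)
  txt <- trimws(gsub("\\[[^][]*\\]", "", text))
  if (!nzchar(txt)) stop("empty Newick string", call. = FALSE)
  if (!grepl(";", txt, fixed = TRUE)) {
    stop("Newick statement must be terminated by ';'", call. = FALSE)
  }
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0)) {
    stop("malformed Newick: unmatched ')' at position ",
         which(depth < 0)[1], call. = FALSE)
  }
  if (depth[length(depth)] != 0) {
    stop("malformed Newick: ", depth[length(depth)],
         " unclosed '(' at end of statement", call. = FALSE)
  }
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick statement: ", substr(txt, 1, 60),
                         if (nchar(txt) > 60) "..." else "", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  phy$node.label <- NULL
  phy$edge.length <- NULL
  if (ape::Ntip(phy) >= 3 && ape::is.rooted(phy)) {
    if (kind == "species") {
      message("species tree input is rooted; unrooting (root placement ignored)")
    }
    phy <- ape::unroot(phy)
  }
  phy
}

#' Write a tree as Newick
#'
#' @param phy A `phylo` object, or a [species_tree()] (its topology is used).
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(phy, file = NULL) {
  if (inherits(phy, "duproot_species_tree")) phy <- phy$phy
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Read a tree from a file path, a Newick string, or pass through a phylo.
.as_phylo <- function(x, kind) {
  if (inherits(x, "phylo")) {
    phy <- x
    phy$node.label <- NULL
    phy$edge.length <- NULL
    if (ape::Ntip(phy) >= 3 && ape::is.rooted(phy)) phy <- ape::unroot(phy)
    return(phy)
  }
  if (length(x) == 1 && !grepl("[(;]", x) || (length(x) == 1 && file.exists(x))) {
    x <- paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x <- paste(x, collapse = "")
  }
  parse_newick(x, kind = kind)
}

# Rooted-traversal cache for an unrooted phylo: for every directed edge
# (v -> u) the species membership of the subtree on u's side. Sets are logical
# vectors over 1..n_species. 'down[u, ]' is the set below node u with respect
# to the arbitrary phylo root; 'up[v, ]' the set on the parent side of v.
.edge_cache <- function(phy, tip_species, n_species) {
  E <- phy$edge
  n_node <- ape::Ntip(phy) + phy$Nnode
  parent <- rep(NA_integer_, n_node)
  parent[E[, 2]] <- E[, 1]
  children <- vector("list", n_node)
  for (i in seq_len(nrow(E))) {
    children[[E[i, 1]]] <- c(children[[E[i, 1]]], E[i, 2])
  }
  root <- E[1, 1]
  while (!is.na(parent[root])) root <- parent[root]

  down <- matrix(FALSE, n_node, n_species)
  ntip <- ape::Ntip(phy)
  down[cbind(seq_len(ntip), tip_species)] <- TRUE
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    down[po[i, 1], ] <- down[po[i, 1], ] | down[po[i, 2], ]
  }

  up <- matrix(FALSE, n_node, n_species)
  for (i in rev(seq_len(nrow(po)))) {      # preorder over edges
    p <- po[i, 1]; ch <- children[[p]]
    sib <- ch[ch != po[i, 2]]
    acc <- up[p, ]
    for (s in sib) acc <- acc | down[s, ]
    up[po[i, 2], ] <- acc
  }

  neighbours <- lapply(seq_len(n_node), function(v) {
    nb <- children[[v]]
    if (!is.na(parent[v])) nb <- c(nb, parent[v])
    nb
  })
  dir_set <- function(v, u) {
    if (!is.na(parent[v]) && parent[v] == u) up[v, ] else down[u, ]
  }
  list(down = down, up = up, parent = parent, children = children,
       root = root, neighbours = neighbours, dir_set = dir_set)
}

# Child and grandchild species sets of the subtree induced by a block. The
# block-side subtree is rooted at v, reached from u across the block's branch.
# A child clade that is a single leaf has its two grandchild slots collapsed
# to that leaf's singleton set.
.grandchild_info <- function(v, u, cache, ntip) {
  if (v <= ntip) {
    sing <- cache$down[v, , drop = TRUE]
    return(list(X = sing, Y = sing, gc = list(sing)))
  }
  ws <- setdiff(cache$neighbours[[v]], u)
  stopifnot(length(ws) == 2)
  X <- cache$dir_set(v, ws[1])
  Y <- cache$dir_set(v, ws[2])
  gc_of <- function(w) {
    if (w <= ntip) return(list(cache$down[w, , drop = TRUE]))
    zs <- setdiff(cache$neighbours[[w]], v)
    lapply(zs, function(z) cache$dir_set(w, z))
  }
  gcl <- c(gc_of(ws[1]), gc_of(ws[2]))
  keys <- vapply(gcl, function(g) paste(which(g), collapse = "."), "")
  list(X = X, Y = Y, gc = gcl[!duplicated(keys)])
}

#' Build an indexed species tree
#'
#' Constructs the package's species-tree object from an unrooted binary
#' topology: the `2t - 3` branches are enumerated as bipartitions of the
#' species set, assigned stable identifiers by canonical block ordering
#' (the block containing the alphabetically first species is `block_a`, and
#' branches are sorted by the `block_a` species key), and indexed so that
#' block containment queries used throughout duplication detection and root
#' inference are simple matrix lookups.
#'
#' @param x A `phylo` object, a Newick string, or a path to a Newick file.
#'   Rooted input is unrooted; branch lengths and node labels are ignored.
#' @return An object of class `duproot_species_tree` with elements including
#'   `phy` (unrooted topology), `species` (sorted labels), `t`, `b`, and the
#'   branch table (see [bipartitions()]).
#' @examples
#' st <- species_tree("((A,B),(C,D));")
#' st$b  # 5 branches for 4 species
#' @export
species_tree <- function(x) {
  phy <- .as_phylo(x, kind = "species")
  t <- ape::Ntip(phy)
  if (t < 4) stop("species tree must have at least 4 taxa", call. = FALSE)
  deg <- tabulate(phy$edge, nbins = t + phy$Nnode)
  if (any(deg[(t + 1):(t + phy$Nnode)] != 3)) {
    stop("species tree must be binary: every internal node must have degree 3",
         call. = FALSE)
  }
  species <- sort(phy$tip.label, method = "radix")
  tipsp <- match(phy$tip.label, species)
  cache <- .edge_cache(phy, tipsp, t)

  E <- phy$edge
  b <- nrow(E)
  stopifnot(b == 2 * t - 3)

  # one bipartition per edge; block_a = block containing species[1]
  blocks_a <- matrix(FALSE, b, t)
  blocks_b <- matrix(FALSE, b, t)
  v_a <- u_a <- v_b <- u_b <- integer(b)
  for (i in seq_len(b)) {
    below <- cache$down[E[i, 2], ]
    if (below[1]) {
      blocks_a[i, ] <- below;  v_a[i] <- E[i, 2]; u_a[i] <- E[i, 1]
      blocks_b[i, ] <- !below; v_b[i] <- E[i, 1]; u_b[i] <- E[i, 2]
    } else {
      blocks_a[i, ] <- !below; v_a[i] <- E[i, 1]; u_a[i] <- E[i, 2]
      blocks_b[i, ] <- below;  v_b[i] <- E[i, 2]; u_b[i] <- E[i, 1]
    }
  }
  key_a <- apply(blocks_a, 1, block_key, species = species)
  key_b <- apply(blocks_b, 1, block_key, species = species)
  ord <- radix_order(key_a)
  blocks_a <- blocks_a[ord, , drop = FALSE]
  blocks_b <- blocks_b[ord, , drop = FALSE]
  key_a <- key_a[ord]; key_b <- key_b[ord]
  v_a <- v_a[ord]; u_a <- u_a[ord]; v_b <- v_b[ord]; u_b <- u_b[ord]

  # rows 2i-1 and 2i of the block matrix are block_a and block_b of branch i
  block_mat <- matrix(FALSE, 2 * b, t)
  block_mat[seq(1, 2 * b, by = 2), ] <- blocks_a
  block_mat[seq(2, 2 * b, by = 2), ] <- blocks_b
  block01 <- block_mat + 0
  block_sizes <- rowSums(block_mat)

  # sub_proper[r1, r2]: block r1 is a proper subset of block r2
  inter <- block01 %*% t(block01)
  sub_proper <- (inter == block_sizes) & outer(block_sizes, block_sizes, `<`)

  # branch_in_block[j, r]: branch j lies strictly inside the subtree of block r
  ia <- seq(1, 2 * b, by = 2); ib <- seq(2, 2 * b, by = 2)
  branch_in_block <- sub_proper[ia, , drop = FALSE] |
    sub_proper[ib, , drop = FALSE]

  # inside_a[j, k]: branch k lies on the block_a side of branch j (j != k)
  inside_a <- matrix(FALSE, b, b)
  for (k in seq_len(b)) {
    inside_a[, k] <- sub_proper[2 * k - 1, ia] | sub_proper[2 * k, ia]
  }

  gc_info <- vector("list", 2 * b)
  for (i in seq_len(b)) {
    gc_info[[2 * i - 1]] <- .grandchild_info(v_a[i], u_a[i], cache, t)
    gc_info[[2 * i]] <- .grandchild_info(v_b[i], u_b[i], cache, t)
  }

  size_a <- block_sizes[ia]; size_b <- block_sizes[ib]
  is_terminal <- size_a == 1 | size_b == 1
  terminal_species <- ifelse(size_a == 1, apply(blocks_a, 1, which.max),
                             ifelse(size_b == 1, apply(blocks_b, 1, which.max),
                                    NA_integer_))
  branches <- data.frame(
    branch_id = seq_len(b),
    block_a = key_a, block_b = key_b,
    size_a = size_a, size_b = size_b,
    is_terminal = is_terminal,
    terminal_species = ifelse(is_terminal, species[terminal_species], NA),
    stringsAsFactors = FALSE
  )

  structure(list(
    phy = phy, species = species, t = t, b = b,
    branches = branches,
    block_mat = block_mat, block01 = block01, block_sizes = block_sizes,
    sub_proper = sub_proper, branch_in_block = branch_in_block,
    inside_a = inside_a, gc_info = gc_info
  ), class = "duproot_species_tree")
}

#' @export
print.duproot_species_tree <- function(x, ...) {
  cat("Unrooted species tree:", x$t, "species,", x$b, "branches\n")
  cat("Species:", paste(utils::head(x$species, 8), collapse = ", "),
      if (x$t > 8) "..." else "", "\n")
  invisible(x)
}

#' Bipartitions of a species tree
#'
#' Every branch of an unrooted species tree splits the species set into two
#' blocks. Branch ids are assigned by canonical block ordering and are stable
#' across runs and input rotations.
#'
#' @param st A [species_tree()].
#' @return A data frame with one row per branch: `branch_id`, `block_a`,
#'   `block_b` (semicolon-joined species), block sizes, and `is_terminal`.
#' @export
bipartitions <- function(st) {
  stopifnot(inherits(st, "duproot_species_tree"))
  st$branches
}

# Logical membership vector of one block of one branch.
.block_of <- function(st, branch_id, side) {
  st$block_mat[2 * branch_id - (side == "a"), , drop = TRUE]
}

.block_row <- function(branch_id, side) 2L * branch_id - (side == "a")
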