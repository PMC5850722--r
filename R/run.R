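#' Infer the root of a species tree from gene duplication events
#'
#' The full pipeline on in-memory objects: detect well-supported duplication
#' events in every gene tree, aggregate them onto species-tree branches, find
#' the maximum-parsimony root, estimate the model parameters (relative
#' false-positive rate `alpha` from the conflict ratio, terminal inward
#' rates), and compute the posterior probability of each branch spanning the
#' root.
#'
#' @param st A [species_tree()].
#' @param gene_trees List of [gene_tree()] objects.
#' @param params A [model_params()]; a fixed `alpha` overrides estimation.
#' @return A `duproot_result` list: `events`, `counts`, `parsimony`
#'   (see [mp_roots()]), `alpha`, `terminal_rates`, `distribution`
#'   (see [root_distribution()]), and summary tallies.
#' @examples
#' st <- species_tree("((A,B),(C,D));")
#' gt <- gene_tree("((A_1,B_1),(A_2,B_2));", st, id = "og1")
#' res <- root_inference(st, list(gt))
#' res$distribution
#' @export
root_inference <- function(st, gene_trees, params = model_params()) {
  stopifnot(inherits(st, "duproot_species_tree"))
  events <- find_all_duplications(gene_trees, st)
  counts <- aggregate_counts(events, st)
  pars <- mp_roots(events, st)
  alpha <- if (!is.null(params$alpha)) {
    max(params$alpha, params$alpha_floor)
  } else {
    estimate_alpha(pars$n_conflicting, pars$n_nonconflicting,
                   params$alpha_floor)
  }
  terminal_rates <- estimate_terminal_rates(counts, pars$plateau, st,
                                            pars$n_nonconflicting,
                                            params$rate_floor)
  dist <- root_distribution(counts, st, alpha, terminal_rates)
  structure(list(
    st = st, events = events, counts = counts, parsimony = pars,
    alpha = alpha, terminal_rates = terminal_rates, distribution = dist,
    n_gene_trees = length(gene_trees),
    n_events = nrow(events),
    n_informative = sum(events$informative),
    n_single_species = sum(!events$informative),
    n_conflicting = pars$n_conflicting,
    discarded = attr(events, "discarded")
  ), class = "duproot_result")
}

#' @export
print.duproot_result <- function(x, ...) {
  cat("Species tree root inference\n")
  cat(sprintf("  %d gene trees; %d duplication events (%d informative, %d single-species)\n",
              x$n_gene_trees, x$n_events, x$n_informative, x$n_single_species))
  cat(sprintf("  conflicting events at MP root: %d; alpha = %.3g\n",
              x$n_conflicting, x$alpha))
  pl <- x$parsimony$plateau
  cat(sprintf("  maximum-parsimony root branch%s: %s\n",
              if (length(pl) > 1) "es (plateau)" else "",
              paste(pl, collapse = ", ")))
  top <- which.max(x$distribution$p_root)
  cat(sprintf("  most probable root: branch %d (%s | %s), p = %.4f\n",
              top, x$distribution$block_a[top], x$distribution$block_b[top],
              x$distribution$p_root[top]))
  invisible(x)
}

# Species tree rooted on a given branch of its unrooted topology, with the
# per-branch root probabilities stored as branch lengths (terminal branches
# cannot carry labels in plain Newick; both root edges carry the root
# branch's probability).
.annotated_tree <- function(st, dist, root_branch) {
  phy <- st$phy
  j <- root_branch
  side <- if (st$branches$size_a[j] <= st$branches$size_b[j]) "a" else "b"
  block <- st$species[.block_of(st, j, side)]
  rooted <- ape::root(phy, outgroup = block, resolve.root = TRUE)
  cache <- .edge_cache(rooted, match(rooted$tip.label, st$species), st$t)
  el <- numeric(nrow(rooted$edge))
  for (i in seq_len(nrow(rooted$edge))) {
    blk <- cache$down[rooted$edge[i, 2], ]
    beta <- .smallest_block(blk, st)
    el[i] <- if (is.null(beta)) NA_real_ else dist$p_root[beta$branch_id]
  }
  rooted$edge.length <- el
  rooted
}

#' Run root inference from files and write the result artifacts
#'
#' Reads a species tree and a directory (or explicit list) of gene-tree
#' Newick files, runs [root_inference()], and writes: `events.tsv`,
#' `branch_scores.tsv` (parsimony score table), `root_distribution.tsv`, an
#' annotated Newick rooted on the most probable branch with per-branch root
#' probabilities as branch lengths (`species_tree_annotated.nwk`), and
#' `summary.json`. Gene trees whose genes map to species missing from the
#' species tree are skipped with a warning; failing to parse any gene tree
#' is an error.
#'
#' @param species_tree_file Newick file with the unrooted species tree.
#' @param gene_tree_dir Directory of gene-tree Newick files (`*.nwk`,
#'   `*.tree`, `*.txt`, `*.newick`), or a character vector of file paths.
#' @param out_dir Output directory, created if needed; `NULL` writes nothing.
#' @param mapping A [mapping_rule()].
#' @param params A [model_params()].
#' @return The `duproot_result`, invisibly when `out_dir` is given.
#' @export
run_root_inference <- function(species_tree_file, gene_tree_dir,
                               out_dir = NULL,
                               mapping = mapping_rule(),
                               params = model_params()) {
  st <- species_tree(species_tree_file)
  files <- if (length(gene_tree_dir) == 1 && dir.exists(gene_tree_dir)) {
    sort(list.files(gene_tree_dir, full.names = TRUE,
                    pattern = "\\.(nwk|newick|tree|txt)$"), method = "radix")
  } else {
    gene_tree_dir
  }
  if (length(files) == 0) {
    stop("no gene tree files found in ", gene_tree_dir, call. = FALSE)
  }
  gts <- list()
  n_skipped <- 0L
  for (f in files) {
    gt <- tryCatch(gene_tree(f, st, mapping = mapping),
                   error = function(e) {
                     warning("skipping '", basename(f), "': ",
                             conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (is.null(gt)) n_skipped <- n_skipped + 1L else gts[[length(gts) + 1]] <- gt
  }
  if (length(gts) == 0) stop("no gene trees could be parsed", call. = FALSE)
  res <- root_inference(st, gts, params = params)
  res$n_skipped <- n_skipped
  if (is.null(out_dir)) return(res)
  write_result(res, out_dir)
  invisible(res)
}

#' Write result artifacts for a finished inference
#'
#' @param res A `duproot_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ev <- res$events
  blk <- ifelse(ev$dup_block == "a",
                res$st$branches$block_a[ev$branch_id],
                res$st$branches$block_b[ev$branch_id])
  ev_out <- data.frame(gene_tree_id = ev$gene_tree_id, node_id = ev$node_id,
                       branch_id = ev$branch_id,
                       dup_block = blk,
                       species_observed = ev$species_observed,
                       n_species_observed = ev$n_species,
                       informative = ev$informative,
                       stringsAsFactors = FALSE)
  utils::write.table(ev_out, file.path(out_dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$parsimony$scores,
                     file.path(out_dir, "branch_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$distribution,
                     file.path(out_dir, "root_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  top <- which.max(res$distribution$p_root)
  ann <- .annotated_tree(res$st, res$distribution, top)
  write_newick(ann, file.path(out_dir, "species_tree_annotated.nwk"))
  summary <- list(
    n_species = res$st$t,
    n_branches = res$st$b,
    n_gene_trees = res$n_gene_trees,
    n_skipped = if (is.null(res$n_skipped)) 0L else res$n_skipped,
    n_events = res$n_events,
    n_informative = res$n_informative,
    n_single_species = res$n_single_species,
    n_conflicting = res$n_conflicting,
    alpha = res$alpha,
    lambda_term_tp = unname(res$terminal_rates[["lambda_tp"]]),
    lambda_term_fp = unname(res$terminal_rates[["lambda_fp"]]),
    mp_roots = res$parsimony$plateau,
    mp_root_blocks = res$parsimony$scores$block_a[res$parsimony$plateau],
    max_probability_branch = top,
    max_probability = res$distribution$p_root[top],
    discarded_candidates = res$discarded
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate a dataset and write it to disk
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @return The dataset (see [simulate_dataset()]), invisibly.
#' @export
run_simulate <- function(cfg = sim_config(), out_dir) {
  ds <- simulate_dataset(cfg)
  write_dataset(ds, out_dir)
  invisible(ds)
}
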