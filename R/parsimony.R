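#' Does a candidate root branch violate a duplication event?
#'
#' A duplication event with duplicates in block `B` is evidence that `B` is a
#' monophyletic clade, which excludes the root from the interior of `B`'s
#' subtree. A candidate branch violates the event exactly when one of its own
#' blocks is a proper subset of `B`. The event's own branch never violates:
#' if the root spans that branch, both of its blocks are clades.
#'
#' @param candidate_branch Branch id of the candidate root.
#' @param event One row of the event data frame (needs `branch_id`,
#'   `dup_block`), or a list with those elements.
#' @param st A [species_tree()].
#' @return Logical.
#' @export
violates <- function(candidate_branch, event, st) {
  r <- .block_row(event$branch_id, event$dup_block)
  st$branch_in_block[candidate_branch, r]
}

#' Maximum-parsimony root of the species tree
#'
#' Scores every branch by the number of informative duplication events it
#' violates and returns the branch (or plateau of tied branches) with the
#' minimum. With no events every branch ties at zero. An event is flagged as
#' conflicting when it is violated by every member of the plateau: such
#' events contradict the maximum-parsimony rooting and are the basis of the
#' false-positive rate estimate used by the probability model.
#'
#' @param events Event data frame from [find_all_duplications()].
#' @param st A [species_tree()].
#' @return A list: `plateau` (branch ids in canonical order), `scores` (data
#'   frame `branch_id`, `block_a`, `block_b`, `n_violations`, `is_mp_root`),
#'   `conflicting` (logical per informative event row), `n_conflicting`,
#'   `n_nonconflicting`.
#' @export
mp_roots <- function(events, st) {
  ev <- events[events$informative, , drop = FALSE]
  rows <- .block_row(ev$branch_id, ev$dup_block)
  cnt <- tabulate(rows, nbins = 2 * st$b)
  n_viol <- as.vector(st$branch_in_block %*% cnt)
  plateau <- which(n_viol == min(n_viol))

  if (nrow(ev) > 0) {
    viol_sub <- st$branch_in_block[plateau, rows, drop = FALSE]
    conflicting <- apply(viol_sub, 2, all)
  } else {
    conflicting <- logical(0)
  }
  scores <- data.frame(
    branch_id = seq_len(st$b),
    block_a = st$branches$block_a,
    block_b = st$branches$block_b,
    n_violations = n_viol,
    is_mp_root = seq_len(st$b) %in% plateau,
    stringsAsFactors = FALSE
  )
  list(plateau = plateau, scores = scores, conflicting = conflicting,
       n_conflicting = sum(conflicting),
       n_nonconflicting = sum(!conflicting))
}
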