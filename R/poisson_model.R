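#' Model parameters for the root probability model
#'
#' @param alpha Optional fixed relative false-positive rate; when `NULL` it
#'   is estimated from the conflict ratio at the maximum-parsimony root (see
#'   [estimate_alpha()]).
#' @param alpha_floor Lower bound on `alpha`. A zero false-positive rate
#'   would make any conflicting observation impossible (probability zero)
#'   and destroy normalization, so a small positive floor is enforced.
#' @param rate_floor Lower bound on the terminal-branch Poisson rates, for
#'   the same reason.
#' @return A `duproot_params` list.
#' @export
model_params <- function(alpha = NULL, alpha_floor = 1e-6, rate_floor = 1e-6) {
  stopifnot(alpha_floor > 0, rate_floor > 0,
            is.null(alpha) || alpha >= 0)
  structure(list(alpha = alpha, alpha_floor = alpha_floor,
                 rate_floor = rate_floor),
            class = "duproot_params")
}

#' Poisson log probability mass
#'
#' Log of `rate^k exp(-rate) / k!`, with the `rate = 0` boundary handled
#' (`0` when `k = 0`, `-Inf` otherwise).
#'
#' @param k Nonnegative integer count(s).
#' @param rate Nonnegative rate.
#' @return Log probability.
#' @export
poisson_log_pmf <- function(k, rate) stats::dpois(k, rate, log = TRUE)

#' Estimate the relative false-positive rate alpha
#'
#' So as not to reward contradictory duplications by creating an expectation
#' for them, alpha is one tenth of the ratio of conflicting to nonconflicting
#' duplications at the maximum-parsimony root, floored at `alpha_floor`.
#'
#' @param n_conflicting,n_nonconflicting Event counts from [mp_roots()].
#' @param alpha_floor Numerical floor (default from [model_params()]).
#' @return Scalar alpha.
#' @examples
#' estimate_alpha(5, 20)   # 0.025
#' @export
estimate_alpha <- function(n_conflicting, n_nonconflicting,
                           alpha_floor = 1e-6) {
  if (n_nonconflicting == 0) return(alpha_floor)
  max(alpha_floor, (n_conflicting / n_nonconflicting) / 10)
}

#' Branch-level log-likelihoods of the three orientations
#'
#' Duplication counts `(m, n)` on a branch are modelled as draws from two
#' Poisson processes, true positives at rate `lambda` and false positives at
#' rate `alpha * lambda`, with `lambda = N / (1 + alpha)` and `N = m + n` so
#' that the total expected count matches the observation. Under orientation
#' "left" (the `m` direction is true) the likelihood is
#' `Po(m; lambda) Po(n; alpha lambda)`; "right" is the mirror image. A
#' root-spanning branch corresponds to two branches of the rooted tree with
#' time flowing in opposite directions away from a root placed a fraction
#' `x` along the branch; integrating `x` over (0, 1) and summing over the
#' unknown split of the counts into true and false positives gives the
#' closed form
#' \deqn{P(d \mid root) = \sum_{s=0}^{m} \sum_{t=0}^{n}
#'   B(m-s+t+1,\; n-t+s+1)\, e^{-\lambda(1+\alpha)}
#'   \frac{\lambda^{m-s}}{(m-s)!} \frac{(\alpha\lambda)^t}{t!}
#'   \frac{\lambda^{n-t}}{(n-t)!} \frac{(\alpha\lambda)^s}{s!}}
#' with `B` the beta function. All arithmetic is in log space via log-gamma.
#'
#' @param m,n Counts supporting the two orientations.
#' @param alpha Relative false-positive rate (> 0 recommended; see
#'   [model_params()]).
#' @return Named numeric: `left`, `right`, `root` log-likelihoods.
#' @export
branch_likelihoods <- function(m, n, alpha) {
  N <- m + n
  lam <- if (N == 0) 0 else N / (1 + alpha)
  c(left = poisson_log_pmf(m, lam) + poisson_log_pmf(n, alpha * lam),
    right = poisson_log_pmf(n, lam) + poisson_log_pmf(m, alpha * lam),
    root = .log_root_likelihood(m, n, alpha, lam))
}

.log_root_likelihood <- function(m, n, alpha, lam) {
  if (m + n == 0) return(0)
  la <- log(lam)
  lal <- log(alpha) + la        # -Inf when alpha = 0; guarded below
  s <- 0:m
  S <- matrix(s, m + 1, n + 1)
  Tm <- matrix(0:n, m + 1, n + 1, byrow = TRUE)
  fp <- ifelse(S + Tm == 0, 0, (S + Tm) * lal)   # avoid 0 * -Inf
  terms <- lbeta(m - S + Tm + 1, n - Tm + S + 1) +
    (m - S + n - Tm) * la + fp -
    lgamma(m - S + 1) - lgamma(Tm + 1) - lgamma(n - Tm + 1) - lgamma(S + 1) -
    lam * (1 + alpha)
  logsumexp(terms)
}

#' Posterior over the three orientations of a single internal branch
#'
#' Applies Bayes' rule to [branch_likelihoods()] with the tree priors
#' `P(root) = 1/b` and `P(left) = P(right) = (b - 1) / (2b)`, where
#' `b = 2t - 3` is the number of branches.
#'
#' @param m,n Counts supporting the two orientations.
#' @param alpha Relative false-positive rate.
#' @param b Number of branches of the unrooted species tree.
#' @return Named probabilities `left`, `right`, `root` summing to one.
#' @examples
#' branch_posterior(0, 0, 0.025, 5)   # equals the prior
#' @export
branch_posterior <- function(m, n, alpha, b) {
  lp <- .log_branch_posterior(m, n, alpha, b)
  p <- exp(lp - logsumexp(lp))
  p / sum(p)
}

.log_branch_posterior <- function(m, n, alpha, b) {
  ll <- branch_likelihoods(m, n, alpha)
  lp <- ll + c(log((b - 1) / (2 * b)), log((b - 1) / (2 * b)), log(1 / b))
  lp - logsumexp(lp)
}

#' Terminal-branch log-likelihoods
#'
#' Duplications observed in just one species are uninformative, so terminal
#' branches are modelled through their inward duplications only (events whose
#' duplicate-containing block is the complement of the terminal species).
#' Only two orientations exist: time flowing toward the leaf (the root is
#' elsewhere; inward events are false positives at rate `lambda_fp`) or the
#' root lying on the terminal branch itself (inward events are true positives
#' at rate `lambda_tp`).
#'
#' @param m_inward Count of inward informative events.
#' @param lambda_tp,lambda_fp True/false positive inward rates (see
#'   [estimate_terminal_rates()]).
#' @return Named numeric: `leafward`, `root` log-likelihoods.
#' @export
terminal_branch_likelihoods <- function(m_inward, lambda_tp, lambda_fp) {
  c(leafward = poisson_log_pmf(m_inward, lambda_fp),
    root = poisson_log_pmf(m_inward, lambda_tp))
}

# Terminal branches keep the same per-orientation priors as internal ones
# (P(root) = 1/b, P(orientation) = (b-1)/(2b)): the outward orientation never
# arises for any candidate root and its prior mass cancels in the tree-level
# normalization. This makes the product over branches equivalent to a uniform
# prior over candidate root branches, so a dataset with no events yields the
# uniform root distribution.
.log_terminal_posterior <- function(m_inward, lambda_tp, lambda_fp, b) {
  ll <- terminal_branch_likelihoods(m_inward, lambda_tp, lambda_fp)
  lp <- ll + c(log((b - 1) / (2 * b)), log(1 / b))
  lp - logsumexp(lp)
}

#' Estimate the terminal-branch inward duplication rates
#'
#' The false-positive rate is the mean inward count over terminal branches
#' outside the maximum-parsimony plateau; the true-positive rate is the mean
#' over terminal branches in the plateau, floored at the false-positive rate.
#' When no terminal branch is in the plateau (the usual case, since most
#' roots are internal) the true-positive rate is undetermined by terminal
#' data and falls back to the tree-wide density of nonconflicting events per
#' branch. Both rates are floored at `rate_floor`.
#'
#' @param counts Per-branch counts from [aggregate_counts()].
#' @param plateau Branch ids of the maximum-parsimony plateau.
#' @param st A [species_tree()].
#' @param n_nonconflicting Nonconflicting informative event count (for the
#'   fallback).
#' @param rate_floor Numerical floor.
#' @return Named numeric `lambda_tp`, `lambda_fp`.
#' @export
estimate_terminal_rates <- function(counts, plateau, st, n_nonconflicting,
                                    rate_floor = 1e-6) {
  inward <- .inward_counts(counts, st)
  term <- which(st$branches$is_terminal)
  in_pl <- term[term %in% plateau]
  out_pl <- setdiff(term, in_pl)
  lambda_fp <- max(rate_floor,
                   if (length(out_pl)) mean(inward[match(out_pl, term)]) else 0)
  lambda_tp <- if (length(in_pl)) {
    max(lambda_fp, mean(inward[match(in_pl, term)]))
  } else {
    max(lambda_fp, n_nonconflicting / st$b)
  }
  c(lambda_tp = lambda_tp, lambda_fp = lambda_fp)
}

# Inward informative counts for the terminal branches, in the order of
# which(st$branches$is_terminal). The inward block is the non-singleton one.
.inward_counts <- function(counts, st) {
  term <- which(st$branches$is_terminal)
  vapply(term, function(j) {
    if (st$branches$size_a[j] == 1) counts$n[j] else counts$m[j]
  }, 0)
}

#' Posterior probability distribution for the root over all branches
#'
#' Combines the branch-level orientation posteriors into a tree-level
#' distribution: a candidate root branch `k` fixes the orientation of every
#' other branch `j` (time flows away from the root, so the block of `j` on
#' the far side from `k` must be the monophyletic one), and the posterior for
#' the root being on `k` is proportional to the product over branches of the
#' probability of the implied orientation given that branch's own counts.
#' Terminal branches use the two-orientation inward model. Products are
#' accumulated in log space and normalized by softmax over all `2t - 3`
#' branches.
#'
#' @param counts Per-branch counts from [aggregate_counts()].
#' @param st A [species_tree()].
#' @param alpha Relative false-positive rate.
#' @param terminal_rates Named vector from [estimate_terminal_rates()].
#' @return Data frame `branch_id`, `block_a`, `block_b`, `m`, `n`, `p_root`,
#'   with `p_root` summing to one; the unnormalized log scores are attached
#'   as attribute `"log_scores"`.
#' @export
root_distribution <- function(counts, st, alpha, terminal_rates) {
  b <- st$b
  if (!identical(counts$branch_id, seq_len(b))) {
    counts <- counts[match(seq_len(b), counts$branch_id), , drop = FALSE]
    if (anyNA(counts$branch_id)) {
      stop("counts must cover every branch of the species tree", call. = FALSE)
    }
  }
  is_term <- st$branches$is_terminal
  inward <- .inward_counts(counts, st)

  lp_left <- lp_right <- lp_root <- numeric(b)
  ti <- 0
  for (j in seq_len(b)) {
    if (is_term[j]) {
      ti <- ti + 1
      lp <- .log_terminal_posterior(inward[ti], terminal_rates[["lambda_tp"]],
                                    terminal_rates[["lambda_fp"]], b)
      lp_left[j] <- lp[1]; lp_right[j] <- lp[1]; lp_root[j] <- lp[2]
    } else {
      lp <- .log_branch_posterior(counts$m[j], counts$n[j], alpha, b)
      lp_left[j] <- lp[1]; lp_right[j] <- lp[2]; lp_root[j] <- lp[3]
    }
  }

  # score(k) = lp_root[k] + sum over j != k of the implied orientation.
  # For internal j, root on the block_a side implies block_b is the clade
  # ("right"); terminal branches always take the leafward term.
  away <- ifelse(st$inside_a, rep(lp_right, b), rep(lp_left, b))
  dim(away) <- c(b, b)
  away[is_term, ] <- lp_left[is_term]
  diag(away) <- lp_root
  scores <- colSums(away)

  p <- exp(scores - logsumexp(scores))
  p <- p / sum(p)
  out <- data.frame(branch_id = seq_len(b),
                    block_a = st$branches$block_a,
                    block_b = st$branches$block_b,
                    m = counts$m, n = counts$n, p_root = p,
                    stringsAsFactors = FALSE)
  attr(out, "log_scores") <- scores
  out
}
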