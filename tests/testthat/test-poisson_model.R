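test_that("alpha follows the one-tenth conflict-ratio rule with a floor", {
  expect_equal(estimate_alpha(5, 20), 0.025)
  expect_equal(estimate_alpha(0, 20), 1e-6)
  expect_equal(estimate_alpha(3, 0), 1e-6)
  expect_equal(estimate_alpha(60, 17649), (60 / 17649) / 10)
})

test_that("Poisson pmf handles the zero-rate boundary", {
  expect_equal(poisson_log_pmf(0, 0), 0)
  expect_equal(poisson_log_pmf(3, 0), -Inf)
  expect_equal(poisson_log_pmf(2, 1), log(exp(-1) / 2))
  # large counts remain finite through log-gamma
  expect_equal(poisson_log_pmf(2000, 1950),
               2000 * log(1950) - 1950 - lgamma(2001))
})

test_that("root-orientation likelihood matches quadrature of its integral", {
  for (mn in list(c(0, 0), c(1, 0), c(3, 2), c(7, 7), c(20, 5))) {
    for (a in c(0.01, 0.5)) {
      lr <- branch_likelihoods(mn[1], mn[2], a)[["root"]]
      if (mn[1] + mn[2] == 0) {
        expect_equal(lr, 0)
      } else {
        expect_equal(exp(lr), quad_root_likelihood(mn[1], mn[2], a),
                     tolerance = 1e-10)
      }
    }
  }
  # direct double-sum transcription of the integrand, small cases
  expect_equal(exp(branch_likelihoods(3, 2, 0.1)[["root"]]),
               quad_root_likelihood_direct(3, 2, 0.1), tolerance = 1e-10)
  expect_equal(exp(branch_likelihoods(6, 4, 0.5)[["root"]]),
               quad_root_likelihood_direct(6, 4, 0.5), tolerance = 1e-10)
})

test_that("root-orientation likelihood is symmetric in (m, n)", {
  for (a in c(1e-6, 0.1, 0.5)) {
    for (mn in list(c(4, 1), c(12, 3), c(25, 0))) {
      expect_equal(branch_likelihoods(mn[1], mn[2], a)[["root"]],
                   branch_likelihoods(mn[2], mn[1], a)[["root"]])
    }
  }
})

test_that("branch posterior reduces to the prior without data", {
  for (b in c(5, 21)) {
    p <- branch_posterior(0, 0, 0.025, b)
    expect_equal(unname(p), c((b - 1) / (2 * b), (b - 1) / (2 * b), 1 / b))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("strong asymmetric counts keep a substantial root probability", {
  # 20 vs 5 duplications, default-rule alpha: root stays >= 30%
  p <- branch_posterior(20, 5, estimate_alpha(5, 20), 5)
  expect_gte(p[["root"]], 0.30)
  # while the reversed orientation is vanishingly unlikely; the bound loosens
  # as alpha grows because false positives become expected
  for (a in c(1e-6, 1e-3, 0.025, 0.1)) {
    expect_lt(branch_posterior(20, 5, a, 5)[["right"]], 1e-6)
  }
  expect_lt(branch_posterior(20, 5, 0.5, 5)[["right"]], 1e-3)
})

test_that("terminal branch model compares inward rates only", {
  ll <- terminal_branch_likelihoods(0, 2, 2)
  expect_equal(ll[["leafward"]], ll[["root"]])
  ll3 <- terminal_branch_likelihoods(3, 2, 0.1)
  expect_equal(ll3[["root"]] - ll3[["leafward"]], 3 * log(20) - 1.9)
})

test_that("terminal rate estimation uses the plateau and its fallback", {
  st <- toy_species_tree()
  ev <- events_from_blocks(list(c("elephant", "dog"),
                                c("elephant", "dog", "bird"),
                                c("elephant", "dog", "bird")), st)
  cnt <- aggregate_counts(ev, st)
  mp <- mp_roots(ev, st)
  tr <- estimate_terminal_rates(cnt, mp$plateau, st, mp$n_nonconflicting)
  expect_equal(unname(tr), c(2, 1e-6))  # fish terminal is the MP root

  # internal plateau, no terminal inward counts: tree-wide fallback for TP
  st4 <- suppressMessages(species_tree("((A,B),(C,D));"))
  ev2 <- events_from_blocks(list(c("A", "B"), c("C", "D")), st4)
  cnt2 <- aggregate_counts(ev2, st4)
  mp2 <- mp_roots(ev2, st4)
  tr2 <- estimate_terminal_rates(cnt2, mp2$plateau, st4, mp2$n_nonconflicting)
  expect_equal(unname(tr2), c(2 / 5, 1e-6))
  # adding internal-branch events does not change the FP rate
  expect_equal(tr2[["lambda_fp"]], 1e-6)
})

test_that("root distribution is normalized and uniform without events", {
  st4 <- suppressMessages(species_tree("((A,B),(C,D));"))
  cnt0 <- aggregate_counts(events_from_blocks(list(c("A", "B")), st4)[0, ], st4)
  d0 <- root_distribution(cnt0, st4, 1e-6, c(lambda_tp = 1e-6,
                                             lambda_fp = 1e-6))
  expect_equal(d0$p_root, rep(0.2, 5), tolerance = 1e-9)
  expect_equal(sum(d0$p_root), 1, tolerance = 1e-9)

  # normalization holds for arbitrary count configurations
  set.seed(5)
  stn <- species_tree(ape::rtree(9))
  cnt <- data.frame(branch_id = seq_len(stn$b),
                    m = rpois(stn$b, 3), n = rpois(stn$b, 1))
  d <- root_distribution(cnt, stn, 0.01, c(lambda_tp = 2, lambda_fp = 0.3))
  expect_equal(sum(d$p_root), 1, tolerance = 1e-9)
  expect_true(all(d$p_root >= 0))
})

test_that("a single duplication excludes only the branches inside its block", {
  st4 <- suppressMessages(species_tree("((A,B),(C,D));"))
  ev <- events_from_blocks(list(c("A", "B")), st4)
  cnt <- aggregate_counts(ev, st4)
  mp <- mp_roots(ev, st4)
  tr <- estimate_terminal_rates(cnt, mp$plateau, st4, mp$n_nonconflicting)
  d <- root_distribution(cnt, st4, estimate_alpha(0, 1), tr)
  cd <- which(st4$branches$terminal_species %in% c("C", "D"))
  central <- which(st4$branches$block_a == "A;B")
  inside <- which(st4$branches$terminal_species %in% c("A", "B"))
  # C and D are equally most probable; the central branch carries half their
  # probability (a root on it splits the expected events over its two sides);
  # the branches inside the duplicated block are excluded almost surely
  expect_equal(d$p_root[cd[1]], d$p_root[cd[2]], tolerance = 1e-12)
  expect_equal(which.max(d$p_root) %in% cd, TRUE)
  expect_equal(d$p_root[central] / d$p_root[cd[1]], 0.5, tolerance = 1e-3)
  expect_true(all(d$p_root[inside] < 1e-6))
})

test_that("the worked four-species example puts the root on the fish branch", {
  st <- toy_species_tree()
  ev <- events_from_blocks(list(c("elephant", "dog"),
                                c("elephant", "dog", "bird"),
                                c("elephant", "dog", "bird")), st)
  cnt <- aggregate_counts(ev, st)
  mp <- mp_roots(ev, st)
  tr <- estimate_terminal_rates(cnt, mp$plateau, st, mp$n_nonconflicting)
  d <- root_distribution(cnt, st, estimate_alpha(mp$n_conflicting,
                                                 mp$n_nonconflicting), tr)
  fish <- which(st$branches$is_terminal & st$branches$terminal_species == "fish")
  expect_equal(which.max(d$p_root), fish)
})

test_that("alpha barely moves the answer on a well-resolved dataset", {
  ds <- simulate_dataset(sim_config(seed = 1))
  res <- root_inference(ds$st, ds$gene_trees)
  argmaxes <- pmaxes <- c()
  for (a in c(1e-6, 1e-4, 1e-3, 0.01, 0.1)) {
    d <- root_distribution(res$counts, ds$st, a, res$terminal_rates)
    argmaxes <- c(argmaxes, which.max(d$p_root))
    pmaxes <- c(pmaxes, max(d$p_root))
  }
  expect_equal(length(unique(argmaxes)), 1)
  # peak probability is stable over the plausible alpha range
  expect_lt(diff(range(pmaxes[1:4])), 0.01)
})
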