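test_that("constraint patterns have the right free-rate counts", {
  expect_equal(biomevol:::n_rate_classes(make_mk_pattern("ER", 5)), 1)
  expect_equal(biomevol:::n_rate_classes(make_mk_pattern("SYM", 5)), 10)
  expect_equal(biomevol:::n_rate_classes(make_mk_pattern("ARD", 5)), 20)
  expect_equal(sum(make_mk_pattern("ARD", 5) > 0), 20)
  sw <- make_mk_pattern("SW")
  expect_equal(biomevol:::n_rate_classes(sw), 12)
  # no direct specialist-specialist moves; marine specialist cannot reach
  # the freshwater+land generalist directly
  spec <- grep("specialist", analysis_states())
  expect_true(all(sw[spec, spec] == 0))
  expect_equal(sw["marine specialist", "freshwater+land generalist"], 0,
               ignore_attr = TRUE)
  expect_error(make_mk_pattern("SW", 4), "five analysis states")

  cust <- make_mk_pattern("custom", 3,
                          mask = matrix(c(0, 1, 0, 1, 0, 2, 0, 2, 0), 3, 3))
  expect_equal(biomevol:::n_rate_classes(cust), 2)
  expect_error(make_mk_pattern("custom", 3,
                               mask = matrix(-1, 3, 3)), "nonnegative")
})

test_that("pruning equals brute-force enumeration on small trees", {
  # impossible-change corner: Q = 0 forces the root to match the tips
  tr <- read_newick("((A:1,B:1):1,C:2);")
  st <- setNames(factor(rep("s1", 3), levels = paste0("s", 1:5)),
                 c("A", "B", "C"))
  expect_equal(mk_loglik(tr, st, matrix(0, 5, 5)), log(1 / 5))
  st2 <- st; st2["C"] <- "s2"
  st2 <- factor(st2, levels = paste0("s", 1:5))
  names(st2) <- names(st)
  expect_equal(mk_loglik(tr, st2, matrix(0, 5, 5)), -Inf)

  # property: random trees (<= 5 tips), random Q (<= 3 states)
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(3:5, 1)
    S <- sample(2:3, 1)
    tree <- simulate_bd_tree(1, 0, n = n)
    Q <- random_rate_matrix(S)
    states <- setNames(factor(paste0("s", sample(S, n, TRUE)),
                              levels = paste0("s", seq_len(S))),
                       tree$tip.label)
    expect_equal(mk_loglik(tree, states, Q),
                 oracle_mk_brute(tree, states, Q), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to relabeling under ER and tip order", {
  tr <- simulate_bd_tree(1, 0, n = 20, seed = 3)
  Q <- matrix(0.4, 3, 3); diag(Q) <- -0.8
  st <- setNames(factor(paste0("s", rep(1:3, length.out = 20)),
                        levels = paste0("s", 1:3)), tr$tip.label)
  base <- mk_loglik(tr, st, Q)
  relab <- factor(c(s1 = "s2", s2 = "s3", s3 = "s1")[as.character(st)],
                  levels = paste0("s", 1:3))
  names(relab) <- names(st)
  expect_equal(mk_loglik(tr, relab, Q), base)
  expect_equal(mk_loglik(tr, st[sample(names(st))], Q), base)
})

test_that("exp(Qt) stays row-stochastic over observed branch scales", {
  set.seed(12)
  for (rep in 1:10) {
    Q <- random_rate_matrix(5, scale = runif(1, 0.05, 5))
    for (t in c(1e-4, 0.1, 1, 10)) {
      P <- biomevol:::mk_pmat_cpp(Q, t)
      expect_true(all(P >= 0))
      expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    }
  }
})

test_that("ER maximum likelihood matches a 1-D grid-search oracle", {
  tr <- simulate_bd_tree(1, 0, n = 50, seed = 17)
  Q <- matrix(0.5, 2, 2); diag(Q) <- -0.5
  st <- simulate_mk_history(tr, Q, root_state = 1L, seed = 18)$tip_states
  fit <- fit_mk(tr, st, make_mk_pattern("ER", 2), n_starts = 2)
  grid <- exp(seq(log(1e-3), log(10), length.out = 4000))
  ll <- vapply(grid, function(q) {
    mk_loglik(tr, st, matrix(c(-q, q, q, -q), 2, 2))
  }, 0)
  q_grid <- grid[which.max(ll)]
  expect_equal(fit$rates, q_grid, tolerance = 2e-3)
  expect_equal(fit$AIC, 2 * 1 - 2 * fit$logL)
})

test_that("richer models never fit worse than nested ones", {
  tr <- simulate_bd_tree(1, 0, n = 60, seed = 23)
  Q <- biomevol:::example_sparse_q()
  st <- simulate_mk_history(tr, Q, root_state = 3L, seed = 24,
                            states = analysis_states())$tip_states
  er <- fit_mk(tr, st, make_mk_pattern("ER", 5), n_starts = 2)
  sym <- fit_mk(tr, st, make_mk_pattern("SYM", 5), n_starts = 2)
  ard <- fit_mk(tr, st, make_mk_pattern("ARD", 5), n_starts = 2)
  expect_gte(ard$logL, er$logL - 1e-6)
  expect_gte(ard$logL, sym$logL - 1e-6)
  expect_gte(sym$logL, er$logL - 1e-6)
})

test_that("ARD simplification prunes and stops on AIC", {
  tr <- simulate_bd_tree(1, 0, n = 120, seed = 41)
  tr <- rescale_tree(tr, 3)
  Q <- biomevol:::example_sparse_q()
  st <- simulate_mk_history(tr, Q, root_state = 3L, seed = 42,
                            states = analysis_states())$tip_states
  ard <- fit_mk(tr, st, make_mk_pattern("ARD", 5), n_starts = 2)
  simp <- simplify_ard(tr, st, ard, n_starts = 1)
  expect_lte(simp$best$k, 20)
  expect_lte(simp$best$AIC, ard$AIC + 1e-6)
  # table starts at the full model and k never increases along the path
  expect_equal(simp$table$k[1], ard$k)
  expect_true(all(diff(simp$table$k) < 0))
  # the best model is the AIC minimum of the whole path
  expect_equal(simp$best$AIC, min(simp$table$AIC))
})

test_that("AIC weights behave on printed and degenerate inputs", {
  # model-comparison column of the diversification analysis
  aic <- c(-346.05, -329.70, -249.08, -233.27, 455.67)
  w <- aic_weights(aic)
  expect_equal(round(w[1], 3), 1)
  expect_true(all(round(w[-1], 3) == 0))
  expect_equal(sum(w), 1)
  expect_equal(aic_weights(c(10, 10)), c(0.5, 0.5))
  expect_equal(aic_weights(42), 1)
  # invariant to a constant shift of all AICs
  expect_equal(aic_weights(aic + 123), w)
})

test_that("source-sink ratios follow the away/into convention", {
  st <- analysis_states()
  Q <- matrix(0.1, 5, 5, dimnames = list(st, st))
  diag(Q) <- 0
  Q["marine generalist", ] <- c(8, 8, 8, 8.7, 0)
  Q[, "marine generalist"] <- c(2, 2, 1.37, 1, 0)
  diag(Q) <- -rowSums(Q)
  ss <- source_sink_ratios(Q)
  mg <- ss[ss$state == "marine generalist", ]
  expect_equal(mg$away, 32.7)
  expect_equal(mg$into, 6.37)
  expect_equal(round(mg$ratio, 2), 5.13)

  sym <- matrix(0.3, 4, 4); diag(sym) <- -0.9
  expect_equal(source_sink_ratios(sym)$ratio, rep(1, 4))

  sink_only <- matrix(c(-1, 0, 1, 0), 2, 2)
  expect_equal(source_sink_ratios(sink_only)$ratio, c(Inf, 0))
})

test_that("bootstrap schemes honour their degenerate contracts", {
  tr <- simulate_bd_tree(1, 0, n = 60, seed = 51)
  Q <- matrix(0.4, 2, 2); diag(Q) <- -0.4
  st <- simulate_mk_history(tr, Q, root_state = 1L, seed = 52)$tip_states
  pat <- make_mk_pattern("ER", 2)
  # one iteration at fraction 1: identical to the full-tree fit
  bs <- bootstrap_rates(tr, st, pat, mode = "tree80", n_iter = 1,
                        fraction = 1, n_starts = 1, seed = 7)
  expect_equal(bs$rates$mean, bs$full$rates, tolerance = 1e-6)
  # equal_n: per-state tip counts equal in every iteration (checked via
  # the subsampler it delegates to)
  sub <- subsample_tree(tr, "equal_per_state", target = min(table(st)),
                        states = st, seed = 1)
  expect_true(length(unique(table(st[sub$tip.label]))) == 1)
})

test_that("bootstrap intervals cover a true ER rate", {
  # scaled-down coverage check: a handful of meta-replicates, each with a
  # percentile interval from tree80 resampling
  q_true <- 0.5
  Q <- matrix(c(-q_true, q_true, q_true, -q_true), 2, 2)
  covered <- 0
  for (r in 1:5) {
    tr <- simulate_bd_tree(1, 0, n = 80, seed = 600 + r)
    st <- simulate_mk_history(tr, Q, root_state = 1L,
                              seed = 700 + r)$tip_states
    bs <- bootstrap_rates(tr, st, make_mk_pattern("ER", 2), n_iter = 40,
                          n_starts = 1, seed = 800 + r)
    if (bs$rates$lower <= q_true && q_true <= bs$rates$upper) {
      covered <- covered + 1
    }
  }
  expect_gte(covered, 3)
})
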