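q5 <- function() {
  Q <- matrix(0.05, 5, 5); diag(Q) <- -0.2
  dimnames(Q) <- list(analysis_states(), analysis_states())
  Q
}

test_that("model constructors count free parameters from structure", {
  Q <- q5()
  expect_equal(build_sse_model("ctd", 5, 4, Q)$n_free, 17)
  expect_equal(build_sse_model("muhisse", 5, 2, Q)$n_free, 13)
  expect_equal(build_sse_model("ctd", 5, 3, Q)$n_free, 10)
  expect_equal(build_sse_model("musse", 5, 1, Q)$n_free, 6)
  expect_equal(build_sse_model("ctd", 5, 2, Q)$n_free, 5)
  expect_error(build_sse_model("musse", 5, 2, Q), "invalid")
  expect_error(build_sse_model("muhisse", 5, 3, Q), "invalid")
  expect_error(build_sse_model("ctd", 5, 5, Q), "invalid")
  expect_error(build_sse_model("ctd", 5, 2, Q, rho = 0), "rho")
})

test_that("likelihood matches the independent fixed-step RK4 oracle", {
  tr <- read_newick("((A:0.4,B:0.4):0.6,C:1.0);")
  Qo <- matrix(c(-0.3, 0.2, 0.3, -0.2), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  st <- setNames(factor(c("x", "y", "x"), levels = c("x", "y")),
                 c("A", "B", "C"))
  m <- build_sse_model("muhisse", S = 2, H = 2, Q_obs = Qo, rho = 0.7)
  p <- sse_params(m, lambda = c(0.5, 1.2, 0.9, 0.3), mu = 0.15,
                  q_hid = c(0.2, 0.4))
  for (rw in c("observed", "uniform")) for (cond in c(TRUE, FALSE)) {
    expect_equal(
      as.numeric(sse_loglik(tr, st, m, p, root_weighting = rw,
                            condition_on_survival = cond)),
      oracle_sse_rk4(tr, st, m, p, nsteps = 4000, root_weighting = rw,
                     condition = cond),
      tolerance = 1e-5)
  }
})

test_that("state-independent SSE factorizes into birth-death times Mk", {
  Q3 <- matrix(0.25, 3, 3); diag(Q3) <- -0.5
  dimnames(Q3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  m <- build_sse_model("musse", S = 3, H = 1, Q_obs = Q3, rho = 1)
  tr <- simulate_bd_tree(1, 0.3, n = 10, seed = 11)
  st <- simulate_mk_history(tr, Q3, root_state = 2L, seed = 4)$tip_states
  for (pars in list(c(0.9, 0.3), c(1.4, 0))) {
    lam <- pars[1]; mu <- pars[2]
    ll <- as.numeric(sse_loglik(tr, st, m,
                                sse_params(m, rep(lam, 3), mu),
                                root_weighting = "uniform",
                                condition_on_survival = FALSE))
    expect_equal(ll, oracle_bd_sse_loglik(tr, lam, mu) +
                   mk_loglik(tr, st, Q3), tolerance = 1e-4)
  }
})

test_that("likelihood is invariant to hidden relabeling and tip order", {
  m <- build_sse_model("ctd", 5, 2, Q_obs = q5())
  p12 <- sse_params(m, lambda = c(0.5, 2), mu = 0.1, q_hid = c(0.15, 0.3))
  p21 <- sse_params(m, lambda = c(2, 0.5), mu = 0.1, q_hid = c(0.3, 0.15))
  sim <- simulate_sse_tree(m, p12, n = 60, seed = 19)
  l1 <- as.numeric(sse_loglik(sim$tree, sim$tip_states, m, p12))
  expect_equal(as.numeric(sse_loglik(sim$tree, sim$tip_states, m, p21)), l1)
  shuffled <- sim$tip_states[sample(names(sim$tip_states))]
  expect_equal(as.numeric(sse_loglik(sim$tree, shuffled, m, p12)), l1)
})

test_that("birth-death fits agree with the reference implementation", {
  tr <- simulate_bd_tree(1, 0.4, n = 150, seed = 5)
  ours <- bd_fit(tr)
  ref <- ape::birthdeath(tr)
  expect_equal(ours$lambda - ours$mu, unname(ref$para["b-d"]),
               tolerance = 1e-3)
  expect_equal(ours$mu / ours$lambda, unname(ref$para["d/b"]),
               tolerance = 2e-2)
  expect_gt(ours$lambda, 0)
  expect_gte(ours$mu, 0)

  # Yule recovery within 15%
  yule <- simulate_bd_tree(1, 0, n = 500, seed = 8)
  fy <- bd_fit(yule)
  expect_lt(abs(fy$lambda - 1), 0.15)
  expect_lt(fy$mu, 0.05)

  # fixed-mu optimum matches a 1-D grid oracle
  fit0 <- bd_fit(tr, fix_mu = 0)
  ages <- sort(tree_height(tr) - branching_times(tr), decreasing = TRUE)
  N <- length(ages) + 1
  gridll <- function(lam) {
    lfactorial(N - 1) + (N - 2) * log(lam) + lam * sum(ages[-1]) -
      2 * sum(log(exp(lam * ages)))
  }
  grid <- seq(0.05, 3, length.out = 6000)
  expect_equal(fit0$lambda, grid[which.max(vapply(grid, gridll, 0))],
               tolerance = 1e-3)
})

test_that("the starting grid has 27 scored points and keeps the best six", {
  m <- build_sse_model("ctd", 5, 2, Q_obs = q5())
  p <- sse_params(m, lambda = c(0.5, 2), mu = 0.1, q_hid = c(0.3, 0.3))
  sim <- simulate_sse_tree(m, p, n = 40, seed = 33)
  bd <- bd_fit(sim$tree)
  g <- starting_grid(sim$tree, sim$tip_states, m, bd, q_mean = 0.05)
  expect_equal(nrow(g$grid), 27)
  expect_lte(length(g$starts), 6)
  expect_true(all(diff(g$scores) <= 0))
  # scoring is a pure function of the parameters
  g2 <- starting_grid(sim$tree, sim$tip_states, m, bd, q_mean = 0.05)
  expect_identical(g$scores, g2$scores)
  # zero extinction degenerates the mu grid without collapsing it
  bd0 <- list(lambda = bd$lambda, mu = 0)
  g0 <- starting_grid(sim$tree, sim$tip_states, m, bd0, q_mean = 0.05)
  expect_equal(nrow(unique(g0$grid[, 1:3])), 27)
})

test_that("MuSSE is nested in MuHiSSE and fits respect it", {
  Q <- q5()
  m1 <- build_sse_model("musse", 5, 1, Q_obs = Q)
  p <- sse_params(m1, lambda = rep(0.9, 5), mu = 0.1)
  sim <- simulate_sse_tree(m1, p, n = 60, seed = 44)
  s1 <- list(sse_params(m1, lambda = rep(0.8, 5), mu = 0.05))
  f1 <- fit_sse(sim$tree, sim$tip_states, m1, s1)
  m2 <- build_sse_model("muhisse", 5, 2, Q_obs = Q)
  s2 <- list(sse_params(m2, lambda = rep(0.8, 10), mu = 0.05,
                        q_hid = c(0.1, 0.1)))
  f2 <- fit_sse(sim$tree, sim$tip_states, m2, s2)
  expect_gte(f2$logL, f1$logL - 0.1)
  expect_equal(f1$k, 6)
  expect_equal(f2$k, 13)
})

test_that("model comparison reproduces AIC bookkeeping and guards data", {
  # worked example from the published diversification comparison: AIC
  # recomputed from the printed (k, logL) pairs
  expect_equal(model_aic(10, 174.85), -329.70)
  expect_equal(model_aic(13, 137.54), -249.08)
  expect_equal(round(model_aic(17, 190.03), 1), -346.1)
  expect_equal(round(model_aic(6, -221.84), 2), 455.68)

  m <- build_sse_model("ctd", 5, 2, Q_obs = q5())
  p <- sse_params(m, lambda = c(0.5, 2), mu = 0.1, q_hid = c(0.3, 0.3))
  sim <- simulate_sse_tree(m, p, n = 50, seed = 55)
  st1 <- list(sse_params(m, lambda = c(0.5, 1.5), mu = 0.05,
                         q_hid = c(0.2, 0.2)))
  f <- fit_sse(sim$tree, sim$tip_states, m, st1)
  dup <- compare_sse_models(list(f, f))
  expect_equal(dup$weight, c(0.5, 0.5))
  # adding a model 50 AIC units worse leaves the leader near weight 1
  worse <- f; worse$AIC <- f$AIC + 50
  tab <- compare_sse_models(list(f, worse))
  expect_gte(tab$weight[1], 0.999)

  other <- simulate_sse_tree(m, p, n = 50, seed = 56)
  f_other <- fit_sse(other$tree, other$tip_states, m, st1)
  expect_error(compare_sse_models(list(f, f_other)), "identical data")
})

test_that("sampling fraction changes rho but not model structure", {
  m_list <- list(build_sse_model("musse", 5, 1, Q_obs = q5()),
                 build_sse_model("ctd", 5, 2, Q_obs = q5()))
  p <- sse_params(m_list[[2]], lambda = c(0.5, 2), mu = 0.1,
                  q_hid = c(0.3, 0.3))
  sim <- simulate_sse_tree(m_list[[2]], p, n = 40, seed = 66)
  sw <- sampling_fraction_sweep(sim$tree, sim$tip_states, m_list,
                                rhos = c(1, 0.5))
  expect_equal(nrow(sw$winners), 2)
  for (tab in sw$tables) {
    expect_setequal(tab$k, c(6, 5))  # free-parameter counts unaffected
  }
  # rho = 1 reproduces a direct fit
  direct <- fit_sse(sim$tree, sim$tip_states, m_list[[1]],
                    list(sse_params(m_list[[1]], lambda = rep(0.2, 5),
                                    mu = 0.05)))
  expect_equal(sw$tables$rho_1[sw$tables$rho_1$model == "musse", "logL"],
               direct$logL, tolerance = 1e-4)
})
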