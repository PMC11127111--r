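# Independent oracle implementations used to validate the package's
# likelihoods and classifiers. These deliberately avoid the code paths they
# check: matrix exponentials via Matrix::expm, ODE integration by fixed-step
# RK4 in plain R, and the classifier decision rule as a straight loop.

# --- Mk: brute-force enumeration over all internal-node state assignments
oracle_mk_brute <- function(tree, states, Q, prior = NULL) {
  S <- nrow(Q)
  prior <- prior %||% rep(1 / S, S)
  nt <- ape::Ntip(tree)
  n_int <- tree$Nnode
  P <- lapply(tree$edge.length,
              function(t) as.matrix(Matrix::expm(Q * t)))
  tip_idx <- as.integer(states[tree$tip.label])
  combos <- as.matrix(expand.grid(rep(list(seq_len(S)), n_int)))
  tot <- 0
  for (r in seq_len(nrow(combos))) {
    assign <- c(tip_idx, combos[r, ])
    lik <- prior[assign[nt + 1]]
    for (e in seq_len(nrow(tree$edge))) {
      lik <- lik * P[[e]][assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
    }
    tot <- tot + lik
  }
  log(tot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- SSE: fixed-step RK4 pruning, all conventions mirrored from the docs
oracle_sse_rk4 <- function(tree, states, model, params, nsteps = 2000,
                           root_weighting = "observed", condition = TRUE) {
  S <- model$S; H <- model$H; K <- S * H
  pl <- biomevol:::sse_expand_params(model, params)
  lam <- pl$lambda; mu <- pl$mu; Q <- pl$Q_comb; rho <- model$rho
  deriv <- function(y) {
    E <- y[1:K]; D <- y[K + 1:K]
    c(mu - (lam + mu) * E + lam * E^2 + as.vector(Q %*% E),
      -(lam + mu) * D + 2 * lam * E * D + as.vector(Q %*% D))
  }
  integrate_branch <- function(y, len) {
    h <- len / nsteps
    for (i in seq_len(nsteps)) {
      k1 <- deriv(y); k2 <- deriv(y + h / 2 * k1)
      k3 <- deriv(y + h / 2 * k2); k4 <- deriv(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  po <- ape::reorder.phylo(tree, "postorder")
  nt <- ape::Ntip(po)
  st <- as.integer(factor(as.character(states[po$tip.label]),
                          levels = model$states))
  n_nodes <- max(po$edge)
  Ey <- matrix(0, K, n_nodes); Dy <- matrix(0, K, n_nodes)
  visits <- integer(n_nodes)
  for (i in seq_len(nt)) {
    Ey[, i] <- 1 - rho
    Dy[(st[i] - 1) * H + seq_len(H), i] <- rho
    visits[i] <- 2L
  }
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    y <- integrate_branch(c(Ey[, ch], Dy[, ch]), po$edge.length[e])
    if (visits[par] == 0L) {
      Ey[, par] <- y[1:K]; Dy[, par] <- y[K + 1:K]
    } else {
      Ey[, par] <- (Ey[, par] + y[1:K]) / 2
      Dy[, par] <- Dy[, par] * y[K + 1:K] * lam
      m <- max(Dy[, par]); Dy[, par] <- Dy[, par] / m
      logscale <- logscale + log(m)
    }
    visits[par] <- visits[par] + 1L
  }
  root <- nt + 1L
  D <- Dy[, root]; E <- Ey[, root]
  w <- if (root_weighting == "observed") D / sum(D) else rep(1 / K, K)
  ll <- log(sum(w * D)) + logscale
  if (condition) ll <- ll - log(sum(w * lam * (1 - E)^2))
  ll
}

# --- constant-rate birth-death log-likelihood in the SSE convention
# (per-branch D-ratio, lambda at every internal merge including the root),
# from the closed-form solutions of the one-state E/D equations with rho = 1
oracle_bd_sse_loglik <- function(tree, lambda, mu) {
  # F(h) solves the one-state D equation from the present (E(0) = 0,
  # D(0) = 1) up to height h; a branch spanning heights [h1, h2]
  # contributes F(h2) / F(h1)
  r <- lambda - mu
  F <- function(h) r^2 * exp(r * h) / (lambda * exp(r * h) - mu)^2
  height <- tree_height(tree)
  node_h <- height - ape::node.depth.edgelength(tree)  # height above tips
  ll <- 0
  for (e in seq_len(nrow(tree$edge))) {
    h2 <- node_h[tree$edge[e, 1]]
    h1 <- node_h[tree$edge[e, 2]]
    ll <- ll + log(F(h2) / F(h1))
  }
  ll + (ape::Ntip(tree) - 1) * log(lambda)
}

# --- PERMANOVA pseudo-F from the classic within-group partition of squared
# distances (Anderson 2001), independent of vegan's Gower-centering code
oracle_permanova_f <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.factor(groups)
  g <- nlevels(groups)
  ss_total <- sum(D[upper.tri(D)]^2) / n
  ss_within <- sum(vapply(levels(groups), function(lv) {
    idx <- which(groups == lv)
    sub <- D[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]^2) / length(idx)
  }, 0))
  ss_between <- ss_total - ss_within
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

# --- weighted UniFrac by direct branch summation
oracle_wunifrac <- function(counts, tree, normalized = TRUE) {
  rel <- sweep(counts, 1, rowSums(counts), "/")
  n <- nrow(rel)
  out <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  tip_sets <- lapply(seq_len(nrow(tree$edge)), function(e) {
    node <- tree$edge[e, 2]
    if (node <= ape::Ntip(tree)) tree$tip.label[node]
    else ape::extract.clade(tree, node)$tip.label
  })
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0
    for (e in seq_along(tip_sets)) {
      pa <- sum(rel[i, tip_sets[[e]]]); pb <- sum(rel[j, tip_sets[[e]]])
      num <- num + tree$edge.length[e] * abs(pa - pb)
      den <- den + tree$edge.length[e] * (pa + pb)
    }
    out[i, j] <- out[j, i] <- if (normalized) num / den else num
  }
  out
}

# --- straight-loop re-implementation of the bootstrap affinity rule
oracle_classify <- function(presence, sample_biomes, avail, n_draws = 100L,
                            n_reps = 1000L, tail = 0.025, seed = NULL) {
  present <- names(presence)[presence > 0]
  pb <- sample_biomes[present]
  if (length(unique(pb)) == 1) return(unique(pb))
  if (!is.null(seed)) set.seed(seed)
  m <- length(pb)
  idx <- sample.int(m, n_draws * n_reps, replace = TRUE)
  hits <- setNames(numeric(length(avail)), names(avail))
  for (r in seq_len(n_reps)) {
    draw <- pb[idx[(r - 1) * n_draws + seq_len(n_draws)]]
    for (b in names(avail)) {
      if (sum(draw == b) / n_draws >= avail[[b]]) hits[b] <- hits[b] + 1
    }
  }
  names(avail)[hits / n_reps >= tail]
}

# --- small random fixtures
random_rate_matrix <- function(S, scale = 1) {
  Q <- matrix(runif(S * S) * scale, S, S)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

balanced_tree <- function(n_tip, height = 1) {
  tr <- ape::stree(n_tip, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  rescale_tree(tr, height)
}
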