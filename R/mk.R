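# Multistate Mk likelihood and ML fitting for biome-preference evolution:
# ER / SYM / ARD / stepwise / custom constraint patterns, iterative AIC
# simplification of the ARD model, AIC weights, source-sink ratios, and two
# bootstrap uncertainty schemes.

#' Build an Mk constraint pattern
#'
#' A constraint pattern is an S x S integer matrix over the off-diagonal
#' cells: 0 marks a transition fixed at rate zero, and positive integers
#' index shared free-rate classes. `ER` has one class, `SYM` one per
#' unordered pair (S(S-1)/2), `ARD` one per ordered pair (S(S-1)). The
#' stepwise model `SW` is defined for the five analysis states only: it is
#' ARD restricted so that specialists never interconvert directly and the
#' marine specialist never exchanges directly with the freshwater+land
#' generalist (an intermediate generalist state is needed to reach a new
#' specialization), leaving 12 free rates.
#'
#' @param kind one of `"ER"`, `"SYM"`, `"ARD"`, `"SW"`, `"custom"`.
#' @param S number of states (5 for `SW`).
#' @param mask integer matrix for `kind = "custom"` (0 = zero, k > 0 = rate
#'   class k; diagonal ignored).
#' @param states state names; defaults to [analysis_states()] when S = 5.
#' @return An `mk_pattern`: integer matrix with `states` attribute.
#' @export
#' @examples
#' sum(make_mk_pattern("ARD", 5) > 0)  # 20 possible transitions
make_mk_pattern <- function(kind = c("ER", "SYM", "ARD", "SW", "custom"),
                            S = 5L, mask = NULL, states = NULL) {
  kind <- match.arg(kind)
  S <- as.integer(S)
  if (is.null(states)) {
    states <- if (S == 5L) analysis_states() else paste0("s", seq_len(S))
  }
  stopifnot(length(states) == S)
  pat <- matrix(0L, S, S, dimnames = list(states, states))
  off <- which(row(pat) != col(pat))
  if (kind == "ER") {
    pat[off] <- 1L
  } else if (kind == "SYM") {
    k <- 0L
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      k <- k + 1L
      pat[i, j] <- k; pat[j, i] <- k
    }
  } else if (kind == "ARD") {
    pat[off] <- seq_along(off)
  } else if (kind == "SW") {
    if (S != 5L || !identical(states, analysis_states())) {
      stop("SW is only defined for the five analysis states")
    }
    pat[off] <- seq_along(off)
    spec <- grep("specialist", states)
    for (i in spec) for (j in spec) pat[i, j] <- 0L
    ms <- which(states == "marine specialist")
    fl <- which(states == "freshwater+land generalist")
    pat[ms, fl] <- 0L; pat[fl, ms] <- 0L
    pat <- relabel_pattern(pat)
  } else {
    if (is.null(mask)) stop("custom pattern needs `mask`")
    mask <- as.matrix(mask)
    stopifnot(all(dim(mask) == S))
    diag(mask) <- 0L
    if (any(is.na(mask)) || any(mask < 0) || any(mask != round(mask))) {
      stop("mask entries must be nonnegative integers (0 = zero rate)")
    }
    pat[] <- as.integer(mask)
    pat <- relabel_pattern(pat)
  }
  structure(pat, class = "mk_pattern", states = states)
}

# renumber rate classes to 1..k in row-major order of first appearance
relabel_pattern <- function(pat) {
  ids <- unique(t(pat)[t(pat) > 0])
  out <- pat
  out[pat > 0] <- match(pat[pat > 0], ids)
  out
}

n_rate_classes <- function(pattern) {
  length(unique(pattern[pattern > 0]))
}

pattern_to_Q <- function(pattern, rates) {
  Q <- matrix(0, nrow(pattern), ncol(pattern),
              dimnames = dimnames(pattern))
  Q[pattern > 0] <- rates[pattern[pattern > 0]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' @param tree ultrametric rooted binary `phylo`.
#' @param states factor of tip states named by tip label; its levels define
#'   the state alphabet and must match `Q`'s dimension.
#' @param Q transition-rate matrix (off-diagonals >= 0, rows sum to 0).
#' @param root_prior `"uniform"`, `"stationary"` (of Q), or a numeric prior
#'   over states.
#' @return Log-likelihood (\code{-Inf} for impossible data).
#' @export
mk_loglik <- function(tree, states, Q, root_prior = "uniform") {
  check_tree(tree, ultrametric = TRUE)
  if (!ape::is.binary(tree)) tree <- resolve_polytomies(tree)
  check_rate_matrix(Q)
  S <- nrow(Q)
  states <- check_tip_states(tree, states, S)
  prior <- resolve_root_prior(root_prior, Q)
  po <- ape::reorder.phylo(tree, "postorder")
  ll <- mk_loglik_cpp(po$edge, po$edge.length, ape::Ntip(po),
                      as.integer(states), Q, prior)
  if (is.nan(ll)) stop("likelihood evaluation returned NaN; check Q scale")
  ll
}

resolve_root_prior <- function(root_prior, Q) {
  S <- nrow(Q)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == S, all(root_prior >= 0),
              sum(root_prior) > 0)
    return(root_prior / sum(root_prior))
  }
  switch(match.arg(root_prior, c("uniform", "stationary")),
         uniform = rep(1 / S, S),
         stationary = stationary_dist(Q))
}

stationary_dist <- function(Q) {
  S <- nrow(Q)
  A <- rbind(t(Q), rep(1, S))
  pi <- qr.solve(A, c(rep(0, S), 1))
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Fit an Mk model by maximum likelihood
#'
#' Optimizes the free rate classes of a constraint pattern on the log-rate
#' scale (bounds 1e-9 to 1e3 on rates; trees are in relative time) with
#' multiple starts: one parsimony-informed start (minimum state changes per
#' unit total branch length) and seeded random perturbations of it.
#'
#' @inheritParams mk_loglik
#' @param pattern an `mk_pattern` from [make_mk_pattern()].
#' @param n_starts number of optimization starts.
#' @param seed integer seed for the random starts.
#' @param init optional numeric vector of starting rates (one per rate
#'   class); replaces the parsimony heuristic for the first start.
#' @return An `mk_model`: `pattern`, `rates` (per class), `Q`, `logL`, `k`,
#'   `AIC`, `root_prior`, `convergence`.
#' @export
fit_mk <- function(tree, states, pattern, root_prior = "uniform",
                   n_starts = 5L, seed = 1L, init = NULL) {
  check_tree(tree, ultrametric = TRUE)
  if (!ape::is.binary(tree)) tree <- resolve_polytomies(tree)
  S <- nrow(pattern)
  states <- check_tip_states(tree, states, S)
  # the state alphabet comes from the pattern; re-level tip states onto it
  states <- factor(as.character(states), levels = attr(pattern, "states"))
  if (anyNA(states)) stop("tip states outside the pattern's alphabet")
  if (any(table(states) == 0)) {
    warning("state(s) unobserved at the tips: ",
            paste(attr(pattern, "states")[table(states) == 0],
                  collapse = ", "))
  }
  names(states) <- tree$tip.label
  k <- n_rate_classes(pattern)
  if (k == 0) stop("pattern has no free rates")
  stationary <- is.character(root_prior) && root_prior == "stationary"
  prior <- if (stationary) NULL else
    resolve_root_prior(root_prior, matrix(0, S, S))
  po <- ape::reorder.phylo(tree, "postorder")
  tipst <- as.integer(states)
  negll <- function(logr) {
    Q <- pattern_to_Q(pattern, exp(logr))
    pr <- if (stationary) stationary_dist(Q) else prior
    ll <- mk_loglik_cpp(po$edge, po$edge.length, ape::Ntip(po), tipst, Q, pr)
    if (!is.finite(ll)) return(1e10)  # impossible data under this pattern
    -ll
  }
  q0 <- if (is.null(init)) parsimony_rate(tree, states) else NULL
  starts <- vector("list", n_starts)
  starts[[1]] <- log(init %||% rep(q0, k))
  if (n_starts > 1) {
    rand <- with_seed(derive_seed(seed, "mk_starts"),
                      matrix(rnorm((n_starts - 1) * k, sd = 1.5),
                             ncol = k))
    for (i in 2:n_starts) starts[[i]] <- starts[[1]] + rand[i - 1, ]
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      nlminb(pmin(pmax(st, log(1e-9)), log(1e3)), negll,
             lower = log(1e-9), upper = log(1e3),
             control = list(rel.tol = 1e-8, iter.max = 400)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective) || fit$objective >= 1e10)
      next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("Mk optimization failed from every start")
  rates <- exp(best$par)
  logL <- -best$objective
  structure(list(pattern = pattern, rates = rates,
                 Q = pattern_to_Q(pattern, rates),
                 logL = logL, k = k, AIC = 2 * k - 2 * logL,
                 root_prior = root_prior,
                 convergence = best$convergence),
            class = "mk_model")
}

# heuristic starting rate: parsimony changes per unit total branch length
parsimony_rate <- function(tree, states) {
  pd <- phangorn::phyDat(setNames(as.character(states), names(states)),
                         type = "USER", levels = levels(states))
  changes <- phangorn::parsimony(tree, pd)
  max(changes, 1) / sum(tree$edge.length)
}

#' @export
print.mk_model <- function(x, ...) {
  cat("Mk model:", x$k, "free rate class(es), logL =",
      formatC(x$logL, digits = 6), ", AIC =", formatC(x$AIC, digits = 6),
      "\n")
  invisible(x)
}

#' Iterative simplification of a fitted ARD model
#'
#' Step 0 zeroes every fitted rate below `prune_threshold` at once and
#' refits; each subsequent step zeroes the single smallest remaining free
#' rate (ties broken by row-major order) and refits, stopping when the AIC
#' increases. Equal AICs (within 1e-6) prefer the simpler model and the
#' search continues one more step. Refits warm-start from the previous fit.
#'
#' @inheritParams fit_mk
#' @param start a fitted ARD `mk_model`.
#' @param prune_threshold rates below this are zeroed together at step 0.
#' @param n_starts optimization starts per refit (warm start included).
#' @return A list: `best` (minimum-AIC `mk_model`), `table` (`data.frame`
#'   with one row per candidate model: step, k, logL, AIC, zeroed cell).
#' @export
simplify_ard <- function(tree, states, start, prune_threshold = 1e-3,
                         root_prior = "uniform", n_starts = 2L, seed = 1L) {
  stopifnot(inherits(start, "mk_model"))
  cur <- start
  tab <- data.frame(step = 0L, k = cur$k, logL = cur$logL, AIC = cur$AIC,
                    zeroed = "")
  best <- cur
  step <- 0L
  repeat {
    pat <- cur$pattern
    free <- which(pat > 0)
    rate_of_cell <- cur$Q[free]
    if (step == 0L && any(rate_of_cell < prune_threshold)) {
      drop_cells <- free[rate_of_cell < prune_threshold]
      label <- paste0(length(drop_cells), " rates < ", prune_threshold)
    } else {
      if (length(free) <= 1) break  # cannot simplify to an empty model
      ord <- order(rate_of_cell, (free - 1) %% nrow(pat),
                   (free - 1) %/% nrow(pat))
      drop_cells <- free[ord[1]]
      st <- attr(pat, "states")
      label <- paste0(st[(drop_cells - 1) %% nrow(pat) + 1], " -> ",
                      st[(drop_cells - 1) %/% nrow(pat) + 1])
    }
    new_pat <- pat
    new_pat[drop_cells] <- 0L
    new_pat <- structure(relabel_pattern(new_pat), class = "mk_pattern",
                         states = attr(pat, "states"))
    if (n_rate_classes(new_pat) == 0) break
    warm <- cur$Q[new_pat > 0]
    warm_classes <- vapply(seq_len(n_rate_classes(new_pat)), function(cl) {
      mean(warm[new_pat[new_pat > 0] == cl])
    }, 0)
    fit <- tryCatch(
      fit_mk(tree, states, new_pat, root_prior = root_prior,
             n_starts = n_starts, seed = derive_seed(seed, step + 1),
             init = pmax(warm_classes, 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) break  # candidate cannot explain the data; stop here
    step <- step + 1L
    tab <- rbind(tab, data.frame(step = step, k = fit$k, logL = fit$logL,
                                 AIC = fit$AIC, zeroed = label))
    if (fit$AIC > best$AIC + 1e-6) break  # AIC stopped decreasing
    # equal AIC (within 1e-6) prefers the simpler model; continue either way
    if (fit$AIC <= best$AIC + 1e-6) best <- fit
    cur <- fit
  }
  list(best = best, table = tab)
}

#' AIC, differences and Akaike weights
#'
#' `model_aic()` computes AIC = 2k - 2 logL; `aic_weights()` converts a set
#' of AICs to Akaike weights w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j /
#' 2) with Delta_i = AIC_i - min(AIC).
#'
#' @param k number of free parameters.
#' @param logL log-likelihood(s).
#' @return `model_aic`: numeric AIC(s). `aic_weights`: weights summing to 1.
#' @export
model_aic <- function(k, logL) 2 * k - 2 * logL

#' @rdname model_aic
#' @param aic numeric vector of AIC values.
#' @export
aic_weights <- function(aic) {
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Source--sink ratios from a transition-rate matrix
#'
#' For each state s, `away` is the total rate out of s (row sum of
#' off-diagonals), `into` the total rate into s (column sum), and the
#' source--sink ratio is away / into: values above 1 mark evolutionary
#' "sources" that feed other states faster than they are replenished. A
#' state with no incoming rate gets ratio `Inf`, reported explicitly.
#'
#' @param Q transition-rate matrix.
#' @return `data.frame` with columns `state`, `away`, `into`, `ratio`.
#' @export
source_sink_ratios <- function(Q) {
  check_rate_matrix(Q)
  off <- Q; diag(off) <- 0
  away <- rowSums(off)
  into <- colSums(off)
  data.frame(state = rownames(Q) %||% paste0("s", seq_len(nrow(Q))),
             away = away, into = into,
             ratio = ifelse(into > 0, away / into, Inf),
             row.names = NULL)
}

#' Bootstrap uncertainty in Mk rates and source--sink ratios
#'
#' Refits a constraint pattern on subsampled trees and reports percentile
#' confidence intervals. Two subsampling schemes: `tree80` keeps a fraction
#' (default 80%) of tips uniformly at random; `equal_n` keeps the same
#' number of tips per state (default the smallest state class).
#'
#' @inheritParams fit_mk
#' @param mode `"tree80"` or `"equal_n"`.
#' @param n_iter bootstrap iterations.
#' @param fraction tip fraction for `tree80`.
#' @param target per-state tip count for `equal_n` (default `min` class).
#' @param level confidence level for the percentile intervals.
#' @param max_fail_frac iteration-failure tolerance before erroring.
#' @return A list: `rates` (`data.frame` of per-class mean and CI), `ratios`
#'   (per-state source--sink mean and CI), `n_ok`, `n_fail`.
#' @export
bootstrap_rates <- function(tree, states, pattern, mode = c("tree80",
                                                            "equal_n"),
                            n_iter = 1000L, fraction = 0.8, target = NULL,
                            root_prior = "uniform", n_starts = 2L,
                            seed = 1L, level = 0.95,
                            max_fail_frac = 0.1) {
  mode <- match.arg(mode)
  states <- check_tip_states(tree, states)
  if (mode == "equal_n" && is.null(target)) {
    target <- min(table(states))
  }
  full <- fit_mk(tree, states, pattern, root_prior = root_prior,
                 n_starts = n_starts, seed = seed)
  k <- full$k
  rates <- matrix(NA_real_, n_iter, k)
  S <- nrow(pattern)
  ratios <- matrix(NA_real_, n_iter, S)
  n_fail <- 0L
  for (it in seq_len(n_iter)) {
    res <- tryCatch({
      sub <- if (mode == "tree80") {
        subsample_tree(tree, "fraction", fraction = fraction,
                       seed = derive_seed(seed, paste0("bs", it)))
      } else {
        subsample_tree(tree, "equal_per_state", target = target,
                       states = states,
                       seed = derive_seed(seed, paste0("bs", it)))
      }
      fit <- fit_mk(sub, states[sub$tip.label], pattern,
                    root_prior = root_prior, n_starts = n_starts,
                    seed = derive_seed(seed, paste0("fit", it)),
                    init = pmax(full$rates, 1e-9))
      list(rates = fit$rates, ratio = source_sink_ratios(fit$Q)$ratio)
    }, error = function(e) NULL)
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    rates[it, ] <- res$rates
    ratios[it, ] <- res$ratio
  }
  if (n_fail > max_fail_frac * n_iter) {
    stop(n_fail, " of ", n_iter, " bootstrap iterations failed")
  }
  a <- (1 - level) / 2
  ci <- function(m) {
    data.frame(mean = colMeans(m, na.rm = TRUE),
               lower = apply(m, 2, quantile, a, na.rm = TRUE),
               upper = apply(m, 2, quantile, 1 - a, na.rm = TRUE))
  }
  rate_ci <- ci(rates)
  rate_ci <- cbind(class = seq_len(k), rate_ci)
  ratio_ci <- ci(ratios)
  ratio_ci <- cbind(state = attr(pattern, "states"), ratio_ci)
  list(rates = rate_ci, ratios = ratio_ci,
       n_ok = n_iter - n_fail, n_fail = n_fail, full = full)
}
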