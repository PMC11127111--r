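# Multistate and hidden-state speciation-extinction models (MuSSE, MuHiSSE,
# CTD) with a single extinction rate, observed-state transitions fixed at
# the best Mk model's rates, free asymmetric hidden-state transitions, tip
# sampling fractions and survival conditioning; plus the birth-death fit
# that supplies starting values and the 27-point starting grid.

#' Build an (unfitted) SSE model
#'
#' Three tying patterns for the speciation rate over the S x H combined
#' (observed x hidden) state space:
#' * `musse`: one rate per observed state (H = 1); S + 1 free parameters.
#' * `muhisse`: one rate per combined state (H = 2); S*H + 1 + H(H-1) free.
#' * `ctd`: concealed-trait-dependent, one rate per hidden state
#'   (H in 2..4); H + 1 + H(H-1) free. The CTD family is the null for
#'   trait-dependent diversification: speciation varies only with the
#'   hidden trait.
#'
#' All models share a single extinction rate. Observed-state transitions are
#' fixed at `Q_obs` (not counted as free parameters); all ordered
#' hidden-state transition pairs are free and may be asymmetric; dual
#' transitions (observed and hidden state changing at once) are disallowed,
#' so the combined transition matrix is `Q_obs` (x) `I_H` + `I_S` (x)
#' `Q_hid`. Combined state (s, h) has index (s - 1) * H + h.
#'
#' @param kind `"musse"`, `"muhisse"` or `"ctd"`.
#' @param S number of observed states.
#' @param H number of hidden states (1 for musse, 2 for muhisse, 2--4 for
#'   ctd).
#' @param Q_obs fixed S x S observed-state transition-rate matrix (from the
#'   best Mk model).
#' @param rho tip sampling fraction in (0, 1], shared across states.
#' @param states observed-state names.
#' @return An `sse_model` with `n_free` counting the free parameters and
#'   `param_names` naming the parameter vector layout
#'   (speciation rates, `mu`, hidden transition rates).
#' @export
#' @examples
#' Q <- matrix(c(-.2, .1, .1, .1, -.2, .1, .1, .1, -.2), 3, 3)
#' build_sse_model("ctd", S = 3, H = 2, Q_obs = Q)$n_free  # 2 + 1 + 2
build_sse_model <- function(kind = c("musse", "muhisse", "ctd"), S = 5L,
                            H = 1L, Q_obs, rho = 1,
                            states = NULL) {
  kind <- match.arg(kind)
  S <- as.integer(S); H <- as.integer(H)
  ok <- switch(kind, musse = H == 1L, muhisse = H == 2L,
               ctd = H %in% 2:4)
  if (!ok) stop("invalid (kind, H) combination: ", kind, ", H = ", H)
  check_rate_matrix(Q_obs)
  if (nrow(Q_obs) != S) stop("Q_obs must be ", S, " x ", S)
  if (!(rho > 0 && rho <= 1)) stop("rho must be in (0, 1]")
  if (is.null(states)) {
    states <- rownames(Q_obs) %||%
      if (S == 5L) analysis_states() else paste0("s", seq_len(S))
  }
  n_lambda <- switch(kind, musse = S, muhisse = S * H, ctd = H)
  n_qhid <- H * (H - 1L)
  lam_names <- switch(kind,
    musse = paste0("lambda_", states),
    muhisse = paste0("lambda_", rep(states, each = H), "_h",
                     rep(seq_len(H), S)),
    ctd = paste0("lambda_h", seq_len(H)))
  qh_names <- if (n_qhid > 0) {
    pairs <- expand.grid(to = seq_len(H), from = seq_len(H))
    pairs <- pairs[pairs$from != pairs$to, c("from", "to")]
    pairs <- pairs[order(pairs$from, pairs$to), ]
    paste0("q_h", pairs$from, "h", pairs$to)
  } else character()
  structure(list(kind = kind, S = S, H = H, Q_obs = Q_obs, rho = rho,
                 states = states,
                 n_free = n_lambda + 1L + n_qhid,
                 n_lambda = n_lambda, n_qhid = n_qhid,
                 param_names = c(lam_names, "mu", qh_names)),
            class = "sse_model")
}

#' @export
print.sse_model <- function(x, ...) {
  cat(toupper(x$kind), "model: S =", x$S, ", H =", x$H, ", rho =", x$rho,
      ",", x$n_free, "free parameters\n")
  invisible(x)
}

#' Assemble an SSE parameter vector
#'
#' @param model an `sse_model`.
#' @param lambda speciation rates in the model's tying order (length S for
#'   musse, S*H for muhisse in observed-major order, H for ctd).
#' @param mu single extinction rate.
#' @param q_hid hidden transition rates, ordered pairs (1->2, 1->3, ...,
#'   2->1, ...); empty for H = 1.
#' @return Named numeric vector matching `model$param_names`.
#' @export
sse_params <- function(model, lambda, mu, q_hid = numeric()) {
  stopifnot(length(lambda) == model$n_lambda, length(mu) == 1,
            length(q_hid) == model$n_qhid)
  setNames(c(lambda, mu, q_hid), model$param_names)
}

# expand a parameter vector to per-combined-state lambda, mu, Q_comb
sse_expand_params <- function(model, params) {
  stopifnot(length(params) == model$n_free)
  S <- model$S; H <- model$H
  lam_par <- params[seq_len(model$n_lambda)]
  mu <- params[model$n_lambda + 1L]
  qh <- if (model$n_qhid > 0) params[model$n_lambda + 1L + seq_len(model$n_qhid)]
        else numeric()
  if (any(c(lam_par, mu, qh) < 0)) stop("rates must be nonnegative")
  lambda <- switch(model$kind,
    musse = rep(lam_par, each = H),
    muhisse = lam_par,                        # already (s, h) obs-major
    ctd = rep(lam_par, times = S))
  Q_hid <- matrix(0, H, H)
  if (model$n_qhid > 0) {
    idx <- which(row(Q_hid) != col(Q_hid))
    ord <- order((idx - 1) %% H, (idx - 1) %/% H)  # by (from, to)
    Q_hid[idx[ord]] <- qh
    diag(Q_hid) <- -rowSums(Q_hid)
  }
  Q_comb <- kronecker(model$Q_obs, diag(H)) + kronecker(diag(S), Q_hid)
  list(lambda = lambda, mu = mu, Q_hid = Q_hid, Q_comb = Q_comb)
}

#' SSE log-likelihood
#'
#' Integrates the extinction/data probability ODE system over the combined
#' observed x hidden states tipward-to-root (see [build_sse_model()] for the
#' model structure). Tips carry observed states only; every hidden level
#' consistent with the observed state receives the sampling fraction `rho`
#' as its initial data probability. The root combines states with
#' observed-data (FitzJohn) weights by default, optionally uniform, and is
#' conditioned on survival of both root lineages by default.
#'
#' @inheritParams mk_loglik
#' @param model an `sse_model`.
#' @param params parameter vector (see [sse_params()]).
#' @param root_weighting `"observed"` (data-weighted) or `"uniform"`.
#' @param condition_on_survival divide by the survival probability term.
#' @param rtol,atol integration tolerances.
#' @return Log-likelihood; attribute `n_clip` counts (tiny) negative-D
#'   clippings during integration.
#' @export
sse_loglik <- function(tree, states, model, params,
                       root_weighting = c("observed", "uniform"),
                       condition_on_survival = TRUE,
                       rtol = 1e-8, atol = 1e-10) {
  root_weighting <- match.arg(root_weighting)
  check_tree(tree, ultrametric = TRUE)
  if (!ape::is.binary(tree)) tree <- resolve_polytomies(tree)
  states <- check_tip_states(tree, states, model$S)
  states <- factor(as.character(states), levels = model$states)
  if (anyNA(states)) stop("tip states outside the model's alphabet")
  names(states) <- tree$tip.label
  pl <- sse_expand_params(model, params)
  po <- ape::reorder.phylo(tree, "postorder")
  res <- sse_loglik_cpp(po$edge, po$edge.length, ape::Ntip(po),
                        as.integer(states), model$S, model$H,
                        pl$lambda, pl$mu, pl$Q_comb, model$rho,
                        root_weighting == "observed",
                        condition_on_survival, rtol, atol)
  if (res$failed_edge > 0) {
    stop("ODE integration failed on postorder branch ", res$failed_edge)
  }
  structure(res$loglik, n_clip = res$n_clip)
}

#' Birth--death fit to branching times
#'
#' Maximum-likelihood constant-rate birth--death fit to a tree's branching
#' times under the reconstructed-process likelihood conditioned on survival
#' (Nee et al.), optimized over (net diversification, relative extinction)
#' or over the speciation rate alone when `fix_mu` is given.
#'
#' @param tree ultrametric `phylo`.
#' @param fix_mu optional fixed extinction rate (e.g. 0 for a Yule fit).
#' @return A `bd_fit` list: `lambda`, `mu`, `loglik`, `convergence`.
#' @export
bd_fit <- function(tree, fix_mu = NULL) {
  check_tree(tree, ultrametric = TRUE)
  ages <- sort(tree_height(tree) - branching_times(tree), decreasing = TRUE)
  N <- length(ages) + 1L
  if (N < 3) stop("need >= 2 branching times")
  loglik <- function(lambda, mu) {
    if (lambda <= 0 || mu < 0 || lambda <= mu) return(-Inf)
    r <- lambda - mu
    a <- mu / lambda
    lfactorial(N - 1) + (N - 2) * log(r) + r * sum(ages[-1]) +
      N * log(1 - a) - 2 * sum(log(exp(r * ages) - a))
  }
  if (!is.null(fix_mu)) {
    opt <- optimize(function(loglam) -loglik(exp(loglam), fix_mu),
                    lower = log(1e-8), upper = log(1e4))
    lam <- exp(opt$minimum)
    out <- list(lambda = lam, mu = fix_mu, loglik = -opt$objective,
                convergence = 0L)
  } else {
    obj <- function(p) {
      r <- exp(p[1]); a <- 1 / (1 + exp(-p[2]))  # a in (0, 1)
      -loglik(r / (1 - a), a * r / (1 - a))
    }
    fit <- nlminb(c(log(max(1e-3, (N - 2) / max(ages))), -2), obj)
    r <- exp(fit$par[1]); a <- 1 / (1 + exp(-fit$par[2]))
    # boundary polish: pure birth often wins; compare against mu ~ 0
    yule <- optimize(function(loglam) -loglik(exp(loglam), 0),
                     lower = log(1e-8), upper = log(1e4))
    if (-yule$objective >= -fit$objective) {
      out <- list(lambda = exp(yule$minimum), mu = 0,
                  loglik = -yule$objective, convergence = 0L)
    } else {
      out <- list(lambda = r / (1 - a), mu = a * r / (1 - a),
                  loglik = -fit$objective, convergence = fit$convergence)
    }
  }
  if (out$lambda <= out$mu) {
    warning("fitted lambda <= mu on a surviving tree; estimates suspect")
  }
  structure(out, class = "bd_fit")
}

#' 27-point starting grid for SSE optimization
#'
#' Builds the grid of all combinations of halving/keeping/doubling three
#' groups of initial values -- speciation (from a birth--death fit),
#' extinction (same fit) and hidden transition rates (mean of the best Mk
#' model's nonzero rates) -- scores each of the 27 combinations by
#' [sse_loglik()], and returns the best `top` as starting parameter sets in
#' descending initial log-likelihood. A zero extinction estimate degenerates
#' the mu grid to \{0, 1e-6, 2e-6\} to keep 27 distinct points.
#'
#' @inheritParams sse_loglik
#' @param bd a [bd_fit()] result (or list with `lambda`, `mu`).
#' @param q_mean mean nonzero Mk transition rate, used for hidden rates.
#' @param top number of starts to keep.
#' @return A list: `starts` (list of parameter vectors, best first),
#'   `scores` (their initial log-likelihoods), `grid` (all 27, with scores).
#' @export
starting_grid <- function(tree, states, model, bd, q_mean, top = 6L, ...) {
  lam0 <- bd$lambda
  mu0 <- if (bd$mu > 0) bd$mu else 1e-6
  q0 <- max(q_mean, 1e-8)
  mult <- c(0.5, 1, 2)
  grid <- expand.grid(ml = mult, mm = mult, mq = mult)
  params <- lapply(seq_len(nrow(grid)), function(i) {
    sse_params(model,
               lambda = rep(lam0 * grid$ml[i], model$n_lambda),
               mu = mu0 * grid$mm[i],
               q_hid = rep(q0 * grid$mq[i], model$n_qhid))
  })
  scores <- vapply(params, function(p) {
    tryCatch(as.numeric(sse_loglik(tree, states, model, p, ...)),
             error = function(e) -Inf)
  }, 0)
  ord <- order(scores, decreasing = TRUE)
  keep <- ord[seq_len(min(top, sum(is.finite(scores))))]
  list(starts = params[keep], scores = scores[keep],
       grid = cbind(grid, score = scores))
}

#' Fit an SSE model by penalized maximum likelihood
#'
#' Optimizes the penalized log-likelihood from each start with
#' simplex-style cycles (repeated Nelder--Mead until the cycle converges or
#' `max_cycles` is reached) followed by a quasi-Newton polish on the
#' log-parameter scale, keeping the best start. The optional penalty guards
#' against runaway speciation estimates: `penalty * sum((log(lambda_i /
#' lambda_bar))^2)` over speciation rates exceeding `10 * lambda_ref`
#' (a soft ridge; raw and penalized log-likelihoods are both reported, and
#' AIC uses the raw one).
#'
#' @inheritParams sse_loglik
#' @param starts list of starting parameter vectors (see [starting_grid()]).
#' @param penalty penalty weight (0 disables).
#' @param lambda_ref reference speciation rate for the penalty threshold
#'   (typically the birth--death estimate); `NULL` disables the penalty.
#' @param max_cycles cap on Nelder--Mead cycles per start.
#' @return An `sse_fit`: `model`, `params`, `logL` (raw), `logL_penalized`,
#'   `AIC`, `k`, `start_used`, `data_sig`.
#' @export
fit_sse <- function(tree, states, model, starts, penalty = 0.1,
                    lambda_ref = NULL, max_cycles = 75L,
                    root_weighting = "observed",
                    condition_on_survival = TRUE, rtol = 1e-8,
                    atol = 1e-10) {
  if (is.numeric(starts)) starts <- list(starts)
  if (!length(starts)) stop("need at least one start")
  nl <- model$n_lambda
  pen_fun <- function(params) {
    if (is.null(lambda_ref) || penalty <= 0) return(0)
    lam <- params[seq_len(nl)]
    hot <- lam > 10 * lambda_ref
    if (!any(hot)) return(0)
    penalty * sum((log(lam[hot] / mean(lam)))^2)
  }
  obj <- function(theta) {
    # keep the (unbounded) simplex phase inside the rate bounds
    excess <- sum(pmax(theta - log(1e3), 0) + pmax(log(1e-9) - theta, 0))
    if (excess > 0) return(1e9 * (1 + excess))
    params <- exp(theta)
    ll <- tryCatch(as.numeric(sse_loglik(tree, states, model, params,
                                         root_weighting = root_weighting,
                                         condition_on_survival =
                                           condition_on_survival,
                                         rtol = rtol, atol = atol)),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -(ll - pen_fun(params))
  }
  lo <- log(1e-9); hi <- log(1e3)
  # starts with tied speciation rates sit exactly on the hidden-label
  # symmetry manifold of the likelihood, where optimizers stall; every
  # start is therefore run twice with the log-rates spread apart in
  # opposite orders (a deterministic +/- log(2.5) fan across the
  # speciation entries)
  if (nl > 1) {
    fan <- log(2.5) * seq(-1, 1, length.out = nl)
    starts <- unlist(lapply(starts, function(s) {
      a <- s; a[seq_len(nl)] <- a[seq_len(nl)] * exp(fan)
      b <- s; b[seq_len(nl)] <- b[seq_len(nl)] * exp(rev(fan))
      list(a, b)
    }), recursive = FALSE)
  }
  best <- NULL
  diagnostics <- character(length(starts))
  for (i in seq_along(starts)) {
    theta <- pmin(pmax(log(pmax(starts[[i]], 1e-9)), lo), hi)
    res <- tryCatch({
      val <- obj(theta)
      if (val >= 1e10) stop("start has undefined likelihood")
      for (cyc in seq_len(max_cycles)) {
        nm <- optim(theta, obj, method = "Nelder-Mead",
                    control = list(maxit = 100 * length(theta)))
        improved <- val - nm$value
        theta <- nm$par; val <- nm$value
        if (nm$convergence == 0 || improved < 1e-4) break
      }
      pol <- nlminb(theta, obj, lower = lo, upper = hi)
      if (pol$objective < val) list(par = pol$par, value = pol$objective)
      else list(par = theta, value = val)
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) {
      diagnostics[i] <- "failed"
      next
    }
    diagnostics[i] <- sprintf("objective %.4f", res$value)
    if (is.null(best) || res$value < best$value) {
      best <- res; best$start <- i
    }
  }
  if (is.null(best)) {
    stop("all SSE starts failed: ", paste(diagnostics, collapse = "; "))
  }
  params <- setNames(exp(best$par), model$param_names)
  raw <- as.numeric(sse_loglik(tree, states, model, params,
                               root_weighting = root_weighting,
                               condition_on_survival = condition_on_survival,
                               rtol = rtol, atol = atol))
  structure(list(model = model, params = params, logL = raw,
                 logL_penalized = -best$value, k = model$n_free,
                 AIC = model_aic(model$n_free, raw),
                 start_used = best$start,
                 data_sig = data_signature(tree, states)),
            class = "sse_fit")
}

data_signature <- function(tree, states) {
  c(ntip = ape::Ntip(tree),
    total_length = round(sum(tree$edge.length), 10),
    states = paste(sort(table(as.character(states))), collapse = ","))
}

#' @export
print.sse_fit <- function(x, ...) {
  cat(toupper(x$model$kind), "H =", x$model$H, ": logL =",
      formatC(x$logL, digits = 6), ", k =", x$k, ", AIC =",
      formatC(x$AIC, digits = 6), "\n")
  invisible(x)
}

#' Compare fitted SSE models by AIC
#'
#' @param fits list of `sse_fit` objects on the same data.
#' @return `data.frame` sorted by AIC ascending: `model`, `H`, `k`, `logL`,
#'   `AIC`, `weight`.
#' @export
compare_sse_models <- function(fits) {
  if (length(fits) < 2) stop("need >= 2 fits")
  sigs <- lapply(fits, `[[`, "data_sig")
  if (!all(vapply(sigs, identical, NA, sigs[[1]]))) {
    stop("fits are not on identical data")
  }
  sse_fit_table(fits)
}

sse_fit_table <- function(fits) {
  tab <- data.frame(
    model = vapply(fits, function(f) f$model$kind, ""),
    H = vapply(fits, function(f) f$model$H, 0L),
    k = vapply(fits, `[[`, 0L, "k"),
    logL = vapply(fits, `[[`, 0, "logL"),
    AIC = vapply(fits, `[[`, 0, "AIC"))
  tab$weight <- aic_weights(tab$AIC)
  tab[order(tab$AIC), ]
}

#' Refit SSE models across assumed sampling fractions
#'
#' Refits every model at each sampling fraction rho and reports the
#' AIC-weight winner per rho, mirroring the robustness check that the
#' favored model class should not depend on the assumed completeness of the
#' phylogeny.
#'
#' @inheritParams fit_sse
#' @param models list of unfitted `sse_model`s.
#' @param rhos sampling fractions to sweep.
#' @param starts_for function(model) returning the list of starts to use;
#'   defaults to a single start at the parameter values 0.2/0.05/0.1.
#' @return A list: `winners` (`data.frame` rho, model, H, weight), `tables`
#'   (per-rho comparison tables).
#' @export
sampling_fraction_sweep <- function(tree, states, models,
                                    rhos = c(1, 0.5, 0.25, 0.125, 0.0625),
                                    starts_for = NULL, ...) {
  if (is.null(starts_for)) {
    starts_for <- function(m) list(sse_params(
      m, lambda = rep(0.2, m$n_lambda), mu = 0.05,
      q_hid = rep(0.1, m$n_qhid)))
  }
  tables <- lapply(rhos, function(r) {
    fits <- lapply(models, function(m) {
      m$rho <- r
      fit_sse(tree, states, m, starts_for(m), ...)
    })
    compare_sse_models(fits)
  })
  names(tables) <- paste0("rho_", rhos)
  winners <- do.call(rbind, lapply(seq_along(rhos), function(i) {
    top <- tables[[i]][1, ]
    data.frame(rho = rhos[i], model = top$model, H = top$H,
               weight = top$weight)
  }))
  list(winners = winners, tables = tables)
}
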