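# Clustering samples into biomes from community composition: weighted
# UniFrac distances, principal coordinates restricted to positive
# eigenvalues, PERMANOVA (global and pairwise with FDR), and k-medoid
# clustering with gap-statistic selection of k.

#' Weighted UniFrac distances between samples
#'
#' Phylogeny-aware dissimilarity weighting each branch of the taxon tree by
#' the difference in relative abundance of its descendant taxa between two
#' samples. Abundances are normalized to relative abundance per sample
#' before computation. Both the raw weighted form and the normalized form
#' (bounded in \[0, 1\]) are available; normalized is the default.
#'
#' @param counts samples x taxa abundance matrix (row/column names required).
#' @param tree rooted `phylo` whose tips cover every taxon in `counts`.
#' @param normalized divide by the abundance-weighted total branch length.
#' @return A symmetric distance matrix with sample labels.
#' @export
weighted_unifrac <- function(counts, tree, normalized = TRUE) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts needs sample row names and taxon column names")
  }
  missing <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing)) {
    stop("taxa missing from tree: ", paste(head(missing, 10), collapse = ", "))
  }
  if (any(counts < 0)) stop("negative abundances")
  if (any(rowSums(counts) == 0)) stop("samples with zero total abundance")
  if (length(tree$tip.label) > ncol(counts)) {
    tree <- ape::keep.tip(tree, colnames(counts))
  }
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(t(counts), taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree)
  )
  d <- phyloseq::UniFrac(ps, weighted = TRUE, normalized = normalized)
  m <- as.matrix(d)
  m[rownames(counts), rownames(counts)]
}

check_distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-12 * max(1, max(abs(D)))) {
    stop("distance matrix not symmetric")
  }
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be 0")
  if (any(D < 0)) stop("negative distances")
  D
}

#' Principal coordinates restricted to positive eigenvalues
#'
#' Classical (metric) multidimensional scaling of a distance matrix via the
#' double-centered -D^2/2 matrix, keeping only axes with positive
#' eigenvalues: non-Euclidean distance matrices produce negative eigenvalues
#' whose axes are discarded (and counted) rather than projected.
#'
#' @param D symmetric distance matrix (zero diagonal).
#' @return A list: `coordinates` (n x k, descending eigenvalue order),
#'   `eigenvalues` (all n), `n_dropped` (axes with eigenvalue <= 0).
#' @export
pcoa_positive <- function(D) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  fit <- suppressWarnings(cmdscale(as.dist(D), k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- 1e-8 * max(abs(eig))
  pos <- which(eig > tol)
  if (!length(pos)) stop("no positive eigenvalues: degenerate distance matrix")
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       n_dropped = sum(eig <= tol))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA partitioning squared distances among
#' groups (Gower-centered inner-product form), with significance from label
#' permutations: p = (1 + #\{permuted F >= observed F\}) / (1 + n_perm), so
#' p can never be exactly 0. A wrapper over [vegan::adonis2()].
#'
#' @param D distance matrix.
#' @param groups group label per sample (>= 2 distinct groups).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return A list with `f` (pseudo-F), `r2`, `p` and `n_perm`.
#' @export
permanova <- function(D, groups, n_perm = 9999L, seed = NULL) {
  D <- check_distance_matrix(D)
  groups <- as.factor(groups)
  if (length(groups) != nrow(D)) stop("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2) {
    stop("need >= 2 groups (a single group spans the whole sample set)")
  }
  dat <- data.frame(grp = droplevels(groups))
  res <- with_seed(seed,
                   vegan::adonis2(as.dist(D) ~ grp, data = dat,
                                  permutations = n_perm))
  list(f = res$F[1], r2 = res$R2[1], p = res$`Pr(>F)`[1],
       n_perm = as.integer(n_perm))
}

#' Pairwise PERMANOVA with FDR adjustment
#'
#' Runs [permanova()] on every pair of groups and adjusts the p-values
#' across pairs with the Benjamini--Hochberg step-up procedure.
#'
#' @inheritParams permanova
#' @return A `data.frame` with one row per pair: `group1`, `group2`, `f`,
#'   `r2`, `p`, `p_adjusted`.
#' @export
pairwise_permanova <- function(D, groups, n_perm = 9999L, seed = NULL) {
  D <- check_distance_matrix(D)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  pairs <- combn(levels(groups), 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    idx <- which(groups %in% pr)
    res <- permanova(D[idx, idx, drop = FALSE], groups[idx], n_perm = n_perm,
                     seed = derive_seed(seed, paste(pr, collapse = "|")))
    data.frame(group1 = pr[1], group2 = pr[2], f = res$f, r2 = res$r2,
               p = res$p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p, method = "BH")
  out
}

#' k-medoid clustering with gap-statistic choice of k
#'
#' Partitioning Around Medoids for each candidate k, with the number of
#' clusters chosen by the gap statistic: Gap(k) compares the observed
#' log within-cluster dispersion to its expectation under B uniform draws
#' over the per-axis bounding box of the data, and the chosen k is the
#' smallest k with Gap(k) >= Gap(k+1) - s_\{k+1\} (the 1-SE rule). Backed by
#' [cluster::pam()], [cluster::clusGap()] and [cluster::maxSE()]; PAM uses
#' the deterministic BUILD initialization, so the seed only affects the
#' reference draws.
#'
#' @param X numeric matrix of coordinates (samples x axes).
#' @param k_max largest number of clusters considered (>= 1; candidate k runs
#'   from 1 to `k_max`, capped at n - 1).
#' @param B number of uniform reference data sets (>= 10).
#' @param seed integer seed for the reference draws.
#' @return A list: `k` (chosen), `assignments` (named integer vector),
#'   `medoids` (row indices of medoids at the chosen k), `gap_curve`
#'   (`data.frame` with `k`, `logW`, `E_logW`, `gap`, `se`).
#' @export
kmedoid_gap <- function(X, k_max = 8L, B = 100L, seed = NULL) {
  X <- as.matrix(X)
  if (B < 10) stop("B must be >= 10")
  k_max <- min(as.integer(k_max), nrow(X) - 1L)
  if (k_max < 1) stop("k_max must be >= 1")
  pam_fun <- function(x, k) list(cluster = cluster::pam(x, k,
                                                        cluster.only = TRUE))
  gap <- with_seed(seed,
                   cluster::clusGap(X, FUNcluster = pam_fun, K.max = k_max,
                                    B = B, spaceH0 = "original",
                                    verbose = FALSE))
  tab <- gap$Tab
  k_hat <- if (k_max == 1L) 1L else
    cluster::maxSE(tab[, "gap"], tab[, "SE.sim"], method = "Tibs2001SEmax")
  fit <- cluster::pam(X, k_hat)
  list(k = as.integer(k_hat),
       assignments = setNames(fit$clustering, rownames(X)),
       medoids = fit$id.med,
       gap_curve = data.frame(k = seq_len(nrow(tab)), logW = tab[, "logW"],
                              E_logW = tab[, "E.logW"], gap = tab[, "gap"],
                              se = tab[, "SE.sim"]))
}

#' Write / read a distance matrix as square TSV
#'
#' @param D distance matrix.
#' @param file path.
#' @export
write_distance_matrix <- function(D, file) {
  write.table(as.matrix(D), file, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(file)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(file) {
  m <- as.matrix(read.table(file, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE))
  check_distance_matrix(m)
}
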