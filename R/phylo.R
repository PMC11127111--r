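# Tree data model and utilities. Trees are rooted ape "phylo" objects with
# branch lengths in relative time; the forward-time convention used
# throughout the package puts the root node at time 0 and (ultrametric) tips
# at time T = tree height.

#' Read a rooted tree from a newick string or file
#'
#' A thin, strict wrapper around [ape::read.tree()]: the newick text is
#' validated before parsing so that malformed input fails with the character
#' position of the offending parenthesis, and trees without a complete set of
#' branch lengths are rejected rather than silently defaulted.
#'
#' @param text newick string (exactly one tree), or `NULL` if `file` is given.
#' @param file path to a newick file, ignored when `text` is supplied.
#' @return A rooted `phylo` object with branch lengths.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tree_height(tr)
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed newick: unmatched ')' at character position ", i)
      }
    }
  }
  if (depth > 0L) {
    stop("malformed newick: ", depth, " unclosed '(' by character position ",
         length(chars))
  }
  if (!grepl(";\\s*$", text)) {
    stop("malformed newick: missing terminal ';' at character position ",
         nchar(text))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick: could not parse tree")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("missing branch length(s): every edge must carry a length")
  }
  check_tree(tree)
  tree
}

#' Write a tree as a newick string or file
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the newick string is returned.
#' @return The newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Basic tree validation
#'
#' Checks the invariants every tree in this package must satisfy: rooted,
#' nonnegative branch lengths, unique tip labels, and (optionally)
#' ultrametricity within a relative tolerance. Trees failing ultrametricity
#' are rejected, never silently rescaled; see [make_ultrametric()] for the
#' explicit repair utility.
#'
#' @param tree a `phylo` object.
#' @param ultrametric require all tip depths equal within `tol` x height.
#' @param tol relative ultrametricity tolerance.
#' @param min_tips minimum number of tips.
#' @return `tree`, invisibly.
#' @export
check_tree <- function(tree, ultrametric = FALSE, tol = 1e-6, min_tips = 2L) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  # basal polytomies are tolerated on input (ape calls such trees
  # unrooted); fully binary trees must be rooted
  if (tree$Nnode == ape::Ntip(tree) - 1L && !ape::is.rooted(tree)) {
    stop("tree must be rooted")
  }
  if (ape::Ntip(tree) < min_tips) {
    stop("tree has ", ape::Ntip(tree), " tips; need at least ", min_tips)
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths present")
  if (anyDuplicated(tree$tip.label)) stop("tip labels are not unique")
  if (ultrametric && !is_ultrametric_tree(tree, tol = tol)) {
    stop("tree is not ultrametric within relative tolerance ", tol,
         "; see make_ultrametric() for an explicit repair")
  }
  invisible(tree)
}

node_times <- function(tree) {
  # forward time of every node, root node = 0
  ape::node.depth.edgelength(tree)
}

#' Tree height (root-to-tip time)
#'
#' @param tree a `phylo` object.
#' @return Maximum root-to-tip path length.
#' @export
tree_height <- function(tree) {
  max(node_times(tree)[seq_len(ape::Ntip(tree))])
}

#' Test ultrametricity under the package's relative tolerance
#'
#' @inheritParams check_tree
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  depths <- node_times(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depths)
  if (h == 0) return(TRUE)
  (max(depths) - min(depths)) <= tol * h
}

#' Branching times in forward time
#'
#' Internal-node times measured from the root (root = 0, tips at the tree
#' height), sorted ascending. A binary `n`-tip tree has `n - 1` of them.
#'
#' @param tree an ultrametric `phylo` object.
#' @param tol relative ultrametricity tolerance.
#' @return Numeric vector of length (number of internal nodes).
#' @export
#' @examples
#' branching_times(read_newick("((A:1,B:1):1,C:2);"))  # 0 1
branching_times <- function(tree, tol = 1e-6) {
  check_tree(tree, ultrametric = TRUE, tol = tol)
  nt <- ape::Ntip(tree)
  times <- node_times(tree)[(nt + 1L):(nt + tree$Nnode)]
  sort(times)
}

#' Lineage-through-time curve
#'
#' Counts reconstructed lineages as a step function of forward time: 2
#' immediately after the root split (time 0), +1 at each later branching
#' event, ending at the tip count at the tree height.
#'
#' @param tree an ultrametric `phylo` object.
#' @return A `data.frame` with columns `time` and `lineages`.
#' @export
compute_ltt <- function(tree) {
  bt <- branching_times(tree)
  data.frame(time = bt, lineages = seq_along(bt) + 1L)
}

#' Subsample tips of a tree
#'
#' Drops tips uniformly at random, either to a fixed fraction of the tree
#' (`fraction` mode; the retained count is `floor(fraction * n)`) or to an
#' equal number of tips per character state (`equal_per_state` mode). The
#' pruned tree has degree-2 nodes collapsed with branch lengths summed, so
#' tip depths (and hence ultrametricity) are unchanged.
#'
#' @param tree a `phylo` object.
#' @param mode `"fraction"` or `"equal_per_state"`.
#' @param fraction fraction of tips to keep, in (0, 1] (`fraction` mode).
#' @param target tips to keep per state (`equal_per_state` mode); must not
#'   exceed the smallest state class.
#' @param states named vector/factor of tip states (`equal_per_state` mode).
#' @param seed integer seed for reproducible tip selection.
#' @return The pruned `phylo` object.
#' @export
subsample_tree <- function(tree, mode = c("fraction", "equal_per_state"),
                           fraction = 0.8, target = NULL, states = NULL,
                           seed = NULL) {
  mode <- match.arg(mode)
  check_tree(tree)
  tips <- tree$tip.label
  with_seed(seed, {
    if (mode == "fraction") {
      if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
        stop("fraction must be in (0, 1]")
      }
      n_keep <- floor(fraction * length(tips))
      if (n_keep < 2) stop("fraction leaves fewer than 2 tips")
      if (n_keep == length(tips)) return(tree)
      keep <- sample(tips, n_keep)
    } else {
      if (is.null(states) || is.null(target)) {
        stop("equal_per_state mode needs `states` and `target`")
      }
      states <- states[tips]
      if (anyNA(states)) stop("states missing for some tips")
      counts <- table(as.character(states))
      if (target > min(counts)) {
        stop("target (", target, ") exceeds the smallest state class (",
             min(counts), ")")
      }
      keep <- unlist(lapply(names(counts), function(s) {
        sample(tips[as.character(states) == s], target)
      }), use.names = FALSE)
    }
    ape::keep.tip(tree, keep)
  })
}

#' Rescale a tree to a given height
#'
#' Multiplies all branch lengths so the tree height equals `height`. Exposed
#' as an explicit option because relative-time trees are sometimes analysed
#' at unit height; it is never applied automatically.
#'
#' @param tree a `phylo` object.
#' @param height target height (> 0).
#' @return The rescaled tree.
#' @export
rescale_tree <- function(tree, height = 1) {
  stopifnot(height > 0)
  h <- tree_height(tree)
  if (h <= 0) stop("tree has zero height")
  tree$edge.length <- tree$edge.length * (height / h)
  tree
}

#' Repair a nearly ultrametric tree by adjusting terminal branches
#'
#' Sets every tip depth to a common target depth by lengthening or shortening
#' terminal branches. This is an explicit utility: likelihood functions
#' reject non-ultrametric trees rather than calling it silently.
#'
#' @param tree a `phylo` object.
#' @param target `"mean"` (average tip depth; errors if a terminal branch
#'   would become negative) or `"max"` (deepest tip; always feasible).
#' @return An ultrametric tree.
#' @export
make_ultrametric <- function(tree, target = c("mean", "max")) {
  target <- match.arg(target)
  check_tree(tree)
  nt <- ape::Ntip(tree)
  depths <- node_times(tree)[seq_len(nt)]
  goal <- if (target == "mean") mean(depths) else max(depths)
  term <- match(seq_len(nt), tree$edge[, 2])
  new_len <- tree$edge.length[term] + (goal - depths)
  if (any(new_len < 0)) {
    stop("mean-depth target makes ", sum(new_len < 0),
         " terminal branch(es) negative; use target = \"max\"")
  }
  tree$edge.length[term] <- new_len
  tree
}

#' Resolve polytomies deterministically
#'
#' Polytomies are tolerated on input but all likelihood computations require
#' binary trees; this resolves them left-to-right with zero-length edges
#' (non-random [ape::multi2di()]).
#'
#' @param tree a `phylo` object.
#' @return A binary tree.
#' @export
resolve_polytomies <- function(tree) {
  ape::multi2di(tree, random = FALSE)
}

#' Read / write tip-state tables
#'
#' Tip states travel as 2-column tab-separated tables (`tip_label`, `state`).
#'
#' @param file path to a TSV file.
#' @return `read_tip_states`: a factor named by tip label.
#' @export
read_tip_states <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("tip-state table needs columns tip_label, state")
  setNames(factor(d[[2]]), d[[1]])
}

#' @rdname read_tip_states
#' @param states factor (or character) named by tip label.
#' @export
write_tip_states <- function(states, file) {
  write.table(data.frame(tip_label = names(states),
                         state = as.character(states)),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

check_tip_states <- function(tree, states, S = NULL) {
  if (is.null(names(states))) stop("tip states must be named by tip label")
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing)) {
    stop("tips without a state: ", paste(head(missing, 5), collapse = ", "))
  }
  states <- states[tree$tip.label]
  if (!is.factor(states)) states <- factor(states)
  if (anyNA(states)) stop("NA tip states")
  if (!is.null(S) && nlevels(states) > S) {
    stop("more observed states (", nlevels(states), ") than the model has (",
         S, ")")
  }
  states
}
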