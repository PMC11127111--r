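# Occupancy bootstrap classification of taxa into biome preferences, and the
# collapse from the seven raw preferences to the five analysis states.

#' State alphabets for biome preference
#'
#' With three biomes (freshwater, marine, land) a taxon's raw preference is
#' one of seven categories: a specialist in one biome, a two-biome
#' generalist, or a full generalist. For comparative analyses the three
#' rarest categories (full generalist, marine+land generalist,
#' freshwater+marine generalist) are merged into a single "marine
#' generalist" state, giving five analysis states.
#'
#' @return Character vector of state names.
#' @export
raw_preference_states <- function() {
  c("freshwater specialist", "marine specialist", "land specialist",
    "freshwater+marine generalist", "marine+land generalist",
    "freshwater+land generalist", "full generalist")
}

#' @rdname raw_preference_states
#' @export
analysis_states <- function() {
  c("freshwater specialist", "marine specialist", "land specialist",
    "freshwater+land generalist", "marine generalist")
}

#' Expected biome availability
#'
#' The expected proportion of presence records that would fall in each biome
#' for a taxon with no biome affinity, "akin to habitat availability".
#' Availability is an explicit input (not derived from sample counts): the
#' default is the study design's printed proportions for land/marine/
#' freshwater, which are close to, but not exactly, the sample-count
#' fractions 27/63, 25/63, 11/63.
#'
#' @param proportions named positive numeric vector summing to 1 (within
#'   1e-6).
#' @return A validated named numeric vector (class `biome_availability`).
#' @export
biome_availability <- function(proportions = c(land = 0.44, marine = 0.38,
                                               freshwater = 0.18)) {
  if (is.null(names(proportions)) || any(!nzchar(names(proportions)))) {
    stop("availability proportions must be named by biome")
  }
  if (any(proportions <= 0)) stop("availability proportions must be > 0")
  if (abs(sum(proportions) - 1) > 1e-6) {
    stop("availability proportions must sum to 1 (got ", sum(proportions), ")")
  }
  structure(proportions, class = "biome_availability")
}

label_for_biome_set <- function(biomes, all_biomes) {
  biomes <- sort(unique(biomes))
  if (length(biomes) == 1) return(paste(biomes, "specialist"))
  if (length(biomes) == length(all_biomes)) return("full generalist")
  canon <- c("freshwater", "marine", "land")
  ord <- if (all(biomes %in% canon)) canon[canon %in% biomes] else biomes
  paste0(paste(ord, collapse = "+"), " generalist")
}

#' Classify one taxon's biome preference from presence/absence
#'
#' A taxon present in exactly one biome is that biome's specialist, no
#' bootstrap needed. Otherwise its preference is read off a bootstrap of its
#' presence records: each of `n_reps` replicates draws `n_draws` records
#' with replacement from the multiset of samples where the taxon is present
#' and computes the per-biome proportion of the draws; the taxon has
#' affinity for biome b if at least a fraction `tail` of replicates put its
#' proportion in b at or above b's availability (equivalently, the upper
#' `1 - tail` bootstrap quantile reaches the availability). The raw
#' preference is the set of affinity biomes.
#'
#' @param presence 0/1 (or count, thresholded at > 0) vector named by sample.
#' @param sample_biomes named character vector mapping sample -> biome.
#' @param avail a [biome_availability()] vector covering every biome.
#' @param n_draws presence records drawn per bootstrap replicate.
#' @param n_reps bootstrap replicates.
#' @param tail affinity threshold on the fraction of replicates.
#' @param seed integer seed.
#' @return A list (class `preference_call`): `raw`, `collapsed`, `biomes`
#'   (affinity set), `bootstrapped` (logical), `quantiles` (per-biome 2.5%,
#'   50%, 97.5% bootstrap proportions, `NULL` for single-biome specialists).
#' @export
classify_taxon <- function(presence, sample_biomes, avail = biome_availability(),
                           n_draws = 100L, n_reps = 1000L, tail = 0.025,
                           seed = NULL) {
  if (is.null(names(presence))) stop("presence vector must be named by sample")
  present <- names(presence)[presence > 0]
  if (!length(present)) stop("all-zero presence vector")
  pb <- sample_biomes[present]
  if (anyNA(pb)) {
    stop("samples without a biome: ",
         paste(head(present[is.na(pb)], 5), collapse = ", "))
  }
  unknown <- setdiff(unique(pb), names(avail))
  if (length(unknown)) {
    stop("biome(s) missing from availability: ",
         paste(unknown, collapse = ", "))
  }
  all_biomes <- names(avail)
  seen <- unique(pb)
  if (length(seen) == 1L) {
    raw <- label_for_biome_set(seen, all_biomes)
    return(structure(list(raw = raw, collapsed = collapse_preference(raw),
                          biomes = seen, bootstrapped = FALSE,
                          quantiles = NULL),
                     class = "preference_call"))
  }
  m <- length(pb)
  props <- with_seed(seed, {
    draws <- matrix(pb[sample.int(m, n_draws * n_reps, replace = TRUE)],
                    nrow = n_draws)
    vapply(all_biomes, function(b) colSums(draws == b) / n_draws,
           numeric(n_reps))
  })
  # affinity: fraction of replicates with proportion >= availability
  exceed <- colMeans(props >= rep(avail, each = n_reps))
  affinity <- all_biomes[exceed >= tail]
  raw <- label_for_biome_set(affinity, all_biomes)
  q <- apply(props, 2, quantile, probs = c(0.025, 0.5, 0.975), names = TRUE)
  structure(list(raw = raw, collapsed = collapse_preference(raw),
                 biomes = affinity, bootstrapped = TRUE, quantiles = q),
            class = "preference_call")
}

#' Collapse a raw 7-state preference to the 5 analysis states
#'
#' Full generalists, marine+land generalists and freshwater+marine
#' generalists merge into "marine generalist"; the three specialists and the
#' freshwater+land generalist map to themselves.
#'
#' @param raw raw preference label(s).
#' @return Character vector of analysis-state labels.
#' @export
collapse_preference <- function(raw) {
  map <- c(setNames(raw_preference_states()[1:3], raw_preference_states()[1:3]),
           "freshwater+marine generalist" = "marine generalist",
           "marine+land generalist" = "marine generalist",
           "freshwater+land generalist" = "freshwater+land generalist",
           "full generalist" = "marine generalist")
  out <- map[raw]
  if (anyNA(out)) {
    stop("unknown raw preference label(s): ",
         paste(unique(raw[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Classify every taxon of an occupancy table
#'
#' Applies [classify_taxon()] to each column, with per-taxon child seeds
#' derived from the root seed and the taxon id (classification is therefore
#' independent of taxon ordering).
#'
#' @param table samples x taxa presence (0/1 or counts) matrix.
#' @param sample_biomes named character vector mapping sample -> biome.
#' @inheritParams classify_taxon
#' @return A list: `calls` (data.frame of per-taxon raw/collapsed labels and
#'   bootstrap flags), `quantiles` (list), `summary` (see
#'   [preference_summary()]).
#' @export
classify_table <- function(table, sample_biomes, avail = biome_availability(),
                           n_draws = 100L, n_reps = 1000L, tail = 0.025,
                           seed = NULL) {
  if (is.null(colnames(table))) stop("taxa must be named (column names)")
  calls <- lapply(colnames(table), function(tx) {
    classify_taxon(setNames(table[, tx], rownames(table)), sample_biomes,
                   avail, n_draws = n_draws, n_reps = n_reps, tail = tail,
                   seed = derive_seed(seed, tx))
  })
  names(calls) <- colnames(table)
  df <- data.frame(
    taxon = colnames(table),
    raw = vapply(calls, `[[`, "", "raw"),
    collapsed = vapply(calls, `[[`, "", "collapsed"),
    bootstrapped = vapply(calls, `[[`, NA, "bootstrapped"),
    row.names = NULL
  )
  raw_counts <- table(factor(df$raw, levels = raw_preference_states()))
  list(calls = df,
       quantiles = lapply(calls, `[[`, "quantiles"),
       summary = preference_summary(raw_counts))
}

#' Summarize biome-preference counts
#'
#' From per-category raw counts, reports the total, the per-category and
#' collapsed-state counts, the percentage of specialists, and the number of
#' taxa spanning the salt barrier (present on both the saline and nonsaline
#' side: marine+land, freshwater+marine and full generalists).
#'
#' @param raw_counts named counts over (a subset of) the seven raw states,
#'   or a factor/character vector of raw calls to be tabulated.
#' @return A list: `n_total`, `raw_counts`, `collapsed_counts`,
#'   `pct_specialist`, `n_salt_crossing`.
#' @export
preference_summary <- function(raw_counts) {
  if (!is.numeric(raw_counts)) {
    raw_counts <- table(factor(raw_counts, levels = raw_preference_states()))
  }
  bad <- setdiff(names(raw_counts), raw_preference_states())
  if (length(bad)) stop("unknown raw states: ", paste(bad, collapse = ", "))
  full <- setNames(numeric(7), raw_preference_states())
  full[names(raw_counts)] <- raw_counts
  n <- sum(full)
  specialists <- sum(full[grep("specialist", names(full))])
  salt <- sum(full[c("freshwater+marine generalist",
                     "marine+land generalist", "full generalist")])
  collapsed <- tapply(full, collapse_preference(names(full)), sum)
  list(n_total = n, raw_counts = full,
       collapsed_counts = collapsed[analysis_states()],
       pct_specialist = 100 * specialists / n,
       n_salt_crossing = salt)
}

#' @export
print.preference_call <- function(x, ...) {
  cat("biome preference:", x$raw,
      if (x$raw != x$collapsed) paste0("(analysis state: ", x$collapsed, ")"),
      "\n")
  cat(if (x$bootstrapped) "bootstrap call" else
    "single-biome specialist (bootstrap skipped)", "\n")
  invisible(x)
}
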