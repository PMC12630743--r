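#' Matching configuration for individual identification
#'
#' @param min_overlap Minimum jointly called loci before a pair of samples
#'   may be linked (pairs below it are never linked, only flagged).
#' @param mismatch_threshold Maximum mismatching loci for two samples to be
#'   treated as the same individual; `"auto"` estimates it from the
#'   pairwise mismatch distribution via [auto_threshold()].
#' @param min_gap Smallest empty gap (in mismatch counts) accepted by the
#'   automatic threshold rule.
#' @return A list of class `match_config`.
#' @export
match_config <- function(min_overlap = 79, mismatch_threshold = 16,
                         min_gap = 3) {
  stopifnot(min_overlap >= 1,
            identical(mismatch_threshold, "auto") || mismatch_threshold >= 0)
  structure(list(min_overlap = min_overlap,
                 mismatch_threshold = mismatch_threshold,
                 min_gap = min_gap), class = "match_config")
}

#' Pairwise allele mismatches between two samples
#'
#' Overlap is the number of loci called in both samples; mismatches are
#' overlap loci whose unordered allele pairs differ. The presence-scored Y
#' marker participates through its call string like any other locus.
#'
#' @param calls_a,calls_b Named call vectors over the same marker universe.
#' @return A list `n_mismatch`, `n_overlap`.
#' @export
pairwise_mismatch <- function(calls_a, calls_b) {
  both <- !is.na(calls_a) & !is.na(calls_b)
  list(n_mismatch = sum(calls_a[both] != calls_b[both]),
       n_overlap = sum(both))
}

#' All pairwise mismatch counts of a genotype table
#'
#' @param geno Genotype table.
#' @return Tibble `sample_a`, `sample_b`, `n_mismatch`, `n_overlap` for all
#'   unordered pairs.
#' @export
pairwise_mismatch_table <- function(geno) {
  cm <- call_matrix(geno)
  n <- nrow(cm)
  if (n < 2) {
    return(tibble::tibble(sample_a = character(0), sample_b = character(0),
                          n_mismatch = integer(0), n_overlap = integer(0)))
  }
  # integer-code the calls so pair comparisons are cheap vector ops
  codes <- matrix(match(cm, sort(unique(as.vector(cm)))), nrow = n)
  called <- !is.na(codes)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  n_mismatch <- integer(np); n_overlap <- integer(np)
  for (k in seq_len(np)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    both <- called[i, ] & called[j, ]
    n_overlap[k] <- sum(both)
    n_mismatch[k] <- sum(codes[i, both] != codes[j, both])
  }
  tibble::tibble(sample_a = rownames(cm)[pairs[1, ]],
                 sample_b = rownames(cm)[pairs[2, ]],
                 n_mismatch = n_mismatch, n_overlap = n_overlap)
}

#' Estimate the mismatch threshold from the pairwise distribution
#'
#' Pairs of samples from the same individual (replicates, resamplings)
#' mismatch only through genotyping error and sit near zero; pairs of
#' different individuals — even full siblings — mismatch at a large
#' fraction of a high-MAF panel. The threshold is the midpoint of the
#' widest run of empty mismatch counts between the low mode and the rest
#' of the mass, computed over pairs with sufficient overlap. When no gap of
#' at least `min_gap` exists the configured default is returned with a
#' warning.
#'
#' @param pairs Output of [pairwise_mismatch_table()].
#' @param config A [match_config()].
#' @return Integer threshold.
#' @export
auto_threshold <- function(pairs, config = match_config()) {
  qual <- pairs[pairs$n_overlap >= config$min_overlap, ]
  fallback <- if (identical(config$mismatch_threshold, "auto")) 16
              else config$mismatch_threshold
  if (nrow(qual) < 20) {
    warning("fewer than 20 qualifying pairs; using fallback threshold ",
            fallback)
    return(fallback)
  }
  counts <- sort(unique(qual$n_mismatch))
  if (length(counts) < 2) {
    warning("degenerate mismatch distribution; using fallback threshold ",
            fallback)
    return(fallback)
  }
  gaps <- diff(counts) - 1L
  if (max(gaps) < config$min_gap) {
    warning("no gap of width >= ", config$min_gap,
            "; using fallback threshold ", fallback)
    return(fallback)
  }
  k <- which.max(gaps)  # widest gap; ties take the lowest (left-most) gap
  lo <- counts[k]; hi <- counts[k + 1]
  as.integer(floor((lo + hi) / 2))
}

#' Cluster samples into individuals by allele matching
#'
#' Builds a graph with an edge between every pair of samples whose overlap
#' reaches `min_overlap` and whose mismatch count is at or below the
#' threshold; connected components are individuals (single linkage — the
#' monitoring semantics of "same animal sampled repeatedly"). Pairs with
#' insufficient overlap are never linked and are returned as flagged pairs.
#' Each cluster receives a consensus genotype by per-locus majority over
#' its members, ties recoded missing, and a stable individual id in
#' first-seen sample order.
#'
#' @param geno Genotype table of passing samples.
#' @param config A [match_config()]; `mismatch_threshold = "auto"` triggers
#'   [auto_threshold()].
#' @return A list of class `individual_clusters`: `clusters` (tibble
#'   `individual_id`, `sample_id`), `consensus` (genotype table keyed by
#'   individual id), `pairs` (all pairwise counts with `linked`),
#'   `threshold` used, and `insufficient_overlap` (flagged pairs).
#' @export
cluster_individuals <- function(geno, config = match_config()) {
  if (nrow(geno) == 0) {
    empty <- tibble::tibble(individual_id = character(0),
                            sample_id = character(0))
    return(structure(list(clusters = empty, consensus = geno,
                          pairs = pairwise_mismatch_table(geno),
                          threshold = NA_integer_,
                          insufficient_overlap = empty),
                     class = "individual_clusters"))
  }
  pairs <- pairwise_mismatch_table(geno)
  thr <- if (identical(config$mismatch_threshold, "auto")) {
    auto_threshold(pairs, config)
  } else config$mismatch_threshold
  pairs$linked <- pairs$n_overlap >= config$min_overlap &
    pairs$n_mismatch <= thr
  g <- igraph::graph_from_data_frame(
    pairs[pairs$linked, c("sample_a", "sample_b")],
    directed = FALSE,
    vertices = data.frame(name = geno$sample_id))
  comp <- igraph::components(g)$membership
  # stable ids in first-seen sample order
  first_seen <- comp[geno$sample_id]
  relabel <- stats::setNames(seq_along(unique(first_seen)),
                             unique(first_seen))
  ind <- sprintf("IND_%03d", relabel[as.character(first_seen)])
  clusters <- tibble::tibble(individual_id = ind, sample_id = geno$sample_id)
  cons <- consensus_by_group(geno, stats::setNames(ind, geno$sample_id))
  structure(list(
    clusters = clusters, consensus = cons, pairs = pairs, threshold = thr,
    insufficient_overlap = pairs[pairs$n_overlap < config$min_overlap,
                                 c("sample_a", "sample_b", "n_overlap")]),
    class = "individual_clusters")
}

# per-locus majority consensus; ties -> missing
consensus_by_group <- function(geno, group_of) {
  cm <- call_matrix(geno)
  ug <- unique(unname(group_of[rownames(cm)]))
  cons <- matrix(NA_character_, length(ug), ncol(cm),
                 dimnames = list(ug, colnames(cm)))
  for (g in ug) {
    rows <- cm[group_of[rownames(cm)] == g, , drop = FALSE]
    for (j in seq_len(ncol(rows))) {
      calls <- rows[!is.na(rows[, j]), j]
      if (!length(calls)) next
      tab <- sort(table(calls), decreasing = TRUE)
      if (length(tab) == 1 || tab[1] > tab[2]) cons[g, j] <- names(tab)[1]
    }
  }
  genotype_table(ug, cons)
}

#' Rand index between two partitions
#'
#' Agreement between a recovered partition and a truth partition of the
#' same samples: the fraction of sample pairs on which the two partitions
#' agree (together in both, or apart in both).
#'
#' @param labels_a,labels_b Cluster labels aligned by position.
#' @return The Rand index in `[0, 1]`.
#' @export
rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) >= 2)
  pairs <- utils::combn(length(labels_a), 2)
  same_a <- labels_a[pairs[1, ]] == labels_a[pairs[2, ]]
  same_b <- labels_b[pairs[1, ]] == labels_b[pairs[2, ]]
  mean(same_a == same_b)
}
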