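#' Build an assignment reference set
#'
#' Pools labelled reference genotypes into groups and tallies per-group
#' allele counts at the autosomal panel markers. When per-sample ancestry
#' coefficients are supplied (from an external admixture analysis), members
#' below `q_threshold` are excluded from the counts — reference groups
#' should contain only confidently assigned individuals.
#'
#' @param geno Reference genotype table.
#' @param groups Tibble `sample_id`, `group`, optional `ancestry_q`.
#' @param markers [marker_info()] tibble; only autosomal markers enter the
#'   reference (X and Y transmission makes their frequencies sex-dependent).
#' @param q_threshold Minimum ancestry coefficient for inclusion.
#' @return A list of class `reference_set`: `groups`, `markers` (ids),
#'   `counts` (per group: matrix markers x 2 allele counts), `members`.
#' @export
build_reference_set <- function(geno, groups, markers, q_threshold = 0.85) {
  groups <- tibble::as_tibble(groups)
  if ("ancestry_q" %in% names(groups)) {
    groups <- groups[is.na(groups$ancestry_q) |
                       groups$ancestry_q >= q_threshold, ]
  }
  auto <- markers$marker_id[markers$chrom_class == "AUTOSOME"]
  auto <- intersect(auto, marker_ids(geno))
  gnames <- unique(groups$group)
  counts <- list(); members <- list()
  for (g in gnames) {
    ids <- intersect(groups$sample_id[groups$group == g], geno$sample_id)
    if (anyDuplicated(unlist(members)) || any(ids %in% unlist(members))) {
      warning("sample(s) present in more than one reference group")
    }
    members[[g]] <- ids
    sub <- geno[geno$sample_id %in% ids, c("sample_id", auto)]
    counts[[g]] <- allele_count_matrix(sub, markers)
  }
  structure(list(groups = gnames, markers = auto, counts = counts,
                 members = members, marker_meta = markers,
                 q_threshold = q_threshold),
            class = "reference_set")
}

# markers x c(n_a, n_b) allele counts from a genotype table
allele_count_matrix <- function(geno, markers) {
  ids <- marker_ids(geno)
  cm <- call_matrix(geno)
  out <- matrix(0, length(ids), 2, dimnames = list(ids, c("a", "b")))
  for (j in seq_along(ids)) {
    mrow <- markers[markers$marker_id == ids[j], ]
    calls <- cm[, j]
    al <- unlist(strsplit(calls[!is.na(calls)], "/", fixed = TRUE))
    out[j, 1] <- sum(al == mrow$allele_a)
    out[j, 2] <- sum(al == mrow$allele_b)
  }
  out
}

#' Assign query genotypes to reference groups
#'
#' Conditional genotype-likelihood assignment: each group's allele
#' frequencies are posterior means under a symmetric Dirichlet(1/2, 1/2)
#' prior on the allele counts (so no genotype ever has likelihood zero),
#' each query's log-likelihood under a group sums log Hardy-Weinberg
#' genotype probabilities over its called autosomal loci, and posteriors
#' combine the likelihoods with equal group priors. A query with no called
#' shared loci gets a flat posterior.
#'
#' @param geno Query genotype table.
#' @param refset A [build_reference_set()] object.
#' @param exclude Optional named list `sample_id -> group`: before scoring
#'   that sample, its own genotype is removed from that group's counts
#'   (leave-one-out machinery).
#' @return A tibble of class `assignment_result`: one row per query with
#'   `best_group`, `posterior_<group>` and `loglik_<group>` columns and
#'   `n_loci` used.
#' @export
assign_species <- function(geno, refset, exclude = NULL) {
  shared <- intersect(refset$markers, marker_ids(geno))
  if (!length(shared)) stop("no shared markers between query and reference")
  cm <- call_matrix(geno, shared)
  rows <- purrr::map(seq_len(nrow(cm)), function(i) {
    sid <- rownames(cm)[i]
    logl <- vapply(refset$groups, function(g) {
      counts <- refset$counts[[g]][shared, , drop = FALSE]
      if (!is.null(exclude) && identical(exclude[[sid]], g)) {
        counts <- counts - allele_count_matrix(
          geno[geno$sample_id == sid, c("sample_id", shared)],
          refset$marker_meta)[shared, , drop = FALSE]
        counts[counts < 0] <- 0
      }
      genotype_loglik(cm[i, ], shared, counts, refset$marker_meta)
    }, 0)
    post <- softmax(logl)
    n_loci <- sum(!is.na(cm[i, ]))
    tibble::tibble(sample_id = sid, n_loci = n_loci,
                   best_group = refset$groups[which.max(post)],
                   posterior = max(post),
                   !!!stats::setNames(as.list(post),
                                      paste0("posterior_", refset$groups)),
                   !!!stats::setNames(as.list(logl),
                                      paste0("loglik_", refset$groups)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("assignment_result", class(out))
  out
}

genotype_loglik <- function(calls, shared, counts, markers) {
  p_b <- (counts[, "b"] + 0.5) / (rowSums(counts) + 1)
  total <- 0
  for (j in seq_along(shared)) {
    call <- calls[j]
    if (is.na(call)) next
    mrow <- markers[markers$marker_id == shared[j], ]
    al <- strsplit(call, "/", fixed = TRUE)[[1]]
    nb <- sum(al == mrow$allele_b)
    p <- p_b[j]
    total <- total + log(switch(nb + 1L,
                                (1 - p)^2, 2 * p * (1 - p), p^2))
  }
  total
}

softmax <- function(logx) {
  if (all(!is.finite(logx))) return(rep(1 / length(logx), length(logx)))
  e <- exp(logx - max(logx))
  e / sum(e)
}

#' Leave-one-out self-assignment of a reference set
#'
#' Each reference member is removed from its own group's allele counts and
#' then assigned; the per-group rate is the fraction of members assigned
#' back to their own group. Groups with a single member are skipped with a
#' warning (their leave-one-out counts would be empty).
#'
#' @param geno Reference genotype table containing the member samples.
#' @param refset A [build_reference_set()] object.
#' @return A list with `per_sample` (assignment tibble plus `true_group`
#'   and `correct`) and `per_group` (tibble `group`, `n`, `rate`).
#' @export
leave_one_out_assignment <- function(geno, refset) {
  res <- list()
  for (g in refset$groups) {
    ids <- refset$members[[g]]
    if (length(ids) < 2) {
      warning("group ", g, " has fewer than 2 members; skipped")
      next
    }
    sub <- geno[geno$sample_id %in% ids, , drop = FALSE]
    excl <- stats::setNames(as.list(rep(g, length(ids))), ids)
    a <- assign_species(sub, refset, exclude = excl)
    a$true_group <- g
    res[[g]] <- a
  }
  per_sample <- dplyr::bind_rows(res)
  per_sample$correct <- per_sample$best_group == per_sample$true_group
  per_group <- per_sample |>
    dplyr::summarise(n = dplyr::n(), rate = mean(correct), .by = "true_group") |>
    dplyr::rename(group = "true_group")
  list(per_sample = per_sample, per_group = per_group)
}

#' Project samples onto reference principal components
#'
#' PCA on the reference samples' autosomal dosage matrix: dosages are
#' centred per marker on the reference mean and missing dosages imputed to
#' that mean; query samples are projected onto the reference axes.
#'
#' @param reference_geno,query_geno Genotype tables (query may be `NULL`).
#' @param markers [marker_info()] tibble; only autosomal markers are used.
#' @param n_components Number of components to return.
#' @return A tibble with `sample_id`, `set` (`reference`/`query`) and
#'   `PC1..PCk` columns, with per-component explained-variance fractions in
#'   attribute `"explained"`.
#' @export
pca_project <- function(reference_geno, query_geno = NULL, markers,
                        n_components = 2) {
  auto <- intersect(markers$marker_id[markers$chrom_class == "AUTOSOME"],
                    marker_ids(reference_geno))
  if (nrow(reference_geno) < 2) stop("PCA needs at least two reference samples")
  ref <- dosage_matrix(reference_geno[, c("sample_id", auto)], markers)
  all_missing <- colSums(!is.na(ref)) == 0
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing), " all-missing marker(s)")
    ref <- ref[, !all_missing, drop = FALSE]
    auto <- auto[!all_missing]
  }
  mu <- colMeans(ref, na.rm = TRUE)
  centred <- sweep(ref, 2, mu)
  centred[is.na(centred)] <- 0
  sv <- svd(centred)
  k <- min(n_components, ncol(sv$v))
  rot <- sv$v[, seq_len(k), drop = FALSE]
  scores_ref <- centred %*% rot
  explained <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  out <- tibble::tibble(sample_id = reference_geno$sample_id,
                        set = "reference")
  for (j in seq_len(k)) out[[paste0("PC", j)]] <- unname(scores_ref[, j])
  if (!is.null(query_geno)) {
    q <- dosage_matrix(query_geno[, c("sample_id", auto)], markers)
    qc <- sweep(q, 2, mu)
    qc[is.na(qc)] <- 0
    scores_q <- qc %*% rot
    outq <- tibble::tibble(sample_id = query_geno$sample_id, set = "query")
    for (j in seq_len(k)) outq[[paste0("PC", j)]] <- unname(scores_q[, j])
    out <- dplyr::bind_rows(out, outq)
  }
  attr(out, "explained") <- explained
  out
}
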