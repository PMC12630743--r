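#' QC configuration for monitoring runs
#'
#' @param sample_pass_callrate Minimum per-sample call rate to enter
#'   analysis; can be overridden per material via a named vector in
#'   `material_overrides` (e.g. `c(hair = 0.7)`).
#' @param material_overrides Named numeric vector of per-material cutoffs.
#' @param ntc_max_calls Calls tolerated in a no-template control before the
#'   run is flagged.
#' @param consensus_first If `TRUE` (default), call rates used by the pass
#'   filter are computed on the replicate-consensus genotype; otherwise on
#'   raw replicates.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(sample_pass_callrate = 0.80,
                      material_overrides = numeric(0),
                      ntc_max_calls = 0,
                      consensus_first = TRUE) {
  stopifnot(sample_pass_callrate >= 0, sample_pass_callrate <= 1,
            all(material_overrides >= 0 & material_overrides <= 1))
  structure(list(sample_pass_callrate = sample_pass_callrate,
                 material_overrides = material_overrides,
                 ntc_max_calls = ntc_max_calls,
                 consensus_first = consensus_first), class = "qc_config")
}

#' Amplification success per sample and per marker
#'
#' Fraction of non-missing calls per sample and per marker. For samples of
#' known female sex, Y markers are excluded from the denominator: absence
#' of a Y call in a female is expected biology, not amplification failure.
#'
#' @param geno A genotype table.
#' @param markers Optional [marker_info()] identifying Y markers.
#' @param samples Optional [sample_record()] supplying `known_sex`.
#' @return A list with `by_sample` (tibble `sample_id`, `n_called`,
#'   `n_markers`, `call_rate`) and `by_marker` (tibble `marker_id`,
#'   `call_rate`).
#' @export
amplification_success <- function(geno, markers = NULL, samples = NULL) {
  stopifnot(nrow(geno) > 0)
  cm <- call_matrix(geno)
  y_ids <- if (!is.null(markers)) {
    markers$marker_id[markers$chrom_class == "Y"]
  } else character(0)
  denom <- matrix(TRUE, nrow(cm), ncol(cm), dimnames = dimnames(cm))
  if (length(y_ids) && !is.null(samples)) {
    fem <- samples$sample_id[!is.na(samples$known_sex) &
                               samples$known_sex == "FEMALE"]
    denom[rownames(cm) %in% fem, colnames(cm) %in% y_ids] <- FALSE
  }
  called <- !is.na(cm) & denom
  by_sample <- tibble::tibble(
    sample_id = rownames(cm),
    n_called = unname(rowSums(called)),
    n_markers = unname(rowSums(denom)),
    call_rate = unname(rowSums(called) / rowSums(denom)))
  by_marker <- tibble::tibble(
    marker_id = colnames(cm),
    call_rate = unname(colSums(!is.na(cm)) / nrow(cm)))
  list(by_sample = by_sample, by_marker = by_marker)
}

#' Consensus genotypes across replicate groups
#'
#' Within each replicate group and at each locus: if every non-missing
#' replicate call agrees, the consensus is that call; any disagreement
#' recodes the locus as missing and counts one mismatch; all-missing stays
#' missing. Groups of one pass through unchanged. Missing calls never count
#' as mismatches, and the consensus never contains a call absent from all
#' replicates.
#'
#' @param geno A genotype table of replicate-level samples.
#' @param samples A [sample_record()] tibble defining `replicate_group`.
#' @return A list with `consensus` (genotype table keyed by replicate
#'   group) and `mismatches` (tibble `replicate_group`, `n_replicates`,
#'   `n_mismatch`, `n_compared`).
#' @export
duplicate_consensus <- function(geno, samples) {
  groups <- samples$replicate_group[match(geno$sample_id, samples$sample_id)]
  groups[is.na(groups)] <- geno$sample_id[is.na(groups)]
  cm <- call_matrix(geno)
  ug <- unique(groups)
  cons <- matrix(NA_character_, length(ug), ncol(cm),
                 dimnames = list(ug, colnames(cm)))
  mm <- purrr::map(ug, function(g) {
    rows <- cm[groups == g, , drop = FALSE]
    n_mismatch <- 0L
    n_compared <- 0L
    for (j in seq_len(ncol(rows))) {
      calls <- rows[, j]
      called <- unique(calls[!is.na(calls)])
      if (length(called) == 1) {
        cons[g, j] <<- called
        if (sum(!is.na(calls)) > 1) n_compared <- n_compared + 1L
      } else if (length(called) > 1) {
        n_mismatch <- n_mismatch + 1L
        n_compared <- n_compared + 1L
      }
    }
    tibble::tibble(replicate_group = g, n_replicates = nrow(rows),
                   n_mismatch = n_mismatch, n_compared = n_compared)
  })
  list(consensus = genotype_table(ug, cons), mismatches = dplyr::bind_rows(mm))
}

#' Pass/fail filtering of monitoring samples
#'
#' Applies the per-sample call-rate threshold (per-material override aware)
#' and summarises pass counts by material, with the overall pass percentage
#' rounded to the nearest integer.
#'
#' @param success `by_sample` output of [amplification_success()] (computed
#'   on consensus genotypes when `config$consensus_first`).
#' @param samples [sample_record()] tibble; matched on `sample_id` (or on
#'   `replicate_group` when `success` is keyed by consensus groups).
#' @param config A [qc_config()].
#' @return A list with `per_sample` (tibble adding `threshold` and `pass`)
#'   and `summary` (per-material `n`, `n_pass`, `pct_pass`, plus an overall
#'   `pct_pass_overall` attribute and `overall` row).
#' @export
pass_filter <- function(success, samples, config = qc_config()) {
  per <- success
  idx <- match(per$sample_id, samples$sample_id)
  if (anyNA(idx)) idx <- match(per$sample_id, samples$replicate_group)
  per$material <- ifelse(is.na(idx), "unknown", samples$material[idx])
  per$material[is.na(per$material)] <- "unknown"
  ov <- config$material_overrides
  per$threshold <- ifelse(per$material %in% names(ov),
                          unname(ov[per$material]),
                          config$sample_pass_callrate)
  per$pass <- per$call_rate >= per$threshold
  smry <- per |>
    dplyr::summarise(n = dplyr::n(), n_pass = sum(pass), .by = "material") |>
    dplyr::mutate(pct_pass = round(100 * n_pass / n))
  overall <- round(100 * sum(smry$n_pass) / sum(smry$n))
  smry <- dplyr::bind_rows(
    smry,
    tibble::tibble(material = "overall", n = sum(smry$n),
                   n_pass = sum(smry$n_pass), pct_pass = overall))
  list(per_sample = tibble::as_tibble(per), summary = smry)
}

#' Overall pass percentage from per-material counts
#'
#' Small arithmetic helper used in season reporting: pooled passing
#' fraction as a percentage rounded to the nearest integer.
#'
#' @param n_pass,n_total Vectors of per-material passing and total counts.
#' @return Integer percentage.
#' @export
overall_pass_pct <- function(n_pass, n_total) {
  stopifnot(length(n_pass) == length(n_total), all(n_pass <= n_total))
  round(100 * sum(n_pass) / sum(n_total))
}

#' Duplicate-mismatch season summary
#'
#' Summarises replicate mismatches the way season reports quote them: the
#' percentage of replicate groups showing at least one mismatch, the mean
#' per-group mismatch count, and that mean divided by the panel size as a
#' per-marker error rate.
#'
#' @param mismatches `mismatches` tibble from [duplicate_consensus()]
#'   (typically restricted to passing, truly replicated groups).
#' @param n_markers Panel size used for the per-marker rate.
#' @return One-row tibble: `n_groups`, `n_mismatching`, `pct_mismatching`,
#'   `mean_mismatch`, `per_marker_error`.
#' @export
duplicate_error_summary <- function(mismatches, n_markers) {
  reps <- mismatches[mismatches$n_replicates > 1, ]
  tibble::tibble(
    n_groups = nrow(reps),
    n_mismatching = sum(reps$n_mismatch > 0),
    pct_mismatching = round(100 * sum(reps$n_mismatch > 0) / nrow(reps)),
    mean_mismatch = mean(reps$n_mismatch),
    per_marker_error = mean(reps$n_mismatch) / n_markers)
}

#' Error rate against a reference genotyping technology
#'
#' Compares panel genotypes with reference genotypes of the same samples
#' at shared markers. Loci are compared only where the reference call is
#' non-missing; a mismatch is a heterozygote called homozygous (or vice
#' versa) or opposite homozygotes — one mismatch per locus. Panel-missing
#' loci are counted separately, regardless of the reference genotype.
#'
#' @param panel_geno,reference_geno Genotype tables sharing sample and
#'   marker ids.
#' @return A list with `n_comparisons`, `n_mismatches`, `n_panel_missing`,
#'   `error_rate`, and `detail` (per sample x marker mismatch records).
#' @export
error_rate_vs_reference <- function(panel_geno, reference_geno) {
  shared_s <- intersect(panel_geno$sample_id, reference_geno$sample_id)
  shared_m <- intersect(marker_ids(panel_geno), marker_ids(reference_geno))
  if (!length(shared_m)) stop("no shared markers between panel and reference")
  if (!length(shared_s)) stop("no shared samples between panel and reference")
  pm <- call_matrix(panel_geno, shared_m)[shared_s, , drop = FALSE]
  rm_ <- call_matrix(reference_geno, shared_m)[shared_s, , drop = FALSE]
  ref_ok <- !is.na(rm_)
  comparable <- ref_ok & !is.na(pm)
  mism <- comparable & pm != rm_
  idx <- which(mism, arr.ind = TRUE)
  detail <- tibble::tibble(
    sample_id = rownames(pm)[idx[, 1]],
    marker_id = colnames(pm)[idx[, 2]],
    panel_call = pm[mism],
    reference_call = rm_[mism])
  n_comp <- sum(ref_ok)
  list(
    n_comparisons = n_comp,
    n_mismatches = sum(mism),
    n_panel_missing = sum(is.na(pm)),
    error_rate = if (n_comp) sum(mism) / n_comp else NaN,
    detail = detail)
}
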