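#' Probability of identity at one locus
#'
#' The probability that two individuals drawn at random from a
#' Hardy-Weinberg population share a genotype:
#' `PID = sum_i p_i^4 + sum_{i<j} (2 p_i p_j)^2`. Implemented for the
#' general k-allele case; a monomorphic locus gives 1.
#'
#' @param p Allele-frequency vector summing to 1.
#' @return PID in `(0, 1]`.
#' @export
pid_locus <- function(p) {
  check_simplex(p)
  hom <- sum(p^4)
  pairs <- if (length(p) > 1) utils::combn(p, 2) else matrix(nrow = 2, ncol = 0)
  het <- sum((2 * pairs[1, ] * pairs[2, ])^2)
  hom + het
}

#' Probability of identity among full siblings at one locus
#'
#' The sibling variant, the conservative statistic used to size panels for
#' populations containing close kin:
#' `PIDsib = 0.25 + 0.5 s2 + 0.5 s2^2 - 0.25 s4` with `s2 = sum p_i^2`,
#' `s4 = sum p_i^4`. Always at least as large as [pid_locus()].
#'
#' @inheritParams pid_locus
#' @return PIDsib in `(0, 1]`.
#' @export
pid_sib_locus <- function(p) {
  check_simplex(p)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
}

check_simplex <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("allele frequencies must be non-negative and sum to 1")
  }
}

#' Markers needed to reach an identity threshold
#'
#' Sorts per-locus identity probabilities ascending (most informative
#' first) and returns the smallest number of loci whose product drops
#' below the threshold; `Inf` when the full panel never reaches it.
#'
#' @param per_locus Vector of per-locus PID or PIDsib values.
#' @param threshold Target multi-locus probability, in `(0, 1)`.
#' @return Integer count, or `Inf`.
#' @export
markers_needed <- function(per_locus, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  if (!length(per_locus)) return(Inf)
  cum <- cumprod(sort(per_locus))
  n <- which(cum < threshold)
  if (!length(n)) Inf else n[1]
}

#' Panel-wide identity summary
#'
#' Per-locus PID and PIDsib from observed genotype frequencies, cumulative
#' products in informativeness order, and the marker counts needed to reach
#' the configured threshold.
#'
#' @param geno Genotype table of unrelated individuals.
#' @param markers [marker_info()] tibble; Y markers are excluded (presence
#'   calls carry no identity information in this framework).
#' @param threshold Multi-locus identity target.
#' @param exclude Marker ids to drop (e.g. loci with excessive missingness).
#' @return A list of class `pid_result`: `per_locus` (tibble `marker_id`,
#'   `maf`, `pid`, `pid_sib`), `n_markers_pid`, `n_markers_pidsib`,
#'   `cum_pid`, `cum_pidsib`, `threshold`.
#' @export
pid_summary <- function(geno, markers, threshold = 1e-4,
                        exclude = character(0)) {
  use <- setdiff(intersect(marker_ids(geno), markers$marker_id),
                 union(markers$marker_id[markers$chrom_class == "Y"], exclude))
  st <- compute_locus_stats(geno[, c("sample_id", use)], markers)
  per <- st |>
    dplyr::filter(!is.na(maf)) |>
    dplyr::mutate(
      pid = purrr::map_dbl(maf, ~ pid_locus(c(.x, 1 - .x))),
      pid_sib = purrr::map_dbl(maf, ~ pid_sib_locus(c(.x, 1 - .x)))) |>
    dplyr::select("marker_id", "maf", "pid", "pid_sib")
  structure(list(
    per_locus = per,
    cum_pid = cumprod(sort(per$pid)),
    cum_pidsib = cumprod(sort(per$pid_sib)),
    n_markers_pid = markers_needed(per$pid, threshold),
    n_markers_pidsib = markers_needed(per$pid_sib, threshold),
    threshold = threshold), class = "pid_result")
}
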