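#' Marker-selection configuration
#'
#' Thresholds of the panel-design cascade. Defaults follow common practice
#' for array-based panel design: samples below 85% genotyping success and
#' markers below 90% call rate are dropped, LD is pruned in 50-SNP windows
#' shifted by 5 SNPs at r^2 > 0.2, the design-stage Hardy-Weinberg screen
#' uses alpha = 0.001 (0.05 at panel-validation stage), high-MAF markers
#' must re-validate at MAF >= 0.3, and X markers must combine moderate
#' female MAF (0.125-0.333) with near-zero apparent male MAF (<= 0.005,
#' males being hemizygous).
#'
#' @param sample_callrate_min,marker_callrate_min Call-rate cutoffs.
#' @param ld_window,ld_step,ld_r2_max Windowed LD-pruning parameters.
#' @param hwe_alpha,hwe_alpha_validation HWE screen levels.
#' @param maf_min High-MAF retention threshold.
#' @param female_x_maf_range,male_x_maf_max X-marker selection criteria.
#' @param ntc_max_calls Calls tolerated in a no-template control before a
#'   marker is flagged "NTC up".
#' @param pid_threshold Probability-of-identity target for panel sizing.
#' @param seed Seed for the random subsampling step.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(sample_callrate_min = 0.85,
                             marker_callrate_min = 0.90,
                             ld_window = 50, ld_step = 5, ld_r2_max = 0.2,
                             hwe_alpha = 0.001, hwe_alpha_validation = 0.05,
                             maf_min = 0.3,
                             female_x_maf_range = c(0.125, 0.333),
                             male_x_maf_max = 0.005,
                             ntc_max_calls = 0,
                             pid_threshold = 1e-4,
                             seed = 1L) {
  stopifnot(ld_window >= ld_step, ld_step >= 1,
            sample_callrate_min >= 0, sample_callrate_min <= 1,
            marker_callrate_min >= 0, marker_callrate_min <= 1,
            hwe_alpha > 0, hwe_alpha < 1, maf_min >= 0, maf_min <= 0.5,
            pid_threshold > 0, pid_threshold < 1)
  structure(as.list(environment()), class = "selection_config")
}

#' Per-locus summary statistics
#'
#' Genotype counts, call rate, minor allele frequency and the exact
#' Hardy-Weinberg p-value for every marker of a genotype table. MAF is
#' computed from observed allele counts, ignoring missing calls; the HWE
#' test uses complete genotypes only. Monomorphic markers get `maf = 0` and
#' are flagged.
#'
#' @param geno A genotype table.
#' @param markers Optional [marker_info()] tibble fixing the allele pair per
#'   marker; without it the two observed alleles are used.
#' @return A tibble with one row per marker: `marker_id`, `n_aa`, `n_ab`,
#'   `n_bb`, `n_missing`, `call_rate`, `maf`, `hwe_p`, `monomorphic`.
#' @export
compute_locus_stats <- function(geno, markers = NULL) {
  ids <- marker_ids(geno)
  cm <- call_matrix(geno)
  n <- nrow(cm)
  rows <- purrr::map(seq_along(ids), function(j) {
    calls <- cm[, j]
    miss <- sum(is.na(calls))
    called <- calls[!is.na(calls)]
    if (!is.null(markers)) {
      mrow <- markers[markers$marker_id == ids[j], ]
      ab <- c(mrow$allele_a, mrow$allele_b)
    } else {
      ab <- sort(unique(unlist(strsplit(called, "/", fixed = TRUE))))
      if (length(ab) == 0) ab <- c("?", "?")
      if (length(ab) == 1) ab <- c(ab, ab)
    }
    hom_a <- paste(ab[1], ab[1], sep = "/")
    hom_b <- paste(ab[2], ab[2], sep = "/")
    n_aa <- sum(called == hom_a)
    n_bb <- sum(called == hom_b)
    n_ab <- length(called) - n_aa - n_bb
    n_called <- length(called)
    p_b <- if (n_called) (2 * n_bb + n_ab) / (2 * n_called) else NA_real_
    maf <- if (is.na(p_b)) NA_real_ else min(p_b, 1 - p_b)
    hwe <- if (n_called >= 1 && ab[1] != ab[2]) {
      hwe_exact_test(n_aa, n_ab, n_bb)
    } else if (n_called >= 1) 1 else NA_real_
    tibble::tibble(
      marker_id = ids[j], n_aa = n_aa, n_ab = n_ab, n_bb = n_bb,
      n_missing = miss, call_rate = n_called / n, maf = maf, hwe_p = hwe,
      monomorphic = !is.na(maf) && maf == 0)
  })
  dplyr::bind_rows(rows)
}

#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Exact conditional test on the heterozygote count: conditional on the
#' observed allele totals, the probability of a configuration with `n_ab`
#' heterozygotes is proportional to `2^n_ab * N! / (n_aa! n_ab! n_bb!)`,
#' and the two-sided p-value sums the probabilities of all configurations
#' (heterozygote counts of the same parity as the minor-allele total) no
#' more probable than the observed one.
#'
#' @param n_aa,n_ab,n_bb Genotype counts.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("HWE test undefined for zero genotypes")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  n_minor <- min(n_a, n_b)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    bb <- (n_b - h) / 2
    h * log(2) + lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Squared genotype correlation between two markers
#'
#' r^2 computed as the squared Pearson correlation of per-sample minor
#' allele dosages over jointly non-missing samples — the genotype (composite)
#' LD measure appropriate for unphased data. Zero dosage variance at either
#' marker makes r^2 undefined (`NaN`), treated downstream as "not linked".
#'
#' @param dos_a,dos_b Numeric dosage vectors (0/1/2, `NA` missing).
#' @return r^2 in `[0, 1]`, or `NaN`.
#' @export
ld_r2 <- function(dos_a, dos_b) {
  ok <- !is.na(dos_a) & !is.na(dos_b)
  if (sum(ok) < 2) return(NaN)
  a <- dos_a[ok]; b <- dos_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NaN)
  stats::cor(a, b)^2
}

#' Windowed LD pruning
#'
#' Slides a window of `ld_window` markers along the map order in steps of
#' `ld_step`; within each window, every remaining pair with
#' r^2 above `ld_r2_max` loses its lower-MAF member (ties drop the later
#' map position). Passes repeat until no retained pair inside any window
#' exceeds the threshold.
#'
#' @param geno A genotype table.
#' @param marker_order Marker ids in map order (defaults to table order).
#' @param config A [selection_config()].
#' @param markers Optional [marker_info()] for dosage coding.
#' @return Character vector of retained marker ids, in map order.
#' @export
ld_prune <- function(geno, marker_order = marker_ids(geno),
                     config = selection_config(), markers = NULL) {
  dos <- dosage_matrix(geno, markers)[, marker_order, drop = FALSE]
  maf <- apply(dos, 2, function(d) {
    d <- d[!is.na(d)]
    if (!length(d)) return(0)
    p <- sum(d) / (2 * length(d))
    min(p, 1 - p)
  })
  keep <- rep(TRUE, length(marker_order))
  names(keep) <- marker_order
  repeat {
    removed_any <- FALSE
    kept_idx <- which(keep)
    if (length(kept_idx) < 2) break
    starts <- seq(1, max(1, length(kept_idx)), by = config$ld_step)
    for (s in starts) {
      win <- kept_idx[s:min(s + config$ld_window - 1, length(kept_idx))]
      win <- win[keep[win]]
      repeat {
        if (length(win) < 2) break
        drop <- first_linked_member(win, dos, maf, config$ld_r2_max)
        if (is.null(drop)) break
        keep[drop] <- FALSE
        win <- setdiff(win, drop)
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  marker_order[keep]
}

# first pair in the window above the r2 cutoff; returns the member to drop
# (lower MAF, ties drop the later map position) or NULL when none
first_linked_member <- function(win, dos, maf, r2_max) {
  for (ii in seq_along(win)) {
    for (jj in seq_len(ii - 1L)) {
      r2 <- ld_r2(dos[, win[jj]], dos[, win[ii]])
      if (!is.nan(r2) && r2 > r2_max) {
        pair <- c(win[jj], win[ii])
        return(if (maf[pair[1]] < maf[pair[2]]) pair[1]
               else if (maf[pair[2]] < maf[pair[1]]) pair[2]
               else max(pair))
      }
    }
  }
  NULL
}

#' Per-locus Weir-Cockerham FST between two populations
#'
#' The two-population theta estimator from the Weir-Cockerham variance
#' components, which accounts for unequal sample sizes and observed
#' heterozygosity. Alleles fixed for opposite states give theta = 1; a
#' marker monomorphic across both populations is undefined (`NaN`). The
#' estimate is invariant to swapping the allele labels.
#'
#' @param geno A genotype table.
#' @param labels Named character vector (or tibble `sample_id`,`population`)
#'   giving each sample's population.
#' @param pop_a,pop_b The two population labels to contrast.
#' @param markers Optional [marker_info()] fixing allele coding.
#' @return A tibble `(marker_id, fst)`.
#' @export
fst_locus <- function(geno, labels, pop_a, pop_b, markers = NULL) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$population, labels$sample_id)
  }
  grp <- labels[geno$sample_id]
  dos <- dosage_matrix(geno, markers)
  fst <- vapply(seq_len(ncol(dos)), function(j) {
    wc_theta(dos[grp %in% pop_a, j], dos[grp %in% pop_b, j])
  }, 0)
  tibble::tibble(marker_id = colnames(dos), fst = fst)
}

# Weir & Cockerham (1984) theta for two samples of a biallelic locus,
# from dosage vectors (alleles per individual = 2).
wc_theta <- function(dos_1, dos_2) {
  d <- list(dos_1[!is.na(dos_1)], dos_2[!is.na(dos_2)])
  n_i <- lengths(d)
  if (any(n_i < 1)) return(NaN)
  p_i <- vapply(d, function(x) mean(x) / 2, 0)
  h_i <- vapply(d, function(x) mean(x == 1), 0)
  r <- 2
  nbar <- mean(n_i)
  p_bar <- sum(n_i * p_i) / (r * nbar)
  if (p_bar == 0 || p_bar == 1) return(NaN)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * nbar)
  h_bar <- sum(n_i * h_i) / (r * nbar)
  if (nbar <= 1 || nc == 0) return(NaN)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- nbar / (nbar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * h_bar)
  c <- h_bar / 2
  if (a + b + c == 0) return(NaN)
  a / (a + b + c)
}

#' Run the marker-selection cascade
#'
#' Applies, in order: the sample call-rate filter, the marker call-rate
#' filter (distinguishing complete amplification failure from partial),
#' the no-template-control screen, windowed LD pruning, the Hardy-Weinberg
#' screen, then the category-specific rules — diagnostic markers must be
#' fixed for opposite alleles between their species pair (FST = 1),
#' high-MAF markers must re-validate at `maf >= maf_min`, X markers must
#' satisfy both the female-MAF range and the male-MAF ceiling (PAR-flagged
#' X markers are excluded up front). An optional seeded random subsample
#' caps each category. A rejection can be counted under several reasons;
#' the attrition table reports counts per reason per category.
#'
#' @param geno Genotype table of the candidate-marker dataset.
#' @param markers Candidate [marker_info()] tibble.
#' @param samples [sample_record()] tibble (sex labels drive the X-marker
#'   criteria; negative controls drive the NTC screen).
#' @param labels Population labels (`sample_id` -> population) for the
#'   diagnostic-marker FST rule; species names `wolf`, `dog`, `jackal`.
#' @param config A [selection_config()].
#' @param n_select Optional named vector capping selected markers per
#'   category, e.g. `c(HIGH_MAF = 145)`; sampling is seeded.
#' @param unreadable Marker ids rejected upstream for unreadable genotype
#'   clusters (a scoring-stage judgement that cannot be derived from calls).
#' @return A list with `panel` (tibble `marker_id`, `category`), `attrition`
#'   (tibble `reason` x category counts) and `rejected` (tibble
#'   `marker_id`, `reason`).
#' @export
select_panel <- function(geno, markers, samples = NULL, labels = NULL,
                         config = selection_config(), n_select = NULL,
                         unreadable = character(0)) {
  reasons <- c("No amplification", "Low amplification", "NTC up",
               "Readability", "Low MAF", "Deviation from HW", "LD")
  rejected <- tibble::tibble(marker_id = character(0), reason = character(0))
  reject <- function(ids, why) {
    if (length(ids)) {
      rejected <<- dplyr::bind_rows(
        rejected, tibble::tibble(marker_id = ids, reason = why))
    }
  }
  markers <- markers[!(markers$chrom_class == "X" & markers$par_flag), ]
  geno <- geno[, c("sample_id", intersect(marker_ids(geno),
                                          markers$marker_id))]
  if (nrow(geno) == 0 || length(marker_ids(geno)) == 0) {
    return(list(panel = tibble::tibble(marker_id = character(0),
                                       category = character(0)),
                attrition = attrition_table(rejected, markers, reasons),
                rejected = rejected))
  }
  ntc_ids <- character(0)
  if (!is.null(samples)) {
    ntc_ids <- samples$sample_id[!is.na(samples$is_control) &
                                   samples$is_control == "NEGATIVE"]
    ntc_geno <- geno[geno$sample_id %in% ntc_ids, , drop = FALSE]
    if (nrow(ntc_geno)) {
      n_amp <- colSums(!is.na(call_matrix(ntc_geno)))
      reject(names(n_amp)[n_amp > config$ntc_max_calls], "NTC up")
    }
    geno <- geno[!geno$sample_id %in% ntc_ids, , drop = FALSE]
  }
  # sample call-rate filter
  cm <- call_matrix(geno)
  s_rate <- rowMeans(!is.na(cm))
  geno <- geno[s_rate >= config$sample_callrate_min, , drop = FALSE]
  # marker call-rate filter
  stats_all <- compute_locus_stats(geno, markers)
  reject(stats_all$marker_id[stats_all$call_rate == 0], "No amplification")
  reject(stats_all$marker_id[stats_all$call_rate > 0 &
                               stats_all$call_rate < config$marker_callrate_min],
         "Low amplification")
  reject(intersect(unreadable, markers$marker_id), "Readability")
  # category rules
  msex <- if (is.null(samples)) rep(NA_character_, nrow(geno)) else
    samples$known_sex[match(geno$sample_id, samples$sample_id)]
  for (cat in unique(markers$category)) {
    ids <- markers$marker_id[markers$category == cat]
    st <- stats_all[stats_all$marker_id %in% ids, ]
    if (cat == "HIGH_MAF") {
      reject(st$marker_id[!is.na(st$maf) & st$maf < config$maf_min], "Low MAF")
      reject(st$marker_id[!is.na(st$hwe_p) & st$hwe_p < config$hwe_alpha],
             "Deviation from HW")
    } else if (cat %in% c("WOLF_DOG_DIAG", "WOLF_JACKAL_DIAG")) {
      if (!is.null(labels)) {
        other <- if (cat == "WOLF_DOG_DIAG") "dog" else "jackal"
        fst <- fst_locus(geno[, c("sample_id", intersect(ids, marker_ids(geno)))],
                         labels, "wolf", other, markers)
        reject(fst$marker_id[is.na(fst$fst) | fst$fst < 1 - 1e-9], "Low MAF")
      }
    } else if (cat == "X_SEX") {
      fem <- geno[!is.na(msex) & msex == "FEMALE",
                  c("sample_id", intersect(ids, marker_ids(geno)))]
      mal <- geno[!is.na(msex) & msex == "MALE",
                  c("sample_id", intersect(ids, marker_ids(geno)))]
      if (nrow(fem) && nrow(mal)) {
        fs <- compute_locus_stats(fem, markers)
        ms <- compute_locus_stats(mal, markers)
        bad_f <- fs$marker_id[is.na(fs$maf) |
                                fs$maf < config$female_x_maf_range[1] |
                                fs$maf > config$female_x_maf_range[2]]
        bad_m <- ms$marker_id[is.na(ms$maf) | ms$maf > config$male_x_maf_max]
        reject(union(bad_f, bad_m), "Low MAF")
      }
    }
  }
  # LD prune what remains among autosomal candidates
  failed_so_far <- unique(rejected$marker_id)
  auto_ids <- markers$marker_id[markers$chrom_class == "AUTOSOME" &
                                  markers$category == "HIGH_MAF"]
  ld_cand <- setdiff(auto_ids, failed_so_far)
  if (length(ld_cand) >= 2) {
    keep_ld <- ld_prune(geno[, c("sample_id", ld_cand)], ld_cand, config,
                        markers)
    reject(setdiff(ld_cand, keep_ld), "LD")
  }
  surviving <- setdiff(markers$marker_id, unique(rejected$marker_id))
  panel <- markers[markers$marker_id %in% surviving, c("marker_id", "category")]
  if (!is.null(n_select)) {
    set.seed(config$seed)
    kept <- purrr::map(split(panel$marker_id, panel$category), function(ids) {
      cat <- panel$category[match(ids[1], panel$marker_id)]
      cap <- n_select[cat]
      if (is.na(cap) || length(ids) <= cap) return(ids)
      sort(sample(ids, cap))
    })
    panel <- panel[panel$marker_id %in% unlist(kept), ]
  }
  if (!is.null(n_select)) {
    got <- vapply(names(n_select), function(cat) sum(panel$category == cat), 0L)
    short <- names(n_select)[got < n_select]
    if (length(short)) {
      warning("insufficient candidates in category: ",
              paste(short, collapse = ", "))
    }
  }
  list(panel = panel,
       attrition = attrition_table(rejected, markers, reasons),
       rejected = dplyr::distinct(rejected))
}

attrition_table <- function(rejected, markers, reasons) {
  cats <- c("HIGH_MAF", "X_SEX", "Y_SEX", "WOLF_DOG_DIAG", "WOLF_JACKAL_DIAG")
  rej <- dplyr::distinct(rejected)
  rej$category <- markers$category[match(rej$marker_id, markers$marker_id)]
  counts <- purrr::map(cats, function(cat) {
    unname(vapply(reasons, function(rn) {
      sum(rej$reason == rn & rej$category %in% cat)
    }, 0L))
  })
  out <- tibble::tibble(reason = reasons)
  for (k in seq_along(cats)) out[[cats[k]]] <- counts[[k]]
  out
}
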