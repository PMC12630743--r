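#' Monitoring-pipeline configuration
#'
#' Bundles the stage configurations of the annual monitoring flow and the
#' scrutiny-flag constants.
#'
#' @param qc A [qc_config()].
#' @param sex A [sex_config()].
#' @param match A [match_config()].
#' @param parentage A [parentage_config()].
#' @param near_threshold_margin Samples within this call-rate distance of
#'   their pass cutoff are flagged "near threshold".
#' @param wolf_group Name of the reference group whose members continue to
#'   individual identification (dogs and putative hybrids inside it are
#'   additionally routed to a confirmatory-panel export).
#' @param run_parentage Whether to attempt parentage on the season's
#'   individuals.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_config(), sex = sex_config(),
                            match = match_config(),
                            parentage = parentage_config(),
                            near_threshold_margin = 0.05,
                            wolf_group = "wolf_dog",
                            run_parentage = FALSE) {
  structure(list(qc = qc, sex = sex, match = match, parentage = parentage,
                 near_threshold_margin = near_threshold_margin,
                 wolf_group = wolf_group, run_parentage = run_parentage),
            class = "pipeline_config")
}

#' Run the annual monitoring workflow
#'
#' Orchestrates the season flow: no-template-control screening, replicate
#' consensus, pass/fail filtering, species assignment, genetic sexing,
#' individual clustering, optional parentage, and a scrutiny list. The
#' scrutiny list flags — never silently discards — individuals seen only
#' once, samples within the near-threshold margin of their cutoff, sex
#' conflicts (the cross-contamination signature) and all urine samples;
#' discarding is an analyst decision.
#'
#' @param geno Replicate-level genotype table of the season's run.
#' @param samples [sample_record()] tibble (controls included).
#' @param markers Panel [marker_info()] tibble.
#' @param refset Optional [build_reference_set()] for species assignment.
#' @param x_freqs Optional tibble `marker_id`, `p` of reference female X
#'   frequencies for sexing.
#' @param config A [pipeline_config()].
#' @return A list of class `monitoring_result` with tibbles: `ntc_flags`,
#'   `pass` (per consensus sample), `pass_summary`, `mismatch_summary`,
#'   `assignments`, `confirmatory_export`, `sex_calls`, `clusters`,
#'   `cluster_threshold`, `parentage`, `scrutiny`, and `log` (a record of
#'   every threshold applied).
#' @export
run_monitoring <- function(geno, samples, markers, refset = NULL,
                           x_freqs = NULL, config = pipeline_config()) {
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  # --- NTC screen -----------------------------------------------------
  ntc <- samples$sample_id[!is.na(samples$is_control) &
                             samples$is_control == "NEGATIVE"]
  ntc_flags <- stage("ntc", {
    if (length(ntc)) {
      calls <- rowSums(!is.na(call_matrix(
        geno[geno$sample_id %in% ntc, , drop = FALSE])))
      tibble::tibble(sample_id = names(calls), n_calls = unname(calls),
                     flag = unname(calls) > config$qc$ntc_max_calls,
                     reason = ifelse(unname(calls) > config$qc$ntc_max_calls,
                                     "NTC up", NA_character_))
    } else {
      tibble::tibble(sample_id = character(0), n_calls = integer(0),
                     flag = logical(0), reason = character(0))
    }
  })
  note("ntc_max_calls=", config$qc$ntc_max_calls, " flagged=",
       sum(ntc_flags$flag))
  work <- geno[!geno$sample_id %in%
                 samples$sample_id[!is.na(samples$is_control)], ,
               drop = FALSE]
  work_samples <- samples[samples$sample_id %in% work$sample_id, ]
  # --- replicate consensus -------------------------------------------
  cons <- stage("consensus", duplicate_consensus(work, work_samples))
  group_meta <- work_samples |>
    dplyr::summarise(material = material[1], .by = "replicate_group")
  cons_samples <- sample_record(group_meta$replicate_group,
                                material = group_meta$material,
                                replicate_group = group_meta$replicate_group)
  # --- pass filter ----------------------------------------------------
  amp <- stage("qc", amplification_success(cons$consensus, markers))
  pf <- stage("qc", pass_filter(amp$by_sample, cons_samples, config$qc))
  note("sample_pass_callrate=", config$qc$sample_pass_callrate)
  passing <- pf$per_sample$sample_id[pf$per_sample$pass]
  passed <- cons$consensus[cons$consensus$sample_id %in% passing, ,
                           drop = FALSE]
  mism <- duplicate_error_summary(
    cons$mismatches[cons$mismatches$replicate_group %in% passing, ],
    n_markers = length(marker_ids(geno)))
  # --- species assignment --------------------------------------------
  assignments <- NULL
  confirmatory <- tibble::tibble(sample_id = character(0))
  keep_for_id <- passing
  if (!is.null(refset) && nrow(passed)) {
    assignments <- stage("assign", assign_species(passed, refset))
    keep_for_id <- assignments$sample_id[assignments$best_group ==
                                           config$wolf_group]
    # wolves, dogs and putative hybrids all sit in the wolf/dog group and
    # go to the confirmatory hybrid panel
    confirmatory <- tibble::tibble(sample_id = keep_for_id)
    note("wolf_group=", config$wolf_group, " assigned_wolf_dog=",
         length(keep_for_id))
  }
  # --- sexing ---------------------------------------------------------
  sex_calls <- NULL
  if (!is.null(x_freqs) && nrow(passed)) {
    xf <- stage("sex", x_inbreeding_f(passed, x_freqs,
                                      config$sex$min_x_typed))
    yd <- y_detection(passed, markers)
    sex_calls <- stage("sex", call_sex(xf, yd, config$sex))
    note("f_male_min=", config$sex$f_male_min,
         " f_female_max=", config$sex$f_female_max)
  }
  # --- individual clustering -----------------------------------------
  id_geno <- passed[passed$sample_id %in% keep_for_id, , drop = FALSE]
  clu <- stage("individuals", cluster_individuals(id_geno, config$match))
  note("min_overlap=", config$match$min_overlap,
       " mismatch_threshold=", clu$threshold)
  # --- parentage ------------------------------------------------------
  par_res <- NULL
  if (config$run_parentage && nrow(clu$consensus) >= 3 &&
      !is.null(sex_calls)) {
    ind_sex <- clu$clusters |>
      dplyr::left_join(sex_calls, by = "sample_id") |>
      dplyr::summarise(
        sex = if (any(call == "MALE", na.rm = TRUE) &&
                  !any(call == "FEMALE", na.rm = TRUE)) "MALE"
              else if (any(call == "FEMALE", na.rm = TRUE) &&
                       !any(call == "MALE", na.rm = TRUE)) "FEMALE"
              else NA_character_,
        .by = "individual_id")
    freqs <- panel_frequencies(clu$consensus, markers)
    par_res <- stage("parentage", assign_parents(
      clu$consensus,
      dplyr::rename(ind_sex, sample_id = "individual_id"),
      freqs, markers, config$parentage))
  }
  # --- scrutiny list --------------------------------------------------
  scrutiny <- stage("scrutiny", {
    flags <- list()
    singles <- clu$clusters |>
      dplyr::add_count(individual_id) |>
      dplyr::filter(n == 1)
    if (nrow(singles)) {
      flags$single <- tibble::tibble(sample_id = singles$sample_id,
                                     reason = "single occurrence")
    }
    near <- pf$per_sample[pf$per_sample$pass &
                            pf$per_sample$call_rate <
                              pf$per_sample$threshold +
                              config$near_threshold_margin, ]
    if (nrow(near)) {
      flags$near <- tibble::tibble(sample_id = near$sample_id,
                                   reason = "near analysis threshold")
    }
    if (!is.null(sex_calls) && any(sex_calls$conflict_flag)) {
      flags$sex <- tibble::tibble(
        sample_id = sex_calls$sample_id[sex_calls$conflict_flag],
        reason = "conflicting sex indicators")
    }
    urine <- cons_samples$sample_id[cons_samples$material == "urine" &
                                      cons_samples$sample_id %in% passing]
    if (length(urine)) {
      flags$urine <- tibble::tibble(sample_id = urine,
                                    reason = "urine sample")
    }
    dplyr::bind_rows(flags)
  })
  note("near_threshold_margin=", config$near_threshold_margin)
  structure(list(
    ntc_flags = ntc_flags, pass = pf$per_sample, pass_summary = pf$summary,
    mismatch_summary = mism, assignments = assignments,
    confirmatory_export = confirmatory, sex_calls = sex_calls,
    clusters = clu$clusters, cluster_threshold = clu$threshold,
    consensus = clu$consensus, parentage = par_res, scrutiny = scrutiny,
    log = log_lines), class = "monitoring_result")
}

#' Observed panel allele frequencies
#'
#' Frequency of `allele_b` per autosomal marker from a genotype table —
#' the frequency input for LOD-based parentage and PID work.
#'
#' @param geno Genotype table.
#' @param markers [marker_info()] tibble.
#' @return Tibble `marker_id`, `p`.
#' @export
panel_frequencies <- function(geno, markers) {
  auto <- intersect(markers$marker_id[markers$chrom_class == "AUTOSOME"],
                    marker_ids(geno))
  counts <- allele_count_matrix(geno[, c("sample_id", auto)], markers)
  tot <- rowSums(counts)
  p <- ifelse(tot > 0, counts[, "b"] / tot, NA_real_)
  tibble::tibble(marker_id = auto, p = unname(p))
}

#' Write a monitoring result as a TSV report bundle
#'
#' @param result A [run_monitoring()] result.
#' @param out_dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_monitoring_reports <- function(result, out_dir) {
  tabs <- list(
    ntc_flags = result$ntc_flags,
    sample_pass = result$pass,
    pass_summary = result$pass_summary,
    mismatch_summary = result$mismatch_summary,
    clusters = result$clusters,
    scrutiny = result$scrutiny)
  if (!is.null(result$assignments)) tabs$assignments <- result$assignments
  if (!is.null(result$sex_calls)) tabs$sex_calls <- result$sex_calls
  if (!is.null(result$parentage)) tabs$parentage <- result$parentage
  tabs$confirmatory_export <- result$confirmatory_export
  paths <- write_reports(tabs, out_dir)
  writeLines(result$log, file.path(out_dir, "applied_thresholds.log"))
  invisible(c(paths, file.path(out_dir, "applied_thresholds.log")))
}
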