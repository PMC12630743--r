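#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an assignment result
#'
#' One row per (sample, group) with the group posterior — the long form
#' convenient for plotting and joins.
#'
#' @param x An `assignment_result` from [assign_species()].
#' @param ... Unused.
#' @return A tibble `sample_id`, `group`, `posterior`, `best`.
#' @method tidy assignment_result
#' @export
tidy.assignment_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("sample_id", "best_group",
                  dplyr::starts_with("posterior_")) |>
    tidyr::pivot_longer(dplyr::starts_with("posterior_"),
                        names_to = "group", names_prefix = "posterior_",
                        values_to = "posterior") |>
    dplyr::mutate(best = group == best_group) |>
    dplyr::select("sample_id", "group", "posterior", "best")
}

#' @rdname tidy.assignment_result
#' @method glance assignment_result
#' @export
glance.assignment_result <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x),
                 n_groups = sum(startsWith(names(x), "posterior_")),
                 mean_posterior = mean(x$posterior),
                 min_posterior = min(x$posterior))
}

#' Tidy a PID result
#'
#' @param x A `pid_result` from [pid_summary()].
#' @param ... Unused.
#' @return Per-locus tibble with cumulative products in informativeness
#'   order (`rank`, `cum_pid`, `cum_pidsib`).
#' @method tidy pid_result
#' @export
tidy.pid_result <- function(x, ...) {
  per <- x$per_locus[order(x$per_locus$pid), ]
  per$rank <- seq_len(nrow(per))
  per$cum_pid <- cumprod(per$pid)
  per$cum_pidsib <- cumprod(sort(x$per_locus$pid_sib))
  tibble::as_tibble(per)
}

#' @rdname tidy.pid_result
#' @method glance pid_result
#' @export
glance.pid_result <- function(x, ...) {
  tibble::tibble(n_loci = nrow(x$per_locus),
                 mean_maf = mean(x$per_locus$maf),
                 n_markers_pid = x$n_markers_pid,
                 n_markers_pidsib = x$n_markers_pidsib,
                 threshold = x$threshold)
}

#' Tidy sex calls
#'
#' @param x A `sex_calls` tibble from [call_sex()].
#' @param ... Unused.
#' @return The calls as a plain tibble.
#' @method tidy sex_calls
#' @export
tidy.sex_calls <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.sex_calls
#' @method glance sex_calls
#' @export
glance.sex_calls <- function(x, ...) {
  tibble::tibble(n = nrow(x),
                 n_male = sum(x$call == "MALE"),
                 n_female = sum(x$call == "FEMALE"),
                 n_uncertain = sum(x$call == "UNCERTAIN"),
                 n_conflict = sum(x$conflict_flag))
}

#' Tidy an individual-clustering result
#'
#' @param x An `individual_clusters` object from [cluster_individuals()].
#' @param ... Unused.
#' @return Tibble `individual_id`, `sample_id`, `n_samples`.
#' @method tidy individual_clusters
#' @export
tidy.individual_clusters <- function(x, ...) {
  x$clusters |> dplyr::add_count(individual_id, name = "n_samples")
}

#' @rdname tidy.individual_clusters
#' @method glance individual_clusters
#' @export
glance.individual_clusters <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$clusters),
                 n_individuals = dplyr::n_distinct(x$clusters$individual_id),
                 threshold = x$threshold,
                 n_insufficient_overlap = nrow(x$insufficient_overlap))
}

#' @export
print.monitoring_result <- function(x, ...) {
  cat("Monitoring season result\n")
  smry <- x$pass_summary
  ov <- smry[smry$material == "overall", ]
  cat("  samples:", ov$n, " passing:", ov$n_pass,
      paste0("(", ov$pct_pass, "%)\n"))
  cat("  individuals:", dplyr::n_distinct(x$clusters$individual_id),
      " mismatch threshold:", x$cluster_threshold, "\n")
  if (!is.null(x$sex_calls)) {
    cat("  sex conflicts flagged:", sum(x$sex_calls$conflict_flag), "\n")
  }
  cat("  scrutiny flags:", nrow(x$scrutiny), "\n")
  invisible(x)
}
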