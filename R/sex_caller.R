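#' Sexing configuration
#'
#' Thresholds for genetic sexing from X-marker homozygosity and a Y
#' presence marker. A sample is called male only when the Y marker is
#' detected and its X-homozygosity statistic is high (males are hemizygous,
#' so every X call looks homozygous); female only when Y is absent and the
#' statistic is low. Conflicting indicators — Y detected together with
#' clearly heterozygous X markers — are the signature of a mixed sample and
#' raise a contamination flag.
#'
#' @param f_male_min Minimum X-inbreeding statistic for a male call.
#' @param f_female_max Maximum statistic for a female call (must be below
#'   `f_male_min`).
#' @param min_x_typed Minimum called X markers before the statistic is
#'   considered defined.
#' @return A list of class `sex_config`.
#' @export
sex_config <- function(f_male_min = 0.8, f_female_max = 0.2,
                       min_x_typed = 5) {
  stopifnot(f_female_max < f_male_min)
  structure(list(f_male_min = f_male_min, f_female_max = f_female_max,
                 min_x_typed = min_x_typed), class = "sex_config")
}

#' X-chromosome inbreeding statistic
#'
#' The method-of-moments homozygosity excess used by standard sex checks:
#' `F = (O_hom - E_hom) / (L - E_hom)` where `O_hom` is the observed count
#' of homozygous typed X markers, `L` the typed count, and
#' `E_hom = sum(1 - 2 p q)` the expectation under Hardy-Weinberg at the
#' supplied reference female allele frequencies. Hemizygous males score 1;
#' outbred females scatter around 0.
#'
#' @param geno Genotype table.
#' @param x_freqs Tibble `marker_id`, `p` — reference female frequency of
#'   `allele_b` per X marker.
#' @param min_x_typed Markers required for a defined statistic.
#' @return A tibble `sample_id`, `n_typed`, `n_hom`, `x_f` (`NA` when fewer
#'   than `min_x_typed` markers are typed).
#' @export
x_inbreeding_f <- function(geno, x_freqs, min_x_typed = 5) {
  mk <- intersect(x_freqs$marker_id, marker_ids(geno))
  if (!length(mk)) stop("no X markers shared with the frequency table")
  cm <- call_matrix(geno, mk)
  p <- x_freqs$p[match(mk, x_freqs$marker_id)]
  e_hom_per <- 1 - 2 * p * (1 - p)
  rows <- purrr::map(seq_len(nrow(cm)), function(i) {
    calls <- cm[i, ]
    typed <- !is.na(calls)
    n_typed <- sum(typed)
    n_hom <- sum(!het_call(calls[typed]))
    f <- NA_real_
    if (n_typed >= min_x_typed) {
      e_hom <- sum(e_hom_per[typed])
      f <- if (n_typed - e_hom > 0) (n_hom - e_hom) / (n_typed - e_hom)
           else NA_real_
    }
    tibble::tibble(sample_id = rownames(cm)[i], n_typed = n_typed,
                   n_hom = n_hom, x_f = f)
  })
  dplyr::bind_rows(rows)
}

#' Call sex from X statistic and Y detection
#'
#' Positive-confirmation rule: MALE requires Y detected and a high (or
#' undefined) X statistic; FEMALE requires Y absent and a low statistic.
#' Y detected together with a sub-male statistic (heterozygous X in a
#' sample carrying Y) is the male+female mixture signature and is flagged
#' as a suspected contamination, with the call left UNCERTAIN. Y absent with a
#' high statistic is the homozygous-female failure mode (common in inbred
#' females) and also stays UNCERTAIN — never FEMALE-by-default.
#'
#' @param x_stats Output of [x_inbreeding_f()].
#' @param y_detected Logical vector (or tibble `sample_id`, `y_detected`).
#' @param config A [sex_config()].
#' @param known_sex Optional character vector of field-recorded sexes; a
#'   known sex overrides the genetic call but conflicts stay flagged.
#' @return A tibble of class `sex_calls`: `sample_id`, `x_f`, `y_detected`,
#'   `call` (`MALE`/`FEMALE`/`UNCERTAIN`), `conflict_flag`.
#' @export
call_sex <- function(x_stats, y_detected, config = sex_config(),
                     known_sex = NULL) {
  if (is.data.frame(y_detected)) {
    y_detected <- y_detected$y_detected[match(x_stats$sample_id,
                                              y_detected$sample_id)]
  }
  stopifnot(length(y_detected) == nrow(x_stats))
  f <- x_stats$x_f
  male <- y_detected & (is.na(f) | f >= config$f_male_min)
  female <- !y_detected & !is.na(f) & f <= config$f_female_max
  # Y present without a male-like X pattern is the mixture signature; Y
  # absent with a fully homozygous X is the inbred-female failure mode
  conflict <- (y_detected & !is.na(f) & f < config$f_male_min) |
    (!y_detected & !is.na(f) & f >= config$f_male_min)
  call <- dplyr::case_when(conflict ~ "UNCERTAIN",
                           male ~ "MALE",
                           female ~ "FEMALE",
                           TRUE ~ "UNCERTAIN")
  if (!is.null(known_sex)) {
    known <- !is.na(known_sex)
    conflict <- conflict | (known & call != "UNCERTAIN" & call != known_sex)
    call[known] <- known_sex[known]
  }
  out <- tibble::tibble(sample_id = x_stats$sample_id, x_f = f,
                        y_detected = y_detected, call = call,
                        conflict_flag = conflict)
  class(out) <- c("sex_calls", class(out))
  out
}

#' Tune sexing thresholds on known-sex samples
#'
#' Grid search over `(f_male_min, f_female_max)` pairs maximising the
#' fraction of known-sex samples given a definite call, subject to zero
#' mis-calls (UNCERTAIN is allowed). Ties prefer the widest uncertainty
#' band — the most conservative of the equally accurate configurations.
#' When no grid point achieves zero mis-calls the most conservative
#' configuration is returned with a warning, along with the conflicting
#' samples.
#'
#' @param x_stats Output of [x_inbreeding_f()] for the known-sex samples.
#' @param y_detected Logical vector aligned with `x_stats`.
#' @param known_sex Character vector `MALE`/`FEMALE` (no `NA`).
#' @param grid Candidate threshold values.
#' @return A list with `config` (tuned [sex_config()]), `called_fraction`,
#'   `n_miscalled` and `conflicts` (known-sex samples that cannot be called
#'   correctly under the tuned thresholds).
#' @export
tune_sex_thresholds <- function(x_stats, y_detected, known_sex,
                                grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(length(known_sex) == nrow(x_stats), length(known_sex) >= 1)
  if (anyNA(known_sex)) stop("known_sex must be complete for tuning")
  score_one <- function(fm, ff) {
    cfg <- sex_config(f_male_min = fm, f_female_max = ff)
    calls <- call_sex(x_stats, y_detected, cfg)
    definite <- calls$call != "UNCERTAIN"
    tibble::tibble(fm = fm, ff = ff,
                   mis = sum(definite & calls$call != known_sex),
                   frac = mean(definite & calls$call == known_sex),
                   band = fm - ff)
  }
  pairs <- expand.grid(fm = grid, ff = grid)
  pairs <- pairs[pairs$ff < pairs$fm, ]
  scores <- dplyr::bind_rows(purrr::map2(pairs$fm, pairs$ff, score_one))
  ok <- scores[scores$mis == 0, ]
  if (nrow(ok)) {
    ok <- ok[order(-ok$frac, -ok$band, ok$fm), ]
    cfg <- sex_config(f_male_min = ok$fm[1], f_female_max = ok$ff[1])
  } else {
    warning("no threshold pair achieves zero mis-calls; ",
            "returning the most conservative configuration")
    cfg <- sex_config(f_male_min = max(grid), f_female_max = min(grid))
  }
  calls <- call_sex(x_stats, y_detected, cfg)
  definite <- calls$call != "UNCERTAIN"
  list(config = cfg,
       called_fraction = mean(definite & calls$call == known_sex),
       n_miscalled = sum(definite & calls$call != known_sex),
       conflicts = x_stats$sample_id[calls$call == "UNCERTAIN" |
                                       (definite & calls$call != known_sex)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Y-marker detection vector from a genotype table
#'
#' @param geno Genotype table.
#' @param markers [marker_info()] tibble identifying Y markers.
#' @return Logical vector aligned with `geno$sample_id`: any Y marker
#'   called.
#' @export
y_detection <- function(geno, markers) {
  y_ids <- intersect(markers$marker_id[markers$chrom_class == "Y"],
                     marker_ids(geno))
  if (!length(y_ids)) return(rep(FALSE, nrow(geno)))
  rowSums(!is.na(call_matrix(geno, y_ids))) > 0
}
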