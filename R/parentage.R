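#' Parentage configuration
#'
#' @param error_rate Per-allele genotyping error rate `epsilon` used by the
#'   transmission likelihood and by the incompatibility tolerance.
#' @param max_incompatible Maximum Mendelian-incompatible loci tolerated
#'   for a candidate (dyad or trio); `"auto"` uses `ceiling(2 * epsilon *
#'   L)` for L shared loci — the expected error load plus headroom.
#' @param prior_parent_present Prior probability that an offspring's true
#'   parents are among the candidates; its complement weights the
#'   "parents unknown" hypothesis.
#' @return A list of class `parentage_config`.
#' @export
parentage_config <- function(error_rate = 0.01, max_incompatible = "auto",
                             prior_parent_present = 0.9) {
  stopifnot(error_rate >= 0, error_rate < 0.5,
            prior_parent_present > 0, prior_parent_present <= 1)
  structure(list(error_rate = error_rate,
                 max_incompatible = max_incompatible,
                 prior_parent_present = prior_parent_present),
            class = "parentage_config")
}

#' Mendelian incompatibilities between offspring and candidate parent(s)
#'
#' Dyad: loci where offspring and candidate share no allele. Trio: loci
#' where no combination of one gamete from each candidate can produce the
#' offspring genotype. Only jointly called loci are examined.
#'
#' @param off Named call vector of the offspring.
#' @param parent1 Named call vector of the (first) candidate parent.
#' @param parent2 Optional second candidate (making it a trio).
#' @return A list `n_incompatible`, `n_shared`.
#' @export
mendel_incompatibilities <- function(off, parent1, parent2 = NULL) {
  shared <- !is.na(off) & !is.na(parent1) &
    (if (is.null(parent2)) TRUE else !is.na(parent2))
  idx <- which(shared)
  n_inc <- 0L
  for (j in idx) {
    o <- strsplit(off[j], "/", fixed = TRUE)[[1]]
    p1 <- strsplit(parent1[j], "/", fixed = TRUE)[[1]]
    if (is.null(parent2)) {
      if (!any(o %in% p1)) n_inc <- n_inc + 1L
    } else {
      p2 <- strsplit(parent2[j], "/", fixed = TRUE)[[1]]
      ok <- (o[1] %in% p1 && o[2] %in% p2) || (o[2] %in% p1 && o[1] %in% p2)
      if (!ok) n_inc <- n_inc + 1L
    }
  }
  list(n_incompatible = n_inc, n_shared = length(idx))
}

# P(allele a transmitted | parent genotype), mixing Mendelian segregation
# with a per-allele error that substitutes a random population allele
transmit_prob <- function(a, parent_alleles, p_of, eps) {
  (1 - eps) * mean(parent_alleles == a) + eps * p_of(a)
}

#' Parentage log-odds (LOD) score
#'
#' `log10 P(offspring | candidate parent(s), epsilon) / P(offspring | HWE)`
#' summed over jointly called loci. Transmission mixes Mendelian
#' segregation with a per-allele error `epsilon` replacing the transmitted
#' allele by a random population allele; in a dyad the unmodelled parental
#' allele is drawn from the population frequencies. With `epsilon = 0` an
#' incompatible locus drives the score to `-Inf`, recovering pure
#' exclusion.
#'
#' @param off Named call vector of the offspring.
#' @param parent1,parent2 Candidate call vectors (`parent2` optional).
#' @param freqs Tibble `marker_id`, `p` (frequency of `allele_b`).
#' @param markers [marker_info()] tibble registering allele labels.
#' @param eps Per-allele error rate.
#' @return The LOD score (may be `-Inf`).
#' @export
parentage_lod <- function(off, parent1, parent2 = NULL, freqs, markers,
                          eps = 0.01) {
  mk <- intersect(names(off), freqs$marker_id)
  lod <- 0
  for (m in mk) {
    if (is.na(off[m]) || is.na(parent1[m])) next
    if (!is.null(parent2) && is.na(parent2[m])) next
    mrow <- markers[markers$marker_id == m, ]
    if (mrow$chrom_class != "AUTOSOME") next
    pb <- freqs$p[freqs$marker_id == m]
    p_of <- function(a) if (a == mrow$allele_b) pb else 1 - pb
    o <- strsplit(off[m], "/", fixed = TRUE)[[1]]
    p1 <- strsplit(parent1[m], "/", fixed = TRUE)[[1]]
    t2 <- if (is.null(parent2)) {
      p_of
    } else {
      p2 <- strsplit(parent2[m], "/", fixed = TRUE)[[1]]
      function(a) transmit_prob(a, p2, p_of, eps)
    }
    t1 <- function(a) transmit_prob(a, p1, p_of, eps)
    num <- if (o[1] == o[2]) t1(o[1]) * t2(o[1])
           else t1(o[1]) * t2(o[2]) + t1(o[2]) * t2(o[1])
    den <- if (o[1] == o[2]) p_of(o[1])^2 else 2 * p_of(o[1]) * p_of(o[2])
    lod <- lod + log10(num) - log10(den)
  }
  lod
}

#' Assign parents by exclusion plus likelihood
#'
#' For each offspring, every candidate mother (females and unknown-sex
#' individuals) and father (males and unknown-sex) passing the Mendelian
#' incompatibility tolerance is scored; the best-scoring parent pair — or
#' single parent when no pair passes — is reported with a confidence equal
#' to its posterior among all surviving hypotheses (equal priors across
#' pairs, the parent-absent hypothesis weighted by
#' `1 - prior_parent_present`). Offspring with no surviving candidate are
#' left unassigned. Ties break by higher shared-locus count, then lexical
#' candidate id.
#'
#' @param geno Genotype table containing offspring and candidates.
#' @param sexes Tibble `sample_id`, `sex` (`MALE`/`FEMALE`/`NA`).
#' @param freqs Tibble `marker_id`, `p` for the autosomal panel.
#' @param markers [marker_info()] tibble.
#' @param config A [parentage_config()].
#' @param offspring Ids to assign (default: everyone).
#' @return A tibble of class `parentage_result`: `offspring_id`, `sire`,
#'   `dam` (NA when unassigned), `lod`, `confidence`, `n_incompatible`,
#'   `hypothesis` (`pair`/`single`/`none`).
#' @export
assign_parents <- function(geno, sexes, freqs, markers,
                           config = parentage_config(),
                           offspring = geno$sample_id) {
  cm <- call_matrix(geno)
  auto <- intersect(colnames(cm),
                    markers$marker_id[markers$chrom_class == "AUTOSOME"])
  cm <- cm[, auto, drop = FALSE]
  sex_of <- stats::setNames(sexes$sex, sexes$sample_id)
  eps <- config$error_rate
  tol <- function(L) {
    if (identical(config$max_incompatible, "auto")) ceiling(2 * eps * L)
    else config$max_incompatible
  }
  rows <- purrr::map(offspring, function(o) {
    off <- cm[o, ]
    others <- setdiff(rownames(cm), o)
    moms <- others[is.na(sex_of[others]) | sex_of[others] == "FEMALE"]
    dads <- others[is.na(sex_of[others]) | sex_of[others] == "MALE"]
    # dyad pre-screen
    screen <- function(cands) {
      keep <- list()
      for (cand in cands) {
        mi <- mendel_incompatibilities(off, cm[cand, ])
        if (mi$n_shared >= 1 && mi$n_incompatible <= tol(mi$n_shared)) {
          keep[[cand]] <- mi
        }
      }
      keep
    }
    moms_ok <- screen(moms)
    dads_ok <- screen(dads)
    hyps <- list()
    for (d in names(dads_ok)) for (m in names(moms_ok)) {
      if (d == m) next
      tri <- mendel_incompatibilities(off, cm[d, ], cm[m, ])
      if (tri$n_shared < 1 || tri$n_incompatible > tol(tri$n_shared)) next
      lod <- parentage_lod(off, cm[d, ], cm[m, ], freqs, markers, eps)
      hyps[[length(hyps) + 1]] <- tibble::tibble(
        sire = d, dam = m, hypothesis = "pair", lod = lod,
        n_incompatible = tri$n_incompatible, n_shared = tri$n_shared)
    }
    if (!length(hyps)) {
      for (d in names(dads_ok)) {
        hyps[[length(hyps) + 1]] <- tibble::tibble(
          sire = d, dam = NA_character_, hypothesis = "single",
          lod = parentage_lod(off, cm[d, ], NULL, freqs, markers, eps),
          n_incompatible = dads_ok[[d]]$n_incompatible,
          n_shared = dads_ok[[d]]$n_shared)
      }
      for (m in names(moms_ok)) {
        hyps[[length(hyps) + 1]] <- tibble::tibble(
          sire = NA_character_, dam = m, hypothesis = "single",
          lod = parentage_lod(off, cm[m, ], NULL, freqs, markers, eps),
          n_incompatible = moms_ok[[m]]$n_incompatible,
          n_shared = moms_ok[[m]]$n_shared)
      }
    }
    none <- tibble::tibble(sire = NA_character_, dam = NA_character_,
                           hypothesis = "none", lod = 0,
                           n_incompatible = NA_integer_,
                           n_shared = NA_integer_)
    tab <- dplyr::bind_rows(c(hyps, list(none)))
    n_named <- max(1L, nrow(tab) - 1L)
    prior <- ifelse(tab$hypothesis == "none",
                    1 - config$prior_parent_present,
                    config$prior_parent_present / n_named)
    logw <- tab$lod * log(10) + log(prior)
    post <- softmax(logw)
    ord <- order(-post, -tidyr::replace_na(tab$n_shared, 0L), tab$sire,
                 tab$dam)
    best <- tab[ord[1], ]
    tibble::tibble(offspring_id = o, sire = best$sire, dam = best$dam,
                   hypothesis = best$hypothesis, lod = best$lod,
                   confidence = post[ord[1]],
                   n_incompatible = best$n_incompatible)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("parentage_result", class(out))
  out
}

#' Pedigree inbreeding coefficients
#'
#' `F` of each individual equals the kinship of its parents, computed by
#' the standard recursive kinship function with founders unrelated and
#' non-inbred: `phi(a, a) = (1 + F_a) / 2` and
#' `phi(a, b) = (phi(sire_a, b) + phi(dam_a, b)) / 2` taking `a` later in
#' the pedigree, with missing parents contributing 0.
#'
#' @param pedigree Tibble `id`, `sire`, `dam` (`NA` for unknown); must be
#'   acyclic.
#' @return A tibble `id`, `f`, with the full kinship matrix in attribute
#'   `"kinship"`.
#' @export
pedigree_inbreeding <- function(pedigree) {
  ped <- tibble::as_tibble(pedigree)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)),
            !anyDuplicated(ped$id))
  ord <- pedigree_order(ped)
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  pos <- stats::setNames(seq_len(n), ped$id)
  parent_idx <- function(p) if (is.na(p) || !p %in% ped$id) NA_integer_
                            else pos[[p]]
  done <- integer(0)
  for (i in ord) {
    si <- parent_idx(ped$sire[i])
    di <- parent_idx(ped$dam[i])
    f_i <- if (!is.na(si) && !is.na(di)) K[si, di] else 0
    K[i, i] <- 0.5 * (1 + f_i)
    for (j in done) {
      k_sj <- if (!is.na(si)) K[si, j] else 0
      k_dj <- if (!is.na(di)) K[di, j] else 0
      K[i, j] <- K[j, i] <- 0.5 * (k_sj + k_dj)
    }
    done <- c(done, i)
  }
  f <- vapply(seq_len(n), function(i) {
    si <- parent_idx(ped$sire[i]); di <- parent_idx(ped$dam[i])
    if (!is.na(si) && !is.na(di)) K[si, di] else 0
  }, 0)
  out <- tibble::tibble(id = ped$id, f = f)
  attr(out, "kinship") <- K
  out
}
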