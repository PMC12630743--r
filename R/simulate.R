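#' Simulation configuration
#'
#' Bundles every free parameter of the synthetic-data generator. Defaults
#' describe the study system the package targets: a 96-assay canid
#' monitoring panel (81 high-MAF autosomal markers, 2 wolf-jackal and 3
#' wolf-dog diagnostic markers, 9 X markers, 1 presence-scored Y marker),
#' five populations with wolf and dog genetically close and jackal, fox and
#' raccoon dog distant, and per-material genotyping error increasing from
#' tissue through scat to urine and hair.
#'
#' @param n_high_maf,n_wolf_jackal,n_wolf_dog,n_x,n_y Marker counts per
#'   category.
#' @param populations Tibble with columns `name`, `fst` (Balding-Nichols
#'   divergence from the ancestral pool, in `[0,1)`) and `n` (reference
#'   individuals to simulate).
#' @param maf_range Ancestral minor-allele-frequency range for high-MAF
#'   markers.
#' @param x_maf_range Ancestral MAF range for X markers (panel X markers are
#'   chosen for moderate female heterozygosity).
#' @param error_model Tibble with columns `material`, `missing_rate`
#'   (whole-call dropout), `dropout_rate` (allelic dropout: a heterozygote
#'   observed as one of its homozygotes) and `false_allele_rate` (one allele
#'   mis-read as the other registered allele).
#' @param scat_replicates Number of genotyping replicates per scat sample.
#' @param quality_dispersion Beta precision of per-sample DNA quality: each
#'   physical sample draws its own whole-call missing rate from
#'   `Beta(m * k, (1 - m) * k)` with `m` the material mean and `k` this
#'   parameter. Small `k` gives the heavy-tailed quality typical of field
#'   samples (most extracts good, a fraction degraded beyond use);
#'   `Inf` disables the variation.
#' @param contamination_rate Probability that a urine sample is a
#'   two-individual mixture (over-marking at a scent post).
#' @param seed Integer seed; identical configurations generate identical
#'   datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_high_maf = 81, n_wolf_jackal = 2, n_wolf_dog = 3,
                       n_x = 9, n_y = 1,
                       populations = default_populations(),
                       maf_range = c(0.292, 0.5),
                       x_maf_range = c(0.125, 0.333),
                       error_model = default_error_model(),
                       scat_replicates = 2,
                       quality_dispersion = 1.2,
                       contamination_rate = 0.1,
                       seed = 1L) {
  stopifnot(
    all(populations$fst >= 0 & populations$fst < 1),
    maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
    all(unlist(error_model[, -1]) >= 0), all(unlist(error_model[, -1]) <= 1),
    contamination_rate >= 0, contamination_rate <= 1,
    quality_dispersion > 0
  )
  structure(list(
    n_high_maf = n_high_maf, n_wolf_jackal = n_wolf_jackal,
    n_wolf_dog = n_wolf_dog, n_x = n_x, n_y = n_y,
    populations = populations, maf_range = maf_range,
    x_maf_range = x_maf_range, error_model = error_model,
    scat_replicates = scat_replicates,
    quality_dispersion = quality_dispersion,
    contamination_rate = contamination_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_populations <- function() {
  tibble::tibble(
    name = c("wolf", "dog", "jackal", "fox", "raccoon_dog"),
    fst = c(0.03, 0.08, 0.35, 0.35, 0.35),
    n = c(40L, 40L, 10L, 10L, 10L)
  )
}

#' @rdname sim_config
#' @export
default_error_model <- function() {
  tibble::tibble(
    material = c("tissue", "blood", "saliva", "scat", "urine", "hair"),
    missing_rate = c(0.005, 0.005, 0.05, 0.15, 0.20, 0.30),
    dropout_rate = c(0.0005, 0.0005, 0.005, 0.001, 0.02, 0.03),
    false_allele_rate = c(0.0001, 0.0001, 0.0005, 0.0002, 0.001, 0.002)
  )
}

#' Simulated marker map for a configuration
#'
#' Lays the configured marker categories out on a canid-like map: autosomal
#' markers cycled over chromosomes 1-38, X markers on X outside the
#' pseudoautosomal region, the Y presence marker on Y.
#'
#' @param config A [sim_config()].
#' @return A [marker_info()] tibble.
#' @export
simulate_markers <- function(config) {
  n_auto <- config$n_high_maf + config$n_wolf_jackal + config$n_wolf_dog
  cats <- c(rep("HIGH_MAF", config$n_high_maf),
            rep("WOLF_JACKAL_DIAG", config$n_wolf_jackal),
            rep("WOLF_DOG_DIAG", config$n_wolf_dog))
  auto_ids <- sprintf("AUT%03d", seq_len(n_auto))
  x_ids <- sprintf("XCH%02d", seq_len(config$n_x))
  y_ids <- sprintf("YCH%02d", seq_len(config$n_y))
  marker_info(
    marker_id = c(auto_ids, x_ids, y_ids),
    chrom = c(as.character(rep_len(1:38, n_auto)),
              rep("X", config$n_x), rep("Y", config$n_y)),
    position = c(1e6 * seq_len(n_auto), 1e6 * seq_len(config$n_x) + 7e6,
                 1e6 * seq_len(config$n_y)),
    allele_a = "A", allele_b = "G",
    category = c(cats, rep("X_SEX", config$n_x), rep("Y_SEX", config$n_y))
  )
}

#' Simulate per-population allele frequencies
#'
#' Ancestral frequencies are drawn uniformly from the configured MAF range;
#' each population's frequency is then drawn from the Balding-Nichols
#' distribution `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is the ancestral
#' frequency and whose spread grows with that population's divergence `F`.
#' `F = 0` copies the ancestral frequency exactly. Diagnostic markers are
#' fixed for opposite alleles in the discriminated species pair (frequency
#' 1 vs 0), the design target of a species-diagnostic assay.
#'
#' @param config A [sim_config()].
#' @param markers Optional marker map; defaults to [simulate_markers()].
#' @return A tibble `(marker_id, population, p)` where `p` is the frequency
#'   of `allele_b`; the Y presence marker carries `NA`.
#' @export
simulate_frequencies <- function(config, markers = simulate_markers(config)) {
  set.seed(config$seed)
  pops <- config$populations
  rows <- purrr::map(seq_len(nrow(markers)), function(i) {
    mk <- markers[i, ]
    if (mk$chrom_class == "Y") {
      return(tibble::tibble(marker_id = mk$marker_id, population = pops$name,
                            p = NA_real_))
    }
    p <- switch(
      mk$category,
      HIGH_MAF = stats::runif(1, config$maf_range[1], config$maf_range[2]),
      X_SEX = stats::runif(1, config$x_maf_range[1], config$x_maf_range[2]),
      WOLF_JACKAL_DIAG = , WOLF_DOG_DIAG = NA_real_)
    if (mk$category %in% c("WOLF_JACKAL_DIAG", "WOLF_DOG_DIAG")) {
      pv <- if (mk$category == "WOLF_JACKAL_DIAG") {
        # dogs share the wolf allele; the distant canids carry the jackal one
        ifelse(pops$name %in% c("wolf", "dog"), 1, 0)
      } else {
        # ascertained within the wolf/dog pair; state in the distant canids
        # is unascertained, modelled as intermediate
        ifelse(pops$name == "wolf", 1, ifelse(pops$name == "dog", 0, 0.5))
      }
      return(tibble::tibble(marker_id = mk$marker_id, population = pops$name,
                            p = pv))
    }
    pv <- vapply(pops$fst, function(f) balding_nichols(p, f), 0)
    tibble::tibble(marker_id = mk$marker_id, population = pops$name, p = pv)
  })
  dplyr::bind_rows(rows)
}

balding_nichols <- function(p, fst) {
  if (fst == 0) return(p)
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  stats::rbeta(1, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Simulate true genotypes down a pedigree
#'
#' Founders are drawn in Hardy-Weinberg proportions at their population's
#' frequencies; each non-founder receives one allele from each parent
#' uniformly at random. X markers follow sex-linked transmission: females
#' carry two X alleles, males carry one (maternal) allele which the array
#' reports as a homozygous-looking call; sons never receive a paternal X.
#' The Y marker is detected exactly in males.
#'
#' @param freqs Frequency tibble from [simulate_frequencies()].
#' @param pedigree Tibble with columns `id`, `sire`, `dam` (NA for
#'   founders), `sex` (`"MALE"`/`"FEMALE"`) and `population`.
#' @param config A [sim_config()].
#' @param markers Marker map matching `freqs`.
#' @return A list with `genotypes` (truth genotype table, one row per
#'   pedigree member) and `truth` (tibble of id, sex, species/population).
#' @export
simulate_individuals <- function(freqs, pedigree, config,
                                 markers = simulate_markers(config)) {
  set.seed(config$seed + 1L)
  ped <- check_pedigree(pedigree)
  ord <- pedigree_order(ped)
  fw <- tidyr::pivot_wider(freqs, names_from = "population", values_from = "p")
  fw <- fw[match(markers$marker_id, fw$marker_id), ]
  n <- nrow(ped)
  # allele pairs held as two character matrices; males carry their single X
  # allele in both slots
  a1 <- a2 <- matrix(NA_character_, n, nrow(markers),
                     dimnames = list(ped$id, markers$marker_id))
  draw <- function(p, mk) ifelse(stats::runif(length(p)) < p,
                                 markers$allele_b[mk], markers$allele_a[mk])
  for (i in ord) {
    sex <- ped$sex[i]
    founder <- is.na(ped$sire[i]) && is.na(ped$dam[i])
    if (founder) {
      p <- fw[[ped$population[i]]]
      for (j in seq_len(nrow(markers))) {
        cls <- markers$chrom_class[j]
        if (cls == "Y") {
          if (sex == "MALE") a1[i, j] <- a2[i, j] <- markers$allele_a[j]
        } else if (cls == "X" && sex == "MALE") {
          a1[i, j] <- a2[i, j] <- draw(p[j], j)
        } else {
          a1[i, j] <- draw(p[j], j)
          a2[i, j] <- draw(p[j], j)
        }
      }
    } else {
      si <- match(ped$sire[i], ped$id)
      di <- match(ped$dam[i], ped$id)
      if (is.na(si) || is.na(di)) {
        stop("non-founder ", ped$id[i], " must have both parents in the pedigree")
      }
      pick <- function(row, j) if (stats::runif(1) < 0.5) a1[row, j] else a2[row, j]
      for (j in seq_len(nrow(markers))) {
        cls <- markers$chrom_class[j]
        if (cls == "Y") {
          if (sex == "MALE") a1[i, j] <- a2[i, j] <- markers$allele_a[j]
        } else if (cls == "X") {
          mat <- pick(di, j)
          if (sex == "MALE") {
            a1[i, j] <- a2[i, j] <- mat
          } else {
            a1[i, j] <- a1[si, j]  # father's single X
            a2[i, j] <- mat
          }
        } else {
          a1[i, j] <- pick(si, j)
          a2[i, j] <- pick(di, j)
        }
      }
    }
  }
  calls <- matrix(NA_character_, n, nrow(markers),
                  dimnames = list(ped$id, markers$marker_id))
  filled <- !is.na(a1)
  calls[filled] <- paste(pmin(a1[filled], a2[filled]),
                         pmax(a1[filled], a2[filled]), sep = "/")
  list(
    genotypes = genotype_table(ped$id, calls),
    truth = tibble::tibble(individual_id = ped$id, sex = ped$sex,
                           species = ped$population,
                           sire = ped$sire, dam = ped$dam)
  )
}

check_pedigree <- function(pedigree) {
  ped <- tibble::as_tibble(pedigree)
  need <- c("id", "sire", "dam", "sex", "population")
  if (!all(need %in% names(ped))) {
    stop("pedigree needs columns ", paste(need, collapse = ", "))
  }
  stopifnot(!anyDuplicated(ped$id), all(ped$sex %in% c("MALE", "FEMALE")))
  sires <- stats::na.omit(unique(ped$sire))
  dams <- stats::na.omit(unique(ped$dam))
  if (any(ped$sex[match(sires, ped$id)] == "FEMALE", na.rm = TRUE)) {
    stop("sire with FEMALE sex in pedigree")
  }
  if (any(ped$sex[match(dams, ped$id)] == "MALE", na.rm = TRUE)) {
    stop("dam with MALE sex in pedigree")
  }
  invisible(pedigree_order(ped))  # errors on cycles
  ped
}

# topological order: parents before offspring; stops on cycles
pedigree_order <- function(ped) {
  n <- nrow(ped)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                     (is.na(ped$sire) | placed[match(ped$sire, ped$id)] %in% TRUE |
                        !ped$sire %in% ped$id) &
                     (is.na(ped$dam) | placed[match(ped$dam, ped$id)] %in% TRUE |
                        !ped$dam %in% ped$id))
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n) stop("pedigree contains a cycle")
  ord
}

#' Corrupt true genotypes into observed monitoring samples
#'
#' Applies the error process of non-invasive genotyping, material by
#' material: whole-call missingness, allelic dropout (a heterozygote
#' observed as a random one of its homozygotes), and false alleles (one
#' allele mis-read as the marker's other allele). Urine samples become
#' two-individual mixtures with the configured probability: at each marker
#' the observed call is the union of the two donors' alleles truncated to a
#' biallelic call, and Y is detected if either donor is male — the
#' over-marking signature that the sex caller later flags.
#'
#' @param truth Output of [simulate_individuals()].
#' @param plan Tibble with columns `individual_id`, `material` and
#'   optionally `n_replicates` (defaults: scat uses
#'   `config$scat_replicates`, everything else 1). One row per physical
#'   sample.
#' @param config A [sim_config()].
#' @param markers Marker map.
#' @return A list with `genotypes` (observed genotype table, one row per
#'   replicate), `samples` (a [sample_record()] tibble with replicate
#'   groups) and `truth` (per-sample truth including contamination pairs).
#' @export
corrupt_samples <- function(truth, plan, config,
                            markers = simulate_markers(config)) {
  set.seed(config$seed + 2L)
  plan <- tibble::as_tibble(plan)
  if (!"n_replicates" %in% names(plan)) {
    plan$n_replicates <- ifelse(plan$material == "scat",
                                config$scat_replicates, 1L)
  }
  em <- config$error_model
  truth_cm <- call_matrix(truth$genotypes)
  truth_tab <- truth$truth
  is_y <- markers$chrom_class == "Y"
  out_calls <- list(); out_samples <- list(); out_truth <- list()
  for (i in seq_len(nrow(plan))) {
    ind <- plan$individual_id[i]
    mat <- plan$material[i]
    er <- em[em$material == mat, ]
    if (!nrow(er)) er <- tibble::tibble(missing_rate = 0, dropout_rate = 0,
                                        false_allele_rate = 0)
    # DNA quality is a property of the physical sample: draw its own
    # missing rate around the material mean (shared by its replicates)
    k <- config$quality_dispersion
    m <- er$missing_rate
    if (is.finite(k) && m > 0 && m < 1) {
      er$missing_rate <- stats::rbeta(1, m * k, (1 - m) * k)
    }
    base <- truth_cm[ind, ]
    donor2 <- NA_character_
    if (mat == "urine" && stats::runif(1) < config$contamination_rate &&
        nrow(truth_cm) > 1) {
      donor2 <- sample(setdiff(rownames(truth_cm), ind), 1)
      base <- mix_calls(base, truth_cm[donor2, ], markers)
    }
    group <- sprintf("S%04d", i)
    for (r in seq_len(plan$n_replicates[i])) {
      obs <- corrupt_one(base, er, markers, is_y)
      sid <- if (plan$n_replicates[i] > 1) paste0(group, "_r", r) else group
      out_calls[[sid]] <- obs
      out_samples[[sid]] <- tibble::tibble(
        sample_id = sid, material = mat, replicate_group = group)
      out_truth[[sid]] <- tibble::tibble(
        sample_id = sid, individual_id = ind,
        true_sex = truth_tab$sex[truth_tab$individual_id == ind],
        true_species = truth_tab$species[truth_tab$individual_id == ind],
        replicate_group = group, contaminant_id = donor2)
    }
  }
  calls <- do.call(rbind, out_calls)
  rownames(calls) <- names(out_calls)
  samples_tab <- dplyr::bind_rows(out_samples)
  truth_out <- dplyr::bind_rows(out_truth)
  # a mixture's Y can come up even when the named donor is female
  list(
    genotypes = genotype_table(names(out_calls), calls),
    samples = sample_record(samples_tab$sample_id,
                            material = samples_tab$material,
                            replicate_group = samples_tab$replicate_group),
    truth = truth_out
  )
}

mix_calls <- function(calls_a, calls_b, markers) {
  out <- calls_a
  for (j in seq_along(calls_a)) {
    if (markers$chrom_class[j] == "Y") {
      if (!is.na(calls_b[j])) out[j] <- calls_b[j] %na% calls_a[j]
      if (!is.na(calls_a[j])) out[j] <- calls_a[j]
      next
    }
    al <- unique(unlist(strsplit(stats::na.omit(c(calls_a[j], calls_b[j])),
                                 "/", fixed = TRUE)))
    if (!length(al)) { out[j] <- NA_character_; next }
    al <- sort(al)[seq_len(min(2, length(al)))]
    if (length(al) == 1) al <- c(al, al)
    out[j] <- paste(al, collapse = "/")
  }
  out
}

`%na%` <- function(a, b) if (is.na(a)) b else a

corrupt_one <- function(base, er, markers, is_y) {
  obs <- base
  n <- length(base)
  u_miss <- stats::runif(n)
  for (j in seq_len(n)) {
    if (is.na(obs[j])) next
    if (u_miss[j] < er$missing_rate) { obs[j] <- NA_character_; next }
    if (is_y[j]) next  # presence marker: only whole-call dropout applies
    al <- strsplit(obs[j], "/", fixed = TRUE)[[1]]
    if (al[1] != al[2] && stats::runif(1) < er$dropout_rate) {
      keep <- sample(al, 1)
      obs[j] <- paste(keep, keep, sep = "/")
      next
    }
    if (stats::runif(1) < er$false_allele_rate) {
      both <- c(markers$allele_a[j], markers$allele_b[j])
      k <- sample(1:2, 1)
      al[k] <- setdiff(both, al[k])[1]
      if (!is.na(al[k])) obs[j] <- paste(sort(al), collapse = "/")
    }
  }
  obs
}

#' Simulate a multi-population reference panel
#'
#' Unrelated founders for every configured population, genotyped at
#' tissue quality, with per-population truth labels — the raw material for
#' building assignment reference sets and estimating panel statistics.
#'
#' @param config A [sim_config()].
#' @return A list with `genotypes`, `markers`, `samples` (with
#'   `known_species`/`known_sex` filled from truth), `freqs` and `truth`.
#' @export
simulate_reference_panel <- function(config = sim_config()) {
  markers <- simulate_markers(config)
  freqs <- simulate_frequencies(config, markers)
  pops <- config$populations
  ped <- dplyr::bind_rows(purrr::map(seq_len(nrow(pops)), function(k) {
    n <- pops$n[k]
    tibble::tibble(
      id = sprintf("%s_%03d", toupper(substr(pops$name[k], 1, 3)), seq_len(n)),
      sire = NA_character_, dam = NA_character_,
      sex = rep_len(c("MALE", "FEMALE"), n),
      population = pops$name[k])
  }))
  sim <- simulate_individuals(freqs, ped, config, markers)
  samples <- sample_record(
    sim$truth$individual_id, material = "tissue",
    known_species = sim$truth$species, known_sex = sim$truth$sex)
  list(genotypes = sim$genotypes, markers = markers, samples = samples,
       freqs = freqs, truth = sim$truth)
}

#' Simulate a monitoring season
#'
#' Emulates the sample structure of an annual non-invasive monitoring
#' season: a set of wolf individuals sampled 1-9 times each through scat
#' (genotyped in duplicate), urine, tissue and hair, with material-specific
#' error rates and optional urine cross-contamination.
#'
#' @param config A [sim_config()].
#' @param n_individuals Number of distinct wolves in the season.
#' @param n_scat,n_urine,n_tissue,n_hair Physical sample counts by material
#'   (defaults mirror a season subset of 282 samples: 188/74/16/4).
#' @return As [corrupt_samples()], plus `markers` and `freqs`.
#' @export
simulate_monitoring_season <- function(config = sim_config(),
                                       n_individuals = 140,
                                       n_scat = 188, n_urine = 74,
                                       n_tissue = 16, n_hair = 4) {
  markers <- simulate_markers(config)
  freqs <- simulate_frequencies(config, markers)
  ped <- tibble::tibble(
    id = sprintf("IND%04d", seq_len(n_individuals)),
    sire = NA_character_, dam = NA_character_,
    sex = rep_len(c("MALE", "FEMALE"), n_individuals),
    population = "wolf")
  sim <- simulate_individuals(freqs, ped, config, markers)
  set.seed(config$seed + 3L)
  n_samples <- n_scat + n_urine + n_tissue + n_hair
  stopifnot(n_samples >= n_individuals)
  # every individual of the season appears at least once; the remaining
  # samples follow a skewed sampling intensity (most wolves seen once or
  # twice, a few resampled often)
  w <- stats::rexp(n_individuals) + 0.2
  owner <- sample(c(ped$id,
                    sample(ped$id, n_samples - n_individuals,
                           replace = TRUE, prob = w)))
  material <- sample(c(rep("scat", n_scat), rep("urine", n_urine),
                       rep("tissue", n_tissue), rep("hair", n_hair)))
  plan <- tibble::tibble(individual_id = owner, material = material)
  out <- corrupt_samples(sim, plan, config, markers)
  out$markers <- markers
  out$freqs <- freqs
  out$individuals <- sim$truth
  out
}
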