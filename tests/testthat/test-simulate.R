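test_that("Balding-Nichols population frequencies centre on the ancestral value", {
  set.seed(99)
  p0 <- 0.4; fst <- 0.2
  draws <- replicate(10000, snpmon:::balding_nichols(p0, fst))
  se <- sqrt(p0 * (1 - p0) * fst / 10000)  # Var = p(1-p)F
  expect_lt(abs(mean(draws) - p0), 3 * se)
  expect_identical(snpmon:::balding_nichols(p0, 0), p0)
  expect_error(snpmon:::balding_nichols(p0, 1.2), "fst")
})

test_that("diagnostic markers are fixed for opposite alleles in their pair", {
  cfg <- sim_config(seed = 5)
  fr <- simulate_frequencies(cfg)
  mk <- simulate_markers(cfg)
  wj <- mk$marker_id[mk$category == "WOLF_JACKAL_DIAG"]
  wd <- mk$marker_id[mk$category == "WOLF_DOG_DIAG"]
  get <- function(m, pop) fr$p[fr$marker_id == m & fr$population == pop]
  for (m in wj) {
    expect_equal(get(m, "wolf"), 1)
    expect_equal(get(m, "jackal"), 0)
  }
  for (m in wd) {
    expect_equal(get(m, "wolf"), 1)
    expect_equal(get(m, "dog"), 0)
  }
})

test_that("identical configurations generate identical datasets", {
  a <- simulate_reference_panel(sim_config(seed = 11))
  b <- simulate_reference_panel(sim_config(seed = 11))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$freqs, b$freqs)
  c <- simulate_reference_panel(sim_config(seed = 12))
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("sex-linked transmission: males hemizygous X, Y tracks sex", {
  cfg <- sim_config(seed = 21)
  mk <- simulate_markers(cfg)
  fr <- simulate_frequencies(cfg, mk)
  ped <- tibble::tibble(
    id = c("F1", "M1", "D1", "S1"),
    sire = c(NA, NA, "M1", "M1"), dam = c(NA, NA, "F1", "F1"),
    sex = c("FEMALE", "MALE", "FEMALE", "MALE"),
    population = "wolf")
  sim <- simulate_individuals(fr, ped, cfg, mk)
  cm <- call_matrix(sim$genotypes)
  x_ids <- mk$marker_id[mk$chrom_class == "X"]
  y_ids <- mk$marker_id[mk$chrom_class == "Y"]
  for (m in x_ids) {
    expect_false(any(het_calls <- grepl("A/G", cm[c("M1", "S1"), m])))
  }
  expect_true(all(!is.na(cm[c("M1", "S1"), y_ids])))
  expect_true(all(is.na(cm[c("F1", "D1"), y_ids])))
  # a son's X allele must be one of his mother's
  for (m in x_ids) {
    son <- strsplit(cm["S1", m], "/")[[1]][1]
    mom <- strsplit(cm["F1", m], "/")[[1]]
    expect_true(son %in% mom)
  }
})

test_that("offspring share at least one allele with each parent at autosomes", {
  cfg <- sim_config(seed = 31)
  mk <- simulate_markers(cfg)
  fr <- simulate_frequencies(cfg, mk)
  ped <- tibble::tibble(
    id = c("A", "B", paste0("kid", 1:10)),
    sire = c(NA, NA, rep("A", 10)), dam = c(NA, NA, rep("B", 10)),
    sex = c("MALE", "FEMALE", rep_len(c("MALE", "FEMALE"), 10)),
    population = "wolf")
  sim <- simulate_individuals(fr, ped, cfg, mk)
  cm <- call_matrix(sim$genotypes)
  auto <- mk$marker_id[mk$chrom_class == "AUTOSOME"]
  for (kid in paste0("kid", 1:10)) {
    for (m in auto[seq(1, length(auto), by = 7)]) {
      k <- strsplit(cm[kid, m], "/")[[1]]
      expect_true(any(k %in% strsplit(cm["A", m], "/")[[1]]))
      expect_true(any(k %in% strsplit(cm["B", m], "/")[[1]]))
    }
  }
})

test_that("HWE founders show the expected heterozygote fraction", {
  cfg <- sim_config(seed = 41, n_high_maf = 1, n_wolf_jackal = 0,
                    n_wolf_dog = 0, n_x = 0, n_y = 0,
                    maf_range = c(0.5, 0.5),
                    populations = tibble::tibble(name = "wolf", fst = 0,
                                                 n = 2000L))
  ref <- simulate_reference_panel(cfg)
  cm <- call_matrix(ref$genotypes)
  het_frac <- mean(cm[, 1] == "A/G")
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(het_frac - 0.5), 3 * se)
})

test_that("pedigree validation catches cycles and sex inconsistencies", {
  cfg <- sim_config(seed = 1)
  fr <- simulate_frequencies(cfg)
  cyc <- tibble::tibble(id = c("A", "B"), sire = c("B", "A"),
                        dam = c(NA, NA), sex = "MALE", population = "wolf")
  expect_error(simulate_individuals(fr, cyc, cfg), "cycle")
  bad <- tibble::tibble(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                        dam = c(NA, NA, "B"),
                        sex = c("FEMALE", "MALE", "MALE"),
                        population = "wolf")
  expect_error(simulate_individuals(fr, bad, cfg), "sire|dam")
})

test_that("zero error rates reproduce truth; full missingness erases it", {
  cfg0 <- sim_config(seed = 51, quality_dispersion = Inf,
                     contamination_rate = 0,
                     error_model = tibble::tibble(
                       material = "tissue", missing_rate = 0,
                       dropout_rate = 0, false_allele_rate = 0))
  mk <- simulate_markers(cfg0)
  fr <- simulate_frequencies(cfg0, mk)
  ped <- tibble::tibble(id = paste0("i", 1:5), sire = NA_character_,
                        dam = NA_character_,
                        sex = rep_len(c("MALE", "FEMALE"), 5),
                        population = "wolf")
  sim <- simulate_individuals(fr, ped, cfg0, mk)
  plan <- tibble::tibble(individual_id = ped$id, material = "tissue")
  obs <- corrupt_samples(sim, plan, cfg0, mk)
  expect_identical(unname(call_matrix(obs$genotypes)),
                   unname(call_matrix(sim$genotypes)))
  cfg1 <- sim_config(seed = 51, quality_dispersion = Inf,
                     contamination_rate = 0,
                     error_model = tibble::tibble(
                       material = "tissue", missing_rate = 1,
                       dropout_rate = 0, false_allele_rate = 0))
  obs1 <- corrupt_samples(sim, plan, cfg1, mk)
  expect_true(all(is.na(call_matrix(obs1$genotypes))))
  amp <- amplification_success(obs1$genotypes)
  expect_true(all(!pass_filter(amp$by_sample, obs1$samples)$per_sample$pass))
})

test_that("allelic dropout converts the expected fraction of heterozygotes", {
  d <- 0.1
  cfg <- sim_config(seed = 61, quality_dispersion = Inf,
                    contamination_rate = 0, maf_range = c(0.5, 0.5),
                    n_high_maf = 100, n_wolf_jackal = 0, n_wolf_dog = 0,
                    n_x = 0, n_y = 0,
                    populations = tibble::tibble(name = "wolf", fst = 0,
                                                 n = 200L),
                    error_model = tibble::tibble(
                      material = "scat", missing_rate = 0,
                      dropout_rate = d, false_allele_rate = 0))
  mk <- simulate_markers(cfg)
  fr <- simulate_frequencies(cfg, mk)
  ped <- tibble::tibble(id = sprintf("i%03d", 1:200), sire = NA_character_,
                        dam = NA_character_,
                        sex = rep_len(c("MALE", "FEMALE"), 200),
                        population = "wolf")
  sim <- simulate_individuals(fr, ped, cfg, mk)
  plan <- tibble::tibble(individual_id = ped$id, material = "scat",
                         n_replicates = 1L)
  obs <- corrupt_samples(sim, plan, cfg, mk)
  tru <- call_matrix(sim$genotypes)
  ob <- call_matrix(obs$genotypes)
  het <- tru == "A/G"
  n_het <- sum(het)
  dropped <- sum(ob[het] != "A/G")
  se <- sqrt(d * (1 - d) / n_het)
  expect_lt(abs(dropped / n_het - d), 3 * se)
})

test_that("urine contamination unions alleles and carries Y from either donor", {
  cfg <- sim_config(seed = 71, quality_dispersion = Inf,
                    contamination_rate = 1,
                    error_model = tibble::tibble(
                      material = "urine", missing_rate = 0,
                      dropout_rate = 0, false_allele_rate = 0))
  mk <- simulate_markers(cfg)
  fr <- simulate_frequencies(cfg, mk)
  ped <- tibble::tibble(id = c("F1", "M1"), sire = NA_character_,
                        dam = NA_character_, sex = c("FEMALE", "MALE"),
                        population = "wolf")
  sim <- simulate_individuals(fr, ped, cfg, mk)
  plan <- tibble::tibble(individual_id = "F1", material = "urine")
  obs <- corrupt_samples(sim, plan, cfg, mk)
  expect_equal(obs$truth$contaminant_id, "M1")
  y_ids <- mk$marker_id[mk$chrom_class == "Y"]
  expect_true(all(!is.na(call_matrix(obs$genotypes, y_ids))))
  # every observed allele at each autosomal locus comes from a donor
  cm <- call_matrix(obs$genotypes)
  tru <- call_matrix(sim$genotypes)
  for (m in mk$marker_id[mk$chrom_class == "AUTOSOME"][1:20]) {
    seen <- strsplit(cm[1, m], "/")[[1]]
    donors <- unique(unlist(strsplit(tru[, m], "/")))
    expect_true(all(seen %in% donors))
  }
})
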