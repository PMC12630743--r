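test_that("amplification success counts non-missing calls", {
  calls <- c(rep("A/A", 48), rep(NA, 48))
  g <- genotype_table("s1", matrix(calls, 1, 96,
                                   dimnames = list(NULL,
                                                   sprintf("m%02d", 1:96))))
  amp <- amplification_success(g)
  expect_equal(amp$by_sample$call_rate, 0.5)
  # a completely failed marker reports per-marker rate 0
  g2 <- make_geno(list(s1 = c("A/A", NA), s2 = c("A/G", NA)),
                  c("ok", "dead"))
  amp2 <- amplification_success(g2)
  expect_equal(amp2$by_marker$call_rate[amp2$by_marker$marker_id == "dead"], 0)
})

test_that("females are not penalised for missing Y calls", {
  mk <- marker_info(c("a1", "y1"), chrom = c("1", "Y"),
                    position = c(100, 100), allele_a = "A", allele_b = "G",
                    category = c("HIGH_MAF", "Y_SEX"))
  g <- make_geno(list(f1 = c("A/A", NA), m1 = c("A/A", "A/A")),
                 c("a1", "y1"))
  samples <- sample_record(c("f1", "m1"), known_sex = c("FEMALE", "MALE"))
  amp <- amplification_success(g, mk, samples)
  expect_equal(amp$by_sample$call_rate[amp$by_sample$sample_id == "f1"], 1)
  expect_equal(amp$by_sample$n_markers[amp$by_sample$sample_id == "f1"], 1)
})

test_that("simulated mean call rate tracks one minus the missing rate", {
  m <- 0.2
  cfg <- sim_config(seed = 67, quality_dispersion = Inf,
                    contamination_rate = 0,
                    populations = tibble::tibble(name = "wolf", fst = 0,
                                                 n = 100L),
                    error_model = tibble::tibble(
                      material = "scat", missing_rate = m,
                      dropout_rate = 0, false_allele_rate = 0))
  mk <- simulate_markers(cfg)
  fr <- simulate_frequencies(cfg, mk)
  ped <- tibble::tibble(id = sprintf("i%03d", 1:100), sire = NA_character_,
                        dam = NA_character_, sex = "FEMALE",
                        population = "wolf")
  sim <- simulate_individuals(fr, ped, cfg, mk)
  plan <- tibble::tibble(individual_id = ped$id, material = "scat",
                         n_replicates = 1L)
  obs <- corrupt_samples(sim, plan, cfg, mk)
  # females carry no Y call: exclude Y from the check
  auto_x <- mk$marker_id[mk$chrom_class != "Y"]
  cm <- call_matrix(obs$genotypes, auto_x)
  rate <- mean(!is.na(cm))
  se <- sqrt(m * (1 - m) / length(cm))
  expect_lt(abs(rate - (1 - m)), 3 * se)
})

test_that("duplicate consensus applies the agreement rules", {
  g <- make_geno(list(r1 = c("A/A", "A/A", "A/A", NA),
                      r2 = c("A/A", "A/G", NA, NA)),
                 c("agree", "clash", "half", "none"))
  samples <- sample_record(c("r1", "r2"), replicate_group = "grp")
  out <- duplicate_consensus(g, samples)
  cons <- call_matrix(out$consensus)
  expect_equal(cons["grp", "agree"], "A/A")
  expect_true(is.na(cons["grp", "clash"]))       # mismatch recoded missing
  expect_equal(cons["grp", "half"], "A/A")       # missing is not a mismatch
  expect_true(is.na(cons["grp", "none"]))
  expect_equal(out$mismatches$n_mismatch, 1L)
  # order invariance
  out2 <- duplicate_consensus(g[2:1, ], samples)
  expect_equal(out2$mismatches$n_mismatch, 1L)
  expect_equal(call_matrix(out2$consensus)["grp", "agree"], "A/A")
  # singleton group passes through
  g1 <- make_geno(list(solo = c("A/G", NA)), c("m1", "m2"))
  s1 <- sample_record("solo")
  out3 <- duplicate_consensus(g1, s1)
  expect_equal(call_matrix(out3$consensus)["solo", "m1"], "A/G")
  expect_equal(out3$mismatches$n_mismatch, 0L)
})

test_that("consensus never invents a call absent from all replicates", {
  set.seed(71)
  for (rep in 1:20) {
    calls <- matrix(sample(c("A/A", "A/G", "G/G", NA), 3 * 8, replace = TRUE),
                    3, 8, dimnames = list(NULL, paste0("m", 1:8)))
    g <- genotype_table(c("r1", "r2", "r3"), calls)
    samples <- sample_record(c("r1", "r2", "r3"), replicate_group = "g")
    cons <- call_matrix(duplicate_consensus(g, samples)$consensus)
    for (j in colnames(cons)) {
      if (!is.na(cons["g", j])) {
        expect_true(cons["g", j] %in% calls[, j])
      }
    }
  }
})

test_that("per-material pass counts reproduce the pooled percentage", {
  # 16/16 tissue, 166/188 scat, 49/74 urine, 2/4 hair -> 83% overall
  expect_equal(overall_pass_pct(c(16, 166, 49, 2), c(16, 188, 74, 4)), 83)
  # the same arithmetic via pass_filter on constructed call rates
  counts <- list(tissue = c(16, 16), scat = c(166, 188), urine = c(49, 74),
                 hair = c(2, 4))
  ids <- character(0); mats <- character(0); rates <- numeric(0)
  for (mat in names(counts)) {
    n_pass <- counts[[mat]][1]; n_tot <- counts[[mat]][2]
    id <- sprintf("%s_%03d", mat, seq_len(n_tot))
    ids <- c(ids, id); mats <- c(mats, rep(mat, n_tot))
    rates <- c(rates, rep(c(0.95, 0.5), c(n_pass, n_tot - n_pass)))
  }
  success <- tibble::tibble(sample_id = ids, n_called = NA, n_markers = NA,
                            call_rate = rates)
  samples <- sample_record(ids, material = mats)
  pf <- pass_filter(success, samples, qc_config(sample_pass_callrate = 0.8))
  smry <- pf$summary
  expect_equal(smry$pct_pass[smry$material == "overall"], 83)
  expect_equal(smry$pct_pass[smry$material == "scat"], 88)
  expect_equal(smry$pct_pass[smry$material == "urine"], 66)
  expect_equal(smry$n_pass[smry$material == "hair"], 2)
})

test_that("duplicate mismatch summary reproduces the season arithmetic", {
  mm <- tibble::tibble(
    replicate_group = sprintf("g%03d", 1:166),
    n_replicates = 2L,
    n_mismatch = c(rep(2L, 8), rep(0L, 158)),
    n_compared = 90L)
  s <- duplicate_error_summary(mm, n_markers = 96)
  expect_equal(s$pct_mismatching, 5)              # 8/166 rounds to 5%
  expect_equal(s$mean_mismatch, 16 / 166, tolerance = 1e-12)
  expect_equal(round(s$per_marker_error, 3), 0.001)
})

test_that("reference comparison counts and classifies discordances", {
  ids <- sprintf("s%02d", 1:15)
  mks <- sprintf("m%02d", 1:95)
  set.seed(5)
  ref_calls <- matrix(sample(c("A/A", "A/G", "G/G"), 15 * 95, replace = TRUE),
                      15, 95, dimnames = list(NULL, mks))
  ref <- genotype_table(ids, ref_calls)
  panel <- genotype_table(ids, ref_calls)
  res <- error_rate_vs_reference(panel, ref)
  expect_equal(res$n_comparisons, 1425)
  expect_equal(res$n_mismatches, 0)
  # plant one het->hom, one opposite-hom, one panel-missing
  pc <- ref_calls
  het <- which(pc == "A/G")[1]
  pc[het] <- "A/A"
  hom <- which(pc == "A/A" & seq_along(pc) != het)[1]
  pc[hom] <- "G/G"
  pc[which(!seq_along(pc) %in% c(het, hom))[1]] <- NA
  panel2 <- genotype_table(ids, pc)
  res2 <- error_rate_vs_reference(panel2, ref)
  expect_equal(res2$n_mismatches, 2)
  expect_equal(res2$n_panel_missing, 1)
  expect_equal(res2$n_comparisons, 1425)  # reference still complete
  expect_error(error_rate_vs_reference(
    genotype_table("s01", matrix("A/A", 1, 1,
                                 dimnames = list(NULL, "zzz"))), ref),
    "shared markers")
})

test_that("replicate mismatch counts track the binomial expectation", {
  d <- 0.05
  cfg <- sim_config(seed = 79, quality_dispersion = Inf,
                    contamination_rate = 0, maf_range = c(0.5, 0.5),
                    n_high_maf = 96, n_wolf_jackal = 0, n_wolf_dog = 0,
                    n_x = 0, n_y = 0,
                    populations = tibble::tibble(name = "wolf", fst = 0,
                                                 n = 150L),
                    error_model = tibble::tibble(
                      material = "scat", missing_rate = 0,
                      dropout_rate = d, false_allele_rate = 0))
  mk <- simulate_markers(cfg)
  fr <- simulate_frequencies(cfg, mk)
  ped <- tibble::tibble(id = sprintf("i%03d", 1:150), sire = NA_character_,
                        dam = NA_character_, sex = "FEMALE",
                        population = "wolf")
  sim <- simulate_individuals(fr, ped, cfg, mk)
  plan <- tibble::tibble(individual_id = ped$id, material = "scat",
                         n_replicates = 2L)
  obs <- corrupt_samples(sim, plan, cfg, mk)
  out <- duplicate_consensus(obs$genotypes, obs$samples)
  # a het locus mismatches when exactly one replicate drops out, or both
  # drop to opposite homozygotes: 2d(1-d) + d^2/2; het fraction is 1/2
  p_mm <- 0.5 * (2 * d * (1 - d) + d^2 / 2)
  expected <- 96 * p_mm
  got <- mean(out$mismatches$n_mismatch)
  se <- sqrt(96 * p_mm * (1 - p_mm) / 150)
  expect_lt(abs(got - expected), 4 * se)
})
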