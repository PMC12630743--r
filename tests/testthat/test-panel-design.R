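test_that("locus stats: counts, call rate, MAF on hand-built genotypes", {
  g <- make_geno(list(s1 = c("A/A", NA), s2 = c("A/G", NA),
                      s3 = c("G/G", NA)), c("m1", "m2"))
  st <- compute_locus_stats(g, simple_markers(c("m1", "m2")))
  m1 <- st[st$marker_id == "m1", ]
  expect_equal(m1$n_aa, 1); expect_equal(m1$n_ab, 1); expect_equal(m1$n_bb, 1)
  expect_equal(m1$maf, 0.5)
  expect_equal(m1$call_rate, 1)
  m2 <- st[st$marker_id == "m2", ]
  expect_equal(m2$call_rate, 0)
  expect_true(is.na(m2$maf))
  # monomorphic marker flagged with maf 0
  gm <- make_geno(list(s1 = "A/A", s2 = "A/A"), "m1")
  stm <- compute_locus_stats(gm, simple_markers("m1"))
  expect_equal(stm$maf, 0)
  expect_true(stm$monomorphic)
})

test_that("MAF estimate falls inside the binomial interval at known truth", {
  cfg <- sim_config(seed = 13, n_high_maf = 1, n_wolf_jackal = 0,
                    n_wolf_dog = 0, n_x = 0, n_y = 0,
                    maf_range = c(0.4, 0.4),
                    populations = tibble::tibble(name = "wolf", fst = 0,
                                                 n = 36L))
  ref <- simulate_reference_panel(cfg)
  st <- compute_locus_stats(ref$genotypes, ref$markers)
  ci <- qnorm(0.995) * sqrt(0.4 * 0.6 / (2 * 36))
  expect_lt(abs(st$maf - 0.4), ci)
})

test_that("HWE exact test: worked example and boundary cases", {
  # counts (2,0,2): support {0,2,4} with probabilities 6/70, 48/70, 16/70
  expect_equal(hwe_exact_test(2, 0, 2), 6 / 70, tolerance = 1e-12)
  expect_equal(hwe_exact_test(5, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 7, 0), hwe_enumeration_oracle(0, 7, 0),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "zero genotypes")
})

test_that("HWE exact test matches the enumeration oracle on a config sweep", {
  for (n in c(3, 5, 8)) {
    for (n_aa in 0:n) for (n_ab in 0:(n - n_aa)) {
      n_bb <- n - n_aa - n_ab
      expect_equal(hwe_exact_test(n_aa, n_ab, n_bb),
                   hwe_enumeration_oracle(n_aa, n_ab, n_bb),
                   tolerance = 1e-12,
                   label = sprintf("(%d,%d,%d)", n_aa, n_ab, n_bb))
    }
  }
})

test_that("dosage r2: perfect correlation, zero variance, independence", {
  expect_equal(ld_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(ld_r2(c(0, 1, 2, 1), c(2, 1, 0, 1)), 1)  # sign-free
  expect_true(is.nan(ld_r2(c(0, 1, 2), c(1, 1, 1))))
  set.seed(7)
  hits <- 0
  for (rep in 1:100) {
    a <- rbinom(300, 2, 0.4); b <- rbinom(300, 2, 0.4)
    if (ld_r2(a, b) < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 97)  # independent markers essentially never look linked
})

test_that("LD pruning keeps one of a duplicated pair and passes its own audit", {
  set.seed(3)
  n <- 60
  base <- matrix(sample(c("A/A", "A/G", "G/G"), n * 10, replace = TRUE),
                 n, 10)
  base[, 6] <- base[, 5]  # duplicated marker
  ids <- paste0("m", 1:10)
  colnames(base) <- ids
  g <- genotype_table(paste0("s", 1:n), base)
  mk <- simple_markers(ids)
  kept <- ld_prune(g, ids, selection_config(ld_window = 10, ld_step = 2),
                   mk)
  expect_equal(sum(c("m5", "m6") %in% kept), 1)
  # audit: no retained pair above the threshold in any window
  dos <- dosage_matrix(g[, c("sample_id", kept)], mk)
  for (i in seq_along(kept)) for (j in seq_len(i - 1)) {
    r2 <- ld_r2(dos[, i], dos[, j])
    expect_false(!is.nan(r2) && r2 > 0.2)
  }
})

test_that("independent markers survive pruning untouched", {
  set.seed(5)
  n <- 200
  m <- 30
  calls <- matrix(sample(c("A/A", "A/G", "G/G"), n * m, replace = TRUE,
                         prob = c(0.25, 0.5, 0.25)), n, m)
  ids <- sprintf("m%02d", 1:m)
  colnames(calls) <- ids
  g <- genotype_table(paste0("s", 1:n), calls)
  kept <- ld_prune(g, ids, selection_config(), simple_markers(ids))
  expect_equal(kept, ids)
})

test_that("Weir-Cockerham theta: fixed difference, null, label swap, oracle", {
  g <- make_geno(c(stats::setNames(as.list(rep("A/A", 5)), paste0("a", 1:5)),
                   stats::setNames(as.list(rep("G/G", 5)), paste0("b", 1:5))),
                 "m1")
  lab <- c(stats::setNames(rep("A", 5), paste0("a", 1:5)),
           stats::setNames(rep("B", 5), paste0("b", 1:5)))
  expect_equal(fst_locus(g, lab, "A", "B")$fst, 1)
  # identical frequencies, large n -> near zero
  set.seed(17)
  calls <- sample(c("A/A", "A/G", "G/G"), 1000, replace = TRUE,
                  prob = c(0.36, 0.48, 0.16))
  g2 <- genotype_table(paste0("s", 1:1000), matrix(calls, ncol = 1,
                                                   dimnames = list(NULL, "m1")))
  lab2 <- stats::setNames(rep(c("A", "B"), each = 500), paste0("s", 1:1000))
  th <- fst_locus(g2, lab2, "A", "B")$fst
  expect_lt(abs(th), 0.02)
  # allele-label swap invariance: swap A<->G in every call
  swapped <- chartr("AG", "GA", calls)
  swapped <- vapply(strsplit(swapped, "/"), function(p)
    paste(sort(p), collapse = "/"), "")
  g3 <- genotype_table(paste0("s", 1:1000),
                       matrix(swapped, ncol = 1,
                              dimnames = list(NULL, "m1")))
  expect_equal(fst_locus(g3, lab2, "A", "B")$fst, th, tolerance = 1e-12)
})

test_that("theta agrees with a direct per-allele transcription of the formulas", {
  set.seed(23)
  for (rep in 1:20) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    p1 <- runif(1, 0.1, 0.9); p2 <- runif(1, 0.1, 0.9)
    d1 <- rbinom(n1, 2, p1); d2 <- rbinom(n2, 2, p2)
    if (sum(c(d1, d2)) %in% c(0, 2 * (n1 + n2))) next
    expect_equal(snpmon:::wc_theta(d1, d2), wc_theta_oracle(d1, d2),
                 tolerance = 1e-12)
  }
})

test_that("selection cascade finds planted diagnostics and reports attrition", {
  set.seed(29)
  n <- 40
  lab <- stats::setNames(rep(c("wolf", "jackal"), each = n / 2),
                         paste0("s", 1:n))
  m_ids <- c(sprintf("hm%02d", 1:10), sprintf("dg%02d", 1:5), "bad1", "bad2")
  calls <- matrix(NA_character_, n, length(m_ids),
                  dimnames = list(NULL, m_ids))
  for (j in 1:10) {
    calls[, j] <- sample(c("A/A", "A/G", "G/G"), n, replace = TRUE,
                         prob = c(0.36, 0.48, 0.16))
  }
  for (j in 11:15) calls[, j] <- rep(c("A/A", "G/G"), each = n / 2)
  calls[, "bad1"] <- NA  # never amplifies
  calls[, "bad2"] <- c(rep("A/A", 17), rep("A/G", 3), rep(NA, 20))  # low rate
  g <- genotype_table(names(lab), calls)
  mk <- marker_info(m_ids, chrom = "1", position = seq_along(m_ids) * 100,
                    allele_a = "A", allele_b = "G",
                    category = c(rep("HIGH_MAF", 10),
                                 rep("WOLF_JACKAL_DIAG", 5),
                                 rep("HIGH_MAF", 2)))
  sel <- select_panel(g, mk, labels = lab,
                      config = selection_config(sample_callrate_min = 0))
  expect_setequal(
    sel$panel$marker_id[sel$panel$category == "WOLF_JACKAL_DIAG"],
    sprintf("dg%02d", 1:5))
  att <- sel$attrition
  expect_equal(att$HIGH_MAF[att$reason == "No amplification"], 1)
  expect_equal(att$HIGH_MAF[att$reason == "Low amplification"], 1)
  expect_false("bad1" %in% sel$panel$marker_id)
})

test_that("a marker can be rejected for more than one reason", {
  # monomorphic (low MAF) and rejected by the NTC screen simultaneously
  n <- 30
  calls <- matrix("A/A", n + 1, 1, dimnames = list(NULL, "m1"))
  ids <- c(paste0("s", 1:n), "NTC_1")
  g <- genotype_table(ids, calls)
  samples <- sample_record(ids, is_control = c(rep(NA, n), "NEGATIVE"))
  mk <- simple_markers("m1")
  sel <- select_panel(g, mk, samples = samples,
                      config = selection_config(sample_callrate_min = 0))
  expect_setequal(sel$rejected$reason[sel$rejected$marker_id == "m1"],
                  c("NTC up", "Low MAF"))
  att <- sel$attrition
  expect_equal(att$HIGH_MAF[att$reason == "NTC up"], 1)
  expect_equal(att$HIGH_MAF[att$reason == "Low MAF"], 1)
})

test_that("empty input yields an empty panel and an all-zero attrition table", {
  g <- genotype_table(character(0),
                      matrix(NA_character_, 0, 1,
                             dimnames = list(NULL, "m1")))
  sel <- select_panel(g[0, 0:1], simple_markers("m1")[0, ])
  expect_equal(nrow(sel$panel), 0)
  expect_true(all(sel$attrition[, -1] == 0))
})

test_that("panel selection is deterministic under a fixed seed", {
  set.seed(37)
  n <- 30
  m <- 20
  calls <- matrix(sample(c("A/A", "A/G", "G/G"), n * m, replace = TRUE,
                         prob = c(0.3, 0.5, 0.2)), n, m,
                  dimnames = list(NULL, sprintf("m%02d", 1:m)))
  g <- genotype_table(paste0("s", 1:n), calls)
  mk <- simple_markers(sprintf("m%02d", 1:m))
  cfg <- selection_config(seed = 4, sample_callrate_min = 0, maf_min = 0.2)
  s1 <- select_panel(g, mk, config = cfg, n_select = c(HIGH_MAF = 5))
  s2 <- select_panel(g, mk, config = cfg, n_select = c(HIGH_MAF = 5))
  expect_identical(s1$panel, s2$panel)
  expect_equal(nrow(s1$panel), 5)
})

test_that("type-I error of the exact test stays at or below nominal", {
  set.seed(43)
  n <- 100; p <- 0.3; reps <- 500
  rej <- 0
  for (r in seq_len(reps)) {
    g <- rbinom(n, 2, p)
    if (hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2)) < 0.05) {
      rej <- rej + 1
    }
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(rej / reps, 0.05 + 3 * se)
})
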