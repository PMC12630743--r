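# Shared fixtures and independent oracles used across the suite.

# Build a genotype table from a list of call-string vectors.
make_geno <- function(calls_by_sample, marker_names = NULL) {
  m <- do.call(rbind, calls_by_sample)
  if (!is.null(marker_names)) colnames(m) <- marker_names
  genotype_table(names(calls_by_sample), m)
}

simple_markers <- function(ids, chrom = "1", category = "HIGH_MAF",
                           allele_a = "A", allele_b = "G") {
  marker_info(ids, chrom = rep_len(chrom, length(ids)),
              position = seq_along(ids) * 1000,
              allele_a = allele_a, allele_b = allele_b, category = category)
}

# Independent HWE oracle: enumerate every genotype configuration with the
# observed allele totals, weight each by its conditional multinomial
# probability (no shared code with hwe_exact_test's log-space scan).
hwe_enumeration_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  configs <- list()
  for (het in 0:n) {
    aa2 <- n_a - het
    if (aa2 < 0 || aa2 %% 2 != 0) next
    aa <- aa2 / 2
    bb <- n - aa - het
    if (bb < 0) next
    w <- choose(n, aa) * choose(n - aa, het) * 2^het
    configs[[length(configs) + 1]] <- c(het = het, w = w)
  }
  tab <- do.call(rbind, configs)
  probs <- tab[, "w"] / sum(tab[, "w"])
  obs <- probs[tab[, "het"] == n_ab]
  sum(probs[probs <= obs + 1e-12])
}

# Direct per-allele transcription of the Weir & Cockerham (1984) theta
# estimator, summing components over both alleles of the locus.
wc_theta_oracle <- function(dos_1, dos_2) {
  d <- list(dos_1[!is.na(dos_1)], dos_2[!is.na(dos_2)])
  n_i <- lengths(d)
  r <- 2
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  num <- 0; den <- 0
  for (allele in c("b", "a")) {
    p_i <- vapply(d, function(x) {
      p <- mean(x) / 2
      if (allele == "b") p else 1 - p
    }, 0)
    h_i <- vapply(d, function(x) mean(x == 1), 0)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Brute-force PID oracle: sum over the genotype distribution of P(g)^2.
pid_bruteforce <- function(p) {
  k <- length(p)
  total <- 0
  for (i in 1:k) for (j in i:k) {
    pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    total <- total + pg^2
  }
  total
}

# Sib-pair PID oracle: enumerate ordered parental genotype pairs under HWE,
# the offspring genotype distribution for each, and the probability two
# independent offspring of the same pair share a genotype.
pid_sib_bruteforce <- function(p) {
  k <- length(p)
  genos <- list()
  for (i in 1:k) for (j in i:k) genos[[length(genos) + 1]] <- c(i, j)
  g_prob <- vapply(genos, function(g) {
    if (g[1] == g[2]) p[g[1]]^2 else 2 * p[g[1]] * p[g[2]]
  }, 0)
  off_dist <- function(g1, g2) {
    out <- stats::setNames(rep(0, length(genos)),
                           vapply(genos, paste, "", collapse = "/"))
    for (a in g1) for (b in g2) {
      key <- paste(sort(c(a, b)), collapse = "/")
      out[key] <- out[key] + 0.25
    }
    out
  }
  total <- 0
  for (i in seq_along(genos)) for (j in seq_along(genos)) {
    d <- off_dist(genos[[i]], genos[[j]])
    total <- total + g_prob[i] * g_prob[j] * sum(d^2)
  }
  total
}

# Gene-dropping estimate of an individual's inbreeding coefficient:
# drop unique founder alleles down the pedigree and count autozygosity.
gene_drop_f <- function(pedigree, target, n_drops = 20000) {
  ped <- tibble::as_tibble(pedigree)
  ord <- order(match(ped$id, ped$id))  # assume parents listed before children
  hits <- 0
  for (rep in seq_len(n_drops)) {
    al <- list()
    for (i in seq_len(nrow(ped))) {
      id <- ped$id[i]
      if (is.na(ped$sire[i]) || is.na(ped$dam[i])) {
        al[[id]] <- c(paste0(id, "_1"), paste0(id, "_2"))
      } else {
        al[[id]] <- c(sample(al[[ped$sire[i]]], 1),
                      sample(al[[ped$dam[i]]], 1))
      }
    }
    if (al[[target]][1] == al[[target]][2]) hits <- hits + 1
  }
  hits / n_drops
}

# Three-generation pedigree: 20 founders, 10 second-generation offspring,
# 10 third-generation offspring.
three_gen_pedigree <- function() {
  founders <- tibble::tibble(
    id = c(sprintf("M%02d", 1:10), sprintf("F%02d", 1:10)),
    sire = NA_character_, dam = NA_character_,
    sex = rep(c("MALE", "FEMALE"), each = 10),
    population = "wolf")
  gen2 <- tibble::tibble(
    id = sprintf("K2_%02d", 1:10),
    sire = sprintf("M%02d", 1:10), dam = sprintf("F%02d", 1:10),
    sex = rep_len(c("MALE", "FEMALE"), 10),
    population = "wolf")
  gen3 <- tibble::tibble(
    id = sprintf("K3_%02d", 1:10),
    sire = rep(gen2$id[gen2$sex == "MALE"][1:5], each = 2),
    dam = rep(gen2$id[gen2$sex == "FEMALE"][1:5], each = 2),
    sex = rep_len(c("MALE", "FEMALE"), 10),
    population = "wolf")
  dplyr::bind_rows(founders, gen2, gen3)
}

# Within-line pedigree built on a grandfather x granddaughter pairing with
# continued line matings over the following generations.
inbred_line_pedigree <- function() {
  tibble::tibble(
    id   = c("GF", "GM", "S2", "U1", "U3",
             "D1", "GD", "G2a", "G2b", "G3a", "G3b", "K4", "K5"),
    sire = c(NA, NA, NA, NA, NA,
             "GF", "S2", "GF", "GF", "G2a", "U3", "G3a", "K4"),
    dam  = c(NA, NA, NA, NA, NA,
             "GM", "D1", "GD", "GD", "U1", "G2b", "G3b", "G2b"),
    sex  = c("MALE", "FEMALE", "MALE", "FEMALE", "MALE",
             "FEMALE", "FEMALE", "MALE", "FEMALE", "MALE", "FEMALE",
             "MALE", "MALE"),
    population = "wolf")
}

# Small reference panel shared by assignment/sexing tests (cached per run).
cached_ref_panel <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) {
      cache <<- simulate_reference_panel(sim_config(seed = seed))
    }
    cache
  }
})

wolf_dog_groups <- function(ref) {
  tibble::tibble(
    sample_id = ref$samples$sample_id,
    group = ifelse(ref$samples$known_species %in% c("wolf", "dog"),
                   "wolf_dog", "other_canid"))
}

wolf_x_freqs <- function(ref) {
  xm <- ref$markers$marker_id[ref$markers$chrom_class == "X"]
  ref$freqs[ref$freqs$population == "wolf" & ref$freqs$marker_id %in% xm,
            c("marker_id", "p")]
}
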