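small_cfg <- function(...) {
  sim_config(n_founders = 12, n_generations = 4, offspring_per_mating = 3,
             n_markers = 120, n_chromosomes = 2, chromosome_length_bp = 1e7,
             risk_allele_freq = 0.05, risk_locus_pos = 3e6,
             freq_tolerance = 1, seed = 3, ...)
}

test_that("the simulator is reproducible and rejects impossible configurations", {
  cfg <- small_cfg()
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$genotypes$h1, p2$genotypes$h1)
  expect_identical(p1$risk_dosage, p2$risk_dosage)
  expect_identical(p1$trait, p2$trait)
  expect_error(sim_config(risk_allele_freq = 0), "carrier matings")
  expect_error(sim_config(risk_locus_pos = 1e12), "risk_locus_pos")
})

test_that("complete perinatal lethality keeps homozygotes out of the breeding pool", {
  pop <- shared_sim_pop()
  ped <- pop$pedigree
  parents <- unique(na.omit(c(ped$sire, ped$dam)))
  expect_true(all(pop$risk_dosage[parents] < 2))
  homs <- names(pop$risk_dosage)[pop$risk_dosage == 2]
  expect_true(all(pop$survival[homs] == "0-2"))
  expect_true(all(is.na(pop$trait[homs])))
  expect_true(all(!is.na(pop$trait[pop$survival == "survived"])))
})

test_that("every offspring haplotype is allele-wise derivable from one parent", {
  pop <- simulate_population(small_cfg())
  ped <- pop$pedigree
  g <- pop$genotypes
  idx <- seq_along(g$ids); names(idx) <- g$ids
  kids <- ped$id[!is.na(ped$sire)]
  for (k in sample(kids, 40)) {
    i <- idx[[k]]; s <- idx[[ped$sire[ped$id == k]]]; d <- idx[[ped$dam[ped$id == k]]]
    expect_true(all(g$h1[i, ] == g$h1[s, ] | g$h1[i, ] == g$h2[s, ]))
    expect_true(all(g$h2[i, ] == g$h1[d, ] | g$h2[i, ] == g$h2[d, ]))
  }
})

test_that("founder marker and risk allele frequencies follow their sampling models", {
  cfg <- sim_config(n_founders = 400, n_generations = 1,
                    offspring_per_mating = 4, n_markers = 300,
                    n_chromosomes = 1, chromosome_length_bp = 1.5e7,
                    risk_allele_freq = 0.10, risk_seeding = "hw_carriers",
                    freq_tolerance = 1, seed = 21)
  pop <- simulate_population(cfg)
  founders <- pop$pedigree$id[pop$pedigree$generation == 0]
  # risk allele: binomial draw over 2 * 400 founder chromosomes
  f_realised <- mean(pop$risk_dosage[founders]) / 2
  se <- sqrt(0.10 * 0.90 / (2 * 400))
  expect_lt(abs(f_realised - 0.10), 3 * se)
  # markers: offspring allele frequencies track founder frequencies closely
  # at this population size (law of large numbers under Mendelian sampling)
  offspring <- pop$pedigree$id[pop$pedigree$generation == 1]
  fr_f <- colMeans(dosage_matrix(subset_genotypes(pop$genotypes,
                                                  individuals = founders))) / 2
  fr_o <- colMeans(dosage_matrix(subset_genotypes(pop$genotypes,
                                                  individuals = offspring))) / 2
  expect_gt(stats::cor(fr_f, fr_o), 0.95)
  expect_lt(max(abs(fr_f - fr_o)), 0.12)
})

test_that("single-founder seeding resamples until the target frequency band is hit", {
  cfg <- sim_config(n_founders = 16, n_generations = 5,
                    offspring_per_mating = 4, n_markers = 60,
                    n_chromosomes = 1, chromosome_length_bp = 1e7,
                    risk_allele_freq = 0.04, seed = 5)
  pop <- simulate_population(cfg)
  expect_lte(abs(pop$realized_freq - 0.04) / 0.04, cfg$freq_tolerance)
  expect_gte(pop$attempts, 1)
  expect_equal(pop$seed_used, cfg$seed + pop$attempts - 1L)
})

test_that("simulated mating outcomes follow the conditional-genotype model", {
  # null effect: every mating type shares the baseline death rate
  tab0 <- simulate_matings(fA = 0.1, penetrance = 0, mu_baseline = 0.05,
                           n_matings = 4e4, seed = 2)
  rates <- tab0$deaths / tab0$n
  se <- sqrt(0.05 * 0.95 / 4e4)
  expect_true(all(abs(rates - 0.05) < 4 * se))
  # closed form: fA = 0.5, penetrance 1, mu 0 gives a 1x1 death rate of 1/6
  tab1 <- simulate_matings(fA = 0.5, penetrance = 1, mu_baseline = 0,
                           n_matings = 2e5, seed = 3)
  r11 <- with(tab1, deaths[mating_type == "1x1"] / n[mating_type == "1x1"])
  expect_lt(abs(r11 - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / 2e5))
  # degenerate request
  expect_equal(nrow(simulate_matings(0.1, 1, 0.05, 0)), 0L)
})

test_that("simulated 1x1 excess mortality converges to the closed-form expectation", {
  fA <- 0.10; mu <- 0.05
  tab <- simulate_matings(fA, penetrance = 1, mu_baseline = mu,
                          n_matings = 2e5, seed = 9)
  r <- with(tab, deaths / n)
  names(r) <- tab$mating_type
  excess <- r[["1x1"]] - r[["0x0"]]
  expected <- expected_increase(fA, mu)
  mc_se <- sqrt(2 * 0.15 * 0.85 / 2e5)
  expect_lt(abs(excess - expected), 3 * mc_se)
})

test_that("accepted replicates honour the shared-haplotype length contract", {
  pop <- shared_sim_pop()
  cfg <- pop$config
  hom <- names(pop$risk_dosage)[pop$risk_dosage == 2]
  expect_gt(length(hom), 0)
  # recompute the shared homozygous run around the locus independently
  g <- pop$genotypes
  ci <- which(g$map$chrom == as.character(cfg$risk_locus_chrom))
  s1 <- g$h1[match(hom, g$ids), ci, drop = FALSE]
  s2 <- g$h2[match(hom, g$ids), ci, drop = FALSE]
  ok <- apply(s1 == s2, 2, all) & apply(s1, 2, function(v) all(v == v[1]))
  a <- which.min(abs(g$map$pos[ci] - cfg$risk_locus_pos))
  expect_true(ok[a])
  lo <- a; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- a; while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
  expect_gte(g$map$pos[ci][hi] - g$map$pos[ci][lo], cfg$min_shared_ibd_bp)
})
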