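test_that("the exact 2x2 test matches enumeration oracles and fisher.test", {
  # hand enumeration: margins (3,3), column 3 -> probs .05/.45/.45/.05
  expect_equal(fisher_exact_2x2(2, 1, 1, 2), 1.0)
  expect_equal(fisher_exact_2x2(0, 7, 0, 3), 1.0)   # degenerate column
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252)
  expect_message(expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1), "convention")
  set.seed(5)
  for (i in 1:60) {
    t <- as.integer(rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    p <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    expect_equal(p, oracle_fisher(t[1], t[2], t[3], t[4]), tolerance = 1e-10)
    expect_equal(p, fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-8)
  }
})

test_that("the exact test is transpose-invariant and monotone toward the extreme", {
  set.seed(8)
  for (i in 1:25) {
    t <- as.integer(rmultinom(1, 30, rep(0.25, 4)))
    expect_equal(fisher_exact_2x2(t[1], t[2], t[3], t[4]),
                 fisher_exact_2x2(t[4], t[3], t[2], t[1]))
  }
  # fixed margins (10, 10), column 10: p decreases as a moves to the corner
  ps <- vapply(5:10, function(a)
    fisher_exact_2x2(a, 10 - a, 10 - a, a), numeric(1))
  expect_true(all(diff(ps) < 0))
  # p is never below the point mass at the observed table
  for (a in 0:10)
    expect_gte(fisher_exact_2x2(a, 10 - a, 10 - a, a),
               dhyper(a, 10, 10, 10))
})

test_that("the Bonferroni threshold transforms alpha and test count correctly", {
  expect_equal(bonferroni_threshold(0.05, 1), -log10(0.05))
  expect_equal(bonferroni_threshold(1, 1), 0)
  expect_equal(bonferroni_threshold(0.05, 100), -log10(5e-4))
})

test_that("a monomorphic-haplotype cohort yields one degenerate test per window", {
  # everyone homozygous for the same haplotype: table [[nc,0],[nk,0]], p = 1.
  # The markers are necessarily monomorphic, so maf_floor = -1 keeps them
  # (the documented rule drops markers with MAF <= floor).
  m <- 30
  h <- matrix(rep(c(0L, 1L), length.out = m), 12, m, byrow = TRUE)
  g <- phased_genotypes(h, h, data.frame(chrom = 1, pos = seq_len(m) * 1000))
  sc <- hap_scan(g, cases = g$ids[1:4], controls = g$ids[5:12],
                 window_size = 10, maf_floor = -1)
  expect_equal(nrow(sc), m - 10 + 1)
  expect_true(all(sc$a == 4 & sc$c == 8 & sc$p_value == 1))
})

test_that("the scan localises a simulated lethal locus and carrier prediction matches truth", {
  pop <- shared_sim_pop()
  cfg <- pop$config
  cc <- sim_case_control(pop)
  expect_gte(length(cc$cases), 2)
  sc <- hap_scan(pop$genotypes, cc$cases, cc$controls)
  top <- sc[which.min(sc$p_value), ]
  expect_equal(top$chrom, as.character(cfg$risk_locus_chrom))
  expect_lte(top$start_pos, cfg$risk_locus_pos + 1.5e6)
  expect_gte(top$end_pos, cfg$risk_locus_pos - 1.5e6)
  mr <- extract_interval(sc)
  expect_equal(mr$chrom, as.character(cfg$risk_locus_chrom))
  expect_lte(mr$interval_start, cfg$risk_locus_pos)
  expect_gte(mr$interval_end, cfg$risk_locus_pos)
  expect_gt(mr$interval_end - mr$interval_start, mr$run_end_pos - mr$run_start_pos)
  status <- predict_status(pop$genotypes, mr)
  expect_gte(mean(status == pop$risk_dosage), 0.99)
})

test_that("interval extraction is invariant to window enumeration order", {
  pop <- shared_sim_pop()
  cc <- sim_case_control(pop)
  sc <- hap_scan(pop$genotypes, cc$cases, cc$controls)
  perm <- sample(nrow(sc))
  sc2 <- sc[perm, ]
  for (at in c("map", "window_size", "n_cases", "n_controls", "n_tests"))
    attr(sc2, at) <- attr(sc, at)
  class(sc2) <- class(sc)
  mr1 <- extract_interval(sc)
  mr2 <- extract_interval(sc2)
  expect_equal(mr1$interval_start, mr2$interval_start)
  expect_equal(mr1$interval_end, mr2$interval_end)
  expect_equal(mr1$risk_haplotype, mr2$risk_haplotype)
})

test_that("a qualifying run at the chromosome edge truncates the interval there", {
  # 12 markers; cases homozygous for a shared haplotype on markers 1-6 only
  m <- 12
  set.seed(3)
  base <- matrix(rbinom(20 * m, 1, 0.5), 20, m)
  h1 <- base; h2 <- matrix(rbinom(20 * m, 1, 0.5), 20, m)
  shared <- rep(c(1L, 0L), 3)
  h1[1:4, 1:6] <- matrix(shared, 4, 6, byrow = TRUE)
  h2[1:4, 1:6] <- matrix(shared, 4, 6, byrow = TRUE)
  h2[1:4, 7:12] <- 1L - h1[1:4, 7:12]   # heterozygous beyond the run
  g <- phased_genotypes(h1, h2, data.frame(chrom = 1, pos = seq_len(m) * 1e5))
  sc <- hap_scan(g, cases = g$ids[1:4], controls = g$ids[5:20],
                 window_size = 4, maf_floor = 0)
  mr <- suppressMessages(extract_interval(sc))
  expect_equal(mr$run_start_pos, 1e5)
  expect_equal(mr$interval_start, 1e5)     # truncated at the chromosome start
  expect_equal(mr$interval_end, 7e5)       # first marker beyond the run
})

test_that("carrier dosage is the count of haplotypes matching the risk haplotype", {
  h1 <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 0, 0))
  h2 <- rbind(c(1, 0, 1), c(0, 1, 1), c(0, 1, 0))
  g <- phased_genotypes(h1, h2, data.frame(chrom = 1, pos = c(10, 20, 30)))
  mapping <- list(marker_index = 1:3, risk_haplotype = c(1L, 0L, 1L),
                  map = g$map)
  expect_equal(unname(predict_status(g, mapping)), c(2L, 1L, 0L))
})
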