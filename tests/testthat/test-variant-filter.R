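# synthetic variant table with a fully known truth assignment
make_variant_table <- function(n = 100, seed = 20) {
  set.seed(seed)
  data.frame(
    chrom = sample(c("28", "5"), n, replace = TRUE, prob = c(0.8, 0.2)),
    pos = sample(1e6:6e6, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("AA", "C", "G", "T"), n, replace = TRUE),
    type = sample(c("SNP", "InDel", "SV"), n, replace = TRUE),
    case1 = sample(c("hom_alt", "het", "hom_ref", "missing"), n,
                   replace = TRUE, prob = c(0.6, 0.2, 0.15, 0.05)),
    case2 = sample(c("hom_alt", "het", "hom_ref"), n, replace = TRUE,
                   prob = c(0.7, 0.2, 0.1)),
    present_in_breed_controls = sample(c(TRUE, FALSE), n, replace = TRUE),
    present_in_other_breeds = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

test_that("staged filtering equals brute-force set arithmetic", {
  v <- make_variant_table()
  interval <- list("28", 2e6, 5e6)
  tr <- suppressMessages(filter_candidates(v, interval, c("case1", "case2")))
  # independent oracle: plain logical indexing in one shot
  in_int <- v$chrom == "28" & v$pos >= 2e6 & v$pos <= 5e6
  hom <- v$case1 == "hom_alt" & v$case2 == "hom_alt"
  no_breed <- !v$present_in_breed_controls
  no_panel <- !v$present_in_other_breeds
  expect_equal(tr$n_input, nrow(v))
  expect_equal(tr$n_in_interval, sum(in_int))
  expect_equal(tr$n_hom_all_cases, sum(in_int & hom))
  expect_equal(tr$n_after_breed_controls, sum(in_int & hom & no_breed))
  expect_equal(tr$n_after_all_controls, sum(in_int & hom & no_breed & no_panel))
  keys <- with(v[in_int & hom & no_breed & no_panel, ],
               paste0(chrom, ":", pos, "_", ref, ">", alt))
  expect_setequal(tr$survivor_keys, keys)
  # counts form a monotone chain
  chain <- c(tr$n_input, tr$n_in_interval, tr$n_hom_all_cases,
             tr$n_after_breed_controls, tr$n_after_all_controls)
  expect_true(all(diff(chain) <= 0))
})

test_that("filtering is idempotent and row-order invariant", {
  v <- make_variant_table(seed = 21)
  interval <- list("28", 1.5e6, 5.5e6)
  tr1 <- suppressMessages(filter_candidates(v, interval, c("case1", "case2")))
  tr2 <- suppressMessages(
    filter_candidates(tr1$survivors, interval, c("case1", "case2")))
  expect_setequal(tr2$survivor_keys, tr1$survivor_keys)
  expect_equal(tr2$n_input, tr2$n_after_all_controls)
  shuffled <- v[sample(nrow(v)), ]
  tr3 <- suppressMessages(filter_candidates(shuffled, interval, c("case1", "case2")))
  expect_setequal(tr3$survivor_keys, tr1$survivor_keys)
})

test_that("interval and missing-genotype rules are enforced", {
  v <- data.frame(chrom = c("28", "28", "1"), pos = c(3e6, 4e6, 3e6),
                  ref = "A", alt = "T", type = "SNP",
                  case1 = c("hom_alt", "missing", "hom_alt"),
                  case2 = "hom_alt",
                  present_in_breed_controls = FALSE,
                  present_in_other_breeds = FALSE, stringsAsFactors = FALSE)
  tr <- suppressMessages(filter_candidates(v, list("28", 1, 5e6), c("case1", "case2")))
  expect_equal(tr$n_in_interval, 2)       # chrom-1 variant excluded at stage (i)
  expect_equal(tr$n_hom_all_cases, 1)     # missing case genotype fails stage (ii)
  expect_equal(tr$survivor_keys, "28:3000000_A>T")
  empty <- filter_candidates(v[0, ], list("28", 1, 5e6), c("case1", "case2"))
  expect_equal(empty$n_input, 0)
  expect_equal(empty$n_after_all_controls, 0)
})

test_that("the supplementary-dialect reader normalises presence flags", {
  v <- make_variant_table(seed = 22)
  names(v)[names(v) == "present_in_breed_controls"] <- "Present_in_39_Aubrac_controls"
  names(v)[names(v) == "present_in_other_breeds"] <- "Present_in_1828_controls_from_other_breeds"
  v$Present_in_39_Aubrac_controls <-
    ifelse(v$Present_in_39_Aubrac_controls, "yes", "no")
  path <- tempfile(fileext = ".tsv")
  write.table(v, path, sep = "\t", row.names = FALSE, quote = FALSE)
  r <- read_variant_table(path,
                          breed_flag = "Present_in_39_Aubrac_controls",
                          panel_flag = "Present_in_1828_controls_from_other_breeds")
  expect_type(r$present_in_breed_controls, "logical")
  expect_equal(sum(r$present_in_breed_controls),
               sum(v$Present_in_39_Aubrac_controls == "yes"))
})

test_that("SV consensus requires two tools and 70% reciprocal overlap", {
  base <- data.frame(individual = "calf1", chrom = "28", type = "DEL",
                     stringsAsFactors = FALSE)
  two_same <- rbind(cbind(base, tool = "pindel", start = 100, end = 200),
                    cbind(base, tool = "delly", start = 100, end = 200))
  expect_equal(nrow(sv_concordance(two_same)), 2)
  expect_equal(unique(sv_concordance(two_same)$cluster), 1)
  # overlap 51 bp of 101/111 bp intervals: 51/101 < 0.70 -> dropped
  partial <- rbind(cbind(base, tool = "pindel", start = 100, end = 200),
                   cbind(base, tool = "delly", start = 150, end = 260))
  expect_equal(nrow(sv_concordance(partial)), 0)
  single <- cbind(base, tool = "lumpy", start = 5, end = 100)
  expect_equal(nrow(sv_concordance(single)), 0)
  # same tool twice does not count as support
  dup <- rbind(cbind(base, tool = "pindel", start = 100, end = 200),
               cbind(base, tool = "pindel", start = 100, end = 200))
  expect_equal(nrow(sv_concordance(dup)), 0)
  bad <- cbind(base, tool = "pindel", start = 10, end = 9)
  expect_error(sv_concordance(bad), "zero-length")
})
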