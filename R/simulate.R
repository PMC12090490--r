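#' Simulate a pedigreed population segregating a recessive lethal haplotype
#'
#' Forward-in-time gene-dropping simulator with discrete generations,
#' monogamous dams, sires drawn with replacement from surviving males,
#' Poisson-recombination meioses and a biallelic risk locus whose homozygotes
#' die according to per-period penetrances. Produces everything the downstream
#' analyses consume: a pedigree, phased marker genotypes, true risk dosages,
#' survival outcomes and a polygenic quantitative trait with an additive
#' heterozygote effect.
#'
#' Under the default `"single_founder"` seeding the risk allele starts on one
#' founder chromosome and drifts; the whole simulation is resampled with an
#' incremented seed until the realised final-generation frequency lands within
#' `freq_tolerance` of the target (attempts are recorded in the result). The
#' drift phase is replayed cheaply, so resampling costs little.
#'
#' A replicate is likewise resampled when its affected homozygotes do not
#' share a homozygous marker haplotype of at least `min_shared_ibd_bp` around
#' the risk locus: the simulator's contract is a megabase-scale
#' identical-by-descent lethal haplotype, and deep pedigrees occasionally
#' recombine the shared segment below that scale.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_population`: list with `pedigree`
#'   (a [as_pedigree()] data frame with `generation`), `genotypes`
#'   (a [phased_genotypes()] object), `risk_dosage` (named 0/1/2), `survival`
#'   (named; period label or `"survived"`), `trait` (named; `NA` for
#'   non-survivors, who are never phenotyped), `realized_freq`,
#'   `attempts`, `seed_used`, `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  for (attempt in seq_len(config$max_tries)) {
    seed_used <- config$seed + attempt - 1L
    set.seed(seed_used)
    drop <- sim_drop_phase(config)
    if (is.null(drop)) next
    rel <- abs(drop$realized_freq - config$risk_allele_freq) / config$risk_allele_freq
    if (rel <= config$freq_tolerance) {
      pop <- sim_marker_phase(config, drop)
      if (sim_shared_run_bp(pop) < config$min_shared_ibd_bp) next
      pop$attempts <- attempt
      pop$seed_used <- seed_used
      return(pop)
    }
  }
  stop("no attempt out of ", config$max_tries, " met both the frequency band ",
       "and the minimum shared-haplotype length; reconsider the configuration")
}

# Phase 1: pedigree structure, risk-locus gene dropping, survival. Marker-free,
# so frequency-targeting retries are cheap. Returns NULL when the allele is
# lost en route to a frequency check failure handled by the caller, or when a
# required seeding condition fails.
sim_drop_phase <- function(cfg) {
  nf <- cfg$n_founders
  periods <- names(cfg$lethality_penetrance_by_period)
  # growing vectors; generations appended
  sex <- rep_len(c("M", "F"), nf)
  gen <- rep(0L, nf)
  sire <- rep(NA_integer_, nf); dam <- rep(NA_integer_, nf)
  zs <- rep(NA_integer_, nf); zd <- rep(NA_integer_, nf)
  if (cfg$risk_seeding == "single_founder") {
    r1 <- c(1L, rep(0L, nf - 1L)); r2 <- rep(0L, nf)
  } else {
    r1 <- stats::rbinom(nf, 1, cfg$risk_allele_freq)
    r2 <- stats::rbinom(nf, 1, cfg$risk_allele_freq)
    if (sum(r1) + sum(r2) == 0L) return(NULL)
  }
  surv <- rep("survived", nf)
  draw_survival <- function(dosage) {
    out <- rep("survived", length(dosage))
    hom <- which(dosage == 2L)
    alive <- hom
    for (p in periods) {
      if (!length(alive)) break
      dies <- stats::rbinom(length(alive), 1,
                            cfg$lethality_penetrance_by_period[[p]]) == 1L
      out[alive[dies]] <- p
      alive <- alive[!dies]
    }
    out
  }
  for (g in seq_len(cfg$n_generations)) {
    prev <- which(gen == g - 1L & surv == "survived")
    dams <- prev[sex[prev] == "F"]
    males <- prev[sex[prev] == "M"]
    if (!length(dams) || !length(males)) return(NULL)
    n_off <- length(dams) * cfg$offspring_per_mating
    d_vec <- rep(dams, each = cfg$offspring_per_mating)
    s_vec <- rep(males[sample.int(length(males), length(dams), replace = TRUE)],
                 each = cfg$offspring_per_mating)
    z_s <- sample.int(2L, n_off, replace = TRUE)
    z_d <- sample.int(2L, n_off, replace = TRUE)
    a_s <- ifelse(z_s == 1L, r1[s_vec], r2[s_vec])
    a_d <- ifelse(z_d == 1L, r1[d_vec], r2[d_vec])
    off_sex <- ifelse(stats::rbinom(n_off, 1, 0.5) == 1L, "M", "F")
    off_surv <- draw_survival(a_s + a_d)
    sex <- c(sex, off_sex); gen <- c(gen, rep(g, n_off))
    sire <- c(sire, s_vec); dam <- c(dam, d_vec)
    zs <- c(zs, z_s); zd <- c(zd, z_d)
    r1 <- c(r1, a_s); r2 <- c(r2, a_d)
    surv <- c(surv, off_surv)
  }
  final <- gen == cfg$n_generations
  list(sex = sex, gen = gen, sire = sire, dam = dam, zs = zs, zd = zd,
       r1 = r1, r2 = r2, surv = surv,
       realized_freq = mean(r1[final] + r2[final]) / 2)
}

# Physical length (bp) of the marker run around the risk locus over which
# every affected homozygote is homozygous for one shared haplotype. Inf when
# there is no homozygote (the condition is vacuous).
sim_shared_run_bp <- function(pop) {
  cfg <- pop$config
  hom <- which(pop$risk_dosage == 2L)
  if (!length(hom)) return(Inf)
  g <- pop$genotypes
  ci <- which(g$map$chrom == as.character(cfg$risk_locus_chrom))
  s1 <- g$h1[hom, ci, drop = FALSE]; s2 <- g$h2[hom, ci, drop = FALSE]
  nh <- length(hom)
  ok <- colSums(s1 == s2) == nh & colSums(s1) %in% c(0L, nh)
  a <- which.min(abs(g$map$pos[ci] - cfg$risk_locus_pos))
  if (!ok[a]) return(0)
  lo <- a; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- a; while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
  g$map$pos[ci][hi] - g$map$pos[ci][lo]
}

# One gamete: recombine the parent's two haplotypes on one chromosome.
# `z`, when non-NA, fixes which parental haplotype is transmitted at
# `constrain_pos` (the risk locus); otherwise the starting haplotype is random.
sim_gamete <- function(h1, h2, pos, len, rate, z = NA_integer_,
                       constrain_pos = NA_real_) {
  k <- stats::rpois(1L, rate * len)
  if (k == 0L) {
    start <- if (is.na(z)) sample.int(2L, 1L) else z
    return(if (start == 1L) h1 else h2)
  }
  xo <- sort(stats::runif(k, 0, len))
  if (is.na(z)) {
    start <- sample.int(2L, 1L)
  } else {
    n_before <- findInterval(constrain_pos, xo)
    start <- 1L + (z - 1L - n_before) %% 2L
  }
  hap_idx <- 1L + (start - 1L + findInterval(pos, xo)) %% 2L
  ifelse(hap_idx == 1L, h1, h2)
}

# Phase 2: marker map, founder haplotypes and the full marker gene drop,
# consistent with the phase-1 risk-locus transmissions.
sim_marker_phase <- function(cfg, drop) {
  n <- length(drop$gen)
  nf <- cfg$n_founders
  m_per <- diff(round(seq(0, cfg$n_markers, length.out = cfg$n_chromosomes + 1L)))
  chrom <- rep(seq_len(cfg$n_chromosomes), m_per)
  pos <- unlist(lapply(m_per, function(mc) {
    sp <- cfg$chromosome_length_bp / mc
    p <- round((seq_len(mc) - 0.5) * sp + stats::runif(mc, -0.45, 0.45) * sp)
    pmin(pmax(p, 1), cfg$chromosome_length_bp)
  }))
  p_freq <- stats::runif(cfg$n_markers, cfg$marker_maf_floor, 0.5)
  H1 <- matrix(0L, n, cfg$n_markers)
  H2 <- matrix(0L, n, cfg$n_markers)
  H1[1:nf, ] <- stats::rbinom(nf * cfg$n_markers, 1, rep(p_freq, each = nf))
  H2[1:nf, ] <- stats::rbinom(nf * cfg$n_markers, 1, rep(p_freq, each = nf))
  if (cfg$risk_seeding == "hw_carriers") {
    # all carrier chromosomes share an identical-by-descent segment around the
    # locus, copied from the first carrier haplotype (their common ancestor)
    seg <- which(chrom == cfg$risk_locus_chrom &
                   abs(pos - cfg$risk_locus_pos) <= cfg$ibd_span_bp)
    carriers1 <- which(drop$r1[1:nf] == 1L)
    carriers2 <- which(drop$r2[1:nf] == 1L)
    template <- if (length(carriers1)) H1[carriers1[1L], seg] else H2[carriers2[1L], seg]
    for (i in carriers1) H1[i, seg] <- template
    for (i in carriers2) H2[i, seg] <- template
  }
  ci_list <- lapply(seq_len(cfg$n_chromosomes), function(cc) which(chrom == cc))
  len <- cfg$chromosome_length_bp
  for (i in (nf + 1L):n) {
    s <- drop$sire[i]; d <- drop$dam[i]
    for (cc in seq_len(cfg$n_chromosomes)) {
      ci <- ci_list[[cc]]
      on_risk <- cc == cfg$risk_locus_chrom
      H1[i, ci] <- sim_gamete(H1[s, ci], H2[s, ci], pos[ci], len,
                              cfg$recomb_rate_per_bp,
                              z = if (on_risk) drop$zs[i] else NA_integer_,
                              constrain_pos = cfg$risk_locus_pos)
      H2[i, ci] <- sim_gamete(H1[d, ci], H2[d, ci], pos[ci], len,
                              cfg$recomb_rate_per_bp,
                              z = if (on_risk) drop$zd[i] else NA_integer_,
                              constrain_pos = cfg$risk_locus_pos)
    }
  }
  ids <- sprintf("I%05d", seq_len(n))
  dosage <- drop$r1 + drop$r2
  # polygenic values: founders from the base distribution, offspring from the
  # parent average plus Mendelian-sampling deviation (inbreeding ignored)
  u <- numeric(n)
  u[1:nf] <- stats::rnorm(nf, 0, sqrt(cfg$polygenic_variance))
  for (g in seq_len(cfg$n_generations)) {
    gi <- which(drop$gen == g)
    u[gi] <- (u[drop$sire[gi]] + u[drop$dam[gi]]) / 2 +
      stats::rnorm(length(gi), 0, sqrt(cfg$polygenic_variance / 2))
  }
  trait <- cfg$trait_mean + pmin(dosage, 1) * cfg$het_trait_effect + u +
    stats::rnorm(n, 0, sqrt(cfg$residual_variance))
  trait[drop$surv != "survived"] <- NA_real_
  ped <- data.frame(id = ids,
                    sire = ifelse(is.na(drop$sire), NA, ids[drop$sire]),
                    dam = ifelse(is.na(drop$dam), NA, ids[drop$dam]),
                    sex = drop$sex,
                    birth_year = 2000L + drop$gen,
                    generation = drop$gen,
                    stringsAsFactors = FALSE)
  geno <- phased_genotypes(H1, H2,
                           data.frame(chrom = chrom, pos = pos,
                                      marker_id = sprintf("M%05d", seq_len(cfg$n_markers))),
                           ids = ids)
  structure(list(pedigree = as_pedigree(ped),
                 genotypes = geno,
                 risk_dosage = stats::setNames(dosage, ids),
                 survival = stats::setNames(drop$surv, ids),
                 trait = stats::setNames(trait, ids),
                 realized_freq = drop$realized_freq,
                 config = cfg),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("Simulated population:", nrow(x$pedigree), "individuals over",
      max(x$pedigree$generation), "generations;",
      sum(x$risk_dosage == 2), "risk homozygotes;",
      sprintf("realised final-generation allele frequency %.4f", x$realized_freq),
      sprintf("(attempt %d, seed %d)\n", x$attempts, x$seed_used))
  invisible(x)
}

#' Case and control ids from a simulated population
#'
#' Cases are risk homozygotes accumulated over the breed's whole history
#' (affected calves are rare, so a surveillance programme pools them across
#' birth cohorts); controls are non-carriers from the last
#' `control_generations` generations. Set `case_generations` to a finite
#' number for a strictly contemporary case cohort.
#'
#' @param pop A `sim_population`.
#' @param control_generations How many trailing generations provide controls.
#' @param case_generations How many trailing generations provide cases
#'   (default `Inf`: every homozygote ever born).
#' @return List with character vectors `cases` and `controls`.
#' @export
sim_case_control <- function(pop, control_generations = 2,
                             case_generations = Inf) {
  stopifnot(inherits(pop, "sim_population"))
  gmax <- max(pop$pedigree$generation)
  gen <- pop$pedigree$generation
  ids <- pop$pedigree$id
  case_pool <- ids[gen > gmax - case_generations]
  cases <- case_pool[pop$risk_dosage[case_pool] == 2]
  recent <- ids[gen > gmax - control_generations]
  controls <- recent[pop$risk_dosage[recent] == 0]
  list(cases = cases, controls = controls)
}

#' Simulate mating-type mortality records
#'
#' Draws `n_matings` calves for each mating type (sire dosage x
#' maternal-grandsire dosage: 1x1, 1x0, 0x1, 0x0). The ungenotyped dam of a
#' heterozygous maternal grandsire is wild-type or heterozygous with the
#' survival-conditioned probabilities (1-fA)/(2-fA) and 1/(2-fA); the daughter
#' of a non-carrier bull is heterozygous with probability fA (the allele
#' frequency in the maternal-granddam population). The calf genotype follows
#' Mendelian segregation; non-homozygotes die with the baseline probability
#' `mu_baseline`, homozygotes with `mu_baseline + penetrance * (1 -
#' mu_baseline)`.
#'
#' @param fA Risk allele frequency in \[0, 1).
#' @param penetrance Probability that a homozygote dies in the period.
#' @param mu_baseline Baseline (non-genetic) mortality in the period.
#' @param n_matings Calves simulated per mating type.
#' @param seed Integer seed.
#' @return `data.frame` with columns `mating_type`, `n`, `deaths`; zero rows
#'   when `n_matings` is 0.
#' @export
simulate_matings <- function(fA, penetrance, mu_baseline, n_matings, seed = 1) {
  stopifnot(fA >= 0, fA < 1, penetrance >= 0, penetrance <= 1,
            mu_baseline >= 0, mu_baseline <= 1, n_matings >= 0)
  if (n_matings == 0)
    return(data.frame(mating_type = character(), n = integer(),
                      deaths = integer(), stringsAsFactors = FALSE))
  set.seed(seed)
  types <- data.frame(mating_type = c("1x1", "1x0", "0x1", "0x0"),
                      sire_d = c(1L, 1L, 0L, 0L),
                      mgs_d = c(1L, 0L, 1L, 0L), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(types)), function(i) {
    p_het_dam <- if (types$mgs_d[i] == 1L) 1 / (2 - fA) else fA
    dam_d <- stats::rbinom(n_matings, 1, p_het_dam)
    a_pat <- stats::rbinom(n_matings, 1, types$sire_d[i] / 2)
    a_mat <- stats::rbinom(n_matings, 1, dam_d / 2)
    hom <- a_pat + a_mat == 2L
    p_die <- mu_baseline + ifelse(hom, penetrance * (1 - mu_baseline), 0)
    deaths <- sum(stats::rbinom(n_matings, 1, p_die))
    data.frame(mating_type = types$mating_type[i], n = n_matings,
               deaths = deaths, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
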