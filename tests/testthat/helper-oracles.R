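# Independent oracles and shared fixtures.

# 12-individual pedigree with an inbreeding loop (L's parents share the
# grandparents A and B through C and D; K is inbred through G).
toy_loop_pedigree <- function() {
  data.frame(
    id   = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L"),
    sire = c(NA,  NA,  "A", "A", NA,  "C", "C", "E", "G", "G", "I", "F"),
    dam  = c(NA,  NA,  "B", "B", NA,  "D", "E", "D", "H", "H", "J", "G"),
    stringsAsFactors = FALSE)
}

# brute-force ancestor set by repeated parent expansion (independent of the
# package's stack-based traversal)
oracle_ancestors <- function(id, ped) {
  parents <- function(x) {
    r <- ped[ped$id == x, ]
    stats::na.omit(c(r$sire, r$dam))
  }
  anc <- character(0)
  frontier <- parents(id)
  while (length(frontier)) {
    anc <- union(anc, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, parents))), anc)
  }
  anc
}

# Monte-Carlo gene dropping: label the ancestor's two gene copies and drop
# them through the pedigree; the contribution is the expected labelled
# fraction averaged over the population.
oracle_gene_drop <- function(ancestor, population, ped, nrep = 1e5, seed = 42) {
  set.seed(seed)
  ids <- ped$id
  idx <- seq_along(ids); names(idx) <- ids
  si <- idx[ped$sire]; di <- idx[ped$dam]
  # topological order by repeated sweeps
  placed <- is.na(si) & is.na(di)
  ord <- which(placed)
  while (length(ord) < length(ids)) {
    ready <- which(!placed &
                     (is.na(si) | placed[ifelse(is.na(si), 1, si)]) &
                     (is.na(di) | placed[ifelse(is.na(di), 1, di)]))
    ord <- c(ord, ready); placed[ready] <- TRUE
  }
  a <- idx[[ancestor]]
  A1 <- matrix(0L, nrep, length(ids))  # labelled copies on "paternal" slot
  A2 <- matrix(0L, nrep, length(ids))
  A1[, a] <- 1L; A2[, a] <- 1L
  for (v in ord) {
    if (v == a) next
    if (!is.na(si[v])) {
      pick <- stats::rbinom(nrep, 1, 0.5)
      A1[, v] <- ifelse(pick == 1, A1[, si[v]], A2[, si[v]])
    } else A1[, v] <- 0L
    if (!is.na(di[v])) {
      pick <- stats::rbinom(nrep, 1, 0.5)
      A2[, v] <- ifelse(pick == 1, A1[, di[v]], A2[, di[v]])
    } else A2[, v] <- 0L
  }
  frac <- (A1[, idx[population], drop = FALSE] +
             A2[, idx[population], drop = FALSE]) / 2
  per_rep <- rowMeans(frac)
  list(mean = mean(per_rep), se = stats::sd(per_rep) / sqrt(nrep))
}

# Two-sided Fisher p by explicit enumeration with lchoose arithmetic
# (independent of dhyper).
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (k == 0 || k == m1 + m2 || m1 == 0 || m2 == 0) return(1)
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(m1 + m2, k)
  p <- exp(logp)
  p_obs <- p[support == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# small shared simulated population, built once per test run
shared_sim_pop <- local({
  pop <- NULL
  function() {
    if (is.null(pop)) {
      cfg <- sim_config(n_founders = 16, n_generations = 6,
                        offspring_per_mating = 4, n_markers = 500,
                        n_chromosomes = 2, chromosome_length_bp = 2.5e7,
                        risk_allele_freq = 0.08, risk_locus_pos = 6e6,
                        seed = 11)
      pop <<- simulate_population(cfg)
    }
    pop
  }
})

# tiny PSSM over ACGT with distinct entries for hand-checkable scores
toy_pssm <- function() {
  m <- matrix(c(1, 0, -1, 2,
                0, 3, 1, -2,
                2, -1, 0, 1), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m
}
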