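#' Configuration for the forward-in-time population simulator
#'
#' Bundles and validates every parameter governing [simulate_population()].
#' Defaults describe a closed beef-cattle-like breed segregating a fully
#' penetrant recessive perinatal lethal at low frequency, genotyped at
#' 50K-array-like marker density.
#'
#' @param n_founders Number of founder individuals (even; half of each sex).
#' @param n_generations Number of discrete generations bred after the founders.
#' @param offspring_per_mating Calves per dam per generation.
#' @param n_markers Total array markers, split evenly across chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length_bp Physical length of each chromosome (bp).
#' @param risk_allele_freq Target population frequency of the lethal allele.
#' @param risk_locus_chrom,risk_locus_pos Location of the (unobserved) lethal
#'   locus; the position need not coincide with a marker.
#' @param lethality_penetrance_by_period Named probabilities that a surviving
#'   homozygote dies in each age period, applied sequentially; names fix the
#'   periods (defaults: 0-2, 3-14, 15-55, 56-365 days).
#' @param het_trait_effect Additive effect of one risk-allele copy on the
#'   quantitative trait (trait units; dosage capped at 1 among survivors).
#' @param polygenic_variance,residual_variance Trait variance components
#'   (trait units squared).
#' @param trait_mean Trait grand mean (adjusted phenotypes: default 0).
#' @param recomb_rate_per_bp Recombination rate in Morgans/bp (default 1e-8,
#'   i.e. 1 cM/Mb, the cattle-genome convention).
#' @param marker_maf_floor Founder marker allele frequencies are drawn uniform
#'   on \[floor, 0.5\].
#' @param risk_seeding `"single_founder"` (default) places the risk allele on
#'   exactly one founder haplotype and lets it drift, resampling with an
#'   incremented seed when the final frequency misses the target by more than
#'   `freq_tolerance`; `"hw_carriers"` draws founder carrier haplotypes
#'   binomially at the target frequency and copies one founder's local marker
#'   haplotype onto all carrier chromosomes around the locus (an
#'   identical-by-descent segment from an ancestral founder).
#' @param ibd_span_bp Half-width of the shared segment copied around the risk
#'   locus under `"hw_carriers"` seeding.
#' @param freq_tolerance Maximum relative deviation of the realised final
#'   frequency from `risk_allele_freq` before resampling (default 0.25).
#' @param min_shared_ibd_bp Minimum physical length (bp) of the marker run
#'   around the risk locus over which every affected homozygote is homozygous
#'   for the same haplotype; replicates realising a shorter shared haplotype
#'   are resampled with an incremented seed, like the frequency band. This
#'   enforces the intended data structure — a megabase-scale
#'   identical-by-descent lethal haplotype — against recombination erosion in
#'   deep pedigrees. Default 1.6e6; 0 disables the check.
#' @param max_tries Maximum seeds tried before giving up.
#' @param seed Integer random seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 20,
                       n_generations = 7,
                       offspring_per_mating = 4,
                       n_markers = 2000,
                       n_chromosomes = 2,
                       chromosome_length_bp = 5e7,
                       risk_allele_freq = 0.026,
                       risk_locus_chrom = 1,
                       risk_locus_pos = 4e6,
                       lethality_penetrance_by_period =
                         c("0-2" = 1, "3-14" = 0, "15-55" = 0, "56-365" = 0),
                       het_trait_effect = -1.0,
                       polygenic_variance = 22.8,
                       residual_variance = 53.1,
                       trait_mean = 0,
                       recomb_rate_per_bp = 1e-8,
                       marker_maf_floor = 0.01,
                       risk_seeding = c("single_founder", "hw_carriers"),
                       ibd_span_bp = 5e6,
                       freq_tolerance = 0.25,
                       min_shared_ibd_bp = 1.6e6,
                       max_tries = 200,
                       seed = 1) {
  risk_seeding <- match.arg(risk_seeding)
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              offspring_per_mating = as.integer(offspring_per_mating),
              n_markers = as.integer(n_markers),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_bp = chromosome_length_bp,
              risk_allele_freq = risk_allele_freq,
              risk_locus_chrom = as.integer(risk_locus_chrom),
              risk_locus_pos = risk_locus_pos,
              lethality_penetrance_by_period = lethality_penetrance_by_period,
              het_trait_effect = het_trait_effect,
              polygenic_variance = polygenic_variance,
              residual_variance = residual_variance,
              trait_mean = trait_mean,
              recomb_rate_per_bp = recomb_rate_per_bp,
              marker_maf_floor = marker_maf_floor,
              risk_seeding = risk_seeding,
              ibd_span_bp = ibd_span_bp,
              freq_tolerance = freq_tolerance,
              min_shared_ibd_bp = min_shared_ibd_bp,
              max_tries = as.integer(max_tries),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_founders >= 2, n_generations >= 1, offspring_per_mating >= 1,
              n_markers >= n_chromosomes, n_chromosomes >= 1,
              chromosome_length_bp >= 1,
              risk_allele_freq >= 0, risk_allele_freq <= 1,
              risk_locus_chrom >= 1, risk_locus_chrom <= n_chromosomes,
              risk_locus_pos >= 1, risk_locus_pos <= chromosome_length_bp,
              all(lethality_penetrance_by_period >= 0),
              all(lethality_penetrance_by_period <= 1),
              polygenic_variance >= 0, residual_variance >= 0,
              recomb_rate_per_bp >= 0,
              marker_maf_floor > 0, marker_maf_floor < 0.5,
              freq_tolerance > 0, min_shared_ibd_bp >= 0, max_tries >= 1)
  })
  if (is.null(names(cfg$lethality_penetrance_by_period)))
    stop("lethality_penetrance_by_period must be a named vector of periods")
  if (cfg$risk_allele_freq == 0)
    stop("risk_allele_freq = 0: no carrier matings can be generated")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_founders, "founders,", x$n_generations,
      "generations,", x$n_markers, "markers on", x$n_chromosomes,
      "chromosome(s); target risk allele frequency", x$risk_allele_freq,
      sprintf("(%s seeding); seed %d\n", x$risk_seeding, x$seed))
  invisible(x)
}
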