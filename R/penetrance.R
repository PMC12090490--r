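#' Period mortality rate
#'
#' Deaths during a period divided by the number of calves at risk at the start
#' of that period.
#'
#' @param deaths,at_risk Non-negative counts with `deaths <= at_risk`.
#' @return Fraction in \[0, 1\]; `NA` with a warning when `at_risk` is 0.
#' @export
mortality_rate <- function(deaths, at_risk) {
  stopifnot(all(deaths >= 0), all(deaths <= at_risk | at_risk == 0))
  out <- deaths / at_risk
  if (any(at_risk == 0)) {
    warning("at_risk = 0: mortality rate undefined")
    out[at_risk == 0] <- NA_real_
  }
  out
}

#' One-way fixed-effect model of mortality by mating type
#'
#' Fits `death ~ mating_type` on per-calf 0/100 indicators (percent scale) by
#' ordinary least squares with the control mating type `0x0` as reference.
#' With mating type as the only factor, each contrast equals the difference of
#' raw group means; standard errors use the pooled residual variance and
#' p-values are two-sided t-tests, as in a GLM with a single categorical
#' factor.
#'
#' @param table `data.frame` with columns `mating_type` (values among `1x1`,
#'   `1x0`, `0x1`, `0x0`) and `died` (0/1 or logical per calf), or columns
#'   `mating_type`, `n`, `deaths` (grouped counts, e.g. from
#'   [simulate_matings()]), which are expanded to calf level.
#' @param period Optional label stored in the result.
#' @return Object of class `mating_fit`: `data.frame` with one row per mating
#'   type (`mating_type`, `n`, `raw_mean` in %, `diff_vs_00` in %, `se` in %,
#'   `p_value`; reference row has `NA` contrast columns), plus the underlying
#'   `lm` fit in attribute `"lm"`.
#' @export
fit_mating_model <- function(table, period = NULL) {
  stopifnot(is.data.frame(table))
  if (all(c("n", "deaths") %in% names(table)) && !"died" %in% names(table)) {
    table <- do.call(rbind, lapply(seq_len(nrow(table)), function(i)
      data.frame(mating_type = table$mating_type[i],
                 died = rep(c(1, 0), c(table$deaths[i],
                                       table$n[i] - table$deaths[i])),
                 stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("mating_type", "died") %in% names(table)))
  if (!"0x0" %in% table$mating_type)
    stop("reference mating type 0x0 absent")
  if (length(unique(table$mating_type)) < 2)
    stop("need at least two mating types")
  dat <- data.frame(
    y = as.numeric(table$died) * 100,
    type = stats::relevel(factor(table$mating_type), ref = "0x0"))
  fit <- stats::lm(y ~ type, data = dat)
  cf <- summary(fit)$coefficients
  lev <- levels(dat$type)
  out <- data.frame(mating_type = lev,
                    n = as.integer(table(dat$type)[lev]),
                    raw_mean = tapply(dat$y, dat$type, mean)[lev],
                    diff_vs_00 = NA_real_, se = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (l in lev[-1L]) {
    row <- paste0("type", l)
    out[out$mating_type == l, c("diff_vs_00", "se", "p_value")] <-
      as.list(cf[row, c("Estimate", "Std. Error", "Pr(>|t|)")])
  }
  rownames(out) <- NULL
  attr(out, "lm") <- fit
  attr(out, "period") <- period
  class(out) <- c("mating_fit", class(out))
  out
}

#' @export
print.mating_fit <- function(x, digits = 2, ...) {
  if (!is.null(attr(x, "period"))) cat("Period:", attr(x, "period"), "\n")
  df <- as.data.frame(x)
  df$raw_mean <- round(df$raw_mean, digits)
  df$diff_vs_00 <- round(df$diff_vs_00, digits)
  df$se <- round(df$se, digits)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mating_fit <- function(object, ...) summary(attr(object, "lm"), ...)

#' @export
coef.mating_fit <- function(object, ...) stats::coef(attr(object, "lm"))

#' Expected mortality increase in at-risk matings under complete penetrance
#'
#' For a heterozygous sire mated to the ungenotyped daughter of a heterozygous
#' bull, the calf is homozygous with probability 1/(4(2 - fA)) (the dam is
#' heterozygous with probability 1/(2 - fA) after conditioning on her own
#' survival, and each heterozygous parent transmits the allele with
#' probability 1/2). A lethal homozygote adds to the baseline mortality `mu`
#' only when it would otherwise have lived, so the expected increase is
#'
#'   1 / (4 (2 - fA)) * (1 - mu)
#'
#' @param fA Risk allele frequency in \[0, 1).
#' @param mu Baseline mortality rate of the period in \[0, 1\].
#' @return Expected mortality increase as a fraction.
#' @examples
#' expected_increase(0.026, 0.0285) # 0.1230: +12.30 percentage points
#' @export
expected_increase <- function(fA, mu) {
  stopifnot(all(fA >= 0), all(fA < 1), all(mu >= 0), all(mu <= 1))
  (1 / (4 * (2 - fA))) * (1 - mu)
}

#' Genotype probabilities of the surviving daughter of a heterozygous bull
#'
#' Unconditionally the daughter is wild-type, heterozygous or homozygous with
#' probabilities (1-fA)/2, 1/2 and fA/2; removing the (lethal, unobserved)
#' homozygotes and renormalising gives wild-type (1-fA)/(2-fA) and
#' heterozygous 1/(2-fA).
#'
#' @param fA Risk allele frequency in \[0, 1).
#' @return Named numeric vector `c(p_wildtype, p_het)` summing to 1.
#' @export
dam_genotype_probs <- function(fA) {
  stopifnot(fA >= 0, fA < 1)
  c(p_wildtype = (1 - fA) / (2 * (1 - fA / 2)),
    p_het = 1 / (2 * (1 - fA / 2)))
}

#' Compare observed/expected mortality increase with case-registration rate
#'
#' An observed excess mortality falling short of the complete-penetrance
#' expectation can reflect incomplete penetrance or under-registration of
#' stillborn calves. This check converts the ratio observed/expected and the
#' registration proportion (`registered / reported`) into count pairs out of
#' `reported` and compares them two ways: a Pearson chi-square goodness-of-fit
#' of the observed/expected counts against the registration proportion (df =
#' 1), and a Fisher exact test of the 2x2 table of the two count pairs. Both
#' p-values are returned; they can differ substantially and no silent choice
#' is made between them.
#'
#' @param observed_increase,expected_increase Mortality increases (fractions);
#'   `expected_increase` must be positive.
#' @param reported Number of cases reported (e.g. to a surveillance network).
#' @param registered Number of those officially registered (`<= reported`).
#' @return List of class `penetrance_check`: `ratio_obs_exp`,
#'   `registration_proportion`, `counts_obs_exp` (c(yes, no)),
#'   `counts_registration`, `p_chisq_gof`, `p_fisher`.
#' @export
penetrance_check <- function(observed_increase, expected_increase,
                             reported, registered) {
  stopifnot(registered <= reported, reported >= 1)
  if (expected_increase <= 0) stop("expected_increase must be positive")
  ratio <- observed_increase / expected_increase
  reg <- registered / reported
  k1 <- round(ratio * reported)
  k2 <- registered
  obs <- c(k1, reported - k1)
  exp_counts <- c(k2, reported - k2)
  terms <- (obs - exp_counts)^2 / exp_counts
  terms[exp_counts == 0 & obs == exp_counts] <- 0   # empty cell, no misfit
  chisq <- sum(terms)
  p_chisq <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  p_fisher <- fisher_exact_2x2(obs[1], obs[2], exp_counts[1], exp_counts[2])
  structure(list(ratio_obs_exp = ratio,
                 registration_proportion = reg,
                 counts_obs_exp = obs,
                 counts_registration = exp_counts,
                 chisq = chisq,
                 p_chisq_gof = p_chisq,
                 p_fisher = p_fisher),
            class = "penetrance_check")
}

#' @export
print.penetrance_check <- function(x, ...) {
  cat(sprintf("Observed/expected mortality increase: %.2f%% (%d:%d of %d)\n",
              100 * x$ratio_obs_exp, x$counts_obs_exp[1], x$counts_obs_exp[2],
              sum(x$counts_obs_exp)))
  cat(sprintf("Registration proportion: %.2f%% (%d:%d)\n",
              100 * x$registration_proportion, x$counts_registration[1],
              x$counts_registration[2]))
  cat(sprintf("Pearson chi-square GOF p = %.3g; Fisher exact p = %.3g\n",
              x$p_chisq_gof, x$p_fisher))
  invisible(x)
}
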