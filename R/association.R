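#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = W W' / (2 sum p(1-p)) where W is the column-centred dosage matrix
#' (w = g - 2p per marker). Markers on `exclude_chrom` are removed first, so
#' the polygenic background excludes the chromosome carrying the tested
#' variant; monomorphic markers are dropped with a warning.
#'
#' @param genotypes A [phased_genotypes()] object, or a numeric dosage matrix
#'   (individuals x markers, 0/1/2).
#' @param exclude_chrom Chromosome(s) to drop (only for `phased_genotypes`
#'   input).
#' @param allele_freq Optional reference allele frequencies per retained
#'   marker; defaults to frequencies observed in the data.
#' @return Symmetric relationship matrix with individual ids as dimnames.
#' @export
grm <- function(genotypes, exclude_chrom = NULL, allele_freq = NULL) {
  if (inherits(genotypes, "phased_genotypes")) {
    keep <- if (is.null(exclude_chrom)) seq_len(nrow(genotypes$map)) else
      which(!genotypes$map$chrom %in% as.character(exclude_chrom))
    M <- dosage_matrix(subset_genotypes(genotypes, markers = keep))
  } else {
    M <- as.matrix(genotypes)
    if (!is.null(exclude_chrom))
      stop("exclude_chrom requires a phased_genotypes object")
  }
  if (nrow(M) < 2) stop("need at least two individuals")
  p <- if (is.null(allele_freq)) colMeans(M) / 2 else allele_freq
  stopifnot(length(p) == ncol(M))
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning("dropping ", sum(mono), " monomorphic marker(s)")
    M <- M[, !mono, drop = FALSE]; p <- p[!mono]
  }
  if (!ncol(M)) stop("no polymorphic markers left")
  W <- sweep(M, 2, 2 * p)
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

# Restricted log-likelihood of the null model y = 1*mu + u + e on the
# eigenbasis of G, profiled over sigma^2_p for a given h^2.
reml_ll_h2 <- function(h2, yt, xt, d) {
  w <- h2 * d + (1 - h2)
  xw <- xt / w
  xtvx <- crossprod(xt, xw)           # p x p
  beta <- solve(xtvx, crossprod(xw, yt))
  r <- yt - xt %*% beta
  rss <- sum(r^2 / w)
  n <- length(yt); p <- ncol(xt)
  s2 <- rss / (n - p)
  -0.5 * ((n - p) * log(s2) + sum(log(w)) +
            determinant(xtvx, logarithm = TRUE)$modulus + (n - p))
}

#' Mixed-linear-model association for a single variant
#'
#' Fits y = 1 mu + x b + u + e with u ~ N(0, G sigma_u^2) and
#' e ~ N(0, I sigma_e^2). Variance components are estimated by REML under the
#' null model (no variant effect), via deterministic 1-D profile optimisation
#' of the heritability on the eigendecomposition of G; (mu, b) are then
#' estimated by generalised least squares at those components and b gets a
#' two-sided Wald p-value.
#'
#' @param y Numeric phenotype vector (adjusted for non-genetic effects).
#' @param x Numeric dosage vector (here 0/1: lethal homozygotes are never
#'   phenotyped).
#' @param G Symmetric PSD relationship matrix from [grm()], or its
#'   eigendecomposition (a list with `values`, `vectors`) to reuse across
#'   traits or replicates.
#' @return Object of class `mlma_fit`: list with `b`, `se`, `p_value`, `mu`,
#'   `h2`, `sigma_u2`, `sigma_e2`, `n`.
#' @export
mlma <- function(y, x, G) {
  n <- length(y)
  stopifnot(length(x) == n, !anyNA(y), !anyNA(x))
  if (stats::var(y) == 0) stop("zero phenotypic variance")
  if (is.matrix(G)) {
    stopifnot(nrow(G) == n, ncol(G) == n)
    if (max(abs(G - t(G))) > 1e-8) stop("G must be symmetric")
    eG <- eigen(G, symmetric = TRUE)
  } else {
    eG <- G
    stopifnot(length(eG$values) == n)
  }
  if (min(eG$values) < -1e-6 * max(abs(eG$values)))
    stop("G is not positive semidefinite")
  d <- pmax(eG$values, 0)
  U <- eG$vectors
  yt <- drop(crossprod(U, y))
  ones_t <- crossprod(U, rep(1, n))
  opt <- stats::optimize(reml_ll_h2, interval = c(0, 0.999), maximum = TRUE,
                         yt = yt, xt = ones_t, d = d, tol = 1e-8)
  h2 <- opt$maximum
  # boundary refinement: REML likelihood can be maximal at h2 = 0
  if (reml_ll_h2(0, yt, ones_t, d) >= opt$objective) h2 <- 0
  w <- h2 * d + (1 - h2)
  # GLS for (mu, b) at the null-model variance components
  Xt <- cbind(ones_t, drop(crossprod(U, x)))
  xw <- Xt / w
  xtvx <- crossprod(Xt, xw)
  beta <- solve(xtvx, crossprod(xw, yt))
  r <- yt - Xt %*% beta
  s2p <- sum(r^2 / w) / (n - ncol(Xt))
  vc <- solve(xtvx) * s2p
  se <- sqrt(diag(vc))
  z <- beta[2] / se[2]
  structure(list(b = unname(beta[2]), se = unname(se[2]),
                 p_value = 2 * stats::pnorm(-abs(z)),
                 mu = unname(beta[1]), h2 = h2,
                 sigma_u2 = h2 * s2p, sigma_e2 = (1 - h2) * s2p, n = n),
            class = "mlma_fit")
}

#' @export
print.mlma_fit <- function(x, ...) {
  cat(sprintf("MLM association (n = %d): b = %.4g (SE %.4g), p = %.3g\n",
              x$n, x$b, x$se, x$p_value))
  cat(sprintf("Null-model REML: h2 = %.3f, sigma_u2 = %.4g, sigma_e2 = %.4g\n",
              x$h2, x$sigma_u2, x$sigma_e2))
  invisible(x)
}

#' @export
coef.mlma_fit <- function(object, ...) c(mu = object$mu, b = object$b)

#' Scale an allele effect in genetic standard deviations
#'
#' @param b Allele substitution effect in trait units.
#' @param gsd Genetic standard deviation of the trait (> 0).
#' @return `|b| / gsd`.
#' @examples
#' effect_in_gsd(-1.00, 4.77) # 0.21: the effect is 21% of a genetic SD
#' @export
effect_in_gsd <- function(b, gsd) {
  stopifnot(gsd > 0)
  abs(b) / gsd
}

#' Benjamini-Hochberg step-up q-values
#'
#' q(k) = min over j >= k of p(j) * n / j (p sorted ascending, n = family
#' size), capped at 1; tied p-values share the smaller q. Returned in the
#' input order. The family is whatever vector the caller passes: no global
#' family is assumed.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_qvalues(c(0.04, 0.53, 0.54, 0.61, 0.91))[1] # 0.20
#' @export
bh_qvalues <- function(pvals) {
  stopifnot(all(pvals >= 0), all(pvals <= 1))
  n <- length(pvals)
  if (!n) return(numeric(0))
  o <- order(pvals)
  q_sorted <- rev(cummin(rev(pvals[o] * n / seq_len(n))))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(n)
  out[o] <- q_sorted
  out
}
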