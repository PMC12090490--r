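#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]` with fixed
#' margins: the sum of hypergeometric point probabilities not exceeding the
#' probability of the observed table (point-probability summation, the
#' conventional two-sided definition). Point masses are evaluated with
#' `dhyper`, which works in log space internally, so large counts are exact.
#'
#' @param a,b,c,d Non-negative counts: `a` cases homozygous, `b` cases with
#'   any other genotype, `c`/`d` the same for controls.
#' @return p-value in (0, 1]. A degenerate table (any margin zero) returns 1.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(length(a) == 1, a >= 0, b >= 0, c >= 0, d >= 0)
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 + m2 == 0) { message("all-zero table: p = 1 by convention"); return(1) }
  if (k == 0 || k == m1 + m2 || m1 == 0 || m2 == 0) return(1)
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  # relative tolerance guards against ties broken by floating-point noise
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Bonferroni-corrected significance threshold on the -log10 scale
#'
#' @param alpha Nominal family-wise type I error rate in (0, 1].
#' @param n_tests Number of tests performed (>= 1).
#' @return `-log10(alpha / n_tests)`.
#' @examples
#' bonferroni_threshold(0.05, 78861) # 6.20 to 2 d.p.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha <= 1, n_tests >= 1)
  -log10(alpha / n_tests)
}

# Rolling window codes: encode each haplotype's w consecutive alleles as an
# exact integer in [0, 2^w) held in a double (w <= 40). Returns a matrix
# (n_hap x n_windows).
window_codes <- function(H, w) {
  n <- nrow(H); m <- ncol(H)
  nw <- m - w + 1L
  codes <- matrix(0, n, nw)
  code <- as.numeric(H[, 1:w, drop = FALSE] %*% 2^((w - 1):0))
  codes[, 1L] <- code
  if (nw > 1L) {
    top <- 2^(w - 1)
    for (j in 2:nw) {
      code <- (code - H[, j - 1L] * top) * 2 + H[, j + w - 1L]
      codes[, j] <- code
    }
  }
  codes
}

#' Sliding-haplotype case/control homozygosity scan
#'
#' Slides windows of `window_size` consecutive informative markers (MAF >
#' `maf_floor`, computed over the scanned individuals) along each chromosome,
#' one marker at a time. An individual is homozygous for a window haplotype
#' when its two phased haplotypes are identical across the window and equal
#' that haplotype. For every haplotype carried homozygously by at least one
#' case, a 2x2 table (cases homozygous vs any other genotype; same for
#' controls) is tested with [fisher_exact_2x2()].
#'
#' @param genotypes A [phased_genotypes()] object.
#' @param cases,controls Disjoint character vectors of individual ids.
#' @param window_size Markers per window (default 20, about 1 Mb at 50K-array
#'   density).
#' @param maf_floor Markers with MAF not exceeding this are dropped before
#'   windowing (default 0.01).
#' @return A `data.frame` of class `hap_scan`, one row per (window, tested
#'   haplotype): `chrom`, `first_marker_index` (into the filtered map),
#'   `start_pos`, `end_pos`, `haplotype` (allele string), `a`, `b`, `c`, `d`,
#'   `p_value`, `neg_log10_p`. Attributes: `map` (filtered marker map),
#'   `window_size`, `n_cases`, `n_controls`, `n_tests`,
#'   `bonferroni_threshold` (at alpha = 0.05).
#' @export
hap_scan <- function(genotypes, cases, controls, window_size = 20,
                     maf_floor = 0.01) {
  stopifnot(inherits(genotypes, "phased_genotypes"))
  cases <- as.character(cases); controls <- as.character(controls)
  if (length(intersect(cases, controls)))
    stop("cases and controls must be disjoint")
  g <- subset_genotypes(genotypes, individuals = c(cases, controls))
  keep <- g$map$maf > maf_floor
  g <- subset_genotypes(g, markers = which(keep))
  is_case <- g$ids %in% cases
  n_cases <- sum(is_case); n_controls <- sum(!is_case)
  res <- vector("list", 64L); nres <- 0L
  for (chr in unique(g$map$chrom)) {
    ci <- which(g$map$chrom == chr)
    if (length(ci) < window_size) {
      warning("chromosome ", chr, " has fewer than ", window_size,
              " informative markers; skipped")
      next
    }
    H1 <- g$h1[, ci, drop = FALSE]; H2 <- g$h2[, ci, drop = FALSE]
    C1 <- window_codes(H1, window_size)
    C2 <- window_codes(H2, window_size)
    hom <- C1 == C2
    for (j in seq_len(ncol(C1))) {
      hj <- hom[, j]
      case_codes <- C1[is_case & hj, j]
      if (!length(case_codes)) next
      for (code in unique(case_codes)) {
        hom_this <- hj & C1[, j] == code
        a <- sum(hom_this & is_case); c_ <- sum(hom_this & !is_case)
        b <- n_cases - a; d <- n_controls - c_
        p <- fisher_exact_2x2(a, b, c_, d)
        # reconstruct the window haplotype from any homozygote
        rep_i <- which(hom_this)[1L]
        alleles <- H1[rep_i, j:(j + window_size - 1L)]
        nres <- nres + 1L
        if (nres > length(res)) res <- c(res, vector("list", length(res)))
        res[[nres]] <- data.frame(
          chrom = chr, first_marker_index = ci[j],
          start_pos = g$map$pos[ci[j]],
          end_pos = g$map$pos[ci[j + window_size - 1L]],
          haplotype = paste(alleles, collapse = ""),
          a = a, b = b, c = c_, d = d,
          p_value = p, neg_log10_p = -log10(p),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (nres) do.call(rbind, res[seq_len(nres)]) else
    data.frame(chrom = character(), first_marker_index = integer(),
               start_pos = integer(), end_pos = integer(),
               haplotype = character(), a = integer(), b = integer(),
               c = integer(), d = integer(), p_value = numeric(),
               neg_log10_p = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "map") <- g$map
  attr(out, "window_size") <- window_size
  attr(out, "n_cases") <- n_cases
  attr(out, "n_controls") <- n_controls
  attr(out, "n_tests") <- nrow(out)
  attr(out, "bonferroni_threshold") <-
    if (nrow(out)) bonferroni_threshold(0.05, nrow(out)) else NA_real_
  class(out) <- c("hap_scan", class(out))
  out
}

#' @export
print.hap_scan <- function(x, ...) {
  if (is.null(attr(x, "n_tests"))) {   # subset without scan attributes
    print(as.data.frame(x), ...)
    return(invisible(x))
  }
  cat("Sliding-haplotype homozygosity scan:", attr(x, "n_tests"),
      "tests with >= 1 homozygous case;",
      attr(x, "n_cases"), "cases,", attr(x, "n_controls"), "controls\n")
  cat("Bonferroni 5% threshold: -log10(p) =",
      round(attr(x, "bonferroni_threshold"), 2), "\n")
  if (nrow(x)) {
    top <- x[which.min(x$p_value), ]
    cat(sprintf("Top window: %s:%d-%d  p = %.3g\n",
                top$chrom, top$start_pos, top$end_pos, top$p_value))
  }
  invisible(x)
}

#' Write a homozygosity scan to TSV (Manhattan-plot-ready)
#'
#' @param scan A `hap_scan` result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge qualifying windows into a mapping interval
#'
#' Windows for which all cases are homozygous for one haplotype and no control
#' is homozygous for it qualify. Overlapping qualifying windows on the same
#' chromosome are merged into maximal marker runs; the longest run — the
#' longest haplotype shared by all cases and no control — is the merged
#' haplotype (p-value breaks length ties). The mapping interval extends
#' to the most proximal informative markers outside the run on either side; at
#' a chromosome edge it is truncated at the run boundary (with a message).
#'
#' @param scan A `hap_scan` result (carries the filtered map).
#' @return An object of class `mapping_result`: list with `chrom`,
#'   `run_start_pos`, `run_end_pos`, `n_markers`, `interval_start`,
#'   `interval_end`, `marker_index` (into the scan's filtered map),
#'   `risk_haplotype` (0/1 vector over the run markers), `n_tests`,
#'   `bonferroni_threshold`. If no window qualifies, returns `NULL` with a
#'   diagnostic message.
#' @export
extract_interval <- function(scan) {
  stopifnot(inherits(scan, "hap_scan"))
  map <- attr(scan, "map")
  w <- attr(scan, "window_size")
  n_cases <- attr(scan, "n_cases")
  qual <- scan$a == n_cases & scan$c == 0
  if (!any(qual)) {
    message("no window with all cases homozygous and no homozygous control")
    return(NULL)
  }
  q <- scan[qual, , drop = FALSE]
  # maximal runs of overlapping/adjacent qualifying windows, per chromosome
  runs <- list()
  for (chr in unique(q$chrom)) {
    s <- sort(unique(q$first_marker_index[q$chrom == chr]))
    brk <- c(0L, which(diff(s) >= w), length(s))
    for (k in seq_len(length(brk) - 1L)) {
      idx <- s[(brk[k] + 1L):brk[k + 1L]]
      runs[[length(runs) + 1L]] <-
        list(chrom = chr, first = idx[1L], last = idx[length(idx)] + w - 1L)
    }
  }
  # the longest run (= the longest haplotype shared by all cases and no
  # control); exact p-value ties across qualifying windows are common, so run
  # length, not window p, discriminates — p breaks remaining ties
  run_len <- vapply(runs, function(r) as.numeric(r$last - r$first + 1L), numeric(1))
  run_p <- vapply(runs, function(r) {
    in_run <- q$chrom == r$chrom & q$first_marker_index >= r$first &
      q$first_marker_index <= r$last - w + 1L
    min(q$p_value[in_run])
  }, numeric(1))
  pick <- order(-run_len, run_p)[1L]
  run <- runs[[pick]]
  chr_idx <- which(map$chrom == run$chrom)
  lo <- run$first; hi <- run$last
  if (lo - 1L >= min(chr_idx) && map$chrom[lo - 1L] == run$chrom) {
    interval_start <- map$pos[lo - 1L]
  } else {
    message("run reaches chromosome start; interval truncated at run boundary")
    interval_start <- map$pos[lo]
  }
  if (hi + 1L <= max(chr_idx) && map$chrom[hi + 1L] == run$chrom) {
    interval_end <- map$pos[hi + 1L]
  } else {
    message("run reaches chromosome end; interval truncated at run boundary")
    interval_end <- map$pos[hi]
  }
  # the shared haplotype across the run, read off the best window's haplotype
  # extended over the merged run: all qualifying windows agree marker-wise, so
  # any case homozygote spans it; recover from window haplotypes.
  risk <- rep(NA_integer_, hi - lo + 1L)
  for (i in which(qual)) {
    if (scan$chrom[i] != run$chrom) next
    f <- scan$first_marker_index[i]
    if (f < lo || f + w - 1L > hi) next
    risk[(f - lo + 1L):(f - lo + w)] <- as.integer(strsplit(scan$haplotype[i], "")[[1L]])
  }
  structure(list(chrom = run$chrom,
                 run_start_pos = map$pos[lo], run_end_pos = map$pos[hi],
                 n_markers = hi - lo + 1L,
                 interval_start = interval_start, interval_end = interval_end,
                 marker_index = lo:hi,
                 risk_haplotype = risk,
                 n_tests = attr(scan, "n_tests"),
                 bonferroni_threshold = attr(scan, "bonferroni_threshold"),
                 map = map),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("Merged haplotype: %d markers, %s:%s-%s bp\n", x$n_markers,
              x$chrom, format(x$run_start_pos, big.mark = ","),
              format(x$run_end_pos, big.mark = ",")))
  cat(sprintf("Mapping interval: %s:%s-%s bp (%.1f Mb)\n", x$chrom,
              format(x$interval_start, big.mark = ","),
              format(x$interval_end, big.mark = ","),
              (x$interval_end - x$interval_start) / 1e6))
  invisible(x)
}

#' Haplotype-based carrier status prediction
#'
#' Predicts allele dosage at the mapped locus for each individual as the
#' number of its two phased haplotypes identical to the risk haplotype over
#' the merged-run markers.
#'
#' @param genotypes A [phased_genotypes()] object covering the run markers.
#' @param mapping A `mapping_result` from [extract_interval()], or a list with
#'   elements `marker_index` (columns of `genotypes` after the same MAF
#'   filtering; use `map` rows) and `risk_haplotype`.
#' @return Named integer vector of dosages in \{0, 1, 2\}.
#' @export
predict_status <- function(genotypes, mapping) {
  stopifnot(inherits(genotypes, "phased_genotypes"))
  mk <- match(mapping$map$marker_id[mapping$marker_index],
              genotypes$map$marker_id)
  if (anyNA(mk)) stop("genotypes do not cover the merged-run markers")
  risk <- mapping$risk_haplotype
  m1 <- colSums(t(genotypes$h1[, mk, drop = FALSE]) == risk) == length(risk)
  m2 <- colSums(t(genotypes$h2[, mk, drop = FALSE]) == risk) == length(risk)
  out <- as.integer(m1) + as.integer(m2)
  names(out) <- genotypes$ids
  out
}
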