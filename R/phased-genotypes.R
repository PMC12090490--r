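#' Phased genotype container
#'
#' Holds two haplotype matrices (individuals x markers, alleles coded 0/1,
#' no missing values — the pipeline consumes phased, imputed data) and a
#' marker map sorted by (chrom, pos).
#'
#' @param h1,h2 Integer/numeric matrices of identical dimension, one row per
#'   individual, one column per marker, entries in \{0, 1\}.
#' @param map `data.frame` with columns `chrom`, `pos` (1-based bp) and
#'   optionally `marker_id`; one row per marker, sorted by (chrom, pos).
#' @param ids Individual identifiers (defaults to rownames of `h1` or
#'   `ind1..indN`).
#' @return An object of class `phased_genotypes` with elements `h1`, `h2`,
#'   `map` (with a `maf` column computed from the data), `ids`.
#' @export
phased_genotypes <- function(h1, h2, map, ids = NULL) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  stopifnot(identical(dim(h1), dim(h2)))
  if (anyNA(h1) || anyNA(h2))
    stop("missing phased genotypes are not permitted; phase/impute upstream")
  if (!all(h1 %in% c(0, 1)) || !all(h2 %in% c(0, 1)))
    stop("alleles must be biallelic, coded 0/1")
  stopifnot(is.data.frame(map), all(c("chrom", "pos") %in% names(map)),
            nrow(map) == ncol(h1))
  map$chrom <- as.character(map$chrom)
  o <- order(map$chrom, map$pos)
  if (!identical(o, seq_len(nrow(map)))) {
    map <- map[o, , drop = FALSE]
    h1 <- h1[, o, drop = FALSE]
    h2 <- h2[, o, drop = FALSE]
  }
  if (is.null(map$marker_id))
    map$marker_id <- paste0(map$chrom, "_", map$pos)
  if (is.null(ids)) ids <- rownames(h1)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(h1)))
  ids <- as.character(ids)
  stopifnot(length(ids) == nrow(h1), !anyDuplicated(ids))
  dimnames(h1) <- dimnames(h2) <- NULL
  p <- (colSums(h1) + colSums(h2)) / (2 * nrow(h1))
  map$maf <- pmin(p, 1 - p)
  rownames(map) <- NULL
  structure(list(h1 = h1, h2 = h2, map = map, ids = ids),
            class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("Phased genotypes:", length(x$ids), "individuals x", nrow(x$map),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Subset a phased genotype set
#'
#' @param x A `phased_genotypes` object.
#' @param individuals Ids to keep (default all).
#' @param markers Logical or integer index over markers (default all).
#' @return A `phased_genotypes` object.
#' @export
subset_genotypes <- function(x, individuals = NULL, markers = NULL) {
  stopifnot(inherits(x, "phased_genotypes"))
  ri <- if (is.null(individuals)) seq_along(x$ids) else match(as.character(individuals), x$ids)
  if (anyNA(ri)) stop("unknown individuals requested")
  ci <- if (is.null(markers)) seq_len(nrow(x$map)) else markers
  phased_genotypes(x$h1[ri, ci, drop = FALSE], x$h2[ri, ci, drop = FALSE],
                   x$map[ci, c("chrom", "pos", "marker_id"), drop = FALSE],
                   ids = x$ids[ri])
}

#' Allele dosage matrix (0/1/2) from phased genotypes
#'
#' @param x A `phased_genotypes` object.
#' @return Numeric matrix individuals x markers with dimnames.
#' @export
dosage_matrix <- function(x) {
  stopifnot(inherits(x, "phased_genotypes"))
  d <- x$h1 + x$h2
  dimnames(d) <- list(x$ids, x$map$marker_id)
  d
}
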