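#' Write phased genotypes as PLINK-style PED/MAP text files
#'
#' The PED file carries two allele columns per marker (the two phased
#' haplotypes, coded 1/2 for alleles 0/1); the MAP file has chromosome, marker
#' id, a zero genetic-distance column and the 1-based bp position.
#'
#' @param genotypes A [phased_genotypes()] object.
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The two paths, invisibly.
#' @export
write_ped_map <- function(genotypes, prefix) {
  stopifnot(inherits(genotypes, "phased_genotypes"))
  map <- genotypes$map
  utils::write.table(
    data.frame(map$chrom, map$marker_id, 0, map$pos),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  n <- length(genotypes$ids); m <- nrow(map)
  alleles <- matrix("", n, 2 * m)
  alleles[, seq(1, 2 * m, 2)] <- as.character(genotypes$h1 + 1L)
  alleles[, seq(2, 2 * m, 2)] <- as.character(genotypes$h2 + 1L)
  ped <- cbind("FAM", genotypes$ids, "0", "0", "0", "-9", alleles)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".ped", ".map")))
}

#' Read phased genotypes from PLINK-style PED/MAP text files
#'
#' Expects the layout written by [write_ped_map()]: two allele columns per
#' marker, first allele column = first haplotype. Allele codes 1/2 map to 0/1.
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return A [phased_genotypes()] object.
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), stringsAsFactors = FALSE,
                           col.names = c("chrom", "marker_id", "cm", "pos"))
  ped <- utils::read.table(paste0(prefix, ".ped"), stringsAsFactors = FALSE)
  ids <- as.character(ped[[2]])
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  if (ncol(al) != 2 * nrow(map)) stop("PED/MAP marker counts disagree")
  h1 <- matrix(as.integer(al[, seq(1, ncol(al), 2)]) - 1L, nrow(al))
  h2 <- matrix(as.integer(al[, seq(2, ncol(al), 2)]) - 1L, nrow(al))
  phased_genotypes(h1, h2, map[, c("chrom", "pos", "marker_id")], ids = ids)
}

#' Write phased genotypes as a minimal phased VCF
#'
#' Alleles 0/1 become REF `A` / ALT `B` placeholders unless the map carries
#' `ref`/`alt` columns; genotypes use the phased separator `|`.
#'
#' @param genotypes A [phased_genotypes()] object.
#' @param path Output `.vcf` path (uncompressed text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "phased_genotypes"))
  map <- genotypes$map
  ref <- if (is.null(map$ref)) rep("A", nrow(map)) else map$ref
  alt <- if (is.null(map$alt)) rep("B", nrow(map)) else map$alt
  gt <- matrix(paste0(t(genotypes$h1), "|", t(genotypes$h2)),
               nrow = nrow(map))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", genotypes$ids), collapse = "\t"))
  body <- paste(map$chrom, map$pos, map$marker_id, ref, alt, ".", ".", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phased genotypes from a VCF
#'
#' Uses vcfR for parsing. All GT fields must be phased (`|` separator) and
#' biallelic with no missing calls; anything else is rejected, since the
#' pipeline consumes phased, imputed data.
#'
#' @param path VCF path.
#' @return A [phased_genotypes()] object.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt) || any(!grepl("^[01]\\|[01]$", gt)))
    stop("VCF genotypes must be phased ('|'), biallelic and complete")
  h1 <- matrix(as.integer(substr(t(gt), 1, 1)), ncol(gt))
  h2 <- matrix(as.integer(substr(t(gt), 3, 3)), ncol(gt))
  fix <- vcfR::getFIX(v)
  map <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                    marker_id = fix[, "ID"], stringsAsFactors = FALSE)
  phased_genotypes(h1, h2, map, ids = colnames(gt))
}
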