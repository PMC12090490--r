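#' Gene model for isoform and ORF analysis
#'
#' A minimal spliced gene model: ordered, non-overlapping exons with their
#' sequences (already oriented 5' to 3') and the CDS boundaries in transcript
#' coordinates (1-based inclusive).
#'
#' @param exons `data.frame` with columns `start`, `end` (genomic, 1-based
#'   inclusive) and `sequence` (one DNA string per exon, length `end - start +
#'   1`).
#' @param cds_start,cds_end CDS boundaries in spliced-transcript coordinates;
#'   the CDS must begin with ATG and its length be a multiple of 3.
#' @param strand `"+"` or `"-"` (metadata only: sequences are supplied
#'   transcript-oriented).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(exons, cds_start, cds_end, strand = "+") {
  stopifnot(is.data.frame(exons),
            all(c("start", "end", "sequence") %in% names(exons)),
            strand %in% c("+", "-"))
  exons$sequence <- toupper(exons$sequence)
  stopifnot(all(exons$end >= exons$start),
            all(nchar(exons$sequence) == exons$end - exons$start + 1))
  if (nrow(exons) > 1) {
    stopifnot(all(diff(exons$start) > 0),
              all(exons$start[-1] > exons$end[-nrow(exons)]))
  }
  tx_len <- sum(nchar(exons$sequence))
  stopifnot(cds_start >= 1, cds_end <= tx_len, cds_end > cds_start,
            (cds_end - cds_start + 1) %% 3 == 0)
  tx <- paste(exons$sequence, collapse = "")
  if (substr(tx, cds_start, cds_start + 2) != "ATG")
    stop("no start codon at cds_start")
  structure(list(exons = exons, cds_start = cds_start, cds_end = cds_end,
                 strand = strand), class = "gene_model")
}

#' Assemble an isoform with an insertion at an exon junction
#'
#' Concatenates the model's exon sequences, splicing the given segment in
#' after exon `after_exon` (e.g. a cryptic exon or retained intron fragment).
#' The inserted segment is treated as an exon of its own, so it contributes
#' two exon-exon junctions. An empty insertion returns the reference spliced
#' isoform.
#'
#' @param model A [gene_model()].
#' @param insertion DNA string to insert (may be `""`).
#' @param after_exon Index of the exon after which to insert; required (and
#'   must be an internal junction, `1 <= after_exon < n_exons`) unless the
#'   insertion is empty.
#' @return Object of class `isoform`: list with `seq`, `junctions`
#'   (transcript positions of the last nucleotide of each exon except the
#'   last), `cds_start` (shifted if the insertion falls upstream of it),
#'   `insertion_length`, `insertion_position` (transcript position of the
#'   first inserted nucleotide, or `NA`).
#' @export
build_isoform <- function(model, insertion = "", after_exon = NULL) {
  stopifnot(inherits(model, "gene_model"))
  insertion <- toupper(insertion)
  seqs <- model$exons$sequence
  if (nzchar(insertion)) {
    if (is.null(after_exon) || after_exon < 1 || after_exon >= length(seqs))
      stop("insertion must be placed at an internal exon junction")
    seqs <- append(seqs, insertion, after = after_exon)
    ins_pos <- sum(nchar(model$exons$sequence[seq_len(after_exon)])) + 1L
  } else {
    ins_pos <- NA_integer_
  }
  lens <- nchar(seqs)
  junctions <- if (length(lens) > 1) cumsum(lens)[-length(lens)] else integer(0)
  cds_start <- model$cds_start
  if (!is.na(ins_pos) && ins_pos <= cds_start)
    cds_start <- cds_start + nchar(insertion)
  structure(list(seq = paste(seqs, collapse = ""),
                 junctions = junctions,
                 cds_start = cds_start,
                 insertion_length = nchar(insertion),
                 insertion_position = ins_pos),
            class = "isoform")
}

# translate a DNA string, returning the AA string (stops as "*")
translate_dna <- function(dna) {
  dna <- substr(dna, 1, 3 * (nchar(dna) %/% 3))
  if (!nchar(dna)) return("")
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(dna), no.init.codon = TRUE)))
}

#' ORF consequence of a mis-spliced isoform
#'
#' Translates the isoform from the reference start codon, locates the first
#' stop, and classifies the outcome: frameshift (inserted length not a
#' multiple of 3), premature termination codon (the protein terminates before
#' reaching the reference length), predicted nonsense-mediated decay (the PTC
#' lies at least `nmd_rule_nt` nucleotides upstream of the final exon-exon
#' junction — the canonical 50-nt rule), and the fraction of the reference
#' protein lost.
#'
#' @param model A [gene_model()] (supplies the reference protein length).
#' @param isoform An [build_isoform()] result.
#' @param nmd_rule_nt PTC-to-last-junction distance triggering NMD (default 50).
#' @return Object of class `isoform_consequence`: list with
#'   `inserted_length`, `insertion_position`, `frameshift`,
#'   `ptc_transcript_pos` (first nucleotide of the premature stop, or `NA`),
#'   `nmd_predicted`, `truncation_fraction`, `mutant_aa`, `reference_aa`.
#' @export
orf_consequence <- function(model, isoform, nmd_rule_nt = 50) {
  stopifnot(inherits(model, "gene_model"), inherits(isoform, "isoform"))
  ref <- build_isoform(model, "")
  ref_cds <- substr(ref$seq, model$cds_start, nchar(ref$seq))
  ref_aa_full <- translate_dna(ref_cds)
  ref_stop <- as.integer(regexpr("*", ref_aa_full, fixed = TRUE))
  ref_n <- if (ref_stop > 0) ref_stop - 1L else nchar(ref_aa_full)
  internal <- as.integer(
    regexpr("*", substr(ref_aa_full, 1,
                        (model$cds_end - model$cds_start + 1) %/% 3 - 1),
            fixed = TRUE))
  if (internal > 0) stop("reference CDS contains an internal stop codon")
  if (substr(isoform$seq, isoform$cds_start, isoform$cds_start + 2) != "ATG")
    stop("no start codon at the isoform CDS start")
  mut_aa_full <- translate_dna(substr(isoform$seq, isoform$cds_start,
                                      nchar(isoform$seq)))
  mut_stop <- as.integer(regexpr("*", mut_aa_full, fixed = TRUE))
  mut_n <- if (mut_stop > 0) mut_stop - 1L else nchar(mut_aa_full)
  ptc <- mut_stop > 0 && mut_n < ref_n
  ptc_pos <- if (mut_stop > 0)
    isoform$cds_start + 3L * (mut_stop - 1L) else NA_integer_
  nmd <- FALSE
  if (ptc && length(isoform$junctions)) {
    last_junction <- isoform$junctions[length(isoform$junctions)]
    nmd <- (last_junction - ptc_pos) >= nmd_rule_nt
  }
  structure(list(inserted_length = isoform$insertion_length,
                 insertion_position = isoform$insertion_position,
                 frameshift = isoform$insertion_length %% 3 != 0,
                 ptc_transcript_pos = if (ptc) ptc_pos else NA_integer_,
                 nmd_predicted = nmd,
                 truncation_fraction = max(0, 1 - mut_n / ref_n),
                 mutant_aa = mut_n, reference_aa = ref_n),
            class = "isoform_consequence")
}

#' @export
print.isoform_consequence <- function(x, ...) {
  cat(sprintf("Insertion: %d bp at transcript position %s; frameshift: %s\n",
              x$inserted_length,
              ifelse(is.na(x$insertion_position), "-", x$insertion_position),
              x$frameshift))
  if (!is.na(x$ptc_transcript_pos))
    cat(sprintf("PTC at transcript position %d; NMD predicted: %s\n",
                x$ptc_transcript_pos, x$nmd_predicted))
  cat(sprintf("Protein: %d of %d reference AAs retained (%.1f%% truncated)\n",
              x$mutant_aa, x$reference_aa, 100 * x$truncation_fraction))
  invisible(x)
}

#' Scan a sequence with an exonic-splicing-enhancer PSSM
#'
#' Additive per-position scoring (no background correction): the score at an
#' offset is the sum over motif positions of the matrix entry for the observed
#' base. Matrices are user-supplied configuration (e.g. SR-protein motif
#' models); none are authoritative here.
#'
#' @param sequence DNA string.
#' @param pssm Numeric matrix, rownames `A`, `C`, `G`, `T`, one column per
#'   motif position.
#' @param threshold Report sites scoring at least this (default `-Inf`: all).
#' @return `data.frame` with `offset` (1-based), `site` and `score`, empty
#'   when the sequence is shorter than the motif.
#' @export
ese_scan <- function(sequence, pssm, threshold = -Inf) {
  stopifnot(is.matrix(pssm), !is.null(rownames(pssm)))
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% rownames(pssm)))
    stop("sequence alphabet not covered by the PSSM rows")
  w <- ncol(pssm); L <- length(bases)
  if (L < w)
    return(data.frame(offset = integer(), site = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  offsets <- seq_len(L - w + 1)
  ri <- match(bases, rownames(pssm))
  scores <- vapply(offsets, function(o)
    sum(pssm[cbind(ri[o:(o + w - 1)], seq_len(w))]), numeric(1))
  keep <- scores >= threshold
  data.frame(offset = offsets[keep],
             site = substring(sequence, offsets[keep], offsets[keep] + w - 1),
             score = scores[keep], stringsAsFactors = FALSE)
}

#' Per-site PSSM score change between two alleles
#'
#' Scores two same-length allelic sequences with [ese_scan()] and reports the
#' per-offset score difference (alt minus ref); swapping the alleles flips the
#' sign of every delta.
#'
#' @param seq_ref,seq_alt Equal-length DNA strings.
#' @param pssm As in [ese_scan()].
#' @return `data.frame` with `offset`, `score_ref`, `score_alt`, `delta`.
#' @export
ese_allelic_delta <- function(seq_ref, seq_alt, pssm) {
  stopifnot(nchar(seq_ref) == nchar(seq_alt))
  a <- ese_scan(seq_ref, pssm)
  b <- ese_scan(seq_alt, pssm)
  data.frame(offset = a$offset, score_ref = a$score, score_alt = b$score,
             delta = b$score - a$score)
}
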