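#' Staged candidate-variant filtering
#'
#' Applies, in order, the three criteria that isolate a recessive candidate
#' among variants called in sequenced cases: (i) located within the mapping
#' interval, (ii) homozygous for the alternate allele in every sequenced case
#' (a missing case genotype fails this stage), (iii) absent from the
#' within-breed control panel and then from the multi-breed panel
#' ("not segregating at all": any presence flag excludes the variant).
#'
#' @param variants `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, optionally `type`, one genotype column per sequenced case (values
#'   `hom_ref`, `het`, `hom_alt`, `missing`), and logical/0-1 columns
#'   `present_in_breed_controls`, `present_in_other_breeds`.
#' @param interval List or vector `(chrom, start, end)`, 1-based inclusive.
#' @param case_cols Names of the case genotype columns.
#' @return Object of class `filter_trace`: list with the per-stage counts
#'   `n_input`, `n_in_interval`, `n_hom_all_cases`, `n_after_breed_controls`,
#'   `n_after_all_controls`, `survivors` (data frame of surviving rows),
#'   `survivor_keys` (chrom:pos_ref>alt strings) and `by_type` (surviving
#'   counts per variant type, when a `type` column is present).
#' @export
filter_candidates <- function(variants, interval, case_cols) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt",
                  "present_in_breed_controls", "present_in_other_breeds",
                  case_cols) %in% c(names(variants), case_cols)))
  if (!all(case_cols %in% names(variants)))
    stop("case genotype columns absent: ",
         paste(setdiff(case_cols, names(variants)), collapse = ", "))
  variants$pos <- as.integer(variants$pos)
  key <- with(variants, paste0(chrom, ":", pos, "_", ref, ">", alt))
  if (anyDuplicated(key)) stop("duplicated (chrom,pos,ref,alt) keys")
  chrom <- as.character(interval[[1]])
  start <- as.numeric(interval[[2]]); end <- as.numeric(interval[[3]])
  stopifnot(start <= end)
  v <- variants
  n_input <- nrow(v)
  v <- v[as.character(v$chrom) == chrom & v$pos >= start & v$pos <= end, , drop = FALSE]
  n_in_interval <- nrow(v)
  gt <- as.matrix(v[, case_cols, drop = FALSE])
  n_missing <- sum(rowSums(gt == "missing") > 0)
  if (n_missing) message(n_missing, " variant(s) with a missing case genotype fail stage (ii)")
  v <- v[rowSums(gt == "hom_alt") == length(case_cols), , drop = FALSE]
  n_hom_all_cases <- nrow(v)
  v <- v[!as.logical(v$present_in_breed_controls), , drop = FALSE]
  n_after_breed <- nrow(v)
  v <- v[!as.logical(v$present_in_other_breeds), , drop = FALSE]
  n_after_all <- nrow(v)
  by_type <- if ("type" %in% names(v)) table(v$type) else NULL
  structure(list(n_input = n_input,
                 n_in_interval = n_in_interval,
                 n_hom_all_cases = n_hom_all_cases,
                 n_after_breed_controls = n_after_breed,
                 n_after_all_controls = n_after_all,
                 survivors = v,
                 survivor_keys = with(v, paste0(chrom, ":", pos, "_", ref, ">", alt)),
                 by_type = by_type),
            class = "filter_trace")
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("Candidate variant filtering:\n")
  cat(sprintf("  input variants:             %d\n", x$n_input))
  cat(sprintf("  (i)   in mapping interval:  %d\n", x$n_in_interval))
  cat(sprintf("  (ii)  hom-alt in all cases: %d\n", x$n_hom_all_cases))
  cat(sprintf("  (iii) absent in breed panel:%d\n", x$n_after_breed_controls))
  cat(sprintf("        absent in all panels: %d\n", x$n_after_all_controls))
  if (length(x$survivor_keys))
    cat("  survivors:", paste(x$survivor_keys, collapse = ", "), "\n")
  invisible(x)
}

#' Read a variant table with control-panel presence flags
#'
#' Reads a TSV in the supplementary-table dialect: one row per variant with
#' `chrom`, `pos`, `ref`, `alt`, case genotype columns, and control-presence
#' flag columns (any column name containing `present_in` is normalised; the
#' within-breed flag is the one also containing `breed_controls` or matching
#' `breed_flag`).
#'
#' @param path TSV path.
#' @param breed_flag,panel_flag Column names of the within-breed and
#'   multi-breed presence flags.
#' @return A `data.frame` with normalised flag columns
#'   `present_in_breed_controls`, `present_in_other_breeds`.
#' @export
read_variant_table <- function(path,
                               breed_flag = "present_in_breed_controls",
                               panel_flag = "present_in_other_breeds") {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!breed_flag %in% names(v) || !panel_flag %in% names(v))
    stop("flag columns not found: ", breed_flag, ", ", panel_flag)
  names(v)[names(v) == breed_flag] <- "present_in_breed_controls"
  names(v)[names(v) == panel_flag] <- "present_in_other_breeds"
  for (f in c("present_in_breed_controls", "present_in_other_breeds"))
    v[[f]] <- v[[f]] %in% c(TRUE, "TRUE", "yes", "Yes", "Y", 1, "1")
  v
}

#' Consensus structural variants across callers
#'
#' Keeps SV calls supported by at least two tools: two calls support each
#' other when they come from different tools, the same individual, the same
#' type, and show reciprocal overlap of at least `min_overlap` (the overlap
#' length divided by each interval's own length must reach the threshold for
#' both intervals).
#'
#' @param calls `data.frame` with columns `tool`, `individual`, `chrom`,
#'   `start`, `end`, `type` (1-based inclusive coordinates). Zero- or
#'   negative-length calls are rejected.
#' @param min_overlap Reciprocal overlap threshold (default 0.70).
#' @return The supported subset of `calls` with an added `cluster` id grouping
#'   mutually supporting calls.
#' @export
sv_concordance <- function(calls, min_overlap = 0.70) {
  need <- c("tool", "individual", "chrom", "start", "end", "type")
  stopifnot(is.data.frame(calls), all(need %in% names(calls)))
  len <- calls$end - calls$start + 1
  if (any(len <= 0)) stop("zero-length SV call(s): rows ",
                          paste(which(len <= 0), collapse = ", "))
  n <- nrow(calls)
  supported <- logical(n)
  cluster <- seq_len(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (calls$tool[i] == calls$tool[j]) next
      if (calls$individual[i] != calls$individual[j]) next
      if (calls$type[i] != calls$type[j]) next
      if (as.character(calls$chrom[i]) != as.character(calls$chrom[j])) next
      ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j]) + 1
      if (ov <= 0) next
      if (ov / len[i] >= min_overlap && ov / len[j] >= min_overlap) {
        supported[i] <- supported[j] <- TRUE
        cluster[cluster == cluster[j]] <- cluster[i]
      }
    }
  }
  out <- calls[supported, , drop = FALSE]
  out$cluster <- match(cluster[supported], unique(cluster[supported]))
  rownames(out) <- NULL
  out
}
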