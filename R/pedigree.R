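#' Read a pedigree from CSV
#'
#' Reads a pedigree file with columns `id`, `sire`, `dam` and optionally
#' `sex` and `birth_year`. Unknown parents are coded `0`, `NA` or the empty
#' string and are normalised to `NA`.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` validated by [as_pedigree()].
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_pedigree(ped)
}

#' Write a pedigree to CSV
#'
#' @param pedigree A pedigree `data.frame` (see [as_pedigree()]).
#' @param path Output file path. Unknown parents are written as `0`.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  ped <- as_pedigree(pedigree)
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a pedigree data frame
#'
#' Checks the schema (id/sire/dam present, ids unique), normalises unknown
#' parent codes (`0`, `""`, `NA`) to `NA`, verifies that every recorded parent
#' exists in the pedigree and that the parentage graph is acyclic (no
#' individual is its own ancestor).
#'
#' @param pedigree A `data.frame` with at least columns `id`, `sire`, `dam`.
#' @return The validated pedigree with character ids, class `c("pedigree",
#'   "data.frame")`, and a topological order stored in attribute `"topo"`.
#' @export
as_pedigree <- function(pedigree) {
  stopifnot(is.data.frame(pedigree))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(pedigree)))
    stop("pedigree must have columns id, sire, dam")
  ped <- pedigree
  for (col in need) {
    v <- as.character(ped[[col]])
    v[v %in% c("0", "") | is.na(v)] <- NA
    ped[[col]] <- v
  }
  if (anyNA(ped$id)) stop("missing individual ids in pedigree")
  if (anyDuplicated(ped$id)) stop("duplicated individual ids in pedigree")
  for (col in c("sire", "dam")) {
    known <- !is.na(ped[[col]])
    bad <- setdiff(ped[[col]][known], ped$id)
    if (length(bad))
      stop("parents absent from pedigree: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  attr(ped, "topo") <- ped_topo_order(ped)
  class(ped) <- unique(c("pedigree", class(ped)))
  ped
}

# Kahn topological sort over the parent -> offspring DAG; errors on cycles.
ped_topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- idx[ped$sire]; di <- idx[ped$dam]   # NA for unknown
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != n)
    stop("pedigree contains a cycle (an individual is its own ancestor)")
  order
}

#' All known ancestors of an individual
#'
#' Transitive closure over recorded parents; the individual itself is not
#' included. A founder (both parents unknown) has an empty ancestor set.
#'
#' @param id Individual identifier (must be present in the pedigree).
#' @param pedigree A pedigree accepted by [as_pedigree()].
#' @return Character vector of ancestor ids (unordered, no duplicates).
#' @export
ancestor_set <- function(id, pedigree) {
  ped <- as_pedigree(pedigree)
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  id <- as.character(id)
  if (!id %in% ped$id) stop("unknown individual: ", id)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  seen <- logical(nrow(ped))
  stack <- c(si[idx[id]], di[idx[id]])
  stack <- stack[!is.na(stack)]
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    for (p in c(si[v], di[v])) if (!is.na(p) && !seen[p]) stack <- c(stack, p)
  }
  ped$id[seen]
}

#' Ancestors common to both parental lineages of cases
#'
#' For each candidate ancestor, counts the cases for which it appears in the
#' ancestry (including as parent) of both the sire and the dam — the signature
#' of an inbreeding loop through that ancestor, as expected for a recessive
#' defect. Cases without both parents recorded are excluded with a message.
#'
#' @param case_ids Character vector of case identifiers.
#' @param pedigree A pedigree accepted by [as_pedigree()].
#' @return A `data.frame` with columns `ancestor` and `n_cases`, sorted by
#'   decreasing `n_cases`; zero rows if no ancestor is shared by any case's
#'   two parental lineages.
#' @export
common_ancestors <- function(case_ids, pedigree) {
  ped <- as_pedigree(pedigree)
  case_ids <- as.character(case_ids)
  missing <- setdiff(case_ids, ped$id)
  if (length(missing)) stop("cases absent from pedigree: ", paste(missing, collapse = ", "))
  rows <- match(case_ids, ped$id)
  usable <- !is.na(ped$sire[rows]) & !is.na(ped$dam[rows])
  if (any(!usable))
    message("excluding ", sum(!usable), " case(s) without both parents recorded")
  counts <- new.env(parent = emptyenv())
  for (i in rows[usable]) {
    sire <- ped$sire[i]; dam <- ped$dam[i]
    side_s <- c(sire, ancestor_set(sire, ped))
    side_d <- c(dam, ancestor_set(dam, ped))
    for (anc in intersect(side_s, side_d)) {
      counts[[anc]] <- (if (is.null(counts[[anc]])) 0L else counts[[anc]]) + 1L
    }
  }
  anc <- ls(counts)
  out <- data.frame(ancestor = anc,
                    n_cases = vapply(anc, function(a) counts[[a]], integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$n_cases, out$ancestor), , drop = FALSE]
}

# Per-individual expected contribution of `ancestor`: c(ancestor) = 1,
# c(i) = (c(sire) + c(dam))/2, unknown parents contributing 0. Computed in one
# topological pass (exact, no recursion depth limit).
ped_contribution_vector <- function(ancestor, ped) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  si <- idx[ped$sire]; di <- idx[ped$dam]
  cv <- numeric(nrow(ped))
  a <- idx[[ancestor]]
  for (v in attr(ped, "topo")) {
    if (v == a) { cv[v] <- 1; next }
    cs <- if (is.na(si[v])) 0 else cv[si[v]]
    cd <- if (is.na(di[v])) 0 else cv[di[v]]
    cv[v] <- (cs + cd) / 2
  }
  names(cv) <- ped$id
  cv
}

#' Expected genetic contribution of an ancestor to a population
#'
#' The expected proportion of the autosomal genome of the population that
#' descends from `ancestor` ("probability of gene origin" semantics): the mean
#' over population members of c(i), where c(ancestor) = 1 and otherwise
#' c(i) = (c(sire) + c(dam))/2 with an unknown parent contributing 0.
#'
#' @param ancestor Ancestor identifier.
#' @param population Character vector of population member ids (non-empty).
#' @param pedigree A pedigree accepted by [as_pedigree()].
#' @return A single number in \\[0, 1\\].
#' @export
genetic_contribution <- function(ancestor, population, pedigree) {
  ped <- as_pedigree(pedigree)
  ancestor <- as.character(ancestor)
  population <- as.character(population)
  if (!length(population)) stop("empty population")
  if (!ancestor %in% ped$id) stop("unknown ancestor: ", ancestor)
  missing <- setdiff(population, ped$id)
  if (length(missing)) stop("population members absent from pedigree: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  cv <- ped_contribution_vector(ancestor, ped)
  mean(cv[population])
}

#' Build a case/control contribution report for one ancestor
#'
#' @param ancestor Ancestor identifier (label only).
#' @param contrib_cases,contrib_controls Contributions in \\[0, 1\\].
#' @return A one-row `data.frame` with columns `ancestor`, `contrib_cases`,
#'   `contrib_controls`, `ratio`. `ratio` is `NA` (with a warning) when the
#'   control contribution is zero.
#' @export
contribution_report <- function(ancestor, contrib_cases, contrib_controls) {
  stopifnot(contrib_cases >= 0, contrib_cases <= 1,
            contrib_controls >= 0, contrib_controls <= 1)
  ratio <- if (contrib_controls > 0) contrib_cases / contrib_controls else NA_real_
  if (is.na(ratio)) warning("zero control contribution: ratio undefined for ", ancestor)
  data.frame(ancestor = as.character(ancestor),
             contrib_cases = contrib_cases,
             contrib_controls = contrib_controls,
             ratio = ratio, stringsAsFactors = FALSE)
}

#' Case/control contribution ratio of an ancestor
#'
#' Computes the ancestor's expected genetic contribution to the case and
#' control populations and their ratio, the statistic used to flag the
#' putative founder of a recessive defect.
#'
#' @inheritParams genetic_contribution
#' @param cases,controls Character vectors of case and control ids.
#' @return A one-row `data.frame`; see [contribution_report()].
#' @export
contribution_ratio <- function(ancestor, cases, controls, pedigree) {
  contribution_report(ancestor,
                      genetic_contribution(ancestor, cases, pedigree),
                      genetic_contribution(ancestor, controls, pedigree))
}

#' Rank ancestors by case/control contribution ratio
#'
#' Contribution reports for every candidate ancestor whose contribution
#' reaches `floor` in both populations (the reporting floor; contributions
#' themselves are unaffected). Also returns the mean and SD of the ratio over
#' qualifying ancestors as attributes `"ratio_mean"` and `"ratio_sd"`.
#'
#' @inheritParams contribution_ratio
#' @param ancestors Candidate ancestor ids; defaults to every individual that
#'   appears as a parent in the pedigree.
#' @param floor Minimum contribution in both populations (default 0.01).
#' @return A `data.frame` of qualifying reports sorted by decreasing ratio.
#' @export
rank_contributions <- function(cases, controls, pedigree,
                               ancestors = NULL, floor = 0.01) {
  ped <- as_pedigree(pedigree)
  if (is.null(ancestors))
    ancestors <- unique(stats::na.omit(c(ped$sire, ped$dam)))
  rows <- lapply(ancestors, function(a) contribution_ratio(a, cases, controls, ped))
  out <- do.call(rbind, rows)
  out <- out[out$contrib_cases >= floor & out$contrib_controls >= floor, , drop = FALSE]
  out <- out[order(-out$ratio), , drop = FALSE]
  attr(out, "ratio_mean") <- mean(out$ratio)
  attr(out, "ratio_sd") <- stats::sd(out$ratio)
  rownames(out) <- NULL
  out
}
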