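#' Best-score arbitration of read placements
#'
#' The core filtering rule: per fragment, only the placements achieving the
#' maximum alignment score are considered, and a fragment is counted
#' towards TE expression only when that best-scoring set touches TE
#' consensus sequences exclusively. A fragment whose best set includes any
#' annotated non-TE sequence (coding, non-coding, or mask) is either
#' discarded as ambiguous (best set mixes TE and non-TE) or classified as
#' non-TE (best set is non-TE only) -- either way it never contributes to
#' TE counts, which is what suppresses exonized TE fragments embedded in
#' canonical transcripts.
#'
#' @name selector
NULL

FRAGMENT_STATUSES <- c("TE_SPECIFIC", "DISCARDED_AMBIGUOUS", "NON_TE",
                       "UNMAPPED")

#' Select the best-scoring placements of a fragment
#'
#' @param frag a `FragmentAlignments` object or a placements `data.table`
#'   with a `score` column.
#' @return the subset of placements whose score equals the maximum; empty
#'   input yields an empty table.
#' @export
select_best <- function(frag) {
  pl <- if (inherits(frag, "FragmentAlignments")) frag$placements else frag
  if (!nrow(pl)) return(pl)
  pl[pl$score == max(pl$score), ]
}

#' Resolve a multi-TE best set into assignment weights
#'
#' Policy for fragments whose best-scoring set spans several distinct TE
#' consensus sequences (all at equal score). `fractional` (default) splits
#' unit weight uniformly over the k distinct TE ids; `first_id` assigns the
#' whole fragment to the lexicographically smallest id. Distinct-id
#' collapse happens first: multiple placements on the same TE count once.
#'
#' @param best_te_placements a placements table restricted to TE
#'   placements, or a character vector of TE ids.
#' @param policy `"fractional"` or `"first_id"`.
#' @return `data.frame` with columns `te_id`, `weight`; weights sum to 1.
#' @export
resolve_multi_te <- function(best_te_placements,
                             policy = c("fractional", "first_id")) {
  policy <- match.arg(policy)
  ids <- if (is.character(best_te_placements)) best_te_placements
         else best_te_placements$ref_id
  ids <- sort(unique(ids))
  if (!length(ids)) stop("no TE placements to resolve", call. = FALSE)
  if (policy == "first_id") {
    data.frame(te_id = ids[1L], weight = 1, stringsAsFactors = FALSE)
  } else {
    data.frame(te_id = ids, weight = rep(1 / length(ids), length(ids)),
               stringsAsFactors = FALSE)
  }
}

empty_assignment <- function() {
  data.frame(te_id = character(0), weight = numeric(0),
             stringsAsFactors = FALSE)
}

#' Classify a fragment from its best-scoring placement set
#'
#' Implements the discard rule: an empty best set is `UNMAPPED`; a best set
#' with only non-TE categories (`CODING`/`NONCODING`/`MASK`) is `NON_TE`;
#' a best set mixing TE and non-TE categories is `DISCARDED_AMBIGUOUS`;
#' a best set with only TE categories is `TE_SPECIFIC` and is assigned to
#' TE id(s) per [resolve_multi_te()].
#'
#' @param best best-scoring placements as returned by [select_best()].
#' @param categories named character vector mapping every reference id to
#'   its category (see [ref_categories()]).
#' @param policy multi-TE assignment policy.
#' @param read_id identifier carried through to the result.
#' @return an object of class `FragmentAssignment`: list with `read_id`,
#'   `status`, `assigned` (te_id/weight table, empty unless TE-specific)
#'   and `best_score` (`NA` when unmapped).
#' @export
classify <- function(best, categories, policy = c("fractional", "first_id"),
                     read_id = "fragment") {
  policy <- match.arg(policy)
  if (inherits(best, "FragmentAlignments")) best <- select_best(best)
  if (!nrow(best)) {
    return(new_assignment(read_id, "UNMAPPED", empty_assignment(), NA_integer_))
  }
  cats <- categories[best$ref_id]
  if (anyNA(cats)) {
    stop(sprintf("unknown reference id '%s'",
                 best$ref_id[which(is.na(cats))[1L]]), call. = FALSE)
  }
  has_te <- any(cats == "TE")
  has_nonte <- any(cats != "TE")
  bs <- max(best$score)
  if (has_te && has_nonte) {
    new_assignment(read_id, "DISCARDED_AMBIGUOUS", empty_assignment(), bs)
  } else if (!has_te) {
    new_assignment(read_id, "NON_TE", empty_assignment(), bs)
  } else {
    new_assignment(read_id, "TE_SPECIFIC",
                   resolve_multi_te(best$ref_id[cats == "TE"], policy), bs)
  }
}

new_assignment <- function(read_id, status, assigned, best_score) {
  stopifnot(status %in% FRAGMENT_STATUSES)
  structure(list(read_id = read_id, status = status, assigned = assigned,
                 best_score = best_score),
            class = "FragmentAssignment")
}

#' @export
print.FragmentAssignment <- function(x, ...) {
  cat(sprintf("FragmentAssignment '%s': %s (best score %s)\n", x$read_id,
              x$status, format(x$best_score)))
  if (nrow(x$assigned)) {
    cat(paste(sprintf("  %s: %.6g", x$assigned$te_id, x$assigned$weight),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Classify a batch of fragments (vectorised pipeline path)
#'
#' Applies [select_best()] + [classify()] semantics to a whole placement
#' table at once. Fragments absent from the table are `UNMAPPED`.
#'
#' @param placements placement table as returned by [align_reads()] (or the
#'   paired variant); must carry `read`, `ref_id`, `category`, `score`.
#' @param n_fragments total number of fragments processed (defines which
#'   `read` indices exist).
#' @param read_ids optional character vector of fragment names.
#' @param policy multi-TE assignment policy.
#' @param strand_mode `"unstranded"` (default: placements on either strand
#'   are eligible) or `"sense"` (restrict to sense-orientation placements
#'   before best-score selection; for pairs, mate 1 on the `+` strand).
#' @return list with `assign` (`data.table`: `read`, `read_id`, `status`,
#'   `best_score`) and `weights` (`data.table`: `read`, `te_id`, `weight`
#'   for TE-specific fragments).
#' @export
classify_fragments <- function(placements, n_fragments, read_ids = NULL,
                               policy = c("fractional", "first_id"),
                               strand_mode = c("unstranded", "sense")) {
  policy <- match.arg(policy)
  strand_mode <- match.arg(strand_mode)
  if (is.null(read_ids)) read_ids <- sprintf("frag%d", seq_len(n_fragments))
  stopifnot(length(read_ids) == n_fragments)
  pl <- data.table::as.data.table(placements)
  if (strand_mode == "sense" && nrow(pl)) {
    scol <- if ("strand1" %in% names(pl)) "strand1" else "strand"
    pl <- pl[pl[[scol]] == "+"]
  }
  status <- rep("UNMAPPED", n_fragments)
  best_score <- rep(NA_integer_, n_fragments)
  weights <- data.table::data.table(read = integer(0), te_id = character(0),
                                    weight = numeric(0))
  if (nrow(pl)) {
    best <- pl[pl[, .I[score == max(score)], by = read]$V1]
    info <- best[, .(best_score = max(score),
                     n_te = length(unique(ref_id[category == "TE"])),
                     any_nonte = any(category != "TE")), by = read]
    st <- ifelse(info$n_te > 0L & info$any_nonte, "DISCARDED_AMBIGUOUS",
                 ifelse(info$n_te == 0L, "NON_TE", "TE_SPECIFIC"))
    status[info$read] <- st
    best_score[info$read] <- info$best_score
    te_reads <- info$read[st == "TE_SPECIFIC"]
    if (length(te_reads)) {
      tb <- unique(best[category == "TE" & read %in% te_reads,
                        .(read, te_id = ref_id)])
      data.table::setorder(tb, read, te_id)
      if (policy == "first_id") {
        tb <- tb[, .SD[1L], by = read]
        tb[, weight := 1]
      } else {
        tb[, weight := 1 / .N, by = read]
      }
      weights <- tb
    }
  }
  list(assign = data.table::data.table(read = seq_len(n_fragments),
                                       read_id = read_ids, status = status,
                                       best_score = best_score),
       weights = weights)
}
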