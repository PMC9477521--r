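#' Per-consensus count tables
#'
#' A `CountTable` aggregates fragment assignments into per-TE-consensus
#' fragment counts plus the run's totals partition:
#' `fragments_total = unmapped + non_te + discarded_ambiguous +
#' te_specific`, and the TE counts sum to `te_specific` (fractional counts
#' arise under the fractional multi-TE policy). Every TE id of the
#' reference appears (zero-filled); non-TE ids never do.
#'
#' @name CountTable
NULL

new_count_table <- function(counts, totals, cpm = NULL) {
  structure(list(counts = counts, totals = totals, cpm = cpm),
            class = "CountTable")
}

# internal fast path shared by count_fragments() and the pipeline
tally_assignments <- function(status, weights, ids) {
  stopifnot(length(ids) >= 1L)
  bad <- setdiff(weights$te_id, ids)
  if (length(bad)) {
    stop(sprintf("assignment names unknown TE id '%s'", bad[1L]),
         call. = FALSE)
  }
  counts <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(weights)) {
    agg <- weights[, .(weight = sum(weight)), by = te_id]
    counts[agg$te_id] <- agg$weight
  }
  totals <- as.numeric(c(
    fragments_total = length(status),
    unmapped = sum(status == "UNMAPPED"),
    non_te = sum(status == "NON_TE"),
    discarded_ambiguous = sum(status == "DISCARDED_AMBIGUOUS"),
    te_specific = sum(status == "TE_SPECIFIC")))
  names(totals) <- c("fragments_total", "unmapped", "non_te",
                     "discarded_ambiguous", "te_specific")
  new_count_table(counts, totals)
}

#' Count TE-specific fragments
#'
#' Aggregates a collection of [classify()] verdicts into a `CountTable`.
#'
#' @param assignments list of `FragmentAssignment` objects (order
#'   irrelevant; counting is associative).
#' @param ids character vector of all TE ids in the reference, in reporting
#'   order (see [te_ids()]).
#' @return a `CountTable`.
#' @export
count_fragments <- function(assignments, ids) {
  stopifnot(all(vapply(assignments, inherits, TRUE, "FragmentAssignment")))
  status <- vapply(assignments, `[[`, "", "status")
  w <- data.table::rbindlist(lapply(assignments, function(a) {
    data.table::as.data.table(a$assigned)
  }))
  if (!nrow(w)) w <- data.table::data.table(te_id = character(0),
                                            weight = numeric(0))
  tally_assignments(status, w, ids)
}

#' Library-size normalisation (counts per million)
#'
#' Adds a CPM column alongside the raw counts:
#' `cpm[te] = counts[te] / denominator * 1e6`. The denominator is either
#' the TE-specific fragment count or all mapped fragments
#' (`te_specific + non_te + discarded_ambiguous`). Raw counts are the
#' default output of the pipeline; CPM is opt-in.
#'
#' @param table a `CountTable`.
#' @param denominator `"mapped_fragments"` (default) or `"te_specific"`.
#' @return the `CountTable` with its `cpm` field populated.
#' @export
normalize_cpm <- function(table,
                          denominator = c("mapped_fragments", "te_specific")) {
  stopifnot(inherits(table, "CountTable"))
  denominator <- match.arg(denominator)
  tot <- table$totals
  den <- if (denominator == "te_specific") tot[["te_specific"]]
         else tot[["te_specific"]] + tot[["non_te"]] +
              tot[["discarded_ambiguous"]]
  if (den <= 0) {
    stop("CPM denominator is zero; report raw counts only", call. = FALSE)
  }
  table$cpm <- table$counts / den * 1e6
  table
}

#' @export
print.CountTable <- function(x, ...) {
  cat(sprintf(
    "CountTable: %d TE(s); fragments %d = unmapped %d + non-TE %d + ambiguous %d + TE-specific %d\n",
    length(x$counts), x$totals[["fragments_total"]], x$totals[["unmapped"]],
    x$totals[["non_te"]], x$totals[["discarded_ambiguous"]],
    x$totals[["te_specific"]]))
  nz <- x$counts[x$counts > 0]
  if (length(nz)) {
    cat("top counts:\n")
    print(utils::head(sort(nz, decreasing = TRUE), 10L))
  }
  invisible(x)
}

# integer-valued counts print without a decimal point; fractional counts
# with 6 decimals
format_count <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, format(round(x), scientific = FALSE,
                                          trim = TRUE),
         sprintf("%.6f", x))
}

#' Write a count table to TSV
#'
#' Writes the per-TE counts (columns `te_id`, `count` and, when present,
#' `cpm`) in reference order, and optionally the totals partition as a
#' second two-column TSV.
#'
#' @param table a `CountTable`.
#' @param counts_path output path for the counts TSV.
#' @param totals_path optional output path for the totals TSV.
#' @return `counts_path`, invisibly.
#' @export
write_count_table <- function(table, counts_path, totals_path = NULL) {
  stopifnot(inherits(table, "CountTable"))
  df <- data.frame(te_id = names(table$counts),
                   count = format_count(table$counts),
                   stringsAsFactors = FALSE)
  if (!is.null(table$cpm)) df$cpm <- sprintf("%.6f", table$cpm)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(totals_path)) {
    utils::write.table(
      data.frame(metric = names(table$totals),
                 value = unname(table$totals)),
      totals_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(counts_path)
}
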