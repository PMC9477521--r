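#' Spearman rank correlation between truth and estimated counts
#'
#' Tie-corrected (average-rank) Spearman correlation between a simulated
#' truth table and an estimated count table over an identical set of TE
#' ids. Undefined (returned as `NA` with a warning) when either vector is
#' constant or fewer than 3 TEs are compared -- never coerced to 0.
#'
#' @param truth named numeric vector of simulated per-consensus counts.
#' @param estimated named numeric vector, or a [CountTable].
#' @return a single numeric value in `[-1, 1]`, or `NA` when undefined.
#' @export
spearman_rho <- function(truth, estimated) {
  if (inherits(estimated, "CountTable")) estimated <- estimated$counts
  if (!setequal(names(truth), names(estimated)) ||
      length(truth) != length(estimated)) {
    stop("truth and estimated tables must share an identical TE id set",
         call. = FALSE)
  }
  if (length(truth) < 3L) {
    stop("need at least 3 TEs to compute a rank correlation", call. = FALSE)
  }
  estimated <- estimated[names(truth)]
  if (length(unique(truth)) < 2L || length(unique(estimated)) < 2L) {
    warning("rank correlation undefined for a constant vector", call. = FALSE)
    return(NA_real_)
  }
  unname(stats::cor(truth, estimated, method = "spearman"))
}

#' Audit a count table for the null-expression experiment
#'
#' For a library simulated exclusively from canonical transcripts, every
#' positive TE count is a false positive. Returns the offenders; an empty
#' result is a pass.
#'
#' @param table a [CountTable].
#' @return `data.frame` with columns `te_id`, `count` for every TE with
#'   positive count mass.
#' @export
audit_null <- function(table) {
  stopifnot(inherits(table, "CountTable"))
  pos <- table$counts[table$counts > 0]
  data.frame(te_id = names(pos), count = unname(pos),
             stringsAsFactors = FALSE)
}

new_validation_report <- function(spearman_rho, n_te, n_nonzero_truth,
                                  false_positive_te, seed) {
  structure(list(spearman_rho = spearman_rho, n_te = n_te,
                 n_nonzero_truth = n_nonzero_truth,
                 false_positive_te = false_positive_te, seed = seed),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("Validation report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  truth recovery : Spearman rho = %s over %d TEs (%d with nonzero truth)\n",
              format(x$spearman_rho, digits = 4), x$n_te, x$n_nonzero_truth))
  if (nrow(x$false_positive_te)) {
    cat(sprintf("  exonization null: FAILED, %d TE(s) with positive counts\n",
                nrow(x$false_positive_te)))
  } else {
    cat("  exonization null: pass (all TE counts zero)\n")
  }
  invisible(x)
}

#' Write a validation report as TSV
#'
#' @param report a `ValidationReport`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  df <- data.frame(
    metric = c("spearman_rho", "n_te", "n_nonzero_truth",
               "n_false_positive_te"),
    value = c(report$spearman_rho, report$n_te, report$n_nonzero_truth,
              nrow(report$false_positive_te)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
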