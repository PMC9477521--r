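#' Alignment parameters
#'
#' Parameters of the built-in ungapped seed-and-extend aligner. Scoring is
#' match +1 / mismatch -1 (`N` on either side never matches and scores as a
#' mismatch); only full-length, gap-free placements are reported.
#'
#' The seed length actually used for a batch of reads is adapted downward
#' from `seed_len` when short reads make a 16-mer seed insufficient: a
#' placement at score `>= min_score_frac * L` has at most
#' `m = floor(L * (1 - min_score_frac) / 2)` mismatches and therefore
#' contains an exact match run of at least `ceiling((L - m) / (m + 1))`
#' bases; the effective seed is the minimum of `seed_len` and that bound
#' over the batch, which makes the reported placement set complete for
#' every placement above threshold.
#'
#' @param seed_len maximum exact-seed length (default 16).
#' @param min_score_frac minimum score as a fraction of read length
#'   (default 0.9); applied per mate for paired reads.
#' @param max_insert maximum outer span of a properly paired fragment
#'   (default 1000).
#' @return an object of class `AlignParams`.
#' @export
align_params <- function(seed_len = 16L, min_score_frac = 0.9,
                         max_insert = 1000L) {
  stopifnot(seed_len >= 4L, seed_len <= 31L,
            min_score_frac > 0, min_score_frac <= 1,
            max_insert >= 1L)
  structure(list(seed_len = as.integer(seed_len),
                 min_score_frac = min_score_frac,
                 max_insert = as.integer(max_insert)),
            class = "AlignParams")
}

validate_reads <- function(reads) {
  reads <- toupper(reads)
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    stop(sprintf("read %d contains characters outside {A,C,G,T,N}",
                 which(bad)[1L]), call. = FALSE)
  }
  reads
}

# smallest guaranteed exact-run length among placements above threshold
effective_seed_len <- function(read_lengths, params) {
  L <- read_lengths
  m <- floor(L * (1 - params$min_score_frac) / 2)
  g <- ceiling((L - m) / (m + 1))
  max(1L, min(params$seed_len, as.integer(min(g))))
}

empty_placements <- function() {
  data.table::data.table(
    read = integer(0), ref_id = character(0), category = character(0),
    start = integer(0), strand = character(0), score = integer(0),
    matches = integer(0), mismatches = integer(0))
}

#' Align a batch of reads against a reference set
#'
#' Returns every full-length ungapped placement scoring at least
#' `min_score_frac` times the read length, on either strand. The returned
#' set contains all placements above threshold (see [align_params()] for
#' the completeness argument), sorted by read, descending score, `ref_id`,
#' `start` for determinism.
#'
#' @param reads character vector of read sequences (`A,C,G,T,N`; lowercase
#'   folded). Every read must be at least `seed_len` bases long.
#' @param ref a [ReferenceSet].
#' @param params an `AlignParams` object.
#' @return a `data.table` with columns `read` (1-based index into `reads`),
#'   `ref_id`, `category`, `start` (0-based), `strand` (`+`/`-`), `score`,
#'   `matches`, `mismatches`.
#' @export
align_reads <- function(reads, ref, params = align_params()) {
  stopifnot(inherits(ref, "ReferenceSet"))
  if (!length(ref$id)) stop("reference set is empty", call. = FALSE)
  if (!length(reads)) return(empty_placements())
  reads <- validate_reads(reads)
  if (any(nchar(reads) < params$seed_len)) {
    stop(sprintf("read %d is shorter than the seed length (%d)",
                 which(nchar(reads) < params$seed_len)[1L], params$seed_len),
         call. = FALSE)
  }
  k <- effective_seed_len(nchar(reads), params)
  hits <- cpp_align_reads(reads, ref$seq, k, params$min_score_frac)
  dt <- data.table::data.table(
    read = hits$read, ref_id = ref$id[hits$ref],
    category = ref$category[hits$ref], start = hits$start,
    strand = c("+", "-")[hits$strand + 1L], score = hits$score,
    matches = hits$matches, mismatches = hits$mismatches)
  data.table::setorder(dt, read, -score, ref_id, start, strand)
  dt[]
}

#' Exhaustive alignment oracle
#'
#' Scores the read (and its reverse complement) at every feasible offset of
#' every reference sequence, ungapped, and returns all placements at or
#' above the score threshold. Quadratic; intended as an independent test
#' oracle for [align_reads()] on small references (total length <= 1e6).
#'
#' @inheritParams align_reads
#' @param read a single read sequence.
#' @return a `data.table` in the same format as [align_reads()] (with
#'   `read` fixed at 1).
#' @export
brute_force_align <- function(read, ref, params = align_params()) {
  stopifnot(inherits(ref, "ReferenceSet"), length(read) == 1L)
  if (sum(nchar(ref$seq)) > 1e6) {
    stop("brute_force_align is quadratic; total reference length > 1e6",
         call. = FALSE)
  }
  read <- validate_reads(read)
  L <- nchar(read)
  thr <- params$min_score_frac * L - 1e-9
  strands <- list(`+` = read, `-` = revcomp(read))
  out <- vector("list", 0L)
  for (i in seq_along(ref$id)) {
    rl <- nchar(ref$seq[i])
    if (rl < L) next
    rv <- utf8ToInt(ref$seq[i])
    for (st in names(strands)) {
      qv <- utf8ToInt(strands[[st]])
      q_ok <- qv != utf8ToInt("N")
      for (off in 0:(rl - L)) {
        seg <- rv[(off + 1L):(off + L)]
        m <- sum(seg == qv & q_ok)
        score <- 2L * m - L
        if (score >= thr) {
          out[[length(out) + 1L]] <- data.table::data.table(
            read = 1L, ref_id = ref$id[i], category = ref$category[i],
            start = off, strand = st, score = score, matches = m,
            mismatches = L - m)
        }
      }
    }
  }
  if (!length(out)) return(empty_placements())
  dt <- data.table::rbindlist(out)
  data.table::setorder(dt, read, -score, ref_id, start, strand)
  dt[]
}

# Pair per-mate placement tables into fragment placements: same reference,
# opposite strands, outer span <= max_insert. Combined score is the sum of
# the mate scores (arbitration judges the pair on the total).
pair_placements <- function(al1, al2, len1, len2, params) {
  if (!nrow(al1) || !nrow(al2)) return(empty_paired_placements())
  p <- merge(al1, al2, by = c("read", "ref_id", "category"),
             allow.cartesian = TRUE, suffixes = c("1", "2"))
  if (!nrow(p)) return(empty_paired_placements())
  p <- p[strand1 != strand2]
  if (!nrow(p)) return(empty_paired_placements())
  e1 <- p$start1 + len1[p$read]
  e2 <- p$start2 + len2[p$read]
  p[, span := pmax(e1, e2) - pmin(p$start1, p$start2)]
  p <- p[span <= params$max_insert]
  if (!nrow(p)) return(empty_paired_placements())
  p[, score := score1 + score2]
  data.table::setnames(p, c("score1", "score2"), c("score_mate1", "score_mate2"))
  data.table::setorder(p, read, -score, ref_id, start1, start2)
  p[]
}

empty_paired_placements <- function() {
  data.table::data.table(
    read = integer(0), ref_id = character(0), category = character(0),
    start1 = integer(0), strand1 = character(0),
    matches1 = integer(0), mismatches1 = integer(0),
    start2 = integer(0), strand2 = character(0),
    matches2 = integer(0), mismatches2 = integer(0),
    span = integer(0), score = integer(0),
    score_mate1 = integer(0), score_mate2 = integer(0))
}

#' Align one read or read pair
#'
#' Fragment-level wrapper around [align_reads()]. For pairs, both mates
#' must place on the same reference on opposite strands with an outer span
#' at most `max_insert`; the placement score is the sum of the mate scores.
#' A pair with only one placeable mate has no placements (it will be
#' classified unmapped).
#'
#' @param read_or_pair a single read sequence, or a character vector /
#'   list of two mate sequences.
#' @inheritParams align_reads
#' @param read_id identifier carried through to the result.
#' @return an object of class `FragmentAlignments`: a list with `read_id`,
#'   `paired` and a `placements` table.
#' @export
align_fragment <- function(read_or_pair, ref, params = align_params(),
                           read_id = "fragment") {
  read_or_pair <- unlist(read_or_pair, use.names = FALSE)
  if (!length(read_or_pair) %in% c(1L, 2L)) {
    stop("read_or_pair must hold one read or two mates", call. = FALSE)
  }
  paired <- length(read_or_pair) == 2L
  if (paired && any(is.na(read_or_pair) | !nchar(read_or_pair))) {
    stop("paired call with mates of unequal presence", call. = FALSE)
  }
  if (!paired) {
    pl <- align_reads(read_or_pair, ref, params)
  } else {
    al1 <- align_reads(read_or_pair[1L], ref, params)
    al2 <- align_reads(read_or_pair[2L], ref, params)
    pl <- pair_placements(al1, al2, nchar(read_or_pair[1L]),
                          nchar(read_or_pair[2L]), params)
  }
  structure(list(read_id = read_id, paired = paired, placements = pl),
            class = "FragmentAlignments")
}

#' @export
print.FragmentAlignments <- function(x, ...) {
  cat(sprintf("FragmentAlignments '%s' (%s): %d placement(s)\n", x$read_id,
              if (x$paired) "paired" else "single", nrow(x$placements)))
  if (nrow(x$placements)) print(x$placements)
  invisible(x)
}
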