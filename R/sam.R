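#' Ingest external alignments from a SAM file
#'
#' Production users substitute a real aligner for the built-in one by
#' aligning their library against the FASTA written by [write_reference()]
#' and feeding the alignments back as SAM. Only reference names, flag bits,
#' `POS` and the integer alignment-score tag (`AS:i:`, or another tag via
#' `score_tag`) are consumed; CIGAR strings are not interpreted beyond the
#' mapped/unmapped flag, and coordinates are converted from 1-based SAM to
#' the internal 0-based convention. Secondary alignments are kept: the
#' arbitration needs the complete placement set per fragment.
#'
#' Records are grouped by read name; mates are paired by flag bits (0x40 /
#' 0x80) on a shared reference with opposite strands, and a paired
#' placement's score is the sum of the two mates' score tags. Fragments
#' whose records are all unmapped yield an empty placement set (classified
#' unmapped downstream), not an error.
#'
#' @param path SAM path (plain text or gzip).
#' @param ref the [ReferenceSet] the alignments were produced against;
#'   every mapped record's reference name must be one of its ids.
#' @param score_tag two-letter tag holding the integer alignment score
#'   (default `"AS"`).
#' @return list of `FragmentAlignments`, in file order of first appearance
#'   of each read name.
#' @export
read_sam <- function(path, ref, score_tag = "AS") {
  stopifnot(inherits(ref, "ReferenceSet"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  cats <- ref_categories(ref)
  tag_re <- paste0("^", score_tag, ":i:")

  n <- length(lines)
  qname <- character(n); flag <- integer(n); rname <- character(n)
  pos <- integer(n); score <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) stop("malformed SAM record at line ", i,
                              call. = FALSE)
    qname[i] <- f[1L]
    flag[i] <- as.integer(f[2L])
    rname[i] <- f[3L]
    pos[i] <- suppressWarnings(as.integer(f[4L]))
    if (length(f) > 11L) {
      hit <- grep(tag_re, f[12:length(f)], value = TRUE)
      if (length(hit)) score[i] <- as.integer(sub(tag_re, "", hit[1L]))
    }
  }
  unmapped <- bitwAnd(flag, 4L) > 0L
  mapped <- !unmapped
  bad <- mapped & !(rname %in% ref$id)
  if (any(bad)) {
    stop(sprintf("SAM reference name '%s' absent from the reference set",
                 rname[which(bad)[1L]]), call. = FALSE)
  }
  if (any(mapped & is.na(score))) {
    i <- which(mapped & is.na(score))[1L]
    stop(sprintf("record for read '%s' lacks the %s score tag", qname[i],
                 score_tag), call. = FALSE)
  }
  mate <- ifelse(bitwAnd(flag, 1L) == 0L, "SINGLE",
                 ifelse(bitwAnd(flag, 64L) > 0L, "MATE1", "MATE2"))
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")

  frag_ids <- unique(qname)
  lapply(frag_ids, function(q) {
    idx <- which(qname == q & mapped)
    paired <- any(bitwAnd(flag[qname == q], 1L) > 0L)
    if (!length(idx)) {
      pl <- if (paired) empty_paired_placements() else empty_placements()
      return(structure(list(read_id = q, paired = paired, placements = pl),
                       class = "FragmentAlignments"))
    }
    recs <- data.table::data.table(
      read = 1L, ref_id = rname[idx], category = unname(cats[rname[idx]]),
      start = pos[idx] - 1L, strand = strand[idx],
      score = score[idx], mate = mate[idx])
    if (!paired) {
      pl <- recs[, .(read, ref_id, category, start, strand, score,
                     matches = NA_integer_, mismatches = NA_integer_)]
      data.table::setorder(pl, -score, ref_id, start, strand)
    } else {
      m1 <- recs[mate == "MATE1"]
      m2 <- recs[mate == "MATE2"]
      pl <- merge(m1[, .(read, ref_id, category, start1 = start,
                         strand1 = strand, score1 = score)],
                  m2[, .(read, ref_id, category, start2 = start,
                         strand2 = strand, score2 = score)],
                  by = c("read", "ref_id", "category"),
                  allow.cartesian = TRUE)
      pl <- pl[strand1 != strand2]
      pl[, score := score1 + score2]
      data.table::setnames(pl, c("score1", "score2"),
                           c("score_mate1", "score_mate2"))
      if (nrow(pl)) data.table::setorder(pl, -score, ref_id, start1, start2)
    }
    structure(list(read_id = q, paired = paired, placements = pl),
              class = "FragmentAlignments")
  })
}
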