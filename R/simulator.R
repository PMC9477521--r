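#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The generator covers the two
#' validation regimes used to benchmark the pipeline: (A) reads drawn from
#' TE consensus sequences with a known per-consensus truth count, and (B)
#' reads drawn from synthetic canonical transcripts carrying embedded
#' TE-derived fragments, for which true TE expression is zero.
#'
#' Truth counts per consensus are drawn log-uniform over
#' `[count_range[1], count_range[2]]` (rounded to integer) with a fixed
#' zero fraction `zero_fraction`, so the truth-recovery benchmark includes
#' unexpressed TEs. The substitution-only error model matches the ungapped
#' scoring of the built-in aligner; no indels, no quality-score realism.
#'
#' All simulator outputs are byte-identical across reruns with the same
#' seed and configuration. Each generator operation re-seeds
#' deterministically from `seed` plus a small fixed per-operation offset,
#' so the operations are individually reproducible and mutually
#' decorrelated.
#'
#' @param read_length read (mate) length in bases, default 50.
#' @param paired generate read pairs instead of single-end reads.
#' @param insert_mean,insert_sd fragment-length law for pairs (bases).
#' @param error_rate per-base substitution probability in `[0, 0.1]`,
#'   default 0.001.
#' @param seed integer RNG seed.
#' @param n_consensus number of TE consensus sequences to generate.
#' @param consensus_length_range consensus length range in bases.
#' @param count_range log-uniform truth-count range (lower bound >= 1).
#' @param zero_fraction fraction of consensus sequences with truth count 0.
#' @return an object of class `SimConfig`.
#' @export
sim_config <- function(read_length = 50L, paired = FALSE, insert_mean = 300,
                       insert_sd = 50, error_rate = 0.001, seed = 1L,
                       n_consensus = 50L,
                       consensus_length_range = c(300L, 6000L),
                       count_range = c(1, 1000), zero_fraction = 0.1) {
  stopifnot(read_length >= 16L, error_rate >= 0, error_rate <= 0.1,
            n_consensus >= 1L, length(consensus_length_range) == 2L,
            count_range[1] >= 1, count_range[2] >= count_range[1],
            zero_fraction >= 0, zero_fraction < 1)
  if (consensus_length_range[1] < read_length) {
    stop("consensus length range starts below the read length", call. = FALSE)
  }
  structure(list(read_length = as.integer(read_length), paired = paired,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, seed = as.integer(seed),
                 n_consensus = as.integer(n_consensus),
                 consensus_length_range = as.integer(consensus_length_range),
                 count_range = count_range, zero_fraction = zero_fraction),
            class = "SimConfig")
}

#' Generate a synthetic TE consensus set
#'
#' Random DNA stands in for curated repeat-consensus libraries (which are
#' licence-restricted); the arbitration logic downstream is
#' sequence-content-agnostic, so benchmark properties transfer. Ids are
#' `TE0001`, `TE0002`, ...
#'
#' @param cfg a [sim_config()] object.
#' @return a [ReferenceSet] with all records in category `TE`.
#' @export
make_consensus_set <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, {
    lens <- sample_range(cfg$consensus_length_range[1],
                         cfg$consensus_length_range[2], cfg$n_consensus)
    seqs <- vapply(lens, random_dna, "")
  })
  ids <- sprintf("TE%04d", seq_len(cfg$n_consensus))
  validate_reference_set(new_reference_set(ids, seqs, rep("TE", length(ids))))
}

draw_truth_counts <- function(cfg, n) {
  zero <- runif(n) < cfg$zero_fraction
  counts <- as.integer(round(exp(runif(n, log(cfg$count_range[1]),
                                       log(cfg$count_range[2])))))
  counts[zero] <- 0L
  counts
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  nerr <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(nerr > 0L)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(length(ch), nerr[i])
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Write reads as FASTQ
#'
#' Phred+33 with constant quality `I`; gzip output when the path ends in
#' `.gz`. Byte-deterministic.
#'
#' @param ids read names (without the leading `@`).
#' @param seqs read sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(ids)) {
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), con)
  } else {
    # empty library: empty file
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (plain or gzip).
#' @return list with `id` (names truncated at first whitespace) and `seq`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(list(id = character(0),
                                         seq = character(0)))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(id = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}

# sample n fragments from one sequence; returns mate sequences and
# reference coordinates. Spans infeasible for the sequence are truncated.
sample_fragments <- function(seq_str, n, cfg) {
  len <- nchar(seq_str)
  L <- cfg$read_length
  if (cfg$paired) {
    span <- as.integer(round(rnorm(n, cfg$insert_mean, cfg$insert_sd)))
    span <- pmax(span, L)
  } else {
    span <- rep(L, n)
  }
  if (any(span > len)) {
    message(sprintf("fragment span truncated to sequence length (%d bp)", len))
    span <- pmin(span, len)
  }
  start <- vapply(span, function(s) sample.int(len - s + 1L, 1L) - 1L, 0L)
  end <- start + span
  strand <- sample(c("+", "-"), n, replace = TRUE)
  region <- substr(rep(seq_str, n), start + 1L, end)
  frag <- ifelse(strand == "+", region, revcomp(region))
  mlen <- pmin(L, span)
  mate1 <- substr(frag, 1L, mlen)
  mate2 <- if (cfg$paired) revcomp(substr(frag, span - mlen + 1L, span))
           else NULL
  list(start = start, end = end, strand = strand,
       mate1 = apply_errors(mate1, cfg$error_rate),
       mate2 = if (cfg$paired) apply_errors(mate2, cfg$error_rate) else NULL)
}

#' Simulate reads from TE consensus sequences with known truth counts
#'
#' Regime A of the validation harness: per consensus a truth count is
#' drawn (see [sim_config()]), that many fragments are sampled at uniform
#' feasible start positions on either strand, substitution errors applied,
#' and reads written as FASTQ. Read names encode the ground truth as
#' `<te_id>:<start>:<end>:<strand>:<serial>` so the emitted library can be
#' audited against the returned truth table, which matches the emitted
#' read counts exactly.
#'
#' @param consensus a [ReferenceSet] of TE records only.
#' @param cfg a [sim_config()] object.
#' @param out_prefix path prefix for the FASTQ file(s): single-end writes
#'   `<prefix>.fastq`, paired writes `<prefix>_1.fastq` / `<prefix>_2.fastq`.
#' @param truth optional named integer vector of per-consensus counts to
#'   use instead of drawing from the configured law.
#' @return list with `fastq` (character vector of paths) and `truth`
#'   (named integer vector over all consensus ids).
#' @export
simulate_te_reads <- function(consensus, cfg, out_prefix, truth = NULL) {
  stopifnot(inherits(consensus, "ReferenceSet"), inherits(cfg, "SimConfig"))
  if (!all(consensus$category == "TE")) {
    stop("consensus set must contain TE records only", call. = FALSE)
  }
  with_seed(cfg$seed + 1L, {
    if (is.null(truth)) {
      truth <- stats::setNames(draw_truth_counts(cfg, length(consensus$id)),
                               consensus$id)
    } else {
      stopifnot(setequal(names(truth), consensus$id))
      truth <- truth[consensus$id]
    }
    ids <- character(0); m1 <- character(0); m2 <- character(0)
    for (i in seq_along(consensus$id)) {
      k <- truth[[i]]
      if (k == 0L) next
      fr <- sample_fragments(consensus$seq[i], k, cfg)
      ids <- c(ids, sprintf("%s:%d:%d:%s:%d", consensus$id[i], fr$start,
                            fr$end, fr$strand, seq_len(k)))
      m1 <- c(m1, fr$mate1)
      if (cfg$paired) m2 <- c(m2, fr$mate2)
    }
  })
  if (cfg$paired) {
    paths <- paste0(out_prefix, c("_1.fastq", "_2.fastq"))
    write_fastq(ids, m1, paths[1L])
    write_fastq(ids, m2, paths[2L])
  } else {
    paths <- paste0(out_prefix, ".fastq")
    write_fastq(ids, m1, paths)
  }
  list(fastq = paths, truth = truth)
}

#' Build a synthetic transcriptome with embedded (exonized) TE fragments
#'
#' Regime B of the validation harness: each transcript is a random backbone
#' into which 0 or more TE-derived fragments are copied from random
#' intervals of random consensus sequences, optionally mutated at rate
#' `frag_divergence`, in random orientation and at random positions. Every
#' insertion is recorded in the annotation. True autonomous TE expression
#' of reads drawn from these transcripts is zero by construction.
#'
#' @param consensus a [ReferenceSet] of TE records (fragment donors).
#' @param cfg a [sim_config()] object (supplies the seed).
#' @param n_transcripts number of transcripts to generate.
#' @param frags_per_transcript maximum fragments per carrier transcript
#'   (carriers get 1..max, uniform); 0 makes plain transcripts.
#' @param frag_length_range fragment length range in bases; a drawn length
#'   is clamped to its donor consensus length.
#' @param frag_divergence per-base substitution rate applied to each copied
#'   fragment.
#' @param backbone_length_range backbone length range in bases.
#' @param carrier_fraction fraction of transcripts that carry fragments.
#' @param coding_fraction fraction of transcripts labelled `CODING` (the
#'   remainder are `NONCODING`).
#' @return list with `transcripts` (a [ReferenceSet]) and `annotation`
#'   (`data.table`: `transcript_id`, `te_source_id`, `te_start`, `te_end`,
#'   `tx_start`, `tx_end`, `orientation`, `identity`; half-open 0-based
#'   intervals).
#' @export
build_exonized_transcriptome <- function(consensus, cfg, n_transcripts = 200L,
                                         frags_per_transcript = 3L,
                                         frag_length_range = c(80L, 400L),
                                         frag_divergence = 0,
                                         backbone_length_range = c(1000L, 3000L),
                                         carrier_fraction = 0.5,
                                         coding_fraction = 0.5) {
  stopifnot(inherits(consensus, "ReferenceSet"), n_transcripts >= 1L)
  if (frags_per_transcript > 0L &&
      frag_length_range[1] > min(nchar(consensus$seq))) {
    stop("minimum fragment length exceeds the shortest consensus",
         call. = FALSE)
  }
  ann <- list()
  with_seed(cfg$seed + 2L, {
    seqs <- character(n_transcripts)
    ids <- sprintf("TX%04d", seq_len(n_transcripts))
    n_coding <- round(n_transcripts * coding_fraction)
    cats <- rep(c("CODING", "NONCODING"),
                c(n_coding, n_transcripts - n_coding))
    for (t in seq_len(n_transcripts)) {
      blen <- sample_range(backbone_length_range[1], backbone_length_range[2])
      backbone <- random_dna(blen)
      nfr <- if (frags_per_transcript > 0L && runif(1) < carrier_fraction) {
        sample.int(frags_per_transcript, 1L)
      } else 0L
      if (nfr == 0L) { seqs[t] <- backbone; next }
      cuts <- sort(sample.int(blen + 1L, nfr, replace = TRUE) - 1L)
      pieces <- character(0)
      prev <- 0L
      offset <- 0L
      for (j in seq_len(nfr)) {
        src <- sample.int(length(consensus$id), 1L)
        slen <- nchar(consensus$seq[src])
        # fragment length clamped to the donor: short consensus sequences
        # donate correspondingly shorter exonized copies
        flen <- min(sample_range(frag_length_range[1], frag_length_range[2]),
                    slen)
        fstart <- sample.int(slen - flen + 1L, 1L) - 1L
        frag <- substr(consensus$seq[src], fstart + 1L, fstart + flen)
        orient <- sample(c("+", "-"), 1L)
        if (orient == "-") frag <- revcomp(frag)
        mfrag <- apply_errors(frag, frag_divergence)
        ident <- 1 - mapply(function(a, b) sum(a != b),
                            strsplit(mfrag, ""), strsplit(frag, "")) / flen
        pieces <- c(pieces, substr(backbone, prev + 1L, cuts[j]), mfrag)
        tx_start <- offset + (cuts[j] - prev)
        ann[[length(ann) + 1L]] <- data.table::data.table(
          transcript_id = ids[t], te_source_id = consensus$id[src],
          te_start = fstart, te_end = fstart + flen,
          tx_start = tx_start, tx_end = tx_start + flen,
          orientation = orient, identity = as.numeric(ident))
        offset <- tx_start + flen
        prev <- cuts[j]
      }
      pieces <- c(pieces, substr(backbone, prev + 1L, blen))
      seqs[t] <- paste(pieces, collapse = "")
    }
  })
  annotation <- if (length(ann)) data.table::rbindlist(ann) else
    data.table::data.table(transcript_id = character(0),
                           te_source_id = character(0), te_start = integer(0),
                           te_end = integer(0), tx_start = integer(0),
                           tx_end = integer(0), orientation = character(0),
                           identity = numeric(0))
  list(transcripts = validate_reference_set(
         new_reference_set(ids, seqs, cats)),
       annotation = annotation)
}

#' Simulate reads from canonical transcripts (null regime for TEs)
#'
#' Samples `depth` fragments, each from a uniformly chosen transcript at a
#' uniform feasible position, with the same error/pair model as
#' [simulate_te_reads()]. Read names encode the source transcript and
#' coordinates (never a TE id). Because no read is drawn from a consensus
#' sequence, true TE expression in this library is zero.
#'
#' @param transcripts a non-empty [ReferenceSet] of transcript records.
#' @param cfg a [sim_config()] object.
#' @param depth total number of fragments to simulate.
#' @param out_prefix FASTQ path prefix (as in [simulate_te_reads()]).
#' @return character vector of FASTQ path(s).
#' @export
simulate_transcript_reads <- function(transcripts, cfg, depth, out_prefix) {
  stopifnot(inherits(transcripts, "ReferenceSet"), inherits(cfg, "SimConfig"),
            length(transcripts$id) >= 1L, depth >= 0L)
  with_seed(cfg$seed + 3L, {
    ids <- character(0); m1 <- character(0); m2 <- character(0)
    if (depth > 0L) {
      src <- sample.int(length(transcripts$id), depth, replace = TRUE)
      ord <- sort.int(src, method = "radix", index.return = TRUE)
      serial <- 0L
      for (i in unique(ord$x)) {
        k <- sum(ord$x == i)
        fr <- sample_fragments(transcripts$seq[i], k, cfg)
        ids <- c(ids, sprintf("%s:%d:%d:%s:%d", transcripts$id[i], fr$start,
                              fr$end, fr$strand, serial + seq_len(k)))
        serial <- serial + k
        m1 <- c(m1, fr$mate1)
        if (cfg$paired) m2 <- c(m2, fr$mate2)
      }
    }
  })
  if (cfg$paired) {
    paths <- paste0(out_prefix, c("_1.fastq", "_2.fastq"))
    write_fastq(ids, m1, paths[1L])
    write_fastq(ids, m2, paths[2L])
  } else {
    paths <- paste0(out_prefix, ".fastq")
    write_fastq(ids, m1, paths)
  }
  paths
}

#' Write / read a truth table
#'
#' Per-consensus simulated fragment counts as a two-column TSV.
#'
#' @param truth named integer vector (te_id -> count).
#' @param path TSV path.
#' @return `path` (write) or named integer vector (read).
#' @export
write_truth <- function(truth, path) {
  utils::write.table(data.frame(te_id = names(truth), count = unname(truth)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab$count), tab$te_id)
}
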