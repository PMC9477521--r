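#' Quantify TE expression from reads or external alignments
#'
#' End-to-end arbitration on one library: align (or ingest alignments),
#' select best-scoring placements per fragment, discard fragments whose
#' best set touches any non-TE reference, and count the survivors per TE
#' consensus.
#'
#' @param ref the joint [ReferenceSet] (must contain at least one TE
#'   record).
#' @param fastq1 FASTQ path (read 1 for paired libraries).
#' @param fastq2 optional FASTQ path for mate 2.
#' @param sam optional SAM path of externally produced alignments;
#'   mutually exclusive with `fastq1`.
#' @param params an [align_params()] object (ignored on the SAM path).
#' @param policy multi-TE assignment policy (see [resolve_multi_te()]).
#' @param strand_mode `"unstranded"` or `"sense"` (see
#'   [classify_fragments()]).
#' @param cpm add a CPM column over mapped fragments to the counts.
#' @return list with `counts` (a [CountTable]) and `audit` (`data.table`:
#'   `read_id`, `status`, `best_score`, `assigned`).
#' @export
quantify <- function(ref, fastq1 = NULL, fastq2 = NULL, sam = NULL,
                     params = align_params(),
                     policy = c("fractional", "first_id"),
                     strand_mode = c("unstranded", "sense"), cpm = FALSE) {
  policy <- match.arg(policy)
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(ref, "ReferenceSet"))
  ids <- te_ids(ref)
  if (!length(ids)) stop("reference set contains no TE records",
                         call. = FALSE)
  if (is.null(fastq1) == is.null(sam)) {
    stop("provide exactly one of fastq1 or sam", call. = FALSE)
  }

  if (!is.null(sam)) {
    frags <- read_sam(sam, ref)
    cats <- ref_categories(ref)
    assignments <- lapply(frags, function(fr) {
      classify(select_best(fr), cats, policy, read_id = fr$read_id)
    })
    status <- vapply(assignments, `[[`, "", "status")
    read_ids <- vapply(assignments, `[[`, "", "read_id")
    best_score <- vapply(assignments, function(a) {
      as.integer(a$best_score)
    }, 0L)
    w <- data.table::rbindlist(lapply(seq_along(assignments), function(i) {
      a <- assignments[[i]]$assigned
      if (!nrow(a)) return(NULL)
      data.table::data.table(read = i, te_id = a$te_id, weight = a$weight)
    }))
    if (is.null(w) || !nrow(w)) {
      w <- data.table::data.table(read = integer(0), te_id = character(0),
                                  weight = numeric(0))
    }
    cf <- list(assign = data.table::data.table(
                 read = seq_along(assignments), read_id = read_ids,
                 status = status, best_score = best_score),
               weights = w)
  } else {
    r1 <- read_fastq(fastq1)
    if (is.null(fastq2)) {
      n <- length(r1$seq)
      pl <- if (n) align_reads(r1$seq, ref, params) else empty_placements()
      cf <- classify_fragments(pl, n, r1$id, policy, strand_mode)
    } else {
      r2 <- read_fastq(fastq2)
      if (length(r1$seq) != length(r2$seq)) {
        stop("mate FASTQ files hold different read counts", call. = FALSE)
      }
      n <- length(r1$seq)
      if (n) {
        al1 <- align_reads(r1$seq, ref, params)
        al2 <- align_reads(r2$seq, ref, params)
        pl <- pair_placements(al1, al2, nchar(r1$seq), nchar(r2$seq), params)
      } else {
        pl <- empty_paired_placements()
      }
      cf <- classify_fragments(pl, n, r1$id, policy, strand_mode)
    }
  }

  ct <- tally_assignments(cf$assign$status, cf$weights, ids)
  if (cpm && ct$totals[["fragments_total"]] > ct$totals[["unmapped"]]) {
    ct <- normalize_cpm(ct, "mapped_fragments")
  }
  audit <- data.table::copy(cf$assign)
  if (nrow(cf$weights)) {
    ws <- cf$weights[, .(assigned = paste(sprintf("%s:%.6g", te_id, weight),
                                          collapse = ";")), by = read]
    audit <- merge(audit, ws, by = "read", all.x = TRUE, sort = TRUE)
  } else {
    audit[, assigned := NA_character_]
  }
  audit[is.na(audit$assigned), assigned := ""]
  data.table::setorder(audit, read)
  list(counts = ct, audit = audit[])
}

#' Run the quantification pipeline and write its outputs
#'
#' Builds the reference from FASTA files, quantifies one library and
#' writes `counts.tsv`, `totals.tsv`, `audit.tsv` and `run.log` into
#' `out_dir`. Outputs are deterministic for fixed inputs and
#' configuration. On any hard error, a directory this call created is
#' removed before the error propagates (no partial outputs).
#'
#' @param te_fasta,cdna_fasta,ncrna_fasta,mask_fasta reference FASTA paths
#'   (see [build_reference()]).
#' @param out_dir output directory (created if absent).
#' @inheritParams quantify
#' @return `out_dir`, invisibly.
#' @export
run_quantify <- function(te_fasta, cdna_fasta = NULL, ncrna_fasta = NULL,
                         mask_fasta = NULL, fastq1 = NULL, fastq2 = NULL,
                         sam = NULL, out_dir, params = align_params(),
                         policy = "fractional", strand_mode = "unstranded",
                         cpm = FALSE) {
  created <- !dir.exists(out_dir)
  if (created) dir.create(out_dir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE))

  ref <- build_reference(te_fasta, cdna_fasta, ncrna_fasta, mask_fasta)
  res <- quantify(ref, fastq1 = fastq1, fastq2 = fastq2, sam = sam,
                  params = params, policy = policy,
                  strand_mode = strand_mode, cpm = cpm)
  write_count_table(res$counts, file.path(out_dir, "counts.tsv"),
                    file.path(out_dir, "totals.tsv"))
  utils::write.table(res$audit[, c("read_id", "status", "best_score",
                                   "assigned")],
                     file.path(out_dir, "audit.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tot <- res$counts$totals
  log_lines <- c(
    "TEquant quantify",
    sprintf("reference: TE=%s cdna=%s ncrna=%s mask=%s",
            te_fasta, cdna_fasta %||% "-", ncrna_fasta %||% "-",
            mask_fasta %||% "-"),
    sprintf("input: fastq1=%s fastq2=%s sam=%s", fastq1 %||% "-",
            fastq2 %||% "-", sam %||% "-"),
    sprintf("params: seed_len=%d min_score_frac=%g max_insert=%d policy=%s strand=%s",
            params$seed_len, params$min_score_frac, params$max_insert,
            policy, strand_mode),
    sprintf("totals: fragments=%d unmapped=%d non_te=%d discarded_ambiguous=%d te_specific=%d",
            tot[["fragments_total"]], tot[["unmapped"]], tot[["non_te"]],
            tot[["discarded_ambiguous"]], tot[["te_specific"]]))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  ok <- TRUE
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full in-silico validation harness
#'
#' Executes both validation regimes with a shared generated consensus set:
#' regime A draws reads from the consensus sequences with known truth
#' counts and reports the Spearman correlation between truth and estimated
#' counts against a reference padded with plain decoy transcripts; regime
#' B draws reads exclusively from synthetic transcripts carrying embedded
#' TE fragments and audits the resulting TE counts, which should be
#' exactly zero.
#'
#' @param seed integer seed driving every random draw.
#' @param n_consensus,consensus_length_range consensus set geometry.
#' @param read_length,error_rate read model.
#' @param n_decoys plain decoy transcripts in the regime-A reference.
#' @param n_transcripts transcripts in the regime-B transcriptome.
#' @param depth regime-B fragments simulated from transcripts.
#' @param frags_per_transcript,frag_length_range,frag_divergence embedded
#'   fragment model (see [build_exonized_transcriptome()]).
#' @param params alignment parameters.
#' @param policy multi-TE assignment policy.
#' @param work_dir scratch directory for FASTQ files (default a tempdir).
#' @return a `ValidationReport`; its `truth` / `estimated` fields carry
#'   the regime-A vectors for downstream inspection.
#' @export
run_validate <- function(seed = 1L, n_consensus = 50L,
                         consensus_length_range = c(300L, 6000L),
                         read_length = 50L, error_rate = 0.001,
                         n_decoys = 100L, n_transcripts = 200L,
                         depth = 100000L, frags_per_transcript = 3L,
                         frag_length_range = c(80L, 400L),
                         frag_divergence = 0, params = align_params(),
                         policy = "fractional", work_dir = NULL) {
  if (is.null(work_dir)) {
    work_dir <- tempfile("tequant_validate_")
    dir.create(work_dir)
    on.exit(unlink(work_dir, recursive = TRUE))
  } else if (!dir.exists(work_dir)) {
    dir.create(work_dir, recursive = TRUE)
  }
  cfg <- sim_config(read_length = read_length, error_rate = error_rate,
                    seed = seed, n_consensus = n_consensus,
                    consensus_length_range = consensus_length_range)
  consensus <- make_consensus_set(cfg)

  # regime A: truth recovery against consensus + plain decoy transcripts
  decoys <- build_exonized_transcriptome(consensus, cfg,
                                         n_transcripts = n_decoys,
                                         frags_per_transcript = 0L)$transcripts
  sim <- simulate_te_reads(consensus, cfg, file.path(work_dir, "regimeA"))
  refA <- ref_combine(consensus, decoys)
  resA <- quantify(refA, fastq1 = sim$fastq[1L], params = params,
                   policy = policy)
  rho <- spearman_rho(sim$truth, resA$counts)

  # regime B: exonization null
  cfgB <- sim_config(read_length = read_length, error_rate = error_rate,
                     seed = seed + 7L, n_consensus = n_consensus,
                     consensus_length_range = consensus_length_range)
  exo <- build_exonized_transcriptome(consensus, cfgB,
                                      n_transcripts = n_transcripts,
                                      frags_per_transcript = frags_per_transcript,
                                      frag_length_range = frag_length_range,
                                      frag_divergence = frag_divergence)
  fqB <- simulate_transcript_reads(exo$transcripts, cfgB, depth,
                                   file.path(work_dir, "regimeB"))
  refB <- ref_combine(consensus, exo$transcripts)
  resB <- quantify(refB, fastq1 = fqB[1L], params = params, policy = policy)
  fp <- audit_null(resB$counts)

  rep <- new_validation_report(
    spearman_rho = rho, n_te = length(sim$truth),
    n_nonzero_truth = sum(sim$truth > 0), false_positive_te = fp,
    seed = seed)
  rep$truth <- sim$truth
  rep$estimated <- resA$counts$counts
  rep$null_counts <- resB$counts
  rep
}
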