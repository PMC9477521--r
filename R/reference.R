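#' Reference sets of TE consensus and transcript sequences
#'
#' A `ReferenceSet` holds the joint reference transcriptome used for read
#' arbitration: TE consensus sequences plus annotated coding and non-coding
#' transcript sequences (already spliced -- introns are never part of the
#' reference) and, optionally, mask sequences such as retained introns.
#' Every record carries a category in `TE`, `CODING`, `NONCODING`, `MASK`;
#' ids are unique across all categories.
#'
#' @name ReferenceSet
NULL

REF_CATEGORIES <- c("TE", "CODING", "NONCODING", "MASK")

new_reference_set <- function(id, seq, category) {
  stopifnot(length(id) == length(seq), length(id) == length(category))
  structure(
    list(id = as.character(id), seq = unname(as.character(seq)),
         category = as.character(category)),
    class = "ReferenceSet"
  )
}

validate_reference_set <- function(ref) {
  if (anyDuplicated(ref$id)) {
    d <- ref$id[duplicated(ref$id)][1L]
    i <- which(ref$id == d)
    stop(sprintf(
      "duplicate reference id '%s' (categories: %s)", d,
      paste(ref$category[i], collapse = ", ")), call. = FALSE)
  }
  if (any(nchar(ref$seq) == 0L)) {
    stop(sprintf("zero-length sequence for record '%s'",
                 ref$id[which(nchar(ref$seq) == 0L)[1L]]), call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", ref$seq)
  if (any(bad)) {
    stop(sprintf("record '%s' contains characters outside {A,C,G,T,N}",
                 ref$id[which(bad)[1L]]), call. = FALSE)
  }
  if (!all(ref$category %in% REF_CATEGORIES)) {
    stop("unknown reference category", call. = FALSE)
  }
  invisible(ref)
}

# Read one FASTA file into (id, seq); headers truncated at first whitespace,
# case folded to upper, U folded to T. IUPAC codes other than N are rejected.
read_fasta_records <- function(path, what = "FASTA") {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path),
                               call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  ids <- names(x)
  trimmed <- sub("\\s.*$", "", ids)
  if (any(trimmed != ids)) {
    warning(sprintf("%s: %d header(s) truncated at first whitespace",
                    basename(path), sum(trimmed != ids)), call. = FALSE)
  }
  seq <- toupper(as.character(x))
  seq <- chartr("U", "T", seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(sprintf(
      "record '%s' in %s contains characters outside {A,C,G,T,N,U}",
      trimmed[which(bad)[1L]], basename(path)), call. = FALSE)
  }
  if (any(nchar(seq) == 0L)) {
    stop(sprintf("record '%s' in %s has a zero-length sequence",
                 trimmed[which(nchar(seq) == 0L)[1L]], basename(path)),
         call. = FALSE)
  }
  list(id = unname(trimmed), seq = unname(seq))
}

#' Build the joint reference transcriptome
#'
#' Reads TE consensus sequences plus (optionally) coding transcripts,
#' non-coding transcripts and mask sequences from FASTA files and assembles
#' them into a single [ReferenceSet]. Record order is deterministic: TE
#' records first, then coding, non-coding and mask records, each in file
#' order. Sequences are normalised to uppercase DNA (`U` folded to `T`);
#' ids must be unique across all files.
#'
#' @param te_fasta path to the TE consensus FASTA (required, >= 1 record).
#' @param cdna_fasta,ncrna_fasta,mask_fasta optional paths to coding,
#'   non-coding and mask FASTA files (plain or gzip).
#' @return a `ReferenceSet`.
#' @examples
#' te <- tempfile(fileext = ".fa")
#' writeLines(c(">TE1", "ACGTACGTACGTACGTACGT"), te)
#' ref <- build_reference(te)
#' ref$category
#' @export
build_reference <- function(te_fasta, cdna_fasta = NULL, ncrna_fasta = NULL,
                            mask_fasta = NULL) {
  te <- read_fasta_records(te_fasta, "TE")
  if (!length(te$id)) stop("TE FASTA contains no records", call. = FALSE)
  parts <- list(list(rec = te, cat = "TE"))
  if (!is.null(cdna_fasta))
    parts <- c(parts, list(list(rec = read_fasta_records(cdna_fasta, "cDNA"),
                                cat = "CODING")))
  if (!is.null(ncrna_fasta))
    parts <- c(parts, list(list(rec = read_fasta_records(ncrna_fasta, "ncRNA"),
                                cat = "NONCODING")))
  if (!is.null(mask_fasta))
    parts <- c(parts, list(list(rec = read_fasta_records(mask_fasta, "mask"),
                                cat = "MASK")))
  id <- unlist(lapply(parts, function(p) p$rec$id), use.names = FALSE)
  seq <- unlist(lapply(parts, function(p) p$rec$seq), use.names = FALSE)
  cat <- unlist(lapply(parts, function(p) rep(p$cat, length(p$rec$id))),
                use.names = FALSE)
  if (anyDuplicated(id)) {
    d <- id[duplicated(id)][1L]
    i <- which(id == d)
    stop(sprintf("id '%s' occurs in more than one record (categories: %s)",
                 d, paste(cat[i], collapse = ", ")), call. = FALSE)
  }
  validate_reference_set(new_reference_set(id, seq, cat))
}

#' Construct a reference set in memory
#'
#' Programmatic counterpart of [build_reference()] for sequences already in
#' R; applies the same validation (unique ids, uppercase `A,C,G,T,N`
#' alphabet, known categories).
#'
#' @param id,seq,category parallel character vectors.
#' @return a `ReferenceSet`.
#' @export
reference_set <- function(id, seq, category) {
  validate_reference_set(new_reference_set(id, seq, category))
}

#' Combine reference sets
#'
#' Concatenates two or more `ReferenceSet` objects, enforcing id uniqueness
#' across the union.
#'
#' @param ... `ReferenceSet` objects.
#' @return a `ReferenceSet`.
#' @export
ref_combine <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  id <- unlist(lapply(sets, `[[`, "id"), use.names = FALSE)
  seq <- unlist(lapply(sets, `[[`, "seq"), use.names = FALSE)
  cat <- unlist(lapply(sets, `[[`, "category"), use.names = FALSE)
  validate_reference_set(new_reference_set(id, seq, cat))
}

#' Category lookup for a reference set
#'
#' @param ref a `ReferenceSet`.
#' @return named character vector mapping id to category.
#' @export
ref_categories <- function(ref) {
  stats::setNames(ref$category, ref$id)
}

#' TE ids of a reference set, in reference order
#'
#' @param ref a `ReferenceSet`.
#' @return character vector.
#' @export
te_ids <- function(ref) {
  ref$id[ref$category == "TE"]
}

#' @export
length.ReferenceSet <- function(x) length(x$id)

#' @export
print.ReferenceSet <- function(x, ...) {
  tab <- table(factor(x$category, levels = REF_CATEGORIES))
  cat(sprintf("ReferenceSet with %d record(s): %s\n", length(x$id),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' @export
as.data.frame.ReferenceSet <- function(x, ...) {
  data.frame(id = x$id, category = x$category, length = nchar(x$seq),
             stringsAsFactors = FALSE)
}

sidecar_path <- function(fasta_path) paste0(fasta_path, ".categories.tsv")

#' Serialize a reference set
#'
#' Writes a single FASTA file (60-column wrapped) plus a tab-separated
#' sidecar table (`id`, `category`, `length`) which is the single source of
#' truth for record categories; FASTA headers carry the bare id only.
#' `read_reference()` on the pair reconstructs an identical set.
#'
#' @param ref a non-empty `ReferenceSet`.
#' @param out_path output FASTA path; the sidecar is written next to it as
#'   `<out_path>.categories.tsv`.
#' @return `out_path`, invisibly.
#' @export
write_reference <- function(ref, out_path) {
  stopifnot(inherits(ref, "ReferenceSet"))
  if (!length(ref$id)) stop("refusing to write an empty ReferenceSet",
                            call. = FALSE)
  dss <- Biostrings::DNAStringSet(stats::setNames(ref$seq, ref$id))
  Biostrings::writeXStringSet(dss, out_path, width = 60L)
  utils::write.table(
    data.frame(id = ref$id, category = ref$category,
               length = nchar(ref$seq)),
    sidecar_path(out_path), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_path)
}

#' Read a serialized reference set
#'
#' @param fasta_path FASTA written by [write_reference()].
#' @param sidecar path to the category sidecar table; defaults to
#'   `<fasta_path>.categories.tsv`.
#' @return a `ReferenceSet`.
#' @export
read_reference <- function(fasta_path, sidecar = sidecar_path(fasta_path)) {
  rec <- read_fasta_records(fasta_path, "reference")
  if (!file.exists(sidecar)) stop("category sidecar not found: ", sidecar,
                                  call. = FALSE)
  tab <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!identical(tab$id, rec$id)) {
    stop("sidecar ids do not match FASTA record ids/order", call. = FALSE)
  }
  validate_reference_set(new_reference_set(rec$id, rec$seq, tab$category))
}
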