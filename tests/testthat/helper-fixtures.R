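# fixtures are generated in code; no binary data ships with the package

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(records, width = 60L) {
  path <- tempfile(fileext = ".fa")
  lines <- unlist(lapply(names(records), function(id) {
    seq <- records[[id]]
    body <- substring(seq, seq(1L, nchar(seq), width),
                      pmin(seq(1L, nchar(seq), width) + width - 1L,
                           nchar(seq)))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  path
}

# 0-based half-open substring
seg <- function(x, from, to) substr(x, from + 1L, to)

mutate_bases <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1L]]
  for (p in positions) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# one TE plus one gene that carries an exact embedded copy of TE[50, 150),
# and two 50-mers: one interior to the shared segment (ties TE/gene), one
# TE-only. The canonical two-read worked example of the arbitration rule.
worked_example_fixture <- function(seed = 20240601L) {
  set.seed(seed)
  te <- rand_dna(200L)
  gene <- paste0(rand_dna(150L), seg(te, 50L, 150L), rand_dna(150L))
  list(te = te, gene = gene,
       read_ambiguous = seg(te, 60L, 110L),
       read_te = seg(te, 0L, 50L))
}

# random small alignment instance for the oracle-equivalence property
random_align_instance <- function(read_len_range = c(30L, 100L),
                                  max_mut_rate = 0.05) {
  nref <- sample(2:3, 1L)
  lens <- sample(150:400, nref, replace = TRUE)
  cats <- sample(c("TE", "CODING", "NONCODING"), nref, replace = TRUE)
  ref <- reference_set(sprintf("R%02d", seq_len(nref)),
                       vapply(lens, rand_dna, ""), cats)
  i <- sample.int(nref, 1L)
  L <- sample(read_len_range[1]:min(read_len_range[2], lens[i]), 1L)
  start <- sample.int(lens[i] - L + 1L, 1L) - 1L
  read <- seg(ref$seq[i], start, start + L)
  nmut <- sample(0:floor(L * max_mut_rate), 1L)
  if (nmut > 0L) read <- mutate_bases(read, sample.int(L, nmut))
  if (runif(1) < 0.5) read <- revcomp(read)
  list(ref = ref, read = read)
}

placement_key <- function(dt) {
  dt <- as.data.frame(dt)[, c("ref_id", "start", "strand", "score",
                              "matches", "mismatches")]
  dt[order(dt$ref_id, dt$start, dt$strand), , drop = FALSE]
}

expect_same_placements <- function(a, b) {
  expect_equal(unname(as.list(placement_key(a))),
               unname(as.list(placement_key(b))))
}

# minimal placements table for selector tests
pl_table <- function(ref_id, score, categories, start = NULL) {
  data.table::data.table(
    read = 1L, ref_id = ref_id,
    category = unname(categories[ref_id]),
    start = if (is.null(start)) seq_along(ref_id) * 10L else start,
    strand = "+", score = as.integer(score),
    matches = NA_integer_, mismatches = NA_integer_)
}

random_assignment <- function(ids) {
  status <- sample(c("TE_SPECIFIC", "DISCARDED_AMBIGUOUS", "NON_TE",
                     "UNMAPPED"), 1L)
  assigned <- if (status == "TE_SPECIFIC") {
    k <- sample.int(min(3L, length(ids)), 1L)
    data.frame(te_id = sample(ids, k), weight = rep(1 / k, k),
               stringsAsFactors = FALSE)
  } else {
    data.frame(te_id = character(0), weight = numeric(0),
               stringsAsFactors = FALSE)
  }
  TEquant:::new_assignment("r", status, assigned,
                           if (status == "UNMAPPED") NA_integer_ else 50L)
}
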