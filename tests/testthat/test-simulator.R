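test_that("consensus generation is seed-deterministic", {
  cfg <- sim_config(seed = 7L, n_consensus = 8L,
                    consensus_length_range = c(300L, 900L))
  a <- make_consensus_set(cfg)
  b <- make_consensus_set(cfg)
  expect_identical(a$seq, b$seq)
  expect_identical(a$id, sprintf("TE%04d", 1:8))
  d <- make_consensus_set(sim_config(seed = 8L, n_consensus = 8L,
                                     consensus_length_range = c(300L, 900L)))
  expect_false(identical(a$seq, d$seq))
})

test_that("simulated TE reads match the truth table exactly", {
  cfg <- sim_config(seed = 9L, n_consensus = 6L, error_rate = 0,
                    consensus_length_range = c(300L, 800L))
  cons <- make_consensus_set(cfg)
  sim <- simulate_te_reads(cons, cfg, tempfile())
  fq <- read_fastq(sim$fastq)
  expect_identical(length(fq$seq), as.integer(sum(sim$truth)))
  census <- table(factor(sub(":.*$", "", fq$id), levels = cons$id))
  expect_identical(as.integer(census), as.integer(sim$truth[cons$id]))

  # with error rate 0 every read is an exact (possibly reverse-complement)
  # substring at its encoded coordinates
  parts <- strsplit(fq$id, ":", fixed = TRUE)
  for (i in seq_along(fq$seq)) {
    p <- parts[[i]]
    src <- cons$seq[cons$id == p[1]]
    region <- seg(src, as.integer(p[2]), as.integer(p[3]))
    expect_identical(fq$seq[i],
                     if (p[4] == "+") region else revcomp(region))
  }
})

test_that("fixed truth counts are honoured and zeros emit nothing", {
  cfg <- sim_config(seed = 10L, n_consensus = 2L,
                    consensus_length_range = c(300L, 400L))
  cons <- make_consensus_set(cfg)
  sim <- simulate_te_reads(cons, cfg, tempfile(),
                           truth = c(TE0001 = 10L, TE0002 = 0L))
  fq <- read_fastq(sim$fastq)
  expect_identical(length(fq$seq), 10L)
  expect_true(all(startsWith(fq$id, "TE0001:")))
})

test_that("paired simulation respects the insert law in read names", {
  cfg <- sim_config(seed = 11L, paired = TRUE, insert_mean = 300,
                    insert_sd = 30, n_consensus = 3L, error_rate = 0,
                    consensus_length_range = c(2000L, 3000L))
  cons <- make_consensus_set(cfg)
  sim <- simulate_te_reads(cons, cfg, tempfile())
  expect_length(sim$fastq, 2L)
  fq1 <- read_fastq(sim$fastq[1]); fq2 <- read_fastq(sim$fastq[2])
  expect_identical(fq1$id, fq2$id)
  parts <- do.call(rbind, strsplit(fq1$id, ":", fixed = TRUE))
  span <- as.integer(parts[, 3]) - as.integer(parts[, 2])
  expect_true(all(span >= 50L))
  expect_gt(mean(span), 200)
  expect_lt(mean(span), 400)
})

test_that("exonized transcriptome records its insertions faithfully", {
  cfg <- sim_config(seed = 12L, n_consensus = 5L,
                    consensus_length_range = c(500L, 800L))
  cons <- make_consensus_set(cfg)

  plain <- build_exonized_transcriptome(cons, cfg, n_transcripts = 10L,
                                        frags_per_transcript = 0L)
  expect_identical(nrow(plain$annotation), 0L)
  expect_length(plain$transcripts$id, 10L)
  expect_true(all(plain$transcripts$category %in% c("CODING", "NONCODING")))

  exo <- build_exonized_transcriptome(cons, cfg, n_transcripts = 15L,
                                      frags_per_transcript = 2L,
                                      frag_length_range = c(80L, 200L),
                                      frag_divergence = 0,
                                      carrier_fraction = 1)
  expect_gt(nrow(exo$annotation), 0L)
  for (i in seq_len(nrow(exo$annotation))) {
    a <- exo$annotation[i]
    tx <- exo$transcripts$seq[exo$transcripts$id == a$transcript_id]
    src <- cons$seq[cons$id == a$te_source_id]
    copied <- seg(tx, a$tx_start, a$tx_end)
    donor <- seg(src, a$te_start, a$te_end)
    expect_identical(copied,
                     if (a$orientation == "+") donor else revcomp(donor))
    expect_identical(a$identity, 1)
  }
})

test_that("single fragment insertion obeys length arithmetic", {
  cfg <- sim_config(seed = 13L, n_consensus = 1L,
                    consensus_length_range = c(500L, 500L))
  cons <- make_consensus_set(cfg)
  exo <- build_exonized_transcriptome(cons, cfg, n_transcripts = 1L,
                                      frags_per_transcript = 1L,
                                      frag_length_range = c(120L, 120L),
                                      backbone_length_range = c(700L, 700L),
                                      carrier_fraction = 1)
  expect_identical(nrow(exo$annotation), 1L)
  expect_identical(nchar(exo$transcripts$seq), 700L + 120L)
})

test_that("transcript reads hit the requested depth and never name a TE", {
  cfg <- sim_config(seed = 14L, n_consensus = 3L,
                    consensus_length_range = c(400L, 600L))
  cons <- make_consensus_set(cfg)
  exo <- build_exonized_transcriptome(cons, cfg, n_transcripts = 8L)
  fq <- read_fastq(simulate_transcript_reads(exo$transcripts, cfg, 500L,
                                             tempfile()))
  expect_identical(length(fq$seq), 500L)
  expect_true(all(startsWith(fq$id, "TX")))

  empty <- read_fastq(simulate_transcript_reads(exo$transcripts, cfg, 0L,
                                                tempfile()))
  expect_identical(length(empty$seq), 0L)
})

test_that("simulator outputs are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 15L, n_consensus = 4L,
                    consensus_length_range = c(300L, 600L))
  cons <- make_consensus_set(cfg)
  p1 <- tempfile(); p2 <- tempfile()
  simulate_te_reads(cons, cfg, p1)
  simulate_te_reads(cons, cfg, p2)
  expect_identical(unname(tools::md5sum(paste0(p1, ".fastq"))),
                   unname(tools::md5sum(paste0(p2, ".fastq"))))
})
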