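test_that("exact substrings place uniquely with full score", {
  set.seed(21)
  te <- rand_dna(300L)
  ref <- reference_set("TE1", te, "TE")
  read <- seg(te, 10L, 60L)
  pl <- align_fragment(read, ref)$placements
  expect_identical(nrow(pl), 1L)
  expect_identical(pl$ref_id, "TE1")
  expect_identical(pl$start, 10L)
  expect_identical(pl$strand, "+")
  expect_identical(pl$score, 50L)

  rc <- align_fragment(revcomp(read), ref)$placements
  expect_identical(rc$strand, "-")
  expect_identical(rc$score, 50L)
  expect_identical(rc$start, 10L)
})

test_that("a segment shared between TE and gene places twice at equal score", {
  fx <- worked_example_fixture()
  ref <- reference_set(c("TE1", "G1"), c(fx$te, fx$gene), c("TE", "CODING"))
  pl <- align_fragment(fx$read_ambiguous, ref)$placements
  expect_identical(nrow(pl), 2L)
  expect_setequal(pl$ref_id, c("TE1", "G1"))
  expect_identical(unique(pl$score), 50L)
})

test_that("degenerate reads behave per contract", {
  set.seed(22)
  ref <- reference_set("TE1", rand_dna(200L), "TE")
  expect_identical(nrow(align_fragment(strrep("N", 50L), ref)$placements), 0L)
  expect_identical(nrow(brute_force_align(strrep("N", 50L), ref)), 0L)
  expect_error(align_reads("ACGTXACGTACGTACGTACG", ref), "outside")
  expect_error(align_reads("ACGT", ref), "shorter than the seed length")
})

test_that("toy aligner matches the exhaustive oracle on random instances", {
  set.seed(23)
  for (rep in 1:60) {
    inst <- random_align_instance()
    fast <- align_reads(inst$read, inst$ref)
    slow <- brute_force_align(inst$read, inst$ref)
    expect_same_placements(fast, slow)
  }
})

test_that("strand symmetry: reverse-complementing a read flips strands", {
  set.seed(24)
  for (rep in 1:20) {
    inst <- random_align_instance()
    a <- align_reads(inst$read, inst$ref)
    b <- align_reads(revcomp(inst$read), inst$ref)
    b$strand <- ifelse(b$strand == "+", "-", "+")
    expect_same_placements(a, b)
  }
})

test_that("an extra mismatch never raises a placement score", {
  set.seed(25)
  te <- rand_dna(400L)
  ref <- reference_set("TE1", te, "TE")
  read <- seg(te, 100L, 160L)
  base <- align_reads(read, ref, align_params(min_score_frac = 0.5))
  for (rep in 1:10) {
    worse <- mutate_bases(read, sample.int(60L, 1L))
    pl <- align_reads(worse, ref, align_params(min_score_frac = 0.5))
    m <- merge(as.data.frame(base), as.data.frame(pl),
               by = c("ref_id", "start", "strand"))
    expect_true(all(m$score.y <= m$score.x))
  }
})

test_that("pairs are placed as fragments on one reference", {
  set.seed(26)
  te <- rand_dna(300L)
  ref <- reference_set(c("TE1", "G1"), c(te, rand_dna(300L)),
                       c("TE", "CODING"))
  mate1 <- seg(te, 10L, 60L)
  mate2 <- revcomp(seg(te, 200L, 250L))
  fr <- align_fragment(c(mate1, mate2), ref)
  expect_true(fr$paired)
  expect_identical(nrow(fr$placements), 1L)
  expect_identical(fr$placements$score, 100L)
  expect_identical(fr$placements$span, 240L)
  expect_true(fr$placements$strand1 != fr$placements$strand2)

  # one unplaceable mate leaves the fragment without placements
  fr2 <- align_fragment(c(mate1, rand_dna(50L)), ref)
  expect_identical(nrow(fr2$placements), 0L)

  # insert cap
  fr3 <- align_fragment(c(mate1, mate2), ref,
                        align_params(max_insert = 100L))
  expect_identical(nrow(fr3$placements), 0L)
})
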