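mk_assign <- function(status, te = character(0), w = numeric(0)) {
  TEquant:::new_assignment("r", status,
                           data.frame(te_id = te, weight = w,
                                      stringsAsFactors = FALSE),
                           if (status == "UNMAPPED") NA_integer_ else 50L)
}

test_that("count_fragments tallies weights and the totals partition", {
  ct <- count_fragments(list(mk_assign("TE_SPECIFIC", "TE1", 1),
                             mk_assign("DISCARDED_AMBIGUOUS"),
                             mk_assign("NON_TE")),
                        c("TE1", "TE2"))
  expect_identical(ct$counts, c(TE1 = 1, TE2 = 0))
  expect_identical(unname(ct$totals),
                   c(3, 0, 1, 1, 1))

  all_disc <- count_fragments(replicate(100, mk_assign("DISCARDED_AMBIGUOUS"),
                                        simplify = FALSE), c("TE1", "TE2"))
  expect_identical(sum(all_disc$counts), 0)
  expect_identical(unname(all_disc$totals[["te_specific"]]), 0)

  halves <- count_fragments(list(
    mk_assign("TE_SPECIFIC", c("TE1", "TE2"), c(0.5, 0.5)),
    mk_assign("TE_SPECIFIC", c("TE1", "TE2"), c(0.5, 0.5))),
    c("TE1", "TE2"))
  expect_equal(halves$counts, c(TE1 = 1, TE2 = 1))

  expect_error(count_fragments(list(mk_assign("TE_SPECIFIC", "TEX", 1)),
                               c("TE1")), "TEX")
})

test_that("count mass equals TE-specific fragments under either policy", {
  set.seed(41)
  ids <- sprintf("TE%02d", 1:6)
  for (rep in 1:20) {
    assigns <- replicate(50, random_assignment(ids), simplify = FALSE)
    ct <- count_fragments(assigns, ids)
    expect_equal(sum(ct$counts), ct$totals[["te_specific"]])
    expect_identical(ct$totals[["fragments_total"]],
                     sum(ct$totals[c("unmapped", "non_te",
                                     "discarded_ambiguous", "te_specific")]))
    # order invariance (streaming equivalence)
    ct2 <- count_fragments(assigns[sample.int(50)], ids)
    expect_equal(ct$counts, ct2$counts)
    expect_identical(ct$totals, ct2$totals)
  }
})

test_that("CPM normalisation follows its definition", {
  ct <- TEquant:::new_count_table(
    c(TE1 = 5), c(fragments_total = 1e6, unmapped = 0, non_te = 999995,
                  discarded_ambiguous = 0, te_specific = 5))
  expect_equal(normalize_cpm(ct, "mapped_fragments")$cpm, c(TE1 = 5))

  ct2 <- TEquant:::new_count_table(
    c(TE1 = 1, TE2 = 3), c(fragments_total = 4, unmapped = 0, non_te = 0,
                           discarded_ambiguous = 0, te_specific = 4))
  expect_equal(normalize_cpm(ct2, "te_specific")$cpm,
               c(TE1 = 250000, TE2 = 750000))

  zero <- TEquant:::new_count_table(
    c(TE1 = 0), c(fragments_total = 10, unmapped = 10, non_te = 0,
                  discarded_ambiguous = 0, te_specific = 0))
  expect_error(normalize_cpm(zero, "te_specific"), "raw counts")
})

test_that("count TSV prints integers bare and fractions at 6 decimals", {
  ct <- TEquant:::new_count_table(
    c(TE1 = 2, TE2 = 0.5), c(fragments_total = 3, unmapped = 0, non_te = 0,
                             discarded_ambiguous = 0.5, te_specific = 2.5))
  p <- tempfile(fileext = ".tsv")
  write_count_table(ct, p)
  lines <- readLines(p)
  expect_identical(lines[2], "TE1\t2")
  expect_identical(lines[3], "TE2\t0.500000")
})
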