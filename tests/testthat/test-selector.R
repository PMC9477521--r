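cats <- c(TE1 = "TE", TE2 = "TE", G1 = "CODING", L1 = "NONCODING",
          INTRON1 = "MASK")

test_that("select_best keeps exactly the maximum-score placements", {
  expect_identical(select_best(pl_table(c("TE1", "G1"), c(100L, 90L),
                                        cats))$ref_id, "TE1")
  tie <- select_best(pl_table(c("TE1", "G1"), c(100L, 100L), cats))
  expect_setequal(tie$ref_id, c("TE1", "G1"))
  empty <- pl_table(character(0), integer(0), cats)
  expect_identical(nrow(select_best(empty)), 0L)
})

test_that("classify implements the discard rule", {
  a <- classify(pl_table("TE1", 100L, cats), cats)
  expect_identical(a$status, "TE_SPECIFIC")
  expect_identical(a$assigned$te_id, "TE1")
  expect_identical(a$assigned$weight, 1)

  expect_identical(classify(pl_table(c("TE1", "G1"), c(100L, 100L), cats),
                            cats)$status, "DISCARDED_AMBIGUOUS")
  expect_identical(classify(pl_table(c("G1", "L1"), c(80L, 80L), cats),
                            cats)$status, "NON_TE")
  # mask sequences discard exactly like coding/non-coding
  expect_identical(classify(pl_table(c("INTRON1", "TE1"), c(90L, 90L), cats),
                            cats)$status, "DISCARDED_AMBIGUOUS")
  expect_identical(classify(pl_table(character(0), integer(0), cats),
                            cats)$status, "UNMAPPED")
  expect_error(classify(pl_table("XX", 10L, cats), cats), "unknown")
})

test_that("multi-TE ties resolve per policy", {
  expect_identical(resolve_multi_te("TE1"),
                   data.frame(te_id = "TE1", weight = 1,
                              stringsAsFactors = FALSE))
  fr <- resolve_multi_te(c("TE1", "TE2"))
  expect_identical(fr$weight, c(0.5, 0.5))
  expect_identical(resolve_multi_te(c("TE2", "TE1"), "first_id")$te_id, "TE1")
  # same-id placements collapse before weighting
  expect_identical(resolve_multi_te(c("TE1", "TE1"))$weight, 1)
})

test_that("adding a top-scoring non-TE placement never yields TE_SPECIFIC", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(1:4, 1L)
    ids <- sample(names(cats), n, replace = TRUE)
    scores <- sample(40:100, n, replace = TRUE)
    tab <- pl_table(ids, scores, cats)
    spiked <- rbind(tab, pl_table(sample(c("G1", "L1", "INTRON1"), 1L),
                                  max(c(scores, 0L)) + sample(0:5, 1L),
                                  cats))
    expect_false(classify(select_best(spiked), cats)$status == "TE_SPECIFIC")
  }
})

test_that("classification is invariant under placement order", {
  set.seed(32)
  for (rep in 1:25) {
    n <- sample(2:6, 1L)
    tab <- pl_table(sample(names(cats), n, replace = TRUE),
                    sample(40:60, n, replace = TRUE), cats)
    a <- classify(select_best(tab), cats)
    b <- classify(select_best(tab[sample.int(n)]), cats)
    expect_identical(a$status, b$status)
    expect_identical(a$assigned, b$assigned)
    expect_identical(a$best_score, b$best_score)
  }
})

test_that("vectorised classification agrees with per-fragment classify", {
  set.seed(33)
  for (policy in c("fractional", "first_id")) {
    tabs <- lapply(1:40, function(i) {
      n <- sample(0:5, 1L)
      if (n == 0L) return(pl_table(character(0), integer(0), cats))
      pl_table(sample(names(cats), n, replace = TRUE),
               sample(40:60, n, replace = TRUE), cats)
    })
    pooled <- data.table::rbindlist(lapply(seq_along(tabs), function(i) {
      t <- data.table::copy(tabs[[i]]); t[, read := i]; t
    }))
    cf <- classify_fragments(pooled, length(tabs), policy = policy)
    for (i in seq_along(tabs)) {
      one <- classify(select_best(tabs[[i]]), cats, policy = policy)
      expect_identical(cf$assign$status[i], one$status)
      w <- cf$weights[read == i]
      expect_identical(w$te_id, one$assigned$te_id)
      expect_equal(w$weight, one$assigned$weight)
    }
  }
})

test_that("every fragment gets exactly one status and they partition", {
  set.seed(34)
  tabs <- data.table::rbindlist(lapply(1:30, function(i) {
    n <- sample(0:4, 1L)
    if (n == 0L) return(NULL)
    t <- pl_table(sample(names(cats), n, replace = TRUE),
                  sample(40:60, n, replace = TRUE), cats)
    t[, read := i]
    t
  }))
  cf <- classify_fragments(tabs, 30L)
  expect_identical(nrow(cf$assign), 30L)
  expect_true(all(cf$assign$status %in% c("TE_SPECIFIC",
                                          "DISCARDED_AMBIGUOUS", "NON_TE",
                                          "UNMAPPED")))
  expect_identical(sum(table(cf$assign$status)), 30L)
})
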