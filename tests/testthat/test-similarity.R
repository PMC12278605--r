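test_that("local alignment scores match hand-computed cases", {
  sc <- simple_scoring(match = 2, mismatch = -1, gap = -1)
  expect_equal(smith_waterman_score("ACG", "ACG", sc), 6)
  expect_equal(smith_waterman_score("AAAA", "GGGG", sc), 0)
  expect_equal(smith_waterman_score("ACGT", "TACG", sc),
               sw_oracle("ACGT", "TACG", sc))
  expect_error(smith_waterman_score("", "ACG", sc), "non-empty")
})

test_that("optimized scorer agrees with the brute-force DP oracle and is symmetric", {
  set.seed(101)
  simple <- simple_scoring(2, -1, -1)
  blosum <- alignment_scoring()  # BLOSUM62, affine gaps
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    a <- paste(sample(aa, sample(3:25, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(3:25, 1), replace = TRUE), collapse = "")
    for (sc in list(simple, blosum)) {
      s_ab <- smith_waterman_score(a, b, sc)
      expect_identical(s_ab, sw_oracle(a, b, sc))
      expect_identical(s_ab, smith_waterman_score(b, a, sc))
    }
  }
})

test_that("self-alignment dominates cross-alignment under simple scoring", {
  set.seed(7)
  sc <- simple_scoring(2, -1, -1)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:12, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), nchar(a), replace = TRUE),
               collapse = "")
    expect_gte(smith_waterman_score(a, a, sc), smith_waterman_score(a, b, sc))
  }
})

test_that("normalized similarity satisfies the kernel contract", {
  sc <- simple_scoring(2, -1, -1)
  # hand-derived: SW(ACG,ACGT)=6, self-scores 6 and 8
  sm <- normalized_similarity(c(a = "ACG", b = "ACGT"), sc)
  expect_equal(sm$values["a", "b"], 6 / sqrt(6 * 8))
  # identical sequences -> off-diagonal 1
  sm2 <- normalized_similarity(c(x = "MKVL", y = "MKVL"),
                               alignment_scoring())
  expect_equal(sm2$values["x", "y"], 1)
  # random records: symmetric, unit diagonal, in [0,1]
  set.seed(5)
  seqs <- random_seqs(8, c(10, 30), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  names(seqs) <- paste0("s", 1:8)
  sm3 <- normalized_similarity(seqs, alignment_scoring())
  expect_equal(sm3$values, t(sm3$values))
  expect_equal(diag(sm3$values), setNames(rep(1, 8), names(seqs)))
  expect_true(all(sm3$values >= 0 & sm3$values <= 1))
})

test_that("degenerate sequences with non-positive self-score are rejected", {
  sc <- simple_scoring(2, -1, -1)
  # a substitution table with a non-positive diagonal makes self-score 0
  tab <- matrix(-1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  bad <- alignment_scoring(substitution = tab, gap_open = -1, gap_extend = -1)
  expect_error(normalized_similarity(c(u = "AB", v = "BA"), bad),
               "not positive")
})

test_that("tanimoto similarity matches set arithmetic", {
  fp <- rbind(d1 = c(1, 1, 0, 0), d2 = c(1, 0, 1, 0), d3 = c(1, 1, 0, 0),
              d4 = c(0, 0, 0, 1))
  tm <- tanimoto_drug_similarity(fp)
  expect_equal(tm$values["d1", "d2"], 1 / 3)
  expect_equal(tm$values["d1", "d3"], 1)     # identical fingerprints
  expect_equal(tm$values["d1", "d4"], 0)     # disjoint
  expect_error(tanimoto_drug_similarity(rbind(d1 = c(1, 0), d2 = c(0, 0))),
               "all-zero")
})
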