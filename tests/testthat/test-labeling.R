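make_toy <- function() {
  im <- interaction_matrix(c("d1", "d2"), c("t1", "t2"),
                           matrix(c(1, 0, 0, 0), 2, 2))
  ds <- similarity_matrix(c("d1", "d2"), matrix(c(1, 0.8, 0.8, 1), 2))
  ts <- similarity_matrix(c("t1", "t2"), matrix(c(1, 0.5, 0.5, 1), 2))
  list(im = im, ds = ds, ts = ts)
}

test_that("pair scores equal the max-product kernel over known positives", {
  toy <- make_toy()
  pairs <- score_unknown_pairs(toy$im, toy$ds, toy$ts)
  expect_equal(nrow(pairs), 3)  # (d1,t1) excluded
  get <- function(d, t) pairs$score[pairs$drug_id == d & pairs$target_id == t]
  expect_equal(get("d2", "t1"), 0.8)
  expect_equal(get("d1", "t2"), 0.5)
  expect_equal(get("d2", "t2"), 0.8 * 0.5)
})

test_that("pair scores match the exhaustive enumeration oracle on random instances", {
  for (s in 1:5) {
    prob <- random_problem(6, 5, seed = 100 + s)
    pairs <- score_unknown_pairs(prob$interactions, prob$drug_sim,
                                 prob$target_sim)
    oracle <- label_score_oracle(prob$interactions, prob$drug_sim,
                                 prob$target_sim)
    m <- merge(pairs, oracle, by = c("drug_id", "target_id"))
    expect_equal(m$score.x, m$score.y, tolerance = 1e-12)
    expect_true(all(pairs$score >= 0 & pairs$score <= 1))
  }
})

test_that("empty positive set scores everything 0 with a warning", {
  im <- interaction_matrix(c("d1", "d2"), c("t1", "t2"), matrix(0, 2, 2))
  toy <- make_toy()
  expect_warning(pairs <- score_unknown_pairs(im, toy$ds, toy$ts),
                 "no known positives")
  expect_equal(pairs$score, rep(0, 4))
})

test_that("id mismatches are rejected", {
  toy <- make_toy()
  ds_bad <- similarity_matrix(c("d1", "dX"), matrix(c(1, 0.8, 0.8, 1), 2))
  expect_error(score_unknown_pairs(toy$im, ds_bad, toy$ts), "dX|match")
})

test_that("top-k labelling partitions pairs and respects floor arithmetic", {
  prob <- random_problem(5, 4, seed = 42)
  pairs <- score_unknown_pairs(prob$interactions, prob$drug_sim,
                               prob$target_sim)
  n <- nrow(pairs)
  lab <- apply_top_k(pairs, k_percent = 10, threshold = 0.5)
  counts <- label_counts(lab)
  expect_equal(unname(counts["selected"]), floor(0.10 * n))
  expect_equal(sum(counts[c("selected", "negative")]), n)
  expect_true(all(lab$label %in% c("positive", "unlabeled", "negative")))
  # all scores below threshold -> selection entirely unlabeled
  hi <- apply_top_k(pairs, k_percent = 50, threshold = 1)
  expect_equal(unname(label_counts(hi)["positive"]), 0L)
  expect_error(apply_top_k(pairs, k_percent = 0), "k_percent")
  expect_error(apply_top_k(pairs, k_percent = 101), "k_percent")
})

test_that("labelling is deterministic and monotone in k", {
  prob <- random_problem(8, 6, seed = 77)
  pairs <- score_unknown_pairs(prob$interactions, prob$drug_sim,
                               prob$target_sim)
  l1 <- apply_top_k(pairs, 30, 0.5)
  l2 <- apply_top_k(pairs, 30, 0.5)
  expect_identical(l1$label, l2$label)
  prev_sel <- 0L
  prev_pos <- 0L
  for (k in c(10, 20, 40, 60, 80, 100)) {
    cnt <- label_counts(apply_top_k(pairs, k, 0.5))
    expect_gte(cnt["selected"], prev_sel)
    expect_gte(cnt["positive"], prev_pos)
    prev_sel <- cnt["selected"]
    prev_pos <- cnt["positive"]
  }
  # at k = 100 every pair is selected
  expect_equal(unname(label_counts(apply_top_k(pairs, 100, 0.5))["negative"]),
               0L)
})
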