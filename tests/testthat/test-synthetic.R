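test_that("generator plants the requested structure deterministically", {
  spec <- synthetic_spec()
  d1 <- generate_dti(spec)
  d2 <- generate_dti(spec)
  expect_identical(d1, d2)
  # top-fraction rule: ceiling(0.05 * 2000) positives
  expect_equal(sum(d1$interactions$values), 100)
  expect_equal(dim(d1$true_scores), c(50, 40))
  # positives are exactly the top-scoring pairs
  thr <- min(d1$true_scores[d1$interactions$values == 1])
  expect_true(all(d1$true_scores[d1$interactions$values == 0] <= thr))
  # emitted matrices satisfy their invariants (constructors enforce them)
  expect_s3_class(d1$drug_sim, "dti_similarity")
  expect_equal(diag(d1$target_sim$values), setNames(rep(1, 40),
                                                    d1$target_sim$ids))
})

test_that("noise-free similarities are exactly the latent cosine geometry", {
  spec <- synthetic_spec(n_drugs = 10, n_targets = 8, latent_dim = 3,
                         interaction_density = 0.1, similarity_noise = 0,
                         seed = 5)
  d <- generate_dti(spec)
  # recompute: regenerate with the same seed and compare
  d2 <- generate_dti(spec)
  expect_identical(d$drug_sim$values, d2$drug_sim$values)
  # the planted scores rank the planted positives essentially perfectly
  expect_gte(compute_auc(as.vector(d$true_scores),
                         as.vector(d$interactions$values)), 0.99)
})

test_that("planted signal is visible to the similarity-kernel labeller", {
  d <- generate_dti(synthetic_spec())
  pairs <- score_unknown_pairs(d$interactions, d$drug_sim, d$target_sim)
  truth <- d$true_scores[cbind(match(pairs$drug_id, d$interactions$drug_ids),
                               match(pairs$target_id, d$interactions$target_ids))]
  expect_gt(cor(pairs$score, truth, method = "spearman"), 0)
})

test_that("fixtures round-trip through the readers and reject degenerate specs", {
  dir <- withr::local_tempdir()
  d <- generate_dti(synthetic_spec(n_drugs = 12, n_targets = 9, latent_dim = 3,
                                   interaction_density = 0.1, seed = 21))
  write_fixture(d, dir)
  back_int <- read_interaction_matrix(file.path(dir, "interactions.tsv"))
  back_ds <- read_similarity_matrix(file.path(dir, "drug_sim.tsv"))
  back_ts <- read_similarity_matrix(file.path(dir, "target_sim.tsv"))
  expect_equal(back_int$values, d$interactions$values)
  expect_equal(back_ds$values, d$drug_sim$values, tolerance = 0)
  expect_equal(back_ts$values, d$target_sim$values, tolerance = 0)
  expect_error(synthetic_spec(n_drugs = 4, n_targets = 4,
                              interaction_density = 0.01),
               "fewer than 2")
  expect_error(synthetic_spec(latent_dim = 100), "latent_dim")
})

test_that("random FASTA companion fixture is readable and seed-stable", {
  path <- withr::local_tempfile(fileext = ".fa")
  s1 <- random_protein_fasta(5, c(20, 30), path, seed = 3)
  seqs <- read_fasta(path)
  expect_identical(unname(seqs), unname(s1))
  expect_equal(length(seqs), 5)
  s2 <- random_protein_fasta(5, c(20, 30), withr::local_tempfile(), seed = 3)
  expect_identical(s1, s2)
})
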