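# Synthetic benchmark generator. A low-rank latent model plants the structure
# the whole method assumes -- similar drugs bind similar targets -- so the
# labelling kernel, the similarity-profile features and the end-to-end
# cross-validation are all exercised without external downloads.

#' Specification of a synthetic DTI benchmark
#'
#' Drugs and targets receive latent vectors; the interaction probability of a
#' pair is a logistic function of their scaled inner product; the top
#' `interaction_density` fraction of pairs by true score become the known
#' positives; and both similarity matrices are noisy cosine similarities of
#' the latent vectors, mapped into \[0,1\].
#'
#' @param n_drugs,n_targets entity counts.
#' @param latent_dim latent dimension (at most `min(n_drugs, n_targets)`).
#' @param interaction_density fraction of pairs marked positive, in (0,1).
#' @param similarity_noise standard deviation of the symmetric Gaussian noise
#'   added to the similarity matrices.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 50, n_targets = 40, latent_dim = 4,
                           interaction_density = 0.05,
                           similarity_noise = 0.05, seed = 7) {
  stopifnot(n_drugs >= 2, n_targets >= 2, latent_dim >= 1,
            latent_dim <= min(n_drugs, n_targets),
            interaction_density > 0, interaction_density < 1,
            similarity_noise >= 0)
  if (ceiling(interaction_density * n_drugs * n_targets) < 2) {
    stop_fmt("density %.3g yields fewer than 2 positives", interaction_density)
  }
  structure(list(n_drugs = as.integer(n_drugs),
                 n_targets = as.integer(n_targets),
                 latent_dim = as.integer(latent_dim),
                 interaction_density = interaction_density,
                 similarity_noise = similarity_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

latent_cosine_sim <- function(L, noise) {
  nrm <- sqrt(rowSums(L^2))
  cs <- (L / nrm) %*% t(L / nrm)
  v <- (cs + 1) / 2
  if (noise > 0) {
    n <- nrow(v)
    eps <- matrix(0, n, n)
    eps[upper.tri(eps)] <- rnorm(n * (n - 1) / 2, sd = noise)
    v <- v + eps + t(eps)
  }
  diag(v) <- 1
  pmin(pmax(v, 0), 1)
}

#' Generate a synthetic DTI benchmark
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `interactions` ([interaction_matrix()]), `drug_sim`
#'   and `target_sim` ([similarity_matrix()] objects) and `true_scores`
#'   (numeric drugs x targets matrix of planted interaction probabilities).
#' @export
generate_dti <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(substream_seed(spec$seed, "synthetic"), {
    Ld <- matrix(rnorm(spec$n_drugs * spec$latent_dim), spec$n_drugs)
    Lt <- matrix(rnorm(spec$n_targets * spec$latent_dim), spec$n_targets)
    raw <- Ld %*% t(Lt) * (2 / sqrt(spec$latent_dim))
    true_scores <- 1 / (1 + exp(-raw))
    n_pos <- ceiling(spec$interaction_density * length(true_scores))
    thr <- sort(true_scores, decreasing = TRUE)[n_pos]
    yv <- (true_scores >= thr) * 1
    # break threshold ties deterministically at exactly n_pos positives
    if (sum(yv) > n_pos) {
      extra <- which(true_scores == thr)
      yv[extra[seq_len(sum(yv) - n_pos)]] <- 0
    }
    if (sum(yv) == 0 || sum(yv) == length(yv)) {
      stop_fmt("degenerate synthetic interaction matrix (all %d)", yv[1])
    }
    drug_ids <- sprintf("D%03d", seq_len(spec$n_drugs))
    target_ids <- sprintf("hsa%03d", seq_len(spec$n_targets))
    ds <- latent_cosine_sim(Ld, spec$similarity_noise)
    ts <- latent_cosine_sim(Lt, spec$similarity_noise)
    dimnames(true_scores) <- list(drug_ids, target_ids)
    list(interactions = interaction_matrix(drug_ids, target_ids, yv),
         drug_sim = similarity_matrix(drug_ids, ds),
         target_sim = similarity_matrix(target_ids, ts),
         true_scores = true_scores)
  })
}

#' Write a synthetic benchmark as plain-text fixture files
#'
#' Files are written in exactly the dialects the readers ingest:
#' `interactions.tsv` (targets x drugs), `drug_sim.tsv`, `target_sim.tsv`
#' and `true_scores.tsv`.
#'
#' @param data output of [generate_dti()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of paths written.
#' @export
write_fixture <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("interactions.tsv", "drug_sim.tsv",
                            "target_sim.tsv", "true_scores.tsv"))
  write_interaction_matrix(data$interactions, paths[1])
  write_similarity_matrix(data$drug_sim, paths[2])
  write_similarity_matrix(data$target_sim, paths[3])
  ts <- data$true_scores
  lines <- c(paste(c("", colnames(ts)), collapse = "\t"),
             vapply(seq_len(nrow(ts)), function(i) {
               paste(c(rownames(ts)[i], sprintf("%.17g", ts[i, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, paths[4])
  invisible(paths)
}

#' Generate a random amino-acid FASTA file
#'
#' Optional companion fixture for exercising the Smith-Waterman path; writes
#' `n` random sequences over the 20-letter alphabet.
#'
#' @param n number of sequences.
#' @param length_range integer range of sequence lengths.
#' @param path output FASTA path.
#' @param seed integer seed.
#' @param ids optional identifiers (default `T001..`).
#' @return Invisibly, the named character vector of sequences.
#' @export
random_protein_fasta <- function(n, length_range = c(30, 80), path, seed = 1,
                                 ids = sprintf("T%03d", seq_len(n))) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- with_seed(substream_seed(seed, "fasta"), {
    vapply(seq_len(n), function(i) {
      paste(sample(aa, sample(length_range[1]:length_range[2], 1),
                   replace = TRUE), collapse = "")
    }, character(1))
  })
  names(seqs) <- ids
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(seqs)
}
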