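# Independent brute-force oracles, implemented separately from the package
# internals and kept deliberately naive.

# full-matrix affine-gap local alignment (Gotoh) over character vectors;
# quadratic memory, no optimizations shared with the production kernel
sw_oracle <- function(a, b, scoring) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  subs <- function(x, y) {
    if (is.null(scoring$substitution)) {
      if (x == y) scoring$match else scoring$mismatch
    } else {
      scoring$substitution[x, y]
    }
  }
  go <- scoring$gap_open
  ge <- scoring$gap_extend
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (left)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (up)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + go, E[i, j - 1] + ge)
      F[i, j] <- max(H[i - 1, j] + go, F[i - 1, j] + ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + subs(av[i - 1], bv[j - 1]),
                     E[i, j], F[i, j])
    }
  }
  max(H)
}

# pairwise-count AUC: fraction of positive-negative pairs ranked correctly,
# ties worth 1/2
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# precision-recall step-curve sweep over distinct thresholds
aupr_oracle <- function(scores, labels) {
  P <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (th in thr) {
    sel <- scores >= th
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# exhaustive max-product labelling scores over every known positive
label_score_oracle <- function(interactions, drug_sim, target_sim) {
  y <- interactions$values
  out <- list()
  for (i in seq_along(interactions$drug_ids)) {
    for (j in seq_along(interactions$target_ids)) {
      if (y[i, j] == 1) next
      best <- 0
      for (a in seq_along(interactions$drug_ids)) {
        for (b in seq_along(interactions$target_ids)) {
          if (y[a, b] == 1) {
            best <- max(best, drug_sim$values[i, a] * target_sim$values[j, b])
          }
        }
      }
      out[[length(out) + 1]] <- data.frame(
        drug_id = interactions$drug_ids[i],
        target_id = interactions$target_ids[j],
        score = best, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# random sequences over a given alphabet
random_seqs <- function(n, len_range, alphabet) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = "")
  }, character(1))
}

# small random dtigru problem for property tests
random_problem <- function(nd, nt, seed) {
  spec <- synthetic_spec(n_drugs = nd, n_targets = nt,
                         latent_dim = min(3, nd, nt),
                         interaction_density = 0.1,
                         similarity_noise = 0.05, seed = seed)
  generate_dti(spec)
}

# numeric finite-difference gradient of the package loss wrt every parameter
fd_gradients <- function(params, X, y, T_, d, eps = 1e-5) {
  lossf <- function(p) {
    fw <- dtigru:::gru_forward_batch(p, X, T_, d)
    dtigru:::bce_loss(fw$p, y)
  }
  g <- lapply(params, function(p) p * 0)
  for (nm in names(params)) {
    for (k in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- params; pm[[nm]][k] <- pm[[nm]][k] - eps
      g[[nm]][k] <- (lossf(pp) - lossf(pm)) / (2 * eps)
    }
  }
  g
}

max_rel_grad_err <- function(ga, gn) {
  max(vapply(names(ga), function(nm) {
    max(abs(ga[[nm]] - gn[[nm]]) / pmax(1e-8, abs(ga[[nm]]) + abs(gn[[nm]])))
  }, numeric(1)))
}
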