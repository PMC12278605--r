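# Positive-unlabeled class labelling of unknown drug-target pairs: score every
# unknown pair by its similarity to the known positives, then split the top-k%
# of pairs into positives/unlabeled by a threshold, treating the rest as
# negatives.

#' Score unknown drug-target pairs against the known positives
#'
#' Each pair (d, t) not in the known-positive set receives the max-product
#' similarity kernel score
#' \deqn{s(d,t) = \max_{(d',t') \in P} sim_D(d, d') \cdot sim_T(t, t')}
#' over the known positives P. With similarities in \[0,1\] the score is in
#' \[0,1\]; with no known positives all scores are 0 (with a warning).
#'
#' @param interactions a [interaction_matrix()] of known positives.
#' @param drug_sim,target_sim [similarity_matrix()] objects whose id lists
#'   match the interaction matrix exactly (same order).
#' @return A `data.frame` of class `dti_pairs` with columns `drug_id`,
#'   `target_id`, `score` and `label` (all `"unlabeled"` until
#'   [apply_top_k()] is applied), ordered by (drug, target) in matrix order.
#' @export
score_unknown_pairs <- function(interactions, drug_sim, target_sim) {
  stopifnot(inherits(interactions, "dti_interactions"),
            inherits(drug_sim, "dti_similarity"),
            inherits(target_sim, "dti_similarity"))
  if (!identical(interactions$drug_ids, drug_sim$ids)) {
    miss <- setdiff(interactions$drug_ids, drug_sim$ids)
    stop_fmt("drug ids of similarity matrix do not match interactions%s",
             if (length(miss)) sprintf(" (first missing: '%s')", miss[1]) else " (order differs)")
  }
  if (!identical(interactions$target_ids, target_sim$ids)) {
    miss <- setdiff(interactions$target_ids, target_sim$ids)
    stop_fmt("target ids of similarity matrix do not match interactions%s",
             if (length(miss)) sprintf(" (first missing: '%s')", miss[1]) else " (order differs)")
  }
  y <- interactions$values
  pos <- which(y == 1, arr.ind = TRUE)
  S <- matrix(0, nrow(y), ncol(y))
  for (p in seq_len(nrow(pos))) {
    S <- pmax(S, outer(drug_sim$values[, pos[p, 1]],
                       target_sim$values[, pos[p, 2]]))
  }
  if (nrow(pos) == 0) {
    warning("no known positives; all pair scores are 0", call. = FALSE)
  }
  unknown <- which(y == 0, arr.ind = TRUE)
  out <- data.frame(
    drug_id = interactions$drug_ids[unknown[, 1]],
    target_id = interactions$target_ids[unknown[, 2]],
    score = S[unknown],
    label = "unlabeled",
    stringsAsFactors = FALSE
  )
  out <- out[order(unknown[, 1], unknown[, 2]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dti_pairs", "data.frame")
  out
}

#' Label the top-k% of scored pairs
#'
#' Pairs are sorted by score descending (ties broken lexicographically by
#' (drug id, target id), making the ordering total and the labelling
#' deterministic). The top \eqn{\lfloor k/100 \cdot N \rfloor} pairs form the
#' selection; within it, pairs scoring at least `threshold` are labelled
#' `"positive"` and the rest stay `"unlabeled"`. Pairs outside the selection
#' are labelled `"negative"` (the negative class required for training).
#'
#' @param pairs a `dti_pairs` frame from [score_unknown_pairs()].
#' @param k_percent selection size as a percentage of pairs, in (0, 100].
#' @param threshold score threshold in \[0,1\] separating positives from
#'   unlabeled pairs inside the selection.
#' @return The `dti_pairs` frame with `label` filled in and attributes
#'   `k_percent` and `threshold` recorded.
#' @export
apply_top_k <- function(pairs, k_percent, threshold = 0.5) {
  stopifnot(inherits(pairs, "dti_pairs"))
  if (!is.numeric(k_percent) || length(k_percent) != 1 ||
      k_percent <= 0 || k_percent > 100) {
    stop_fmt("k_percent must be in (0, 100], got %s", format(k_percent))
  }
  if (threshold < 0 || threshold > 1) stop_fmt("threshold must be in [0,1]")
  n <- nrow(pairs)
  ord <- order(-pairs$score, pairs$drug_id, pairs$target_id)
  n_sel <- floor(k_percent / 100 * n)
  label <- rep("negative", n)
  sel <- ord[seq_len(n_sel)]
  label[sel] <- ifelse(pairs$score[sel] >= threshold, "positive", "unlabeled")
  pairs$label <- label
  attr(pairs, "k_percent") <- k_percent
  attr(pairs, "threshold") <- threshold
  pairs
}

#' Summarize a labelling
#'
#' @param pairs a labelled `dti_pairs` frame.
#' @return Named integer vector with counts of `selected`, `positive`,
#'   `unlabeled` (within the selection) and `negative` pairs.
#' @export
label_counts <- function(pairs) {
  stopifnot(inherits(pairs, "dti_pairs"))
  tab <- table(factor(pairs$label, levels = c("positive", "unlabeled", "negative")))
  c(selected = sum(tab[c("positive", "unlabeled")]),
    positive = unname(tab["positive"]),
    unlabeled = unname(tab["unlabeled"]),
    negative = unname(tab["negative"]))
}
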