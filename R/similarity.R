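# Sequence similarity by normalized Smith-Waterman local alignment, and a
# Tanimoto fingerprint fallback for drug-drug similarity when no precomputed
# chemical-structure similarity matrix is available.

#' Alignment scoring scheme
#'
#' Two modes are supported. With `substitution` given (a named square matrix,
#' or `"BLOSUM62"` for the Biostrings copy of that table), scores are looked
#' up per residue pair and gaps are affine: a gap of length k costs
#' `gap_open + (k-1) * gap_extend`. Without `substitution`, a simple
#' match/mismatch scheme is used with a linear gap penalty equal to
#' `gap_open` per gapped residue.
#'
#' The default is BLOSUM62 with gap open \eqn{-10} / extend \eqn{-1}, the
#' customary protein local-alignment setting; [simple_scoring()] gives the
#' toy match/mismatch mode.
#'
#' @param match,mismatch scores for the simple mode (`match > mismatch`).
#' @param gap_open,gap_extend non-positive gap penalties; in simple mode only
#'   `gap_open` is used (linear gaps).
#' @param substitution `NULL`, `"BLOSUM62"`, or a named square numeric matrix.
#' @return An object of class `dti_scoring`.
#' @export
#' @examples
#' simple_scoring(match = 2, mismatch = -1, gap = -1)
#' alignment_scoring()  # BLOSUM62, affine gaps
alignment_scoring <- function(substitution = "BLOSUM62",
                              gap_open = -10, gap_extend = -1,
                              match = 2, mismatch = -1) {
  if (is.character(substitution)) {
    if (!identical(substitution, "BLOSUM62")) {
      stop_fmt("unknown substitution table '%s'", substitution)
    }
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    substitution <- env$BLOSUM62
  }
  if (!is.null(substitution)) {
    substitution <- as.matrix(substitution)
    if (is.null(rownames(substitution)) ||
        !identical(rownames(substitution), colnames(substitution))) {
      stop_fmt("substitution matrix must have identical row and column names")
    }
    gap_extend <- gap_extend %||% gap_open
  } else {
    if (!(match > mismatch)) stop_fmt("match score must exceed mismatch score")
    gap_extend <- gap_open  # linear gaps in simple mode
  }
  if (gap_open > 0 || gap_extend > 0) stop_fmt("gap penalties must be non-positive")
  structure(list(substitution = substitution, match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "dti_scoring")
}

#' @rdname alignment_scoring
#' @param gap linear per-residue gap penalty for the simple mode.
#' @export
simple_scoring <- function(match = 2, mismatch = -1, gap = -1) {
  alignment_scoring(substitution = NULL, gap_open = gap, gap_extend = gap,
                    match = match, mismatch = mismatch)
}

# encode sequences as integer codes into a shared alphabet / the table rows
encode_seqs <- function(seqs, scoring) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  if (is.null(scoring$substitution)) {
    alph <- sort(unique(unlist(chars)))
    subst <- matrix(scoring$mismatch, length(alph), length(alph),
                    dimnames = list(alph, alph))
    diag(subst) <- scoring$match
  } else {
    subst <- scoring$substitution
    alph <- rownames(subst)
    unknown <- setdiff(unique(unlist(chars)), alph)
    if (length(unknown)) {
      stop_fmt("residue(s) %s not present in the substitution table",
               paste(sQuote(unknown), collapse = ", "))
    }
  }
  list(codes = lapply(chars, function(ch) match(ch, alph)), subst = subst)
}

#' Smith-Waterman local alignment score
#'
#' Returns the optimal local alignment score (the maximum cell of the
#' dynamic-programming matrix, floored at 0); no traceback is computed. The
#' production implementation is a linear-memory score-only Gotoh kernel in
#' C++.
#'
#' @param a,b non-empty character scalars (sequences).
#' @param scoring an [alignment_scoring()] scheme.
#' @return A non-negative number.
#' @export
#' @examples
#' sc <- simple_scoring(match = 2, mismatch = -1, gap = -1)
#' smith_waterman_score("ACG", "ACG", sc)  # 6
smith_waterman_score <- function(a, b, scoring = alignment_scoring()) {
  stopifnot(inherits(scoring, "dti_scoring"))
  if (!is.character(a) || !is.character(b) || !nzchar(a) || !nzchar(b)) {
    stop_fmt("sequences must be non-empty strings")
  }
  enc <- encode_seqs(c(a, b), scoring)
  sw_score_cpp(enc$codes[[1]], enc$codes[[2]], enc$subst,
               scoring$gap_open, scoring$gap_extend)
}

#' Normalized Smith-Waterman similarity matrix
#'
#' For sequences \eqn{A_i}, the similarity is the self-score-normalized local
#' alignment score
#' \deqn{Sim(A_i, A_j) = SW(A_i, A_j) / (\sqrt{SW(A_i, A_i)}\sqrt{SW(A_j, A_j)})}
#' so that identical sequences score 1. Ratios marginally above 1 (possible
#' with affine gaps and heterogeneous lengths) are clipped to 1 with a
#' warning.
#'
#' @param records named character vector of sequences (e.g. from
#'   [read_fasta()]).
#' @param scoring an [alignment_scoring()] scheme.
#' @return A [similarity_matrix()] over the record names.
#' @export
normalized_similarity <- function(records, scoring = alignment_scoring()) {
  if (length(records) < 2) stop_fmt("need at least 2 sequences")
  ids <- names(records)
  if (is.null(ids) || anyDuplicated(ids)) stop_fmt("records must have unique names")
  enc <- encode_seqs(unname(records), scoring)
  n <- length(records)
  self <- vapply(seq_len(n), function(i) {
    sw_score_cpp(enc$codes[[i]], enc$codes[[i]], enc$subst,
                 scoring$gap_open, scoring$gap_extend)
  }, numeric(1))
  if (any(self <= 0)) {
    stop_fmt("self-alignment score of record '%s' is not positive under this scoring",
             ids[self <= 0][1])
  }
  v <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sw_score_cpp(enc$codes[[i]], enc$codes[[j]], enc$subst,
                        scoring$gap_open, scoring$gap_extend)
      # sqrt of the product (not product of sqrts): exact for identical
      # sequences, where s == self so the ratio must be exactly 1
      v[i, j] <- v[j, i] <- s / sqrt(self[i] * self[j])
    }
  }
  if (any(v > 1 + 1e-12)) {
    warning(sprintf("%d normalized similarity value(s) exceeded 1 and were clipped",
                    sum(v > 1 + 1e-12) / 2L), call. = FALSE)
  }
  similarity_matrix(ids, pmin(v, 1))
}

#' Tanimoto (Jaccard) similarity between binary fingerprints
#'
#' Fallback drug-drug similarity for when no precomputed chemical-structure
#' similarity matrix is supplied: \eqn{|a \wedge b| / |a \vee b|}.
#'
#' @param fingerprints a binary matrix with one row per drug (rownames are
#'   drug ids), or a named list of equal-length binary vectors.
#' @return A [similarity_matrix()] over the drug ids.
#' @export
tanimoto_drug_similarity <- function(fingerprints) {
  if (is.list(fingerprints)) {
    fingerprints <- do.call(rbind, fingerprints)
  }
  fp <- as.matrix(fingerprints)
  if (is.null(rownames(fp))) stop_fmt("fingerprints must carry drug ids as names")
  if (!all(fp %in% c(0, 1))) stop_fmt("fingerprints must be binary")
  ones <- rowSums(fp)
  if (any(ones == 0)) {
    stop_fmt("all-zero fingerprint for drug '%s'", rownames(fp)[ones == 0][1])
  }
  inter <- fp %*% t(fp)
  uni <- outer(ones, ones, `+`) - inter
  similarity_matrix(rownames(fp), inter / uni)
}
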