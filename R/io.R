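# Readers and writers for the tab-delimited matrix dialect used by the
# bipartite interaction benchmarks (rows = targets, columns = drugs), plus
# FASTA ingestion and deterministic report serialization.

split_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop_fmt("%s: no data rows", path)
  strsplit(lines, "\t", fixed = TRUE)
}

# parse a labeled matrix file; returns list(row_ids, col_ids, values)
parse_labeled_matrix <- function(path) {
  fields <- split_tsv_lines(path)
  header <- fields[[1]]
  body <- fields[-1]
  widths <- lengths(body)
  if (length(unique(widths)) != 1) {
    stop_fmt("%s: ragged rows (row %d has %d fields, row 1 has %d)",
             path, which(widths != widths[1])[1] + 1L,
             widths[widths != widths[1]][1], widths[1])
  }
  # header may or may not carry a corner cell for the row-label column
  if (length(header) == widths[1]) {
    col_ids <- header[-1]
  } else if (length(header) == widths[1] - 1L) {
    col_ids <- header
  } else {
    stop_fmt("%s: header has %d fields but data rows have %d",
             path, length(header), widths[1])
  }
  row_ids <- vapply(body, `[`, character(1), 1L)
  vals <- suppressWarnings(
    do.call(rbind, lapply(body, function(f) as.numeric(f[-1])))
  )
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_fmt("%s: non-numeric cell at row '%s', column '%s'",
             path, row_ids[bad[1]], col_ids[bad[2]])
  }
  if (anyDuplicated(row_ids)) {
    stop_fmt("%s: duplicate row id '%s'", path, row_ids[anyDuplicated(row_ids)])
  }
  if (anyDuplicated(col_ids)) {
    stop_fmt("%s: duplicate column id '%s'", path, col_ids[anyDuplicated(col_ids)])
  }
  list(row_ids = row_ids, col_ids = col_ids,
       values = matrix(vals, nrow = length(row_ids),
                       dimnames = list(row_ids, col_ids)))
}

#' Construct a drug-target interaction matrix
#'
#' The known-positive set of a DTI problem: a binary adjacency matrix over
#' ordered drug and target identifier lists.
#'
#' @param drug_ids,target_ids character vectors of unique identifiers.
#' @param values numeric 0/1 matrix of shape `length(drug_ids)` x
#'   `length(target_ids)`.
#' @return An object of class `dti_interactions` with fields `drug_ids`,
#'   `target_ids` and `values` (drugs in rows).
#' @export
interaction_matrix <- function(drug_ids, target_ids, values) {
  values <- as.matrix(values)
  if (anyDuplicated(drug_ids)) stop_fmt("duplicate drug id '%s'", drug_ids[anyDuplicated(drug_ids)])
  if (anyDuplicated(target_ids)) stop_fmt("duplicate target id '%s'", target_ids[anyDuplicated(target_ids)])
  if (nrow(values) != length(drug_ids) || ncol(values) != length(target_ids)) {
    stop_fmt("interaction matrix is %dx%d but there are %d drugs and %d targets",
             nrow(values), ncol(values), length(drug_ids), length(target_ids))
  }
  if (!all(values %in% c(0, 1))) {
    bad <- which(!(values %in% c(0, 1)), arr.ind = FALSE)[1]
    ij <- arrayInd(bad, dim(values))
    stop_fmt("non-binary cell %g at drug '%s', target '%s'",
             values[bad], drug_ids[ij[1]], target_ids[ij[2]])
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(drug_ids, target_ids)
  structure(list(drug_ids = as.character(drug_ids),
                 target_ids = as.character(target_ids),
                 values = values),
            class = "dti_interactions")
}

#' @export
print.dti_interactions <- function(x, ...) {
  cat(sprintf("DTI interaction matrix: %d drugs x %d targets, %d known positives\n",
              length(x$drug_ids), length(x$target_ids), sum(x$values)))
  invisible(x)
}

#' Construct a similarity matrix
#'
#' Symmetric entity-by-entity similarity with unit diagonal and entries in
#' \[0,1\]; the container for both chemical-structure similarity between drugs
#' and normalized Smith-Waterman similarity between targets.
#'
#' @param ids character vector of unique identifiers.
#' @param values square numeric matrix.
#' @param sym_tol maximum tolerated asymmetry `max|A - t(A)|`.
#' @return An object of class `dti_similarity` with fields `ids`, `values`.
#' @export
similarity_matrix <- function(ids, values, sym_tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop_fmt("similarity matrix must be square, got %dx%d", nrow(values), ncol(values))
  }
  if (length(ids) != nrow(values)) stop_fmt("%d ids for a %d-row matrix", length(ids), nrow(values))
  if (anyDuplicated(ids)) stop_fmt("duplicate id '%s'", ids[anyDuplicated(ids)])
  asym <- abs(values - t(values))
  if (max(asym) > sym_tol) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop_fmt("asymmetric similarity: |A[%s,%s] - A[%s,%s]| = %.3g exceeds %g",
             ids[ij[1]], ids[ij[2]], ids[ij[2]], ids[ij[1]], max(asym), sym_tol)
  }
  values <- clip01(values, what = "similarity values")
  diag(values) <- 1
  values <- (values + t(values)) / 2
  dimnames(values) <- list(ids, ids)
  structure(list(ids = as.character(ids), values = values),
            class = "dti_similarity")
}

#' @export
print.dti_similarity <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("similarity matrix: %d entities, off-diagonal range [%.3f, %.3f]\n",
              length(x$ids), min(off), max(off)))
  invisible(x)
}

#' Read a binary interaction matrix from a tab-delimited file
#'
#' The expected file layout follows the public gold-standard benchmark
#' convention: rows are targets, columns are drugs, with identifier labels on
#' both axes and 0/1 cells. Use `orientation = "drugs_by_targets"` for files
#' written the other way around.
#'
#' @param path file path.
#' @param orientation `"targets_by_drugs"` (default) or `"drugs_by_targets"`.
#' @return A [interaction_matrix()] object.
#' @export
read_interaction_matrix <- function(path,
                                    orientation = c("targets_by_drugs",
                                                    "drugs_by_targets")) {
  orientation <- match.arg(orientation)
  m <- parse_labeled_matrix(path)
  if (orientation == "targets_by_drugs") {
    interaction_matrix(drug_ids = m$col_ids, target_ids = m$row_ids,
                       values = t(m$values))
  } else {
    interaction_matrix(drug_ids = m$row_ids, target_ids = m$col_ids,
                       values = m$values)
  }
}

#' Write an interaction matrix in the tab-delimited benchmark layout
#'
#' Rows are targets, columns are drugs (the layout [read_interaction_matrix()]
#' reads back by default). Output is byte-deterministic.
#'
#' @param x a [interaction_matrix()] object.
#' @param path output file path.
#' @export
write_interaction_matrix <- function(x, path) {
  stopifnot(inherits(x, "dti_interactions"))
  v <- t(x$values)
  lines <- c(paste(c("", x$drug_ids), collapse = "\t"),
             vapply(seq_along(x$target_ids), function(i) {
               paste(c(x$target_ids[i], format(v[i, ], trim = TRUE, scientific = FALSE)),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(NULL)
}

#' Read a labeled square similarity matrix
#'
#' Enforces the similarity contract: square, symmetric within `1e-8`,
#' entries clipped into \[0,1\] (silently for rounding noise up to `1e-6`,
#' with a warning for larger excursions), diagonal forced to exactly 1.
#'
#' @param path file path to a tab-delimited labeled square matrix.
#' @return A [similarity_matrix()] object.
#' @export
read_similarity_matrix <- function(path) {
  m <- parse_labeled_matrix(path)
  if (length(m$row_ids) != length(m$col_ids) ||
      !identical(m$row_ids, m$col_ids)) {
    stop_fmt("%s: row and column labels differ; similarity matrices must be square and labeled identically", path)
  }
  similarity_matrix(m$row_ids, m$values)
}

#' Write a similarity matrix with full-precision values
#'
#' @param x a [similarity_matrix()] object.
#' @param path output file path.
#' @export
write_similarity_matrix <- function(x, path) {
  stopifnot(inherits(x, "dti_similarity"))
  lines <- c(paste(c("", x$ids), collapse = "\t"),
             vapply(seq_along(x$ids), function(i) {
               paste(c(x$ids[i], sprintf("%.17g", x$values[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(NULL)
}

#' Read protein (or toy) sequences from FASTA
#'
#' Parsing is delegated to Biostrings; this wrapper uppercases sequences,
#' takes the header token up to the first whitespace as the identifier, and
#' enforces the record contract: unique non-empty ids, non-empty sequences,
#' no gap characters, and (for `alphabet = "aa"`) residues restricted to the
#' 20 standard amino acids plus X.
#'
#' @param path FASTA file path.
#' @param alphabet `"aa"` (default) to enforce the amino-acid alphabet, or
#'   `"any"` to accept arbitrary letters (useful for toy alphabets in tests).
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, alphabet = c("aa", "any")) {
  alphabet <- match.arg(alphabet)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_fmt("%s: FASTA parse error: %s",
                                               path, conditionMessage(e)))
  if (length(set) == 0) stop_fmt("%s: no FASTA records", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(ids) | is.na(ids))) stop_fmt("%s: empty record id", path)
  if (anyDuplicated(ids)) {
    stop_fmt("%s: duplicate record id '%s'", path, ids[anyDuplicated(ids)])
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop_fmt("%s: empty sequence for record '%s'", path, ids[nchar(seqs) == 0][1])
  }
  if (any(grepl("[-.]", seqs))) {
    stop_fmt("%s: gap characters in record '%s'", path, ids[grepl("[-.]", seqs)][1])
  }
  if (alphabet == "aa") {
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
    if (any(bad)) {
      stop_fmt("%s: illegal residues in record '%s' (allowed: 20 amino acids + X)",
               path, ids[bad][1])
    }
  } else if (any(grepl("[^A-Z]", seqs))) {
    stop_fmt("%s: non-letter characters in record '%s'", path,
             ids[grepl("[^A-Z]", seqs)][1])
  }
  names(seqs) <- ids
  seqs
}
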