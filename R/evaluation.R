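# Ranking metrics and the seeded cross-validation protocol, including the
# with/without-tuning ablation.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly drawn positive
#' outscores a uniformly drawn negative, with ties counted 1/2 (computed via
#' average ranks).
#'
#' @param scores numeric vector.
#' @param labels binary vector; both classes must be present.
#' @return Value in \[0,1\].
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1))) stop_fmt("labels must be binary")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop_fmt("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-curve area from a descending-score sweep, with tied scores processed
#' as a single block (precision evaluated at the end of the block).
#'
#' @param scores numeric vector.
#' @param labels binary vector with at least one positive.
#' @return Value in \[0,1\].
#' @export
compute_aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1))) stop_fmt("labels must be binary")
  P <- sum(labels == 1)
  if (P == 0) stop_fmt("at least one positive is required to compute AUPR")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  block_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y)[block_end]
  n_seen <- block_end
  prec <- tp / n_seen
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Create an evaluation report
#'
#' One row per cross-validation seed with AUC and AUPR as percentages, plus
#' mean/SD aggregates and the configuration snapshot that produced them.
#'
#' @param dataset dataset name.
#' @param rows data.frame with columns `cv_seed`, `auc`, `aupr` (percent).
#' @param config list snapshot of the resolved configuration.
#' @return An object of class `dti_report`.
#' @export
eval_report <- function(dataset, rows, config = list()) {
  stopifnot(is.data.frame(rows),
            all(c("cv_seed", "auc", "aupr") %in% names(rows)))
  if (nrow(rows) > 0) {
    stopifnot(all(rows$auc >= 0 & rows$auc <= 100),
              all(rows$aupr >= 0 & rows$aupr <= 100))
  }
  agg <- if (nrow(rows) > 0) {
    list(mean_auc = mean(rows$auc), sd_auc = stats::sd(rows$auc),
         mean_aupr = mean(rows$aupr), sd_aupr = stats::sd(rows$aupr))
  } else {
    list(mean_auc = NA_real_, sd_auc = NA_real_,
         mean_aupr = NA_real_, sd_aupr = NA_real_)
  }
  structure(list(dataset = dataset,
                 rows = rows[, c("cv_seed", "auc", "aupr")],
                 aggregate = agg, config = config),
            class = "dti_report")
}

#' @export
print.dti_report <- function(x, ...) {
  cat(sprintf("evaluation report: %s (%d seeds)\n", x$dataset, nrow(x$rows)))
  if (nrow(x$rows)) {
    print(x$rows, row.names = FALSE)
    cat(sprintf("mean AUC %.2f%% (SD %.2f), mean AUPR %.2f%% (SD %.2f)\n",
                x$aggregate$mean_auc, x$aggregate$sd_auc,
                x$aggregate$mean_aupr, x$aggregate$sd_aupr))
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' TSV output is byte-deterministic: fixed column order, `.` decimal
#' separator, two-decimal percentages, seed rows followed by `mean`/`sd`
#' rows. JSON output additionally carries the configuration snapshot with
#' fixed key order.
#'
#' @param report a [eval_report()] object.
#' @param path output file path.
#' @param format `"tsv"` (default) or `"json"`.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  stopifnot(inherits(report, "dti_report"))
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- "cv_seed\tauc\taupr"
    if (nrow(report$rows) > 0) {
      lines <- c(lines,
                 sprintf("%d\t%.2f\t%.2f", as.integer(report$rows$cv_seed),
                         report$rows$auc, report$rows$aupr),
                 sprintf("mean\t%.2f\t%.2f", report$aggregate$mean_auc,
                         report$aggregate$mean_aupr),
                 sprintf("sd\t%.2f\t%.2f", report$aggregate$sd_auc,
                         report$aggregate$sd_aupr))
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  } else {
    obj <- list(dataset = report$dataset,
                rows = report$rows,
                aggregate = report$aggregate,
                config = report$config)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(NULL)
}

# stratified fold assignment for pair indices; returns integer fold ids
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    f <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  })
}

# build the training frame for one fold: known train positives get label 1;
# similarity-labelled positives get label 1; top-k negatives get label 0,
# downsampled to `negative_ratio` negatives per positive
build_training_set <- function(train_int, drug_sim, target_sim, train_mask,
                               k_percent, threshold, negative_ratio, seed) {
  pairs <- score_unknown_pairs(train_int, drug_sim, target_sim)
  # restrict the labelling to pairs that belong to the training folds
  key <- paste(pairs$drug_id, pairs$target_id)
  pairs <- pairs[key %in% train_mask, , drop = FALSE]
  class(pairs) <- c("dti_pairs", "data.frame")
  pairs <- apply_top_k(pairs, k_percent, threshold)
  pos_known <- which(train_int$values == 1, arr.ind = TRUE)
  df_pos <- data.frame(
    drug_id = train_int$drug_ids[pos_known[, 1]],
    target_id = train_int$target_ids[pos_known[, 2]],
    y = 1, stringsAsFactors = FALSE)
  df_lab <- pairs[pairs$label == "positive", c("drug_id", "target_id")]
  df_lab[["y"]] <- rep(1, nrow(df_lab))
  df_neg <- pairs[pairs$label == "negative", c("drug_id", "target_id")]
  n_pos <- nrow(df_pos) + nrow(df_lab)
  n_neg <- min(nrow(df_neg), ceiling(negative_ratio * max(n_pos, 1)))
  keep <- with_seed(seed, sample.int(nrow(df_neg), n_neg))
  df_neg <- df_neg[keep, , drop = FALSE]
  df_neg[["y"]] <- rep(0, nrow(df_neg))
  out <- rbind(df_pos, df_lab, df_neg)
  rownames(out) <- NULL
  out
}

train_and_score <- function(train_df, test_df, drug_sim, target_sim, hp,
                            time_steps, seed) {
  enc_tr <- encode_pairs(train_df$drug_id, train_df$target_id,
                         drug_sim, target_sim, time_steps)
  d <- attr(enc_tr, "features")
  params <- init_weights_from_interactions(drug_sim, target_sim,
                                           d = d, h = hp$hidden_units,
                                           seed = seed)
  fit <- train_gru(params, enc_tr, train_df$y, hp, seed = seed)
  enc_te <- encode_pairs(test_df$drug_id, test_df$target_id,
                         drug_sim, target_sim, time_steps)
  list(probs = gru_predict(fit$params, enc_te), fit = fit)
}

# decode a WDO position into a gru_hyperparameters record
position_to_hp <- function(decoded) {
  gru_hyperparameters(learning_rate = decoded$learning_rate,
                      epochs = decoded$epochs,
                      batch_size = decoded$batch_size,
                      hidden_units = decoded$hidden_units)
}

#' Desk-scale hyperparameter search space for cross-validation
#'
#' A reduced version of [default_gru_space()] sized so that a full
#' cross-validated ablation runs in minutes on one CPU; see the methods
#' vignette for the sizing rationale.
#'
#' @return A [search_space()].
#' @export
cv_gru_space <- function() {
  search_space(dim_log("learning_rate", 0.03, 1),
               dim_integer("hidden_units", 4, 32),
               dim_integer("epochs", 30, 160),
               dim_integer("batch_size", 8, 64))
}

#' Seeded cross-validated evaluation of the DTI classifier
#'
#' For each seed, labelled pairs (all drug-target cells) are assigned to
#' `folds` folds, stratified by the true interaction label. Per fold, the
#' test fold's positives are masked out of the interaction matrix, the
#' similarity-kernel labelling runs on training positives only (no test
#' leakage), the GRU is trained on the resulting positives/negatives, and
#' the test fold's pairs are scored. AUC/AUPR are pooled over folds per seed
#' and reported as percentages. With `use_wdo = TRUE`, hyperparameters are
#' tuned per fold by Wind Driven Optimization on an inner 80/20 split of the
#' training pairs, minimizing the validation error rate, before the final
#' training on the full training set.
#'
#' @param interactions a [interaction_matrix()].
#' @param drug_sim,target_sim [similarity_matrix()] objects matching the
#'   interaction matrix id lists.
#' @param seeds integer vector of cross-validation seeds (default the five
#'   canonical seeds `3201, 2033, 5179, 2931, 9117`).
#' @param folds number of folds (default 5).
#' @param hp baseline [gru_hyperparameters()] used when no tuning runs.
#' @param use_wdo logical: tune hyperparameters by WDO per fold?
#' @param tuner `"none"` (fixed `hp`), `"wdo"`, or `"random"` (random search
#'   with exactly the WDO evaluation budget -- the equal-cost reference arm
#'   of the tuning ablation). Defaults to `"wdo"` when `use_wdo = TRUE`.
#' @param wdo_cfg [wdo_config()] for the tuner (a small budget by default).
#' @param space [search_space()] for the tuner (default [cv_gru_space()]).
#' @param k_percent,threshold labelling parameters (see [apply_top_k()]).
#' @param negative_ratio negatives kept per positive in the training set.
#' @param time_steps encoder time steps (see [encode_pair()]).
#' @param dataset name recorded in the report.
#' @param .label_hook optional function called with the per-fold masked
#'   interaction matrix and the test-pair keys (used by tests to verify that
#'   labelling never observes test positives).
#' @return An [eval_report()].
#' @export
cross_validate <- function(interactions, drug_sim, target_sim,
                           seeds = c(3201, 2033, 5179, 2931, 9117),
                           folds = 5,
                           hp = gru_hyperparameters(),
                           use_wdo = FALSE,
                           tuner = c(if (use_wdo) "wdo" else "none",
                                     "wdo", "random", "none"),
                           wdo_cfg = wdo_config(population = 5, iterations = 4,
                                                seed = 1),
                           space = cv_gru_space(),
                           k_percent = 10, threshold = 0.5,
                           negative_ratio = 3,
                           time_steps = 8,
                           dataset = "dataset",
                           .label_hook = NULL) {
  tuner <- match.arg(tuner)
  stopifnot(inherits(interactions, "dti_interactions"), folds >= 2,
            length(seeds) >= 1)
  y <- interactions$values
  all_pairs <- expand.grid(di = seq_along(interactions$drug_ids),
                           ti = seq_along(interactions$target_ids))
  truth <- y[cbind(all_pairs$di, all_pairs$ti)]
  rows <- data.frame(cv_seed = integer(0), auc = numeric(0), aupr = numeric(0))
  for (sd_ in seeds) {
    fold_seed <- substream_seed(sd_, "cv-folds")
    fold_id <- NULL
    for (attempt in 0:4) {
      cand <- stratified_folds(truth, folds, fold_seed + attempt)
      ok <- all(vapply(seq_len(folds), function(f) {
        length(unique(truth[cand == f])) == 2
      }, logical(1)))
      if (ok) { fold_id <- cand; break }
      warning(sprintf("seed %d: single-class fold, refolding (attempt %d)",
                      sd_, attempt + 1), call. = FALSE)
    }
    if (is.null(fold_id)) stop_fmt("seed %d: could not build folds with both classes", sd_)
    scores <- numeric(length(truth))
    for (f in seq_len(folds)) {
      test_idx <- which(fold_id == f)
      train_idx <- which(fold_id != f)
      masked <- y
      masked[cbind(all_pairs$di[test_idx], all_pairs$ti[test_idx])] <- 0
      train_int <- interaction_matrix(interactions$drug_ids,
                                      interactions$target_ids, masked)
      train_mask <- paste(interactions$drug_ids[all_pairs$di[train_idx]],
                          interactions$target_ids[all_pairs$ti[train_idx]])
      if (!is.null(.label_hook)) {
        .label_hook(train_int,
                    paste(interactions$drug_ids[all_pairs$di[test_idx]],
                          interactions$target_ids[all_pairs$ti[test_idx]]))
      }
      ts_seed <- substream_seed(sd_, sprintf("fold-%d", f))
      train_df <- build_training_set(train_int, drug_sim, target_sim,
                                     train_mask, k_percent, threshold,
                                     negative_ratio, ts_seed)
      hp_fold <- hp
      if (tuner != "none") {
        # tuner randomness descends from both the CV seed and the tuner seed
        tune_seed <- substream_seed(sd_ + wdo_cfg$seed,
                                    sprintf("wdo-fold-%d", f))
        hp_fold <- tune_fold_hp(train_df, drug_sim, target_sim, wdo_cfg,
                                space, time_steps, tune_seed, tuner = tuner)
      }
      test_df <- data.frame(
        drug_id = interactions$drug_ids[all_pairs$di[test_idx]],
        target_id = interactions$target_ids[all_pairs$ti[test_idx]],
        stringsAsFactors = FALSE)
      res <- train_and_score(train_df, test_df, drug_sim, target_sim,
                             hp_fold, time_steps, ts_seed)
      # scores are rank-normalized within the fold before pooling: the five
      # fold classifiers are independently calibrated models, and pooled
      # AUC/AUPR should measure their ranking quality, not accidental
      # agreement of their probability scales
      scores[test_idx] <- (rank(res$probs) - 0.5) / length(res$probs)
    }
    rows <- rbind(rows, data.frame(
      cv_seed = sd_,
      auc = round(100 * compute_auc(scores, truth), 2),
      aupr = round(100 * compute_aupr(scores, truth), 2)))
  }
  eval_report(dataset, rows,
              config = list(seeds = seeds, folds = folds, hp = unclass(hp),
                            tuner = tuner,
                            wdo = if (tuner != "none") unclass(wdo_cfg),
                            k_percent = k_percent, threshold = threshold,
                            negative_ratio = negative_ratio,
                            time_steps = time_steps))
}

# inner 80/20 tuning of hyperparameters, fitness = validation error rate.
# `tuner` is "wdo" or "random" (random search with the identical evaluation
# budget, the conventional equal-cost reference for a metaheuristic).
# Tuning-time trainings are capped at `max_inner` samples to keep the search
# affordable; the final per-fold training always uses the full training set.
tune_fold_hp <- function(train_df, drug_sim, target_sim, wdo_cfg, space,
                         time_steps, seed, tuner = "wdo", max_inner = 512) {
  n <- nrow(train_df)
  split <- with_seed(substream_seed(seed, "inner-split"), {
    idx <- sample.int(n)
    list(tr = idx[seq_len(floor(0.8 * n))],
         va = idx[(floor(0.8 * n) + 1):n])
  })
  inner_tr <- train_df[split$tr, , drop = FALSE]
  inner_va <- train_df[split$va, , drop = FALSE]
  if (nrow(inner_tr) > max_inner) {
    keep <- with_seed(substream_seed(seed, "inner-subsample"),
                      sample.int(nrow(inner_tr), max_inner))
    inner_tr <- inner_tr[keep, , drop = FALSE]
  }
  if (length(unique(inner_tr$y)) < 2 || length(unique(inner_va$y)) < 2) {
    return(position_to_hp(decode_position(numeric(length(space)), space)))
  }
  evals <- new.env()
  evals$dec <- list()
  evals$fit <- numeric(0)
  objective <- function(decoded) {
    hp_try <- position_to_hp(decoded)
    res <- train_and_score(inner_tr, inner_va, drug_sim, target_sim, hp_try,
                           time_steps, substream_seed(seed, "inner-train"))
    f <- fitness_error_rate(res$probs, inner_va$y)
    evals$dec[[length(evals$dec) + 1]] <- decoded
    evals$fit <- c(evals$fit, f)
    f
  }
  if (tuner == "wdo") {
    cfg <- wdo_cfg
    cfg$seed <- seed
    wdo_optimize(objective, space, cfg)
  } else {
    budget <- wdo_cfg$population * wdo_cfg$iterations
    D <- length(space)
    cand <- with_seed(substream_seed(seed, "random-search"),
                      matrix(runif(budget * D, -1, 1), budget, D))
    apply(cand, 1, function(pos) objective(decode_position(pos, space)))
  }
  select_parsimonious(evals$dec, evals$fit, space, length(inner_va$y))
}

# encode decoded coordinates back into [-1,1] per dimension
encode_coords <- function(decoded, space) {
  vapply(seq_along(space), function(j) {
    dm <- space[[j]]
    v <- decoded[[dm$name]]
    u <- switch(dm$kind,
                continuous = (v - dm$low) / (dm$high - dm$low),
                log_continuous = (log(v) - log(dm$low)) /
                  (log(dm$high) - log(dm$low)),
                integer = (v - dm$low) / (dm$high - dm$low))
    2 * u - 1
  }, numeric(1))
}

# one-standard-error selection rule over all evaluated candidates: among
# configurations whose validation error is within one binomial standard
# error of the best, deterministically prefer the one closest to the
# search-space midpoint. This stabilizes the per-fold choice when the
# fitness surface is flat near its optimum (the analog of glmnet's
# lambda.1se rule), and is applied identically to every tuner.
select_parsimonious <- function(decoded_list, fits, space, n_val) {
  best <- min(fits)
  p <- best / 100
  se <- 100 * sqrt(max(p * (1 - p), 1e-6) / n_val)
  ok <- which(fits <= best + se)
  dist <- vapply(ok, function(i) {
    sum(encode_coords(decoded_list[[i]], space)^2)
  }, numeric(1))
  position_to_hp(decoded_list[[ok[which.min(dist)]]])
}
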