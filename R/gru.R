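# A gated recurrent unit binary classifier implemented from first principles:
#   R_t = sigmoid(X_t W_xr + H_{t-1} W_hr + b_r)          (reset gate)
#   Z_t = sigmoid(X_t W_xz + H_{t-1} W_hz + b_z)          (update gate)
#   Hb_t = tanh(X_t W_xh + (R_t * H_{t-1}) W_hh + b_h)    (candidate state)
#   H_t = (1 - Z_t) * H_{t-1} + Z_t * Hb_t                (convex mixing)
# with a logistic output head p = sigmoid(H_T w_out + b_out), binary
# cross-entropy loss, and exact backpropagation through time.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Encode a drug-target pair as a similarity-profile time series
#'
#' The drug's similarity row and the target's similarity row are
#' concatenated, zero-padded to a multiple of `time_steps`, and reshaped
#' row-major into a `time_steps` x d matrix, so the recurrent model consumes
#' the pair's full similarity profile as a short multivariate sequence.
#'
#' @param drug_id,target_id identifiers present in the similarity matrices.
#' @param drug_sim,target_sim [similarity_matrix()] objects.
#' @param time_steps number of time steps T (default 8).
#' @return A `time_steps` x d numeric matrix of class `pair_encoding`.
#' @export
encode_pair <- function(drug_id, target_id, drug_sim, target_sim,
                        time_steps = 8) {
  stopifnot(inherits(drug_sim, "dti_similarity"),
            inherits(target_sim, "dti_similarity"), time_steps >= 1)
  if (!drug_id %in% drug_sim$ids) stop_fmt("unknown drug id '%s'", drug_id)
  if (!target_id %in% target_sim$ids) stop_fmt("unknown target id '%s'", target_id)
  v <- c(drug_sim$values[match(drug_id, drug_sim$ids), ],
         target_sim$values[match(target_id, target_sim$ids), ])
  d <- ceiling(length(v) / time_steps)
  v <- c(v, numeric(d * time_steps - length(v)))
  structure(matrix(v, nrow = time_steps, ncol = d, byrow = TRUE),
            class = "pair_encoding")
}

# encode many pairs at once: returns n x (T*d) matrix, features of step t in
# columns ((t-1)d+1):(td), matching encode_pair's row-major reshape
encode_pairs <- function(drug_ids, target_ids, drug_sim, target_sim,
                         time_steps = 8) {
  di <- match(drug_ids, drug_sim$ids)
  ti <- match(target_ids, target_sim$ids)
  if (anyNA(di)) stop_fmt("unknown drug id '%s'", drug_ids[is.na(di)][1])
  if (anyNA(ti)) stop_fmt("unknown target id '%s'", target_ids[is.na(ti)][1])
  raw <- cbind(drug_sim$values[di, , drop = FALSE],
               target_sim$values[ti, , drop = FALSE])
  d <- ceiling(ncol(raw) / time_steps)
  pad <- d * time_steps - ncol(raw)
  if (pad > 0) raw <- cbind(raw, matrix(0, nrow(raw), pad))
  structure(raw, time_steps = time_steps, features = d, dimnames = NULL)
}

new_gru_params <- function(W_xr, W_xz, W_xh, W_hr, W_hz, W_hh,
                           b_r, b_z, b_h, W_out, b_out) {
  p <- list(W_xr = W_xr, W_xz = W_xz, W_xh = W_xh,
            W_hr = W_hr, W_hz = W_hz, W_hh = W_hh,
            b_r = b_r, b_z = b_z, b_h = b_h,
            W_out = W_out, b_out = b_out)
  stopifnot(all(vapply(p, function(x) all(is.finite(x)), logical(1))))
  structure(p, class = "gru_params")
}

#' @export
print.gru_params <- function(x, ...) {
  cat(sprintf("GRU parameters: d = %d input features, h = %d hidden units (%d parameters)\n",
              nrow(x$W_xr), ncol(x$W_xr), sum(vapply(x, length, integer(1)))))
  invisible(x)
}

#' Interaction-informed GRU weight initialization
#'
#' The input-side weight matrices are seeded with the dominant singular
#' structure of the similarity data: the top-h left singular vectors of the
#' block-diagonal matrix `diag(drug_sim, target_sim)` (the matrix whose rows
#' are exactly the similarity profiles the encoder feeds the network),
#' truncated/padded to d rows and rescaled into the Glorot uniform range
#' \eqn{\pm\sqrt{6/(d+h)}}. Singular-vector signs are fixed by the
#' first-nonzero-component-positive convention so initialization is fully
#' deterministic. Recurrent matrices are seeded uniform in
#' \eqn{\pm\sqrt{6/(2h)}}; biases start at zero.
#'
#' @param drug_sim,target_sim [similarity_matrix()] objects.
#' @param d input features per time step.
#' @param h hidden units.
#' @param seed integer seed for the uniform draws.
#' @return A `gru_params` object.
#' @export
init_weights_from_interactions <- function(drug_sim, target_sim, d, h, seed) {
  stopifnot(inherits(drug_sim, "dti_similarity"),
            inherits(target_sim, "dti_similarity"),
            d >= 1, h >= 1)
  nd <- length(drug_sim$ids); nt <- length(target_sim$ids)
  B <- matrix(0, nd + nt, nd + nt)
  B[seq_len(nd), seq_len(nd)] <- drug_sim$values
  B[nd + seq_len(nt), nd + seq_len(nt)] <- target_sim$values
  sv <- svd(B, nu = min(h, nd + nt), nv = 0)
  U <- sv$u
  # sign convention: first nonzero component of each singular vector positive
  for (j in seq_len(ncol(U))) {
    nz <- which(abs(U[, j]) > 1e-12)[1]
    if (!is.na(nz) && U[nz, j] < 0) U[, j] <- -U[, j]
  }
  with_seed(substream_seed(seed, "gru-init"), {
    bound_x <- sqrt(6 / (d + h))
    Wx <- matrix(runif(d * h, -bound_x, bound_x), d, h)
    avail_r <- min(d, nrow(U))
    avail_c <- ncol(U)
    if (avail_c < h) {
      warning(sprintf("only %d singular vectors available for %d hidden units; padding with uniform draws",
                      avail_c, h), call. = FALSE)
    }
    block <- U[seq_len(avail_r), seq_len(min(h, avail_c)), drop = FALSE]
    sc <- max(abs(block))
    if (sc > 0) block <- block * (bound_x / sc)
    Wx[seq_len(avail_r), seq_len(ncol(block))] <- block
    bound_h <- sqrt(6 / (2 * h))
    Wh <- function() matrix(runif(h * h, -bound_h, bound_h), h, h)
    bound_o <- sqrt(6 / (h + 1))
    new_gru_params(W_xr = Wx, W_xz = Wx, W_xh = Wx,
                   W_hr = Wh(), W_hz = Wh(), W_hh = Wh(),
                   b_r = numeric(h), b_z = numeric(h), b_h = numeric(h),
                   W_out = matrix(runif(h, -bound_o, bound_o), h, 1),
                   b_out = 0)
  })
}

# plain seeded Glorot-uniform initialization (used when no similarity
# matrices are in play, e.g. toy tests)
init_weights_random <- function(d, h, seed) {
  with_seed(substream_seed(seed, "gru-init-random"), {
    bx <- sqrt(6 / (d + h)); bh <- sqrt(6 / (2 * h)); bo <- sqrt(6 / (h + 1))
    W <- function(n, m, b) matrix(runif(n * m, -b, b), n, m)
    new_gru_params(W_xr = W(d, h, bx), W_xz = W(d, h, bx), W_xh = W(d, h, bx),
                   W_hr = W(h, h, bh), W_hz = W(h, h, bh), W_hh = W(h, h, bh),
                   b_r = numeric(h), b_z = numeric(h), b_h = numeric(h),
                   W_out = W(h, 1, bo), b_out = 0)
  })
}

# batched forward pass: X is n x (T*d); returns hidden states and
# per-step caches needed by the backward pass
gru_forward_batch <- function(params, X, time_steps, features, keep_cache = FALSE) {
  n <- nrow(X); h <- ncol(params$W_hr); d <- features
  H <- matrix(0, n, h)
  cache <- if (keep_cache) vector("list", time_steps) else NULL
  Hs <- vector("list", time_steps)
  for (t in seq_len(time_steps)) {
    Xt <- X[, ((t - 1) * d + 1):(t * d), drop = FALSE]
    R <- sigmoid(Xt %*% params$W_xr + H %*% params$W_hr +
                   rep(params$b_r, each = n))
    Z <- sigmoid(Xt %*% params$W_xz + H %*% params$W_hz +
                   rep(params$b_z, each = n))
    RH <- R * H
    Hb <- tanh(Xt %*% params$W_xh + RH %*% params$W_hh +
                 rep(params$b_h, each = n))
    Hnew <- (1 - Z) * H + Z * Hb
    if (any(!is.finite(Hnew))) stop_fmt("non-finite hidden state at time step %d", t)
    if (keep_cache) cache[[t]] <- list(Xt = Xt, Hprev = H, R = R, Z = Z,
                                       RH = RH, Hb = Hb)
    H <- Hnew
    Hs[[t]] <- H
  }
  logits <- drop(H %*% params$W_out) + params$b_out
  list(H = Hs, H_last = H, logits = logits, p = sigmoid(logits), cache = cache)
}

#' GRU forward pass for a single pair encoding
#'
#' Runs the gate equations with \eqn{H_0 = 0} and returns every hidden state
#' together with the output probability \eqn{p = \sigma(H_T w_{out} + b_{out})}.
#'
#' @param params a `gru_params` object.
#' @param x a T x d matrix (e.g. from [encode_pair()]).
#' @return A list with `hidden` (T x h matrix of hidden states) and `p`
#'   (probability in (0,1)).
#' @export
gru_forward <- function(params, x) {
  stopifnot(inherits(params, "gru_params"))
  x <- as.matrix(x)
  if (ncol(x) != nrow(params$W_xr)) {
    stop_fmt("encoding has %d features per step but params expect %d",
             ncol(x), nrow(params$W_xr))
  }
  fw <- gru_forward_batch(params, matrix(t(x), nrow = 1),
                          time_steps = nrow(x), features = ncol(x))
  list(hidden = do.call(rbind, fw$H), p = unname(fw$p))
}

# backward pass: exact gradients of mean binary cross-entropy
gru_backward <- function(params, fw, y, time_steps) {
  n <- length(y)
  g <- lapply(params, function(p) p * 0)
  dlogit <- (fw$p - y) / n                      # d(mean BCE)/d logits
  g$W_out <- t(fw$H_last) %*% dlogit
  g$b_out <- sum(dlogit)
  dH <- outer(dlogit, drop(params$W_out))       # n x h
  for (t in rev(seq_len(time_steps))) {
    cc <- fw$cache[[t]]
    dZ <- dH * (cc$Hb - cc$Hprev)
    dHb <- dH * cc$Z
    dAh <- dHb * (1 - cc$Hb^2)
    dRH <- dAh %*% t(params$W_hh)
    dR <- dRH * cc$Hprev
    dAr <- dR * cc$R * (1 - cc$R)
    dAz <- dZ * cc$Z * (1 - cc$Z)
    g$W_xh <- g$W_xh + t(cc$Xt) %*% dAh
    g$W_hh <- g$W_hh + t(cc$RH) %*% dAh
    g$b_h <- g$b_h + colSums(dAh)
    g$W_xr <- g$W_xr + t(cc$Xt) %*% dAr
    g$W_hr <- g$W_hr + t(cc$Hprev) %*% dAr
    g$b_r <- g$b_r + colSums(dAr)
    g$W_xz <- g$W_xz + t(cc$Xt) %*% dAz
    g$W_hz <- g$W_hz + t(cc$Hprev) %*% dAz
    g$b_z <- g$b_z + colSums(dAz)
    dH <- dH * (1 - cc$Z) + dRH * cc$R +
      dAr %*% t(params$W_hr) + dAz %*% t(params$W_hz)
  }
  g
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

#' GRU training hyperparameters
#'
#' Defaults were calibrated once on the synthetic benchmark (plain
#' mini-batch gradient descent needs a larger step size than adaptive
#' optimizers); see the methods vignette.
#'
#' @param learning_rate positive step size for mini-batch gradient descent.
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param hidden_units number of hidden units h.
#' @return A named list of class `gru_hp`.
#' @export
gru_hyperparameters <- function(learning_rate = 0.3, epochs = 120,
                                batch_size = 32, hidden_units = 16) {
  stopifnot(learning_rate >= 0, epochs >= 1, batch_size >= 1, hidden_units >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 hidden_units = as.integer(hidden_units)),
            class = "gru_hp")
}

#' Train the GRU classifier by backpropagation through time
#'
#' Minimizes mean binary cross-entropy with mini-batch gradient descent.
#' Shuffling is driven entirely by `seed`; gradients are clipped at global
#' norm 5 (clip events are counted in the result). Per-epoch mean training
#' loss (computed before each update, so full-batch runs report the exact
#' loss trajectory) is returned.
#'
#' @param params initial `gru_params` (see
#'   [init_weights_from_interactions()]).
#' @param encodings n x (T*d) matrix of stacked pair encodings, or a list of
#'   `pair_encoding` matrices.
#' @param labels binary vector of length n; both classes must be present.
#' @param hp a [gru_hyperparameters()] record.
#' @param seed integer seed controlling shuffling.
#' @return A list with `params` (trained), `loss` (per-epoch mean loss) and
#'   `clipped` (number of clipped gradient steps).
#' @export
train_gru <- function(params, encodings, labels, hp = gru_hyperparameters(),
                      seed = 1) {
  stopifnot(inherits(params, "gru_params"))
  if (is.list(encodings) && !is.matrix(encodings)) {
    tl <- vapply(encodings, nrow, integer(1))
    stopifnot(length(unique(tl)) == 1)
    X <- do.call(rbind, lapply(encodings, function(e) as.vector(t(e))))
    attr(X, "time_steps") <- tl[1]
    attr(X, "features") <- ncol(encodings[[1]])
    encodings <- X
  }
  T_ <- attr(encodings, "time_steps")
  d <- attr(encodings, "features")
  stopifnot(!is.null(T_), !is.null(d), nrow(encodings) == length(labels))
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop_fmt("labels must be binary")
  if (length(unique(y)) < 2) stop_fmt("training data must contain both classes")
  clip_norm <- 5
  n <- length(y)
  # shuffling semantics (and seed determinism) live in R; the compiled
  # training loop consumes the precomputed per-epoch permutations
  perms <- with_seed(substream_seed(seed, "gru-train"), {
    do.call(rbind, lapply(seq_len(hp$epochs), function(ep) sample.int(n)))
  })
  res <- gru_train_cpp(unclass(params), encodings, y, T_, d,
                       hp$learning_rate, perms, hp$batch_size, clip_norm)
  trained <- res$params
  trained$b_r <- drop(trained$b_r)
  trained$b_z <- drop(trained$b_z)
  trained$b_h <- drop(trained$b_h)
  list(params = do.call(new_gru_params, trained),
       loss = drop(res$loss), clipped = res$clipped)
}

#' Predict interaction probabilities for stacked encodings
#'
#' @param params trained `gru_params`.
#' @param encodings n x (T*d) matrix from the internal batch encoder, or a
#'   list of `pair_encoding` matrices.
#' @return Numeric vector of probabilities.
#' @export
gru_predict <- function(params, encodings) {
  if (is.list(encodings) && !is.matrix(encodings)) {
    return(vapply(encodings, function(e) gru_forward(params, e)$p, numeric(1)))
  }
  drop(gru_predict_cpp(unclass(params), encodings,
                       attr(encodings, "time_steps"),
                       attr(encodings, "features")))
}
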