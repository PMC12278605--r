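#' @useDynLib dtigru, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd median quantile
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' Every source of randomness in the pipeline draws from a named substream so
#' that toggling one stage (e.g. hyperparameter tuning) does not perturb the
#' random draws of another. The substream seed is a deterministic hash of the
#' global seed and the stage name, kept below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage name, e.g. `"training"`, `"wdo"`.
#' @return An integer seed.
#' @export
#' @examples
#' substream_seed(42, "training")
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(stage)) h <- (h * 131 + c) %% m
  as.integer(h)
}

# evaluate `expr` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# clip values into [0,1]; warn only when the excursion exceeds `quiet_tol`
clip01 <- function(x, quiet_tol = 1e-6, what = "values") {
  lo <- min(x)
  hi <- max(x)
  if (hi > 1 + quiet_tol || lo < -quiet_tol) {
    warning(sprintf("%s outside [0,1] by up to %.3g; clipped", what,
                    max(hi - 1, -lo)), call. = FALSE)
  }
  pmin(pmax(x, 0), 1)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
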