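# Wind Driven Optimization: a population metaheuristic in which candidate
# solutions ("air parcels") move through the bounded search space [-1,1]^D
# under friction, gravity, a rank-scaled pressure-gradient pull toward the
# best parcel, and a Coriolis-like cross-dimension deflection:
#   u_new = (1 - alpha) u_cur - g x_cur
#           + RT |1 - 1/i| (x_opt - x_cur) + c u_cur[other dim] / i
#   x_new = x_cur + u_new                       (time step 1)
# where i is the parcel's pressure rank (1 = best). Pressure is the fitness
# being minimized; actual fitness values are replaced by ranks in the
# velocity update.

#' WDO configuration
#'
#' @param alpha friction coefficient in \[0,1\].
#' @param g gravitation constant (pull toward the origin), >= 0.
#' @param RT pressure-gradient coefficient (gas constant x temperature), >= 0.
#' @param c Coriolis coefficient, >= 0.
#' @param population number of air parcels, >= 2.
#' @param iterations number of iterations, >= 1.
#' @param v_max velocity clamp, > 0.
#' @param seed integer seed for initialization and the Coriolis dimension
#'   draws.
#' @return A list of class `wdo_config`.
#' @export
wdo_config <- function(alpha = 0.4, g = 0.2, RT = 3, c = 0.4,
                       population = 20, iterations = 500, v_max = 0.3,
                       seed = 1) {
  stopifnot(alpha >= 0, alpha <= 1, g >= 0, RT >= 0, c >= 0,
            population >= 2, iterations >= 1, v_max > 0,
            is.finite(c(alpha, g, RT, c, v_max)))
  structure(list(alpha = alpha, g = g, RT = RT, c = c,
                 population = as.integer(population),
                 iterations = as.integer(iterations),
                 v_max = v_max, seed = as.integer(seed)),
            class = "wdo_config")
}

#' Hyperparameter search space
#'
#' Each dimension is searched on \[-1,1\] internally and decoded affinely to
#' `[low, high]`; `log_continuous` dimensions decode on the log scale and
#' `integer` dimensions round half-even after decoding.
#'
#' @param ... one or more dimension specs created by [dim_continuous()],
#'   [dim_log()] or [dim_integer()].
#' @return A list of class `search_space`.
#' @export
search_space <- function(...) {
  dims <- list(...)
  nm <- vapply(dims, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_fmt("duplicate dimension name '%s'", nm[anyDuplicated(nm)])
  structure(dims, class = "search_space", names = nm)
}

new_dim <- function(name, kind, low, high) {
  stopifnot(is.character(name), nzchar(name))
  if (!(low < high)) stop_fmt("dimension '%s': low must be < high", name)
  if (kind == "log_continuous" && low <= 0) stop_fmt("dimension '%s': log scale needs low > 0", name)
  list(name = name, kind = kind, low = low, high = high)
}

#' @rdname search_space
#' @param name dimension name.
#' @param low,high bounds of the decoded dimension.
#' @export
dim_continuous <- function(name, low, high) new_dim(name, "continuous", low, high)

#' @rdname search_space
#' @export
dim_log <- function(name, low, high) new_dim(name, "log_continuous", low, high)

#' @rdname search_space
#' @export
dim_integer <- function(name, low, high) new_dim(name, "integer", low, high)

#' Decode a position in [-1,1]^D into search-space coordinates
#'
#' @param position numeric vector in \[-1,1\]^D.
#' @param space a [search_space()].
#' @return Named list of decoded values.
#' @export
decode_position <- function(position, space) {
  stopifnot(length(position) == length(space))
  out <- lapply(seq_along(space), function(j) {
    dm <- space[[j]]
    u <- (position[j] + 1) / 2
    switch(dm$kind,
           continuous = dm$low + u * (dm$high - dm$low),
           log_continuous = exp(log(dm$low) + u * (log(dm$high) - log(dm$low))),
           integer = round(dm$low + u * (dm$high - dm$low)))
  })
  names(out) <- names(space)
  out
}

#' Rank parcels by pressure
#'
#' Lower pressure (fitness) is better; rank 1 is the best parcel. Ties break
#' by parcel index; non-finite pressures are pushed to the worst ranks with a
#' warning.
#'
#' @param pressures numeric vector of fitness values.
#' @return Integer permutation of `1:length(pressures)`.
#' @export
rank_parcels <- function(pressures) {
  stopifnot(length(pressures) >= 1)
  if (any(!is.finite(pressures))) {
    warning("non-finite pressure(s) assigned worst rank", call. = FALSE)
    pressures[!is.finite(pressures)] <- Inf
  }
  rk <- integer(length(pressures))
  rk[order(pressures, seq_along(pressures))] <- seq_along(pressures)
  rk
}

#' WDO velocity update
#'
#' Applies the velocity update for one parcel. The pressure-gradient term is
#' scaled by `|1 - 1/i|`, so the rank-1 parcel feels no pull; the Coriolis
#' term deflects each dimension by the parcel's current velocity in one
#' uniformly drawn *other* dimension (0 when D = 1). The result is clamped to
#' `±v_max`. Draws come from the current RNG state.
#'
#' @param velocity,position numeric vectors of length D.
#' @param rank parcel's pressure rank (1 = best).
#' @param x_opt position of the rank-1 parcel.
#' @param cfg a [wdo_config()].
#' @return New velocity vector.
#' @export
velocity_update <- function(velocity, position, rank, x_opt, cfg) {
  D <- length(position)
  stopifnot(length(velocity) == D, length(x_opt) == D, rank >= 1)
  cor_term <- if (D == 1) 0 else {
    other <- vapply(seq_len(D), function(j) {
      k <- sample.int(D - 1L, 1L)
      if (k >= j) k + 1L else k
    }, integer(1))
    cfg$c * velocity[other] / rank
  }
  u <- (1 - cfg$alpha) * velocity - cfg$g * position +
    cfg$RT * abs(1 - 1 / rank) * (x_opt - position) + cor_term
  pmin(pmax(u, -cfg$v_max), cfg$v_max)
}

#' WDO position update with reflecting boundaries
#'
#' Moves the parcel by its new velocity (unit time step) and reflects any
#' out-of-bounds coordinate back into \[-1,1\], flipping the corresponding
#' velocity component's sign.
#'
#' @param position current position in \[-1,1\]^D.
#' @param velocity new (clamped) velocity.
#' @return List with `position` and `velocity` after reflection.
#' @export
position_update <- function(position, velocity) {
  x <- position + velocity
  for (j in seq_along(x)) {
    while (x[j] > 1 || x[j] < -1) {
      if (x[j] > 1) { x[j] <- 2 - x[j]; velocity[j] <- -velocity[j] }
      else { x[j] <- -2 - x[j]; velocity[j] <- -velocity[j] }
    }
  }
  list(position = x, velocity = velocity)
}

#' Run Wind Driven Optimization
#'
#' Positions start uniform in \[-1,1\]^D and velocities uniform in
#' `±v_max/10`, all drawn from `cfg$seed`. Each iteration evaluates the
#' objective at every parcel's decoded position, ranks parcels by fitness,
#' then applies [velocity_update()] and [position_update()]. An objective
#' error sets that parcel's pressure to `+Inf` for the iteration.
#'
#' @param objective function taking a named list of decoded coordinates and
#'   returning a scalar fitness to minimize.
#' @param space a [search_space()].
#' @param cfg a [wdo_config()].
#' @return List with `best` (decoded coordinates), `best_fitness`,
#'   `best_position` (raw, in \[-1,1\]^D) and `history` (data.frame with
#'   iteration, best-so-far and mean fitness).
#' @export
wdo_optimize <- function(objective, space, cfg = wdo_config()) {
  stopifnot(inherits(space, "search_space"), inherits(cfg, "wdo_config"))
  D <- length(space)
  with_seed(substream_seed(cfg$seed, "wdo"), {
    x <- matrix(runif(cfg$population * D, -1, 1), cfg$population, D)
    v <- matrix(runif(cfg$population * D, -cfg$v_max / 10, cfg$v_max / 10),
                cfg$population, D)
    best_fit <- Inf
    best_x <- x[1, ]
    hist <- data.frame(iteration = seq_len(cfg$iterations),
                       best_fitness = NA_real_, mean_fitness = NA_real_)
    for (it in seq_len(cfg$iterations)) {
      press <- vapply(seq_len(cfg$population), function(k) {
        val <- tryCatch(objective(decode_position(x[k, ], space)),
                        error = function(e) {
                          message(sprintf("objective error at parcel %d: %s",
                                          k, conditionMessage(e)))
                          Inf
                        })
        if (!is.numeric(val) || length(val) != 1 || is.na(val)) Inf else val
      }, numeric(1))
      rk <- suppressWarnings(rank_parcels(press))
      if (min(press) < best_fit) {
        best_fit <- min(press)
        best_x <- x[which.min(press), ]
      }
      hist$best_fitness[it] <- best_fit
      hist$mean_fitness[it] <- mean(press[is.finite(press)])
      x_opt <- x[which(rk == 1L), ]
      for (k in seq_len(cfg$population)) {
        u <- velocity_update(v[k, ], x[k, ], rk[k], x_opt, cfg)
        upd <- position_update(x[k, ], u)
        x[k, ] <- upd$position
        v[k, ] <- upd$velocity
      }
    }
    list(best = decode_position(best_x, space), best_fitness = best_fit,
         best_position = best_x, history = hist)
  })
}

#' Classification error rate (percent)
#'
#' The fitness minimized during hyperparameter tuning: the percentage of
#' misclassified samples, with predicted class `p >= threshold`.
#'
#' @param probabilities numeric vector of predicted probabilities.
#' @param labels binary vector of the same length.
#' @param threshold decision threshold (default 0.5).
#' @return Percentage in \[0, 100\].
#' @export
fitness_error_rate <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) != length(labels) || length(labels) < 1) {
    stop_fmt("probabilities and labels must have equal positive length")
  }
  if (!all(labels %in% c(0, 1))) stop_fmt("labels must be binary")
  pred <- as.numeric(probabilities >= threshold)
  100 * mean(pred != labels)
}

#' Default GRU hyperparameter search space
#'
#' Learning rate on the log scale, hidden units, epochs and batch size as
#' integers.
#'
#' @return A [search_space()].
#' @export
default_gru_space <- function() {
  search_space(dim_log("learning_rate", 1e-4, 1e-1),
               dim_integer("hidden_units", 8, 128),
               dim_integer("epochs", 20, 200),
               dim_integer("batch_size", 8, 64))
}
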