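sphere_space <- function(D = 10) {
  do.call(search_space, lapply(seq_len(D), function(j) {
    dim_continuous(paste0("x", j), -1, 1)
  }))
}
sphere <- function(p) sum(unlist(p)^2)

test_that("velocity update matches the hand-evaluated case and its structure", {
  cfg <- wdo_config(alpha = 0.8, g = 0.2, RT = 3, c = 0, v_max = 10)
  u <- velocity_update(velocity = 0.1, position = 0.5, rank = 2,
                       x_opt = -0.5, cfg = cfg)
  expect_equal(u, 0.2 * 0.1 - 0.2 * 0.5 + 3 * 0.5 * (-1))  # -1.58
  # clamped when v_max is small
  cfg2 <- wdo_config(alpha = 0.8, g = 0.2, RT = 3, c = 0, v_max = 1)
  expect_equal(velocity_update(0.1, 0.5, 2, -0.5, cfg2), -1)
  # alpha = 1, g = RT = c = 0: every term vanishes
  cfg3 <- wdo_config(alpha = 1, g = 0, RT = 0, c = 0)
  set.seed(1)
  expect_equal(velocity_update(runif(4), runif(4), 3, runif(4), cfg3),
               rep(0, 4))
  # the rank-1 parcel feels no pressure-gradient pull
  cfg4 <- wdo_config(alpha = 0, g = 0, RT = 7, c = 0, v_max = 100)
  expect_equal(velocity_update(0.3, 0.2, 1, 0.9, cfg4), 0.3)
})

test_that("position update reflects at the boundary and flips velocity", {
  upd <- position_update(0.9, 0.3)
  expect_equal(upd$position, 0.8)
  expect_equal(upd$velocity, -0.3)
  upd2 <- position_update(c(0.5, -0.9), c(0, -0.4))
  expect_equal(upd2$position, c(0.5, -0.7))
  expect_equal(upd2$velocity, c(0, 0.4))
  expect_true(all(abs(position_update(runif(5, -1, 1), runif(5, -2, 2))$position) <= 1))
})

test_that("rank substitution sorts pressures with index tie-breaks and NaN worst", {
  expect_equal(rank_parcels(c(3, 1, 2)), c(3L, 1L, 2L))
  expect_equal(rank_parcels(rep(5, 4)), 1:4)
  expect_warning(rk <- rank_parcels(c(1, NaN, 2)), "non-finite")
  expect_equal(rk, c(1L, 3L, 2L))
})

test_that("optimizer maintains its invariants on the sphere", {
  sp <- sphere_space(3)
  cfg <- wdo_config(population = 6, iterations = 40, seed = 5)
  # instrumented objective records every decoded position
  seen <- new.env(); seen$x <- list()
  obj <- function(p) {
    seen$x[[length(seen$x) + 1]] <- unlist(p)
    sphere(p)
  }
  res <- wdo_optimize(obj, sp, cfg)
  expect_true(all(diff(res$history$best_fitness) <= 0))
  pos <- do.call(rbind, seen$x)
  expect_true(all(pos >= -1 & pos <= 1))
  expect_equal(nrow(pos), 6 * 40)
  # determinism
  res2 <- wdo_optimize(sphere, sp, cfg)
  expect_identical(res$history, res2$history)
  # constant objective: best fitness fixed after the first iteration
  resc <- wdo_optimize(function(p) 7, sp,
                       wdo_config(population = 4, iterations = 10, seed = 2))
  expect_equal(unique(resc$history$best_fitness), 7)
  # erroring objective is survivable
  rese <- wdo_optimize(function(p) if (p$x1 > 0) stop("boom") else sphere(p),
                       sp, wdo_config(population = 4, iterations = 5, seed = 3))
  expect_true(is.finite(rese$best_fitness))
})

test_that("search-space decoding covers all three kinds", {
  sp <- search_space(dim_continuous("a", -2, 6),
                     dim_log("b", 1e-4, 1e-1),
                     dim_integer("c", 8, 128))
  mid <- decode_position(c(0, 0, 0), sp)
  expect_equal(mid$a, 2)
  expect_equal(mid$b, sqrt(1e-4 * 1e-1))  # geometric midpoint
  expect_equal(mid$c, 68)
  lo <- decode_position(c(-1, -1, -1), sp)
  expect_equal(unlist(lo), c(a = -2, b = 1e-4, c = 8))
  hi <- decode_position(c(1, 1, 1), sp)
  expect_equal(unlist(hi), c(a = 6, b = 1e-1, c = 128))
  expect_error(search_space(dim_continuous("a", 1, 0)), "low")
  expect_error(search_space(dim_continuous("a", 0, 1),
                            dim_continuous("a", 0, 2)), "duplicate")
})

test_that("error-rate fitness implements the percentage definition", {
  expect_equal(fitness_error_rate(c(0.9, 0.1), c(1, 0)), 0)
  expect_equal(fitness_error_rate(c(0.1, 0.9), c(1, 0)), 100)
  expect_equal(fitness_error_rate(c(rep(0.9, 7), rep(0.1, 3)), rep(1, 10)), 30)
  # threshold semantics: p >= threshold predicts positive
  expect_equal(fitness_error_rate(0.5, 1, threshold = 0.5), 0)
  expect_error(fitness_error_rate(c(0.5, 0.5), 1), "equal")
})
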