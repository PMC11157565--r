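cmopso_toy <- function(n = 40, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * 5), n, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- X[, 1] - X[, 2] + rnorm(n, sd = 0.3)
  dplyr::bind_cols(tibble::as_tibble(X), tibble::tibble(y = y))
}

test_that("inertia schedule hits its endpoints and midpoint exactly", {
  expect_equal(inertia_weight(0, 300), 0.9, tolerance = 1e-15)
  expect_equal(inertia_weight(300, 300), 0.4, tolerance = 1e-15)
  expect_equal(inertia_weight(150, 300), 0.525, tolerance = 1e-15)
  # strictly decreasing and convex over the run
  w <- inertia_weight(0:100, 100)
  expect_true(all(diff(w) < 0))
  expect_true(all(diff(diff(w)) > 0))
  expect_true(all(w >= 0.4 & w <= 0.9))
  expect_error(inertia_weight(301, 300), "must lie")
})

test_that("acceleration ramps run between their quoted endpoints", {
  expect_equal(acceleration_factors(0, 300), c(c1 = 2.75, c2 = 0.5),
               tolerance = 1e-15)
  expect_equal(acceleration_factors(300, 300), c(c1 = 1.25, c2 = 2.25),
               tolerance = 1e-15)
  expect_equal(acceleration_factors(150, 300), c(c1 = 2.0, c2 = 1.375),
               tolerance = 1e-15)
  # the verbatim (sign-flipped) c2 variant leaves the intended range
  lit <- acceleration_factors(300, 300, literal_c2 = TRUE)
  expect_equal(unname(lit["c2"]), 2 * 0.5 - 2.25, tolerance = 1e-15)
})

test_that("velocity update follows the two-attractor rule", {
  # no attraction: velocity persists under w = 1
  expect_equal(
    swarmselect:::update_velocity(0.2, 0.5, 0.7, 0.9, w = 1, c1 = 2, c2 = 2,
                                  r1 = 0, r2 = 0),
    0.2
  )
  # both attractors at the particle: pure inertia
  expect_equal(
    swarmselect:::update_velocity(0.3, 0.4, 0.4, 0.4, w = 0.5, c1 = 2,
                                  c2 = 2, r1 = 0.8, r2 = 0.3),
    0.15
  )
  # hand-evaluated scalar case, then the clamp
  v <- swarmselect:::update_velocity(0.1, 0.3, 0.5, 0.9, w = 0.5, c1 = 2,
                                     c2 = 1, r1 = 0.5, r2 = 1, v_max = 1)
  expect_equal(v, 0.85)
  expect_equal(
    swarmselect:::update_velocity(0.1, 0.3, 0.5, 0.9, w = 0.5, c1 = 2,
                                  c2 = 1, r1 = 0.5, r2 = 1),
    0.5 # default v_max
  )
})

test_that("position update clips to the unit box and zeroes clipped velocity", {
  up <- swarmselect:::update_position(0.3, 0.2)
  expect_equal(up$x, 0.5)
  expect_equal(up$v, 0.2)
  up2 <- swarmselect:::update_position(0.9, 0.5)
  expect_equal(up2$x, 1.0)
  expect_equal(up2$v, 0)
  set.seed(2)
  x <- runif(20); v <- runif(20, -1, 1)
  up3 <- swarmselect:::update_position(x, v)
  expect_equal(up3$x, pmin(pmax(x + v, 0), 1))
  expect_true(all(up3$v[x + v < 0 | x + v > 1] == 0))
})

test_that("particle decoding thresholds and repairs", {
  expect_equal(decode_particle(c(0.7, 0.2, 0.9), 0.6), c(1L, 3L))
  expect_equal(decode_particle(c(0.1, 0.55, 0.3), 0.6), 2L) # repair rule
  expect_equal(decode_particle(c(0.7, 0.2, 0.9), 1e-9), 1:3)
  expect_error(decode_particle(c(0.5), 1.2), "threshold")
})

test_that("pbest replacement follows dominance with a fair coin on ties", {
  expect_true(swarmselect:::pbest_replace(c(5, 2), c(3, 1)))
  expect_false(swarmselect:::pbest_replace(c(3, 1), c(5, 2)))
  set.seed(99)
  flips <- replicate(10000,
                     swarmselect:::pbest_replace(c(3, 2), c(5, 1)))
  expect_equal(mean(flips), 0.5, tolerance = 0.02)
})

test_that("subset evaluation is memoized and consistent with the wrapper", {
  d <- cmopso_toy()
  X <- as.matrix(d[, 1:5])
  ev <- swarmselect:::make_evaluator(X, d$y, folds = 5, ncomp = 2,
                                     shuffle_seed = 7,
                                     aggregate = "fold_mean")
  o1 <- ev$eval(c(1, 3))
  o2 <- ev$eval(c(1, 3))
  expect_identical(o1, o2)
  expect_equal(ev$n_unique(), 1L)
  expect_equal(o1[1], 2)
  expect_equal(o1[2], kfold_pls_rmse(d, y, features = c("f1", "f3"),
                                     folds = 5, shuffle_seed = 7))
  expect_equal(ev$eval(1)[1], 1)
})

test_that("a single-feature candidate space yields the forced front", {
  d <- cmopso_toy()
  res <- cmopso(d, y, features = "f1", iterations = 5, pop_size = 5,
                folds = 5, seed = 1)
  expect_equal(nrow(res$front), 1)
  expect_equal(res$front$n_features, 1L)
  expect_equal(res$front$rmse,
               kfold_pls_rmse(d, y, features = "f1", folds = 5, ncomp = 1))
})

test_that("identical seed and configuration reproduce the front exactly", {
  d <- cmopso_toy()
  a <- cmopso(d, y, iterations = 10, pop_size = 8, folds = 5, seed = 11)
  b <- cmopso(d, y, iterations = 10, pop_size = 8, folds = 5, seed = 11)
  expect_identical(a$front, b$front)
  expect_identical(a$history, b$history)
})

test_that("front is non-dominated and bounded by the candidate set", {
  d <- cmopso_toy()
  res <- cmopso(d, y, iterations = 15, pop_size = 10, folds = 5, seed = 4)
  obj <- cbind(res$front$n_features, res$front$rmse)
  expect_equal(oracle_non_dominated(obj), seq_len(nrow(obj)))
  expect_true(all(res$front$n_features <= 5))
  expect_true(all(res$front$n_features >= 1))
  expect_true(all(vapply(res$front$features, length, numeric(1)) ==
                    res$front$n_features))
  # best RMSE never worsens over iterations
  expect_true(all(diff(res$history$best_rmse) <= 1e-12))
})

test_that("frozen dynamics leave the swarm and its front invariant", {
  d <- cmopso_toy()
  res <- cmopso(d, y, iterations = 8, pop_size = 6, folds = 5, seed = 2,
                w_max = 1e-9, w_min = 0, c1i = 0, c1f = 0, c2i = 0, c2f = 0)
  # zero coefficients and zero initial velocity: nothing ever moves
  expect_equal(length(unique(res$history$archive_size)), 1)
  expect_equal(length(unique(res$history$best_rmse)), 1)
})

test_that("scheduled optimizer recovers a planted subset within a known core", {
  # candidate set of 3 relevant + 3 noisy duplicates + 14 noise features
  sim <- synth_hdss(50, 3, 3, 14, noise_sd = 0.3, seed = 21)
  res <- cmopso(sim$data, y, iterations = 60, pop_size = 30, folds = 5,
                seed = 21)
  best <- res$front$features[[which.min(res$front$rmse)]]
  expect_true(all(paste0("rel_", 1:3) %in% best))
  dup <- sum(grepl("^red_", best))
  expect_lte(dup, 1)
})
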