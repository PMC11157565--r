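test_that("single feature gets rank 1", {
  d <- tibble::tibble(f1 = c(1, 2, 3, 4), y = c(1, 2, 1, 2))
  r <- mrmr_rank(d, y)
  expect_equal(r$index, 1)
  expect_equal(r$feature, "f1")
})

test_that("an exact duplicate is demoted below an independent noise feature", {
  # balanced factorial design: x0 (4 levels), noise bit b, independent x2;
  # y = x0 + b has overlapping levels so I(x0, y) < H(x0), which makes the
  # duplicate's step-2 criterion I(x1,y) - I(x1,x0) strictly negative while
  # the independent feature scores exactly 0.
  g <- expand.grid(x0 = 0:3, b = 0:1, x2 = 0:1)
  g <- rbind(g, g)
  d <- tibble::tibble(x0 = g$x0, x1 = g$x0, x2 = g$x2, y = g$x0 + g$b)
  r <- mrmr_rank(d, y)
  expect_equal(r$index, c(1, 3, 2))
  expect_equal(r$index, oracle_mrmr_order(cbind(g$x0, g$x0, g$x2), g$x0 + g$b))
})

test_that("greedy ranking equals the step-by-step criterion oracle", {
  set.seed(23)
  for (i in 1:10) {
    toy <- random_discrete_toy(m = 6, n = 40)
    r <- mrmr_rank(toy$data, y)
    expect_equal(r$index, oracle_mrmr_order(toy$X, toy$y))
  }
})

test_that("first-ranked feature maximizes relevance", {
  set.seed(31)
  for (i in 1:10) {
    toy <- random_discrete_toy(m = 8, n = 50)
    r <- mrmr_rank(toy$data, y)
    rel <- vapply(seq_len(8), function(j) oracle_mi(toy$X[, j], toy$y),
                  numeric(1))
    expect_equal(r$index[1], which.max(rel))
    expect_equal(max(r$relevance), max(rel), tolerance = 1e-12)
  }
})

test_that("relevance-only scheme sorts by relevance; max_rank truncates", {
  set.seed(5)
  toy <- random_discrete_toy(m = 6, n = 40)
  r <- mrmr_rank(toy$data, y, scheme = "relevance")
  expect_equal(r$score, sort(r$relevance, decreasing = TRUE))
  r3 <- mrmr_rank(toy$data, y, max_rank = 3)
  expect_equal(nrow(r3), 3)
  expect_equal(r3$index, mrmr_rank(toy$data, y)$index[1:3])
})

test_that("mutually independent features rank by relevance alone", {
  # orthogonal factorial design: pairwise sample MI between features is
  # exactly 0, so the redundancy charge never reorders
  g <- expand.grid(a = 0:1, b = 0:1, c = 0:1, d = 0:1)
  g <- rbind(g, g, g)
  y <- 3 * g$a + 2 * g$b + g$c
  d <- dplyr::bind_cols(tibble::as_tibble(g), tibble::tibble(y = y))
  inc <- mrmr_rank(d, y)
  rel <- mrmr_rank(d, y, scheme = "relevance")
  expect_equal(inc$index, rel$index)
})

test_that("correlation baselines rank by absolute correlation", {
  set.seed(11)
  x0 <- rnorm(50)
  d <- tibble::tibble(
    x0 = x0, x1 = rnorm(50), x2 = rnorm(50), y = 3 * x0
  )
  rp <- correlation_rank(d, y, method = "pearson")
  expect_equal(rp$feature[1], "x0")
  expect_equal(rp$score[1], 1, tolerance = 1e-12)

  # monotone transform: Spearman stays 1, Pearson drops below
  d2 <- tibble::tibble(x0 = x0, x1 = rnorm(50), y = exp(x0))
  expect_equal(correlation_rank(d2, y, method = "spearman")$score[1], 1,
               tolerance = 1e-12)
  expect_lt(correlation_rank(d2, y, method = "pearson")$score[1], 1)
})

test_that("correlation ranking equals direct recomputation on a 5-feature toy", {
  set.seed(17)
  X <- matrix(rnorm(150), 30, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- X[, 2] - 0.5 * X[, 4] + rnorm(30, sd = 0.3)
  d <- dplyr::bind_cols(tibble::as_tibble(X), tibble::tibble(y = y))
  for (meth in c("pearson", "spearman")) {
    r <- correlation_rank(d, y, method = meth)
    direct <- abs(drop(cor(X, y, method = meth)))
    expect_equal(r$index, order(-direct, 1:5))
    expect_equal(r$score, unname(direct[r$index]), tolerance = 1e-12)
  }
})

test_that("constant features and targets are handled", {
  d <- tibble::tibble(f1 = rep(1, 10), f2 = rnorm(10), y = rnorm(10))
  expect_warning(r <- correlation_rank(d, y), "constant")
  expect_equal(r$feature[2], "f1")
  expect_equal(r$score[2], 0)

  dc <- tibble::tibble(f1 = rep(2, 8), y = rnorm(8))
  expect_error(mrmr_rank(dc, y), "no informative features")
  dy <- tibble::tibble(f1 = rnorm(8), y = rep(1, 8))
  expect_error(mrmr_rank(dy, y), "constant")
})
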