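test_that("rank transform uses midranks for ties", {
  expect_identical(rank_transform(c(0.3, 0.1, 0.2)), c(3, 1, 2))
  expect_identical(rank_transform(c(0.5, 0.5, 0.1)), c(2.5, 2.5, 1))
  expect_identical(rank_transform(sort(runif(20))), as.numeric(1:20))
  expect_error(rank_transform(c(1, NA)), "non-finite")
})

test_that("perfect monotone dependence gives a coefficient of one", {
  set.seed(1)
  X <- matrix(runif(300), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1]
  expect_equal(partial_rank_correlation(X, y, 1), 1, tolerance = 1e-12)
  expect_equal(partial_rank_correlation(X, y, "a"), 1, tolerance = 1e-12)
  pr <- prcc(X, y)
  expect_true(pr$significant[pr$parameter == "a"])
  expect_identical(classify_significance(pr), "a")
})

test_that("regression-residual PRCC equals the matrix-inversion oracle", {
  set.seed(42)
  worst <- 0
  for (rep in 1:10) {
    n <- sample(30:200, 1)
    k <- sample(2:8, 1)
    X <- matrix(runif(n * k), ncol = k,
                dimnames = list(NULL, paste0("x", seq_len(k))))
    y <- X %*% runif(k, -1, 1) + rnorm(n, sd = 0.3)
    got <- prcc(X, as.numeric(y))$rho
    want <- prcc_oracle(X, as.numeric(y))
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-10)
})

test_that("a small hand-checkable instance matches the oracle", {
  X <- cbind(x1 = c(1, 4, 2, 6, 3, 5), x2 = c(2, 1, 4, 3, 6, 5))
  y <- c(1.2, 3.4, 2.6, 5.8, 3.9, 4.9)
  got <- prcc(X, y)$rho
  expect_equal(got, prcc_oracle(X, y), tolerance = 1e-12)
  # y follows x1 closely (one adjacent rank swap) and x2 barely at all
  expect_gt(got[1], 0.8)
  expect_lt(abs(got[2]), abs(got[1]))
})

test_that("coefficients are invariant under strictly monotone transforms", {
  set.seed(5)
  X <- matrix(runif(240), ncol = 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 2]^2 + 0.2 * runif(60)
  base <- prcc(X, y)$rho
  Xt <- X
  Xt[, 1] <- exp(3 * Xt[, 1])
  Xt[, 3] <- -1 / (1 + Xt[, 3])
  expect_equal(prcc(Xt, y^3)$rho, base, tolerance = 1e-12)
})

test_that("an independent output yields only small coefficients", {
  set.seed(17)
  r <- build_ranges(emt_parameters())
  d <- latin_hypercube(r, 2000, seed = 17)
  y <- runif(2000)
  expect_lt(max(abs(prcc(d, y)$rho)), 0.08)
})

test_that("two columns reduce to the ordinary Spearman correlation", {
  set.seed(3)
  X <- matrix(runif(160), ncol = 2, dimnames = list(NULL, c("u", "v")))
  M <- interparameter_prcc(X)
  expect_equal(M["u", "v"], stats::cor(X[, 1], X[, 2],
                                       method = "spearman"),
               tolerance = 1e-12)
  expect_identical(diag(M), c(u = 1, v = 1))
})

test_that("inter-parameter screening flags duplicated columns", {
  set.seed(8)
  X <- matrix(runif(200), ncol = 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  X[, 4] <- X[, 1]
  M <- interparameter_prcc(X)
  expect_equal(M["x1", "x4"], 1, tolerance = 1e-12)
  expect_true(isSymmetric(M))
})

test_that("LHS columns show no hidden relationships", {
  r <- build_ranges(emt_parameters())
  d <- latin_hypercube(r, 2000, seed = 4)
  M <- interparameter_prcc(d)
  expect_lt(max(abs(M[upper.tri(M)])), 0.5)
})

test_that("significance classification applies the cutoff with signs kept", {
  pr <- tibble::tibble(parameter = c("alpha2", "beta2", "k1"),
                       rho = c(0.93, -0.88, 0.2),
                       significant = c(TRUE, TRUE, FALSE))
  attr(pr, "threshold") <- 0.5
  expect_identical(classify_significance(pr), c("alpha2", "beta2"))
  expect_identical(classify_significance(pr, threshold = 0.1),
                   c("alpha2", "beta2", "k1"))
})

test_that("one-at-a-time scans are monotone and directional as expected", {
  r <- build_ranges(emt_parameters())
  ms <- monotonicity_scan(r, contact = 6, tgfb = 0, points = 9)
  # higher E-cadherin degradation lowers its steady state
  b1E <- ms[ms$parameter == "beta1" & ms$output == "E", ]
  expect_true(b1E$monotone)
  expect_identical(b1E$direction, "decreasing")
  # more Slug production lowers E-cadherin
  a2E <- ms[ms$parameter == "alpha2" & ms$output == "E", ]
  expect_identical(a2E$direction, "decreasing")
  expect_true(all(ms$monotone))
  bad <- r
  bad$lo[bad$name == "beta1"] <- bad$hi[bad$name == "beta1"]
  expect_error(monotonicity_scan(bad, 6, 0, points = 5), "degenerate")
  expect_error(monotonicity_scan(r, 6, 0, points = 2), "points >= 3")
})
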