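test_that("dimensional right-hand side matches closed-form anchor points", {
  p <- emt_parameters()

  # all Hill terms vanish at the origin with zero inputs: bare production
  expect_equal(unname(rhs_dimensional(c(0, 0), p, 0, 0)),
               c(0.19355, 0.080))

  # half-maximal identities: each Hill factor is exactly 1/2 at its IC
  v <- dim_values()
  d <- rhs_dimensional(c(v[["IC_E"]], 0), p, v[["IC_C"]], v[["IC_T"]])
  expect_equal(unname(d[1]),
               0.19355 + 0.1245 / 2 - 6.035 * v[["IC_E"]])
  expect_equal(unname(d[2]),
               0.080 - 0.080 / 2 + 0.040 / 2 - 0)

  # the printed epithelial steady state is (numerically) a fixed point
  d6 <- rhs_dimensional(c(0.0522, 0.0034), p, 6, 0)
  expect_lt(max(abs(d6)), 5e-4)

  expect_error(rhs_dimensional(c(0, 0), p, -1, 0), "nonnegative")
  expect_error(rhs_dimensional(c(NaN, 0), p, 0, 0), "non-finite")
})

test_that("nondimensional right-hand side anchors hold for every set", {
  for (s in 1:7) {
    ps <- emt_parameters("nondimensional", set = s)
    v <- stats::setNames(ps$value, ps$name)
    d0 <- rhs_nondimensional(c(0, 0), ps, 0, 0)
    expect_equal(unname(d0), unname(c(v["A1"], v["A2"])))
    # theta = 1 with n4 = 3: TGF-beta Hill factor exactly 1/2
    d1 <- rhs_nondimensional(c(0, 0), ps, 0, 1)
    expect_equal(unname(d1[2] - d0[2]), unname(v["K2"] / 2))
  }
  # rescaled epithelial state is near-stationary under Set 7 at mu = 2.76
  p7 <- emt_parameters("nondimensional", set = 7)
  d <- rhs_nondimensional(c(0.0522 / 0.010, 0.0034 / 0.0192), p7, 2.76, 0)
  expect_lt(max(abs(d)), 0.05)
})

test_that("nondimensionalization reproduces the printed grouping values", {
  tab3 <- list(
    `3` = c(A1 = 3.207, K0 = 2.063, B1 = 1.000, A2 = 0.690, K1 = 0.690,
            K2 = 0.345, B2 = 0.138),
    `4` = c(A1 = 4.645, K0 = 2.988, B1 = 1.448, A2 = 1.000, K1 = 1.000,
            K2 = 0.500, B2 = 0.199),
    `7` = c(A1 = 23.319, K0 = 15.000, B1 = 7.271, A2 = 5.020, K1 = 5.020,
            K2 = 2.510, B2 = 1.000)
  )
  p <- emt_parameters()
  for (s in names(tab3)) {
    nd <- nondimensionalize(p, as.integer(s))
    got <- stats::setNames(nd$value, nd$name)[names(tab3[[s]])]
    expect_equal(round(unname(got), 3), unname(tab3[[s]]),
                 info = paste("set", s))
  }
  # exactly one grouping is held at unity, the gamma-defining one (in Sets
  # 4 and 5 the K1/A2 counterpart also evaluates to 1.000 because
  # alpha2 = k1 in the baseline table, but it remains varied)
  for (s in 1:7) {
    nd <- nondimensionalize(p, s)
    core <- nd[nd$name %in% c("A1", "K0", "B1", "A2", "K1", "K2", "B2"), ]
    expect_identical(core$name[!core$varied], nondim_schemes()$fixed[s])
    expect_identical(core$value[!core$varied], 1)
  }
})

test_that("printed Set 1 K0 value is internally inconsistent and reported as computed", {
  p <- emt_parameters()
  k0_computed <- nondimensionalize(p, 1)$value[2]
  expect_equal(k0_computed, 0.1245 / 0.19355, tolerance = 1e-12)
  # the printed 0.646 disagrees with the computed grouping ...
  expect_gt(abs(k0_computed - 0.646), 2e-3)
  # ... while the printed Set 2 A1 = 1.555 is its exact reciprocal
  a1_set2 <- nondimensionalize(p, 2)$value[1]
  expect_equal(a1_set2 * k0_computed, 1, tolerance = 1e-12)
  # and the consistency check flags exactly this entry
  rc <- range_consistency()
  bad <- rc[!rc$consistent, ]
  expect_identical(nrow(bad), 1L)
  expect_identical(bad$name, "K0")
  expect_identical(bad$set_id, 1L)
})

test_that("reciprocal grouping identities across sets hold", {
  p <- emt_parameters()
  v <- function(s, nm) {
    nd <- nondimensionalize(p, s)
    nd$value[nd$name == nm]
  }
  expect_equal(v(2, "A1") * v(1, "K0"), 1, tolerance = 1e-12)
  expect_equal(v(3, "K0") * v(2, "B1"), 1, tolerance = 1e-12)
})

test_that("frames are consistent under the change of variables", {
  # evaluating the nondimensional rhs at the rescaled state equals the
  # rescaled dimensional rhs, for random parameter vectors and all sets
  set.seed(11)
  worst <- 0
  for (rep in 1:10) {
    q <- random_params()
    v <- stats::setNames(q$value, q$name)
    E <- runif(1, 0, 0.06); S <- runif(1, 0, 0.12)
    C <- runif(1, 0, 6); T <- runif(1, 0, 4e-6)
    dd <- rhs_dimensional(c(E, S), q, C, T)
    for (s in 1:7) {
      nd <- nondimensionalize(q, s)
      gam <- attr(nd, "gamma")
      dn <- rhs_nondimensional(c(E / v[["IC_E"]], S / v[["IC_S"]]), nd,
                               C / v[["IC_C"]], T / v[["IC_T"]])
      want <- c(dd[[1]] * gam / v[["IC_E"]], dd[[2]] * gam / v[["IC_S"]])
      worst <- max(worst, max(abs(unname(dn) - want) /
                                pmax(abs(want), 1e-12)))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("Hill factors are bounded and monotone", {
  x <- seq(0, 50, length.out = 400)
  for (n in c(2, 3, 4)) {
    h <- hill(x, n)
    expect_true(all(h >= 0 & h < 1))
    expect_true(all(diff(h) > 0))
    expect_identical(h[1], 0)
  }
  expect_equal(hill(1, 3), 0.5)
  expect_error(hill(-0.1, 2), "nonnegative")
})

test_that("grouping composition is derived symbolically with cancellation", {
  gc <- grouping_composition()
  # the gamma-defining grouping cancels completely: no rows for it
  fixed <- nondim_schemes()$fixed
  for (s in 1:7) {
    expect_false(fixed[s] %in% gc$grouping[gc$set_id == s])
  }
  # input-rescaling half-maximal constants appear in no grouping
  expect_false(any(c("IC_C", "IC_T") %in% gc$symbol))
  # spot-check: Set 7 A1 = alpha1 / (beta2 IC_E)
  a1s7 <- gc[gc$set_id == 7 & gc$grouping == "A1", ]
  expect_setequal(a1s7$symbol, c("alpha1", "beta2", "IC_E"))
  expect_identical(a1s7$exponent[a1s7$symbol == "alpha1"], 1)
  expect_identical(a1s7$exponent[a1s7$symbol == "beta2"], -1)
})

test_that("treatment groups and initial conditions follow the study design", {
  tg <- treatment_groups("dimensional")
  expect_identical(nrow(tg), 8L)
  expect_setequal(unique(tg$contact), c(0, 1, 2, 6))
  expect_setequal(unique(tg$tgfb), c(0, 3.64e-6))
  expect_identical(tg$E0[tg$contact == 6 & tg$tgfb == 0], 0.0522)
  tn <- treatment_groups("nondimensional")
  expect_setequal(unique(tn$contact), c(0, 0.46, 0.92, 2.76))
  expect_setequal(unique(tn$tgfb), c(0, 1))
  expect_identical(tn$S0[tn$contact == 0 & tn$tgfb == 0], 5.0220)
})
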