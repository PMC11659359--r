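test_that("rounding is half-away-from-zero at the frame grain", {
  expect_identical(round_output(0.09634, "dimensional"), 0.0963)
  expect_identical(round_output(5.0156, "nondimensional"), 5.02)
  # tie cases round away from zero
  expect_identical(round_output(0.00005, "dimensional"), 1e-4)
  expect_identical(round_output(-0.00005, "dimensional"), -1e-4)
  expect_identical(round_output(0.005, "nondimensional"), 0.01)
  expect_error(round_output(Inf, "dimensional"), "non-finite")
})

test_that("steady-state readouts reproduce the printed treatment anchors", {
  p <- emt_parameters()
  ep <- integrate_to_steady_state(p, 6, 0)
  expect_identical(c(ep$rounded_E, ep$rounded_S), c(0.0522, 0.0034))
  expect_true(ep$converged)
  expect_false(ep$negative_excursion)

  mes <- integrate_to_steady_state(p, 0, 0)
  expect_identical(c(mes$rounded_E, mes$rounded_S), c(0.0003, 0.0963))
})

test_that("pure decay drives any state to the origin", {
  p <- emt_parameters()
  p$value[p$name %in% c("alpha1", "alpha2", "k0", "k2")] <- 0
  ss <- integrate_to_steady_state(p, 3, 0, init = c(0.05, 0.1))
  expect_identical(c(ss$rounded_E, ss$rounded_S), c(0, 0))
  eq <- find_equilibria(p, 3, 0)
  expect_identical(nrow(eq), 1L)
  expect_equal(c(eq$E, eq$S), c(0, 0), tolerance = 1e-9)
  expect_identical(eq$stability, "stable")
})

test_that("equilibrium enumeration finds the bistable structure", {
  p <- emt_parameters()
  # monostable epithelial at full contact
  e6 <- find_equilibria(p, 6, 0)
  expect_identical(nrow(e6), 1L)
  expect_identical(e6$stability, "stable")
  expect_equal(c(e6$E, e6$S), c(0.0522, 0.0034), tolerance = 1e-2)
  # inside the bistable window: stable / saddle / stable ordered by S
  e15 <- find_equilibria(p, 1.5, 0)
  expect_identical(nrow(e15), 3L)
  expect_identical(e15$stability, c("stable", "saddle", "stable"))
  # residual vanishes at each reported fixed point
  red <- equilibrium_residual(p, 1.5, 0)
  expect_lt(max(abs(red$residual(e15$S))), 1e-10)
})

test_that("integration lands on an enumerated stable equilibrium in every group", {
  for (frame in c("dimensional", "nondimensional")) {
    p <- if (frame == "dimensional") emt_parameters() else
      emt_parameters("nondimensional", set = 3)
    tg <- treatment_groups(frame)
    for (i in seq_len(nrow(tg))) {
      ss <- integrate_to_steady_state(p, tg$contact[i], tg$tgfb[i],
                                      frame = frame)
      eq <- find_equilibria(p, tg$contact[i], tg$tgfb[i], frame = frame)
      stab <- eq[eq$stability == "stable", ]
      d <- sqrt((stab$E - ss$E_ss)^2 + (stab$S - ss$S_ss)^2)
      expect_lt(min(d), 1e-6)
      expect_false(ss$negative_excursion)
      expect_true(ss$converged)
    }
  }
})

test_that("basins separate the epithelial and mesenchymal initial states", {
  p <- emt_parameters()
  # C = 1.5 lies in the bistable window; epithelial IC stays high-E,
  # mesenchymal IC stays low-E
  hi <- integrate_to_steady_state(p, 1.5, 0, init = c(0.0399, 0.0057))
  lo <- integrate_to_steady_state(p, 1.5, 0, init = c(0.0003, 0.0963))
  expect_gt(hi$E_ss, 0.025)
  expect_lt(lo$E_ss, 0.005)
})

test_that("the readout time is long enough that doubling it changes nothing", {
  p <- emt_parameters()
  tg <- treatment_groups("dimensional")
  for (i in seq_len(nrow(tg))) {
    a <- integrate_to_steady_state(p, tg$contact[i], tg$tgfb[i],
                                   t_end = 10000, n_check = 2)
    b <- integrate_to_steady_state(p, tg$contact[i], tg$tgfb[i],
                                   t_end = 20000, n_check = 2)
    expect_identical(c(a$rounded_E, a$rounded_S),
                     c(b$rounded_E, b$rounded_S))
  }
})

test_that("batched steady states agree with single integrations", {
  p <- emt_parameters()
  r <- build_ranges(p)
  d <- latin_hypercube(r, 20, seed = 3)
  sets <- assemble_parameter_sets(d, p)
  bulk <- steady_states(sets, 6, 0, frame = "dimensional")
  for (i in c(1, 5, 20)) {
    prm <- p
    prm$value <- as.numeric(sets[i, ])
    one <- integrate_to_steady_state(prm, 6, 0, n_check = 2)
    expect_equal(bulk$E_ss[i], one$E_ss, tolerance = 1e-10)
    expect_equal(bulk$S_ss[i], one$S_ss, tolerance = 1e-10)
  }
  expect_identical(nrow(steady_states(sets[0, ], 6, 0,
                                      frame = "dimensional")), 0L)
})

test_that("trajectory export returns the full time course", {
  tr <- trajectory(emt_parameters(), 6, 0, times = seq(0, 100, by = 1))
  expect_identical(nrow(tr), 101L)
  expect_identical(names(tr), c("t", "E", "S"))
  expect_true(all(tr$E >= 0 & tr$S >= 0))
})
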