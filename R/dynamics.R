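# Time-course integration and equilibrium analysis.  Readout follows the
# study protocol: state at t = 10000 (min or tau), rounded to the frame's
# grain (1e-4 dimensional, 1e-2 nondimensional).  The integrator is lsoda
# with the compiled rhs and analytic Jacobian, rtol 1e-10 / atol 1e-12:
# dimensional steady states reach ~1e-4 ng/mL, so looser tolerances would
# corrupt the 4-decimal rounding.

.rtol <- 1e-10
.atol <- 1e-12
.converge_tol <- 1e-9

ode_final <- function(g, y0, t_end, times = c(0, t_end)) {
  out <- deSolve::ode(
    y = y0, times = times, func = "emt_derivs", parms = unname(g[1:11]),
    dllname = "emtsens", initfunc = "emt_init",
    jacfunc = "emt_jac", jactype = "fullusr",
    rtol = .rtol, atol = .atol, maxsteps = 50000
  )
  if (attr(out, "istate")[1] < 0 || any(!is.finite(out[nrow(out), -1]))) {
    stop("integration failed (parameters: ",
         paste(sprintf("%s=%g", names(g), g), collapse = ", "), ")")
  }
  out
}

#' Round a steady-state readout to the frame's grain
#'
#' Rounds half away from zero to the nearest 1e-4 (dimensional frame) or
#' 1e-2 (nondimensional frame), the rounding applied to all recorded outputs
#' before rank transformation.
#'
#' @param value Finite numeric vector.
#' @param frame `"dimensional"` or `"nondimensional"`.
#' @return Rounded numeric vector.
#' @examples
#' round_output(0.09634, "dimensional")   # 0.0963
#' round_output(5.0156, "nondimensional") # 5.02
#' @export
round_output <- function(value, frame = c("dimensional", "nondimensional")) {
  frame <- match.arg(frame)
  if (any(!is.finite(value))) stop("non-finite value in round_output")
  digits <- if (frame == "dimensional") 4L else 2L
  grain <- 10^(-digits)
  # the final round() snaps k * grain to the shortest representable double
  round(sign(value) * floor(abs(value) / grain + 0.5) * grain, digits)
}

#' Integrate one treatment condition to its steady-state readout
#'
#' Runs the model from the prescribed initial state to `t_end` and records
#' the state there (no early exit on convergence: the readout rule is "state
#' at t_end", with a convergence flag as a diagnostic).
#'
#' @param params Parameter tibble for the chosen frame.
#' @param contact Contact level (C in cells, or mu).
#' @param tgfb TGF-beta level (T in ng/mL, or theta).
#' @param init Optional length-2 initial state `c(E0, S0)`; defaults to the
#'   tabulated initial condition for this contact level.
#' @param t_end Readout time, default 10000.
#' @param frame `"dimensional"` or `"nondimensional"`.
#' @param n_check Number of saved time points used to screen for negative
#'   excursions (default 51).
#' @return One-row tibble: `contact`, `tgfb`, `E_ss`, `S_ss`, `rounded_E`,
#'   `rounded_S`, `converged` (max |rhs| at readout < 1e-9), and
#'   `negative_excursion`.
#' @examples
#' integrate_to_steady_state(emt_parameters(), contact = 6, tgfb = 0)
#' @export
integrate_to_steady_state <- function(params, contact, tgfb, init = NULL,
                                      t_end = 10000,
                                      frame = c("dimensional",
                                                "nondimensional"),
                                      n_check = 51) {
  frame <- match.arg(frame)
  if (is.null(init)) {
    ic <- initial_conditions(frame)
    j <- match(contact, ic$contact)
    if (is.na(j)) stop("no tabulated initial condition for contact = ",
                       contact, "; supply `init`")
    init <- c(ic$E0[j], ic$S0[j])
  }
  check_state(init)
  g <- grouped_form(params, contact, tgfb, frame)
  times <- seq(0, t_end, length.out = max(2, n_check))
  out <- ode_final(g, c(E = init[[1]], S = init[[2]]), t_end, times)
  fin <- out[nrow(out), c("E", "S")]
  # clamp sub-atol numerical undershoot before the Hill terms
  rhs <- grouped_rhs(max(fin[["E"]], 0), max(fin[["S"]], 0), g)
  tibble::tibble(
    contact = contact, tgfb = tgfb,
    E_ss = fin[["E"]], S_ss = fin[["S"]],
    rounded_E = round_output(fin[["E"]], frame),
    rounded_S = round_output(fin[["S"]], frame),
    converged = max(abs(rhs)) < .converge_tol,
    negative_excursion = any(out[, c("E", "S")] < -10 * .atol)
  )
}

#' Full time course of one treatment condition
#'
#' @inheritParams integrate_to_steady_state
#' @param times Output time grid.
#' @return Tibble with `t`, `E`, `S`.
#' @export
trajectory <- function(params, contact, tgfb, init = NULL,
                       times = seq(0, 10000, by = 10),
                       frame = c("dimensional", "nondimensional")) {
  frame <- match.arg(frame)
  if (is.null(init)) {
    ic <- initial_conditions(frame)
    init <- unlist(ic[match(contact, ic$contact), c("E0", "S0")])
  }
  g <- grouped_form(params, contact, tgfb, frame)
  out <- ode_final(g, c(E = init[[1]], S = init[[2]]), max(times), times)
  tibble::tibble(t = out[, "time"], E = out[, "E"], S = out[, "S"])
}

#' Reduced scalar equilibrium residual
#'
#' At equilibrium the E-cadherin equation gives E explicitly in terms of S,
#' `E(S) = (a1/(1 + (S/IC_S)^n1) + hc) / b1`; substituting into the Slug
#' equation leaves one scalar residual `g(S)` whose roots are the fixed
#' points.  Returns that residual (and its analytic derivative) as functions
#' of S, used for root bracketing and fold (tangency) diagnostics.
#'
#' @inheritParams integrate_to_steady_state
#' @return List with functions `residual(S)`, `dresidual(S)`, `E_of_S(S)`,
#'   and the scan bound `s_max = 2 (a2 + k2) / b2`.
#' @export
equilibrium_residual <- function(params, contact, tgfb,
                                 frame = c("dimensional", "nondimensional")) {
  frame <- match.arg(frame)
  g <- grouped_form(params, contact, tgfb, frame)
  a1 <- g[["a1"]]; icS <- g[["icS"]]; n1 <- g[["n1"]]; hc <- g[["hc"]]
  b1 <- g[["b1"]]; a2 <- g[["a2"]]; k1 <- g[["k1"]]; icE <- g[["icE"]]
  n3 <- g[["n3"]]; ht <- g[["ht"]]; b2 <- g[["b2"]]
  E_of_S <- function(S) (a1 / (1 + (S / icS)^n1) + hc) / b1
  residual <- function(S) {
    a2 - k1 * hill(E_of_S(S) / icE, n3) + ht - b2 * S
  }
  dresidual <- function(S) {
    sr <- S / icS
    dE <- -a1 * n1 * ifelse(S > 0, sr^(n1 - 1), 0) / icS /
      (1 + sr^n1)^2 / b1
    E <- E_of_S(S)
    er <- E / icE
    dH <- n3 * ifelse(E > 0, er^(n3 - 1), 0) / icE / (1 + er^n3)^2
    -k1 * dH * dE - b2
  }
  list(residual = residual, dresidual = dresidual, E_of_S = E_of_S,
       s_max = 2 * g[["prod2"]] / b2, grouped = g)
}

#' Enumerate the fixed points of one treatment condition
#'
#' Brackets every sign change of the reduced scalar residual on a bounded
#' S-grid, polishes each root, and classifies stability from the analytic
#' 2x2 Jacobian (trace is always negative, so the determinant sign separates
#' stable nodes/foci from saddles).
#'
#' @inheritParams integrate_to_steady_state
#' @param n_grid Scan grid size over `[0, s_max]`, default 2000.
#' @param s_max Upper scan bound for S; default `2 (a2 + k2) / b2`, which
#'   exceeds any attainable steady-state Slug level.
#' @return Tibble with `E`, `S`, `stability` (`"stable"` or `"saddle"`),
#'   sorted by S.
#' @examples
#' find_equilibria(emt_parameters(), contact = 1.5, tgfb = 0)  # bistable
#' @export
find_equilibria <- function(params, contact, tgfb,
                            frame = c("dimensional", "nondimensional"),
                            n_grid = 2000, s_max = NULL) {
  frame <- match.arg(frame)
  red <- equilibrium_residual(params, contact, tgfb, frame)
  if (is.null(s_max)) s_max <- red$s_max
  if (s_max <= 0) s_max <- .Machine$double.eps
  grid <- seq(0, s_max, length.out = n_grid)
  res <- red$residual(grid)
  if (res[n_grid] > 0) {
    stop("equilibrium scan bound clipped a root (residual positive at ",
         "s_max = ", s_max, "); widen `s_max`")
  }
  roots <- grid[res == 0]
  flips <- which(res[-n_grid] * res[-1] < 0)
  for (i in flips) {
    r <- stats::uniroot(red$residual, lower = grid[i], upper = grid[i + 1],
                        f.lower = res[i], f.upper = res[i + 1],
                        tol = 1e-12)
    roots <- c(roots, r$root)
  }
  roots <- sort(unique(roots))
  if (length(roots) > 1) {
    roots <- roots[c(TRUE, diff(roots) > 1e-9 * max(1, s_max))]
  }
  if (length(roots) == 0) {
    return(tibble::tibble(E = numeric(), S = numeric(),
                          stability = character()))
  }
  E <- red$E_of_S(roots)
  stab <- vapply(seq_along(roots), function(i) {
    J <- grouped_jacobian(E[i], roots[i], red$grouped)
    if (det(J) < 0) "saddle" else "stable"
  }, character(1))
  tibble::tibble(E = E, S = roots, stability = stab)
}
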