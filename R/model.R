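#' Saturating Hill factor
#'
#' Computes x^n / (1 + x^n) for x = value/half_max, defined as 0 at x = 0
#' (no 0/0 ambiguity arises since all exponents are >= 2).  Lies in [0, 1)
#' and is monotone increasing in its argument.
#'
#' @param x Nonnegative argument (already scaled by its half-maximal constant).
#' @param n Hill coefficient.
#' @return Numeric vector of the same length as `x`.
#' @export
hill <- function(x, n) {
  if (any(x < 0, na.rm = TRUE)) stop("Hill argument must be nonnegative")
  xn <- x^n
  ifelse(x == 0, 0, xn / (1 + xn))
}

# Collapse either frame to the grouped form evaluated by the compiled rhs:
# (a1, icS, n1, hc, b1, a2, k1, icE, n3, ht, b2), with hc and ht the
# trajectory-constant contact and TGF-beta Hill inputs.
grouped_form <- function(params, contact, tgfb,
                         frame = c("dimensional", "nondimensional")) {
  frame <- match.arg(frame)
  if (contact < 0) stop("contact must be nonnegative")
  if (tgfb < 0) stop("TGF-beta level must be nonnegative")
  v <- check_params(params)
  if (frame == "dimensional") {
    c(a1 = unname(v["alpha1"]), icS = unname(v["IC_S"]), n1 = unname(v["n1"]),
      hc = unname(v["k0"] * hill(contact / v["IC_C"], v["n2"])),
      b1 = unname(v["beta1"]),
      a2 = unname(v["alpha2"]), k1 = unname(v["k1"]), icE = unname(v["IC_E"]),
      n3 = unname(v["n3"]),
      ht = unname(v["k2"] * hill(tgfb / v["IC_T"], v["n4"])),
      b2 = unname(v["beta2"]),
      prod2 = unname(v["alpha2"] + v["k2"]))  # bound for equilibrium scans
  } else {
    c(a1 = unname(v["A1"]), icS = 1, n1 = unname(v["n1"]),
      hc = unname(v["K0"] * hill(contact, v["n2"])),
      b1 = unname(v["B1"]),
      a2 = unname(v["A2"]), k1 = unname(v["K1"]), icE = 1,
      n3 = unname(v["n3"]),
      ht = unname(v["K2"] * hill(tgfb, v["n4"])),
      b2 = unname(v["B2"]),
      prod2 = unname(v["A2"] + v["K2"]))
  }
}

grouped_rhs <- function(E, S, g) {
  dE <- g[["a1"]] / (1 + (S / g[["icS"]])^g[["n1"]]) + g[["hc"]] - g[["b1"]] * E
  dS <- g[["a2"]] - g[["k1"]] * hill(E / g[["icE"]], g[["n3"]]) +
    g[["ht"]] - g[["b2"]] * S
  c(dE, dS)
}

check_state <- function(state) {
  stopifnot(length(state) == 2)
  if (any(!is.finite(state))) stop("non-finite model state")
  state
}

#' Time derivatives of the dimensional model
#'
#' Evaluates dE/dt and dS/dt of the E-cadherin/Slug system at a state, for a
#' given neighbor count `contact` (C, cells) and TGF-beta level `tgfb`
#' (T, ng/mL).  The contact and TGF-beta Hill terms are 0 when the input is 0.
#'
#' @param state Numeric length-2 vector `c(E, S)` (ng/mL).
#' @param params Dimensional parameter tibble ([emt_parameters()]).
#' @param contact Neighbor count C >= 0.
#' @param tgfb TGF-beta level T >= 0.
#' @return Named numeric vector `c(dE = ..., dS = ...)` (ng/(mL min)).
#' @examples
#' rhs_dimensional(c(0, 0), emt_parameters(), contact = 0, tgfb = 0)
#' @export
rhs_dimensional <- function(state, params, contact, tgfb) {
  check_state(state)
  g <- grouped_form(params, contact, tgfb, "dimensional")
  stats::setNames(grouped_rhs(state[1], state[2], g), c("dE", "dS"))
}

#' Time derivatives of the nondimensional model
#'
#' Evaluates de/dtau and ds/dtau for grouped parameters A1, K0, B1, A2, K1,
#' K2, B2 and nondimensional inputs mu (contact) and theta (TGF-beta).
#'
#' @param state Numeric length-2 vector `c(e, s)`.
#' @param params Nondimensional parameter tibble ([nondimensionalize()]).
#' @param mu Nondimensional contact, >= 0.
#' @param theta Nondimensional TGF-beta, >= 0.
#' @return Named numeric vector `c(de = ..., ds = ...)`.
#' @examples
#' p7 <- emt_parameters("nondimensional", set = 7)
#' rhs_nondimensional(c(0, 0), p7, mu = 0, theta = 0)
#' @export
rhs_nondimensional <- function(state, params, mu, theta) {
  check_state(state)
  g <- grouped_form(params, mu, theta, "nondimensional")
  stats::setNames(grouped_rhs(state[1], state[2], g), c("de", "ds"))
}

# Analytic Jacobian of the grouped-form system at (E, S); closed-form Hill
# derivatives, used for stability classification.
grouped_jacobian <- function(E, S, g) {
  sr <- S / g[["icS"]]; er <- E / g[["icE"]]
  hs <- sr^g[["n1"]]; he <- er^g[["n3"]]
  dhs <- if (S > 0) g[["n1"]] * sr^(g[["n1"]] - 1) / g[["icS"]] else 0
  dhe <- if (E > 0) g[["n3"]] * er^(g[["n3"]] - 1) / g[["icE"]] else 0
  matrix(c(
    -g[["b1"]],                                -g[["a1"]] * dhs / (1 + hs)^2,
    -g[["k1"]] * dhe / (1 + he)^2,             -g[["b2"]]
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("dE", "dS"), c("E", "S")))
}
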