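# Canonical parameter values and treatment conditions for the E-cadherin/Slug
# EMT switch model.  Values are the higher-precision set (earlier published
# values were rounded); units: rates ng/(mL min) or 1/min, half-maximal
# constants ng/mL, IC_C in cells, Hill coefficients dimensionless.

.dim_values <- c(
  alpha1 = 0.19355, alpha2 = 0.080, beta1 = 6.035, beta2 = 0.830,
  k0 = 0.1245, k1 = 0.080, k2 = 0.040,
  IC_S = 0.01920, IC_E = 0.010, IC_T = 3.64e-6, IC_C = 2.17,
  n1 = 3, n2 = 4, n3 = 2, n4 = 3
)

.dim_units <- c(
  alpha1 = "ng/(mL min)", alpha2 = "ng/(mL min)", beta1 = "1/min",
  beta2 = "1/min", k0 = "ng/(mL min)", k1 = "ng/(mL min)",
  k2 = "ng/(mL min)", IC_S = "ng/mL", IC_E = "ng/mL", IC_T = "ng/mL",
  IC_C = "cells", n1 = "", n2 = "", n3 = "", n4 = ""
)

# The 11 sampled parameters; Hill coefficients are fixed and never sampled.
.dim_varied <- c("alpha1", "alpha2", "beta1", "beta2", "k0", "k1", "k2",
                 "IC_S", "IC_E", "IC_T", "IC_C")

.nondim_names <- c("A1", "K0", "B1", "A2", "K1", "K2", "B2")

# Time-scale choice per nondimensionalization set: gamma is the reciprocal of
# one parameter grouping; the grouping that equals gamma collapses to 1.
# Stored as exponent maps over the dimensional symbols so that grouping
# composition (and hence which dimensional parameters survive) is derived
# symbolically, not hand-coded.
.gamma_exponents <- list(
  set1 = c(IC_E = 1, alpha1 = -1),
  set2 = c(IC_E = 1, k0 = -1),
  set3 = c(beta1 = -1),
  set4 = c(IC_S = 1, alpha2 = -1),
  set5 = c(IC_S = 1, k1 = -1),
  set6 = c(IC_S = 1, k2 = -1),
  set7 = c(beta2 = -1)
)

.gamma_labels <- c(
  set1 = "IC_E/alpha1", set2 = "IC_E/k0", set3 = "1/beta1",
  set4 = "IC_S/alpha2", set5 = "IC_S/k1", set6 = "IC_S/k2",
  set7 = "1/beta2"
)

# Grouping definitions before multiplying by gamma: A1 = alpha1*gamma/IC_E etc.
.base_exponents <- list(
  A1 = c(alpha1 = 1, IC_E = -1),
  K0 = c(k0 = 1, IC_E = -1),
  B1 = c(beta1 = 1),
  A2 = c(alpha2 = 1, IC_S = -1),
  K1 = c(k1 = 1, IC_S = -1),
  K2 = c(k2 = 1, IC_S = -1),
  B2 = c(beta2 = 1)
)

# Grouping held at unity per set (its definition cancels against gamma).
.fixed_grouping <- c(set1 = "A1", set2 = "K0", set3 = "B1", set4 = "A2",
                     set5 = "K1", set6 = "K2", set7 = "B2")

#' Baseline model parameters
#'
#' Returns the canonical parameter table for the dimensional E-cadherin/Slug
#' model, or (via [nondimensionalize()]) a nondimensional variant.  The
#' dimensional model reads
#' \deqn{dE/dt = \alpha_1/(1+(S/IC_S)^{n_1}) +
#'   k_0 (C/IC_C)^{n_2}/(1+(C/IC_C)^{n_2}) - \beta_1 E}
#' \deqn{dS/dt = \alpha_2 - k_1 (E/IC_E)^{n_3}/(1+(E/IC_E)^{n_3}) +
#'   k_2 (T/IC_T)^{n_4}/(1+(T/IC_T)^{n_4}) - \beta_2 S}
#' with contact \eqn{C} (cells) and TGF-beta \eqn{T} (ng/mL) as inputs.
#'
#' @param frame `"dimensional"` or `"nondimensional"`.
#' @param set Nondimensionalization set (1-7); required when
#'   `frame = "nondimensional"`.
#' @return A tibble with columns `name`, `value`, `varied`, `units`, `frame`,
#'   `set_id`.  The 11 rate and half-maximal parameters are marked varied;
#'   Hill coefficients (n1 = 3, n2 = 4, n3 = 2, n4 = 3) are fixed.
#' @examples
#' emt_parameters()
#' emt_parameters("nondimensional", set = 7)
#' @export
emt_parameters <- function(frame = c("dimensional", "nondimensional"),
                           set = NULL) {
  frame <- match.arg(frame)
  if (frame == "nondimensional") {
    if (is.null(set)) stop("`set` (1-7) is required for the nondimensional frame")
    return(nondimensionalize(emt_parameters("dimensional"), set))
  }
  tibble::tibble(
    name = names(.dim_values),
    value = unname(.dim_values),
    varied = names(.dim_values) %in% .dim_varied,
    units = unname(.dim_units[names(.dim_values)]),
    frame = "dimensional",
    set_id = NA_integer_
  )
}

#' The seven time-scale choices for nondimensionalization
#'
#' Each set rescales state by the half-maximal constants
#' (E = IC_E e, S = IC_S s, C = IC_C mu, T = IC_T theta) and time by a
#' characteristic scale gamma; the grouping whose value equals gamma collapses
#' to 1 and is not sampled.
#'
#' @return A tibble with `set_id`, `gamma` (symbolic definition), `gamma_value`
#'   (at the baseline parameter values), and `fixed` (the grouping held at 1).
#' @export
nondim_schemes <- function() {
  v <- .dim_values
  gv <- vapply(.gamma_exponents, function(e) prod(v[names(e)]^e), numeric(1))
  tibble::tibble(
    set_id = 1:7,
    gamma = unname(.gamma_labels),
    gamma_value = unname(gv),
    fixed = unname(.fixed_grouping)
  )
}

param_values <- function(params) {
  stats::setNames(params$value, params$name)
}

# Degradation rates, half-maximal constants and Hill coefficients must be
# strictly positive; production/interaction rates may be zero (the pure-decay
# limit is admissible).
.strictly_positive <- c("beta1", "beta2", "IC_S", "IC_E", "IC_T", "IC_C",
                        "n1", "n2", "n3", "n4", "B1", "B2")

check_params <- function(params) {
  stopifnot(is.data.frame(params), all(c("name", "value") %in% names(params)))
  v <- param_values(params)
  strict <- names(v) %in% .strictly_positive
  bad <- !is.finite(v) | v < 0 | (strict & v == 0)
  if (any(bad)) {
    stop("invalid (negative, zero where positivity is required, or ",
         "non-finite) parameter value(s): ",
         paste(names(v)[bad], collapse = ", "))
  }
  invisible(v)
}

#' Nondimensionalize the dimensional parameter table
#'
#' Computes the grouped dimensionless parameters for one of the seven
#' time-scale choices: with gamma from [nondim_schemes()],
#' A1 = alpha1 gamma / IC_E, K0 = k0 gamma / IC_E, B1 = beta1 gamma,
#' A2 = alpha2 gamma / IC_S, K1 = k1 gamma / IC_S, K2 = k2 gamma / IC_S,
#' B2 = beta2 gamma.  The gamma-defining grouping equals exactly 1 and is
#' marked not varied.
#'
#' @param params Dimensional parameter tibble ([emt_parameters()]).
#' @param set Integer 1-7.
#' @return Tibble with columns `name` (A1, K0, B1, A2, K1, K2, B2 plus the
#'   fixed Hill coefficients), `value`, `varied`, `units`, `frame`, `set_id`.
#' @examples
#' nondimensionalize(emt_parameters(), set = 7)
#' @export
nondimensionalize <- function(params, set) {
  stopifnot(length(set) == 1, set %in% 1:7)
  v <- check_params(params)
  key <- paste0("set", set)
  gamma <- prod(v[names(.gamma_exponents[[key]])]^.gamma_exponents[[key]])
  val <- c(
    A1 = unname(v["alpha1"] * gamma / v["IC_E"]),
    K0 = unname(v["k0"] * gamma / v["IC_E"]),
    B1 = unname(v["beta1"] * gamma),
    A2 = unname(v["alpha2"] * gamma / v["IC_S"]),
    K1 = unname(v["k1"] * gamma / v["IC_S"]),
    K2 = unname(v["k2"] * gamma / v["IC_S"]),
    B2 = unname(v["beta2"] * gamma)
  )
  fixed <- .fixed_grouping[[key]]
  val[fixed] <- 1  # exact by construction; avoid rounding residue
  hill <- v[c("n1", "n2", "n3", "n4")]
  out <- tibble::tibble(
    name = c(names(val), names(hill)),
    value = unname(c(val, hill)),
    varied = c(names(val) != fixed, rep(FALSE, 4)),
    units = "",
    frame = "nondimensional",
    set_id = as.integer(set)
  )
  attr(out, "gamma") <- gamma
  out
}

#' Symbolic composition of the nondimensional groupings
#'
#' Expands each grouping definition (including the gamma factor) into integer
#' exponents over the dimensional parameters, with cancellation.  This is the
#' basis for detecting dimensional parameters that no nondimensionalization
#' can see: IC_C and IC_T rescale the inputs and appear in no grouping.
#'
#' @return A tibble with `set_id`, `grouping`, `symbol`, `exponent`; groupings
#'   that cancel completely (the gamma-defining one) contribute no rows.
#' @export
grouping_composition <- function() {
  purrr::map_dfr(1:7, function(set) {
    g <- .gamma_exponents[[paste0("set", set)]]
    purrr::map_dfr(names(.base_exponents), function(grp) {
      e <- .base_exponents[[grp]]
      all_syms <- union(names(e), names(g))
      tot <- stats::setNames(numeric(length(all_syms)), all_syms)
      tot[names(e)] <- tot[names(e)] + e
      tot[names(g)] <- tot[names(g)] + g
      tot <- tot[tot != 0]
      if (length(tot) == 0) return(tibble::tibble())
      tibble::tibble(set_id = set, grouping = grp,
                     symbol = names(tot), exponent = unname(tot))
    })
  })
}

#' Experimental treatment groups
#'
#' The eight conditions per frame: the cross of four contact levels and two
#' TGF-beta levels, each with its prescribed initial state.  Nondimensional
#' contact levels are the printed rounded values (0, 0.46, 0.92, 2.76), shared
#' by all seven sets.
#'
#' @param frame `"dimensional"` or `"nondimensional"`.
#' @return Tibble with `contact`, `tgfb`, `E0`, `S0` (state symbols e/s in the
#'   nondimensional frame), and `frame`.
#' @export
treatment_groups <- function(frame = c("dimensional", "nondimensional")) {
  frame <- match.arg(frame)
  ic <- initial_conditions(frame)
  tg <- if (frame == "dimensional") c(0, 3.64e-6) else c(0, 1)
  tidyr::crossing(ic, tgfb = tg) |>
    dplyr::arrange(.data$contact, .data$tgfb) |>
    dplyr::mutate(frame = frame) |>
    dplyr::select("contact", "tgfb", "E0", "S0", "frame")
}

#' Initial conditions per contact level
#'
#' @param frame `"dimensional"` or `"nondimensional"`.
#' @return Tibble with `contact`, `E0`, `S0` (dimensional: ng/mL at C = 0, 1,
#'   2, 6 cells; nondimensional: the printed e(0), s(0) at mu = 0, 0.46, 0.92,
#'   2.76, shared across Sets 1-7).
#' @export
initial_conditions <- function(frame = c("dimensional", "nondimensional")) {
  frame <- match.arg(frame)
  if (frame == "dimensional") {
    tibble::tibble(
      contact = c(0, 1, 2, 6),
      E0 = c(0.0003, 0.0280, 0.0399, 0.0522),
      S0 = c(0.0963, 0.0109, 0.0057, 0.0034)
    )
  } else {
    tibble::tibble(
      contact = c(0, 0.46, 0.92, 2.76),
      E0 = c(0.0251, 2.7923, 3.9869, 5.2185),
      S0 = c(5.0220, 0.5712, 0.2974, 0.1780)
    )
  }
}
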