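# Partial rank correlation coefficients (PRCC).  The coefficient for
# parameter j against output y is the Pearson correlation of the residuals
# from regressing rank(X_j) and rank(y) on the rank columns of all other
# parameters (plus an intercept).  The double-regression route is used as
# the implementation because it is numerically stabler with tied ranks; the
# classical inverse-correlation-matrix construction serves as an independent
# oracle in the test suite.

#' Rank-transform a vector
#'
#' Ranks 1..N with ties assigned the average of the tied positions; the
#' output rounding step makes ties routine.
#'
#' @param values Finite numeric vector.
#' @return Numeric vector of (mid)ranks.
#' @examples
#' rank_transform(c(0.5, 0.5, 0.1))  # 2.5 2.5 1
#' @export
rank_transform <- function(values) {
  if (any(!is.finite(values))) stop("non-finite values in rank_transform")
  rank(values, ties.method = "average")
}

resid_on <- function(qz, x) {
  qr.resid(qz, x)
}

safe_cor <- function(a, b) {
  sa <- sqrt(sum((a - mean(a))^2))
  sb <- sqrt(sum((b - mean(b))^2))
  if (sa == 0 || sb == 0) return(NA_real_)
  sum((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

rank_matrix <- function(X) {
  X <- as.matrix(X)
  apply(X, 2, rank_transform)
}

#' Partial rank correlation of one parameter with an output
#'
#' @param X Sample matrix (N x K) of parameter draws, or an `emt_lhs` tibble.
#' @param y Output vector of length N (steady-state readouts, already
#'   rounded to the frame grain).
#' @param j Column index or name of the parameter of interest.
#' @return The coefficient `rho_j` in \[-1, 1\].
#' @export
partial_rank_correlation <- function(X, y, j) {
  R <- rank_matrix(X)
  if (is.character(j)) j <- match(j, colnames(R))
  stopifnot(nrow(R) >= ncol(R) + 2)
  yr <- rank_transform(y)
  Z <- cbind(1, R[, -j, drop = FALSE])
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    stop("singular regressor matrix: collinear rank columns among ",
         paste(colnames(R)[-j], collapse = ", "))
  }
  safe_cor(resid_on(qz, R[, j]), resid_on(qz, yr))
}

#' PRCC of every sampled parameter against one output
#'
#' @inheritParams partial_rank_correlation
#' @param threshold Significance cutoff on |rho|, default 0.5.
#' @return Tibble of class `emt_prcc` with `parameter`, `rho`, `significant`
#'   (|rho| >= threshold; `FALSE` when rho is undefined because the output
#'   is constant after rounding).
#' @export
prcc <- function(X, y, threshold = 0.5) {
  R <- rank_matrix(X)
  yr <- rank_transform(y)
  rho <- vapply(seq_len(ncol(R)), function(j) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    qz <- qr(Z)
    safe_cor(resid_on(qz, R[, j]), resid_on(qz, yr))
  }, numeric(1))
  out <- tibble::tibble(
    parameter = colnames(R),
    rho = rho,
    significant = !is.na(rho) & abs(rho) >= threshold
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("emt_prcc", class(out))
  out
}

#' Names of the parameters deemed significant
#'
#' Applies the |rho| >= threshold cutoff, keeping the order (and, via the
#' returned tibble from [prcc()], the sign) of the coefficients.
#'
#' @param result `emt_prcc` tibble.
#' @param threshold Cutoff; defaults to the one stored in `result`.
#' @return Character vector of parameter names.
#' @export
classify_significance <- function(result, threshold = NULL) {
  if (is.null(threshold)) threshold <- attr(result, "threshold") %||% 0.5
  result$parameter[!is.na(result$rho) & abs(result$rho) >= threshold]
}

#' Inter-parameter PRCC screen
#'
#' Partial rank correlation of every column pair controlling for the
#' remaining K - 2 columns; values below 0.5 in magnitude indicate no hidden
#' relationships among the sampled parameters.  A perfectly collinear pair
#' (after ranking) is returned as +/- 1 rather than propagating the
#' singularity.
#'
#' @param X Sample matrix or `emt_lhs` tibble (N x K, K >= 2).
#' @return Symmetric K x K matrix with unit diagonal.
#' @export
interparameter_prcc <- function(X) {
  R <- rank_matrix(X)
  k <- ncol(R)
  stopifnot(k >= 2, nrow(R) >= k + 2)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(R), colnames(R))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      rest <- setdiff(seq_len(k), c(i, j))
      Z <- cbind(rep(1, nrow(R)), R[, rest, drop = FALSE])
      qz <- qr(Z)
      r <- safe_cor(resid_on(qz, R[, i]), resid_on(qz, R[, j]))
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

#' One-at-a-time monotonicity diagnostic
#'
#' PRCC is only valid when each output responds monotonically to each
#' parameter varied alone.  For every varied parameter the rounded
#' steady-state outputs are evaluated along an evenly spaced grid over its
#' sampling range, all other parameters held at baseline, and the rounded
#' sequence is checked for nonstrict monotonicity.
#'
#' @param ranges Range tibble from [build_ranges()] (baseline values in
#'   `value`, sampling bounds in `lo`, `hi`).
#' @param contact,tgfb Treatment condition.
#' @param frame `"dimensional"` or `"nondimensional"`.
#' @param points Grid size per parameter (>= 3), default 50.
#' @param t_end Readout time, default 10000.
#' @return Tibble with one row per (parameter, output): `monotone`,
#'   `direction` (`"increasing"`, `"decreasing"`, `"flat"`,
#'   `"nonmonotone"`), `negative_values`, plus `grid` and `values`
#'   list-columns.
#' @export
monotonicity_scan <- function(ranges, contact, tgfb,
                              frame = c("dimensional", "nondimensional"),
                              points = 50, t_end = 10000) {
  frame <- match.arg(frame)
  stopifnot(points >= 3)
  varied <- dplyr::filter(ranges, .data$varied)
  if (any(varied$lo >= varied$hi)) stop("degenerate range in scan")
  ic <- initial_conditions(frame)
  init <- unlist(ic[match(contact, ic$contact), c("E0", "S0")])
  outputs <- if (frame == "dimensional") c("E", "S") else c("e", "s")
  purrr::map_dfr(varied$name, function(p) {
    grid <- seq(varied$lo[varied$name == p], varied$hi[varied$name == p],
                length.out = points)
    base <- ranges[, c("name", "value")]
    res <- purrr::map(grid, function(v) {
      prm <- base
      prm$value[prm$name == p] <- v
      prm$varied <- ranges$varied
      prm$frame <- frame
      tryCatch(
        integrate_to_steady_state(prm, contact, tgfb, init = init,
                                  t_end = t_end, frame = frame,
                                  n_check = 21),
        error = function(e) NULL
      )
    })
    ok <- !vapply(res, is.null, logical(1))
    ss <- dplyr::bind_rows(res[ok])
    neg <- any(ss$negative_excursion) || any(ss$E_ss < 0) || any(ss$S_ss < 0)
    purrr::map_dfr(c(E = "rounded_E", S = "rounded_S"), function(col) {
      vals <- ss[[col]]
      d <- diff(vals)
      mono <- all(d >= 0) || all(d <= 0)
      dir <- if (all(d == 0)) "flat"
      else if (all(d >= 0)) "increasing"
      else if (all(d <= 0)) "decreasing"
      else "nonmonotone"
      tibble::tibble(
        parameter = p,
        output = outputs[if (col == "rounded_E") 1 else 2],
        monotone = mono, direction = dir,
        negative_values = neg,
        n_failed = sum(!ok),
        grid = list(grid[ok]), values = list(vals)
      )
    })
  })
}

#' Plot PRCC coefficients
#'
#' Bar chart of the coefficients with the significance cutoff as dashed
#' lines.
#'
#' @param object `emt_prcc` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emt_prcc <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 0.5
  ggplot2::ggplot(object, ggplot2::aes(x = .data$parameter, y = .data$rho)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(y = "PRCC", x = NULL) +
    ggplot2::theme_minimal()
}
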