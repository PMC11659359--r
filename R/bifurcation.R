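# One-parameter bifurcation analysis in contact (C or mu) or TGF-beta
# (T or theta).  Folds are located by bisection on the equilibrium count
# rather than pseudo-arclength continuation: adequate for a two-state model
# whose branch structure is an S-curve with zero or two folds per sweep.

default_admissible <- function(control, frame) {
  if (frame == "dimensional") {
    if (control == "contact") c(0, 6) else c(0, 3.64e-6)
  } else {
    if (control == "contact") c(0, 2.76) else c(0, 1)
  }
}

#' Trace equilibrium branches along a control input
#'
#' Sweeps the control (contact or TGF-beta) over an interval on a fine grid,
#' enumerates equilibria at each value, links them into branches by
#' nearest-neighbour continuation, and bisects every change in equilibrium
#' count to locate fold (saddle-node) points.
#'
#' @param params Parameter tibble for the chosen frame.
#' @param control `"contact"` or `"tgfb"`: which input is varied.
#' @param frozen_value The fixed value of the other input.
#' @param interval Length-2 sweep interval; defaults to the admissible range
#'   (dimensional: C in \[0, 6\] cells, T in \[0, 3.64e-6\] ng/mL).
#' @param frame `"dimensional"` or `"nondimensional"`.
#' @param n_grid Sweep grid size, default 600.
#' @return An object of class `emt_bifurcation`: list with `points` (tibble
#'   `control`, `E`, `S`, `stability`, `branch_id`), `folds` (tibble
#'   `control`, `E`, `S`), and sweep metadata.
#' @examples
#' \donttest{
#' bd <- trace_branches(emt_parameters(), "contact", frozen_value = 0)
#' bd$folds  # L_M and L_E
#' }
#' @export
trace_branches <- function(params, control = c("contact", "tgfb"),
                           frozen_value, interval = NULL,
                           frame = c("dimensional", "nondimensional"),
                           n_grid = 600) {
  control <- match.arg(control)
  frame <- match.arg(frame)
  if (is.null(interval)) interval <- default_admissible(control, frame)
  if (any(interval < 0)) stop("control interval must be nonnegative")
  grid <- seq(interval[1], interval[2], length.out = n_grid)
  eq_at <- function(v) {
    if (control == "contact") {
      find_equilibria(params, v, frozen_value, frame)
    } else {
      find_equilibria(params, frozen_value, v, frame)
    }
  }
  eqs <- purrr::map(grid, eq_at)
  counts <- vapply(eqs, nrow, integer(1))

  # nearest-neighbour branch linking on (E, S), scaled by typical magnitudes
  sE <- max(purrr::map_dbl(eqs, ~ if (nrow(.x)) max(.x$E) else 0), 1e-12)
  sS <- max(purrr::map_dbl(eqs, ~ if (nrow(.x)) max(.x$S) else 0), 1e-12)
  next_id <- 0L
  prev <- NULL
  pts <- vector("list", n_grid)
  for (i in seq_len(n_grid)) {
    eq <- eqs[[i]]
    if (nrow(eq) == 0) { prev <- NULL; next }
    ids <- rep(NA_integer_, nrow(eq))
    if (!is.null(prev) && nrow(prev) > 0) {
      for (j in seq_len(nrow(eq))) {
        d <- sqrt(((eq$E[j] - prev$E) / sE)^2 + ((eq$S[j] - prev$S) / sS)^2)
        jbest <- which.min(d)
        if (d[jbest] < 0.5 && !prev$branch_id[jbest] %in% ids) {
          ids[j] <- prev$branch_id[jbest]
        }
      }
    }
    for (j in which(is.na(ids))) {
      next_id <- next_id + 1L
      ids[j] <- next_id
    }
    eq$branch_id <- ids
    eq$control <- grid[i]
    pts[[i]] <- eq
    prev <- eq
  }
  points <- dplyr::bind_rows(pts) |>
    dplyr::select("control", "E", "S", "stability", "branch_id")

  folds <- dplyr::bind_rows(
    tibble::tibble(control = numeric(), E = numeric(), S = numeric()),
    purrr::map_dfr(which(diff(counts) != 0), function(i) {
      locate_fold(params, control, frozen_value,
                  bracket = c(grid[i], grid[i + 1]), frame = frame)
    })
  )
  structure(
    list(points = points, folds = folds, control = control,
         frozen_value = frozen_value, frame = frame, interval = interval),
    class = "emt_bifurcation"
  )
}

#' @export
print.emt_bifurcation <- function(x, ...) {
  other <- if (x$control == "contact") "tgfb" else "contact"
  cat("Bifurcation sweep of", x$control, "over [",
      paste(signif(x$interval, 6), collapse = ", "), "] (", x$frame,
      "frame),", other, "=", x$frozen_value, "\n")
  cat(nrow(x$points), "branch points,", nrow(x$folds), "fold(s)\n")
  if (nrow(x$folds)) print(x$folds)
  invisible(x)
}

# Root of the residual derivative nearest S_guess, by geometric bracket
# expansion; the critical point persists smoothly through the fold.
crit_point <- function(red, s_guess) {
  w <- max(1e-8, 1e-4 * s_guess)
  for (it in 1:60) {
    lo <- max(0, s_guess - w); hi <- s_guess + w
    flo <- red$dresidual(lo); fhi <- red$dresidual(hi)
    if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0) {
      return(stats::uniroot(red$dresidual, lower = lo, upper = hi,
                            f.lower = flo, f.upper = fhi,
                            tol = 1e-14)$root)
    }
    w <- w * 2
  }
  stop("failed to bracket the residual critical point near S = ", s_guess)
}

#' Locate a fold (saddle-node) point
#'
#' The bracket must contain exactly one change in the number of equilibria.
#' At a fold the reduced scalar residual and its S-derivative vanish
#' together (tangency); the fold is found as the control value at which the
#' residual's critical value -- tracked from the merging saddle-node pair on
#' the many-equilibria side -- crosses zero.  This is insensitive to the
#' finite resolution of the equilibrium scan near the fold, where the
#' merging pair of roots becomes arbitrarily close.
#'
#' @inheritParams trace_branches
#' @param bracket Length-2 interval bracketing the fold (the search is
#'   allowed to extend moderately past the far end, since a root pair closer
#'   than the scan grid is counted as merged slightly before the true fold).
#' @param tol Convergence tolerance on the control; default 1e-9 for contact
#'   (cells), 1e-15 for TGF-beta (ng/mL scale).
#' @return One-row tibble `control`, `E`, `S` (the double-root state).
#' @export
locate_fold <- function(params, control = c("contact", "tgfb"),
                        frozen_value, bracket,
                        frame = c("dimensional", "nondimensional"),
                        tol = NULL) {
  control <- match.arg(control)
  frame <- match.arg(frame)
  if (is.null(tol)) tol <- if (control == "contact") 1e-9 else 1e-15
  red_at <- function(v) {
    if (control == "contact") {
      equilibrium_residual(params, v, frozen_value, frame)
    } else {
      equilibrium_residual(params, frozen_value, v, frame)
    }
  }
  eq_at <- function(v) {
    if (control == "contact") {
      find_equilibria(params, v, frozen_value, frame)
    } else {
      find_equilibria(params, frozen_value, v, frame)
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  n_lo <- nrow(eq_at(lo)); n_hi <- nrow(eq_at(hi))
  if (n_lo == n_hi) {
    stop("no change in equilibrium count over bracket [", lo, ", ", hi, "]")
  }
  many <- if (n_lo > n_hi) lo else hi
  other <- if (n_lo > n_hi) hi else lo
  eq <- eq_at(many)
  i <- which.min(diff(eq$S))
  s_track <- new.env()
  s_track$s <- crit_point(red_at(many), mean(eq$S[c(i, i + 1)]))
  phi <- function(v) {
    s <- crit_point(red_at(v), s_track$s)
    s_track$s <- s
    red_at(v)$residual(s)
  }
  f_many <- phi(many)
  f_other <- phi(other)
  # expand past `other` if the scan-resolution bias put the true fold there
  step <- other - many
  while (sign(f_many) == sign(f_other)) {
    other <- other + 0.5 * step
    if (other < 0 || abs(other - many) > 4 * abs(step)) {
      stop("failed to bracket the fold tangency beyond [",
           bracket[1], ", ", bracket[2], "]")
    }
    f_other <- phi(other)
  }
  r <- stats::uniroot(phi, lower = min(many, other),
                      upper = max(many, other), tol = tol)
  red <- red_at(r$root)
  s_fold <- crit_point(red, s_track$s)
  tibble::tibble(control = r$root, E = red$E_of_S(s_fold), S = s_fold)
}

#' Classify the hysteresis of a traced diagram
#'
#' A sweep with no folds is not a switch; two folds interior to the
#' admissible interval give a reversible switch; a single interior fold whose
#' return fold is absent within the admissible range (e.g. it would require
#' negative TGF-beta) is an irreversible switch.
#'
#' @param diagram `emt_bifurcation` object from [trace_branches()].
#' @param admissible Length-2 admissible control interval; defaults to the
#'   sweep's own interval.
#' @return List of class `emt_switch` with `kind` (`"none"`, `"reversible"`,
#'   `"irreversible"`) and `thresholds` (fold control values inside the
#'   admissible interval).
#' @export
classify_switch <- function(diagram, admissible = NULL) {
  stopifnot(inherits(diagram, "emt_bifurcation"))
  if (is.null(admissible)) admissible <- diagram$interval
  th <- diagram$folds$control
  th <- th[th >= admissible[1] & th <= admissible[2]]
  kind <- if (length(th) == 0) "none"
  else if (length(th) >= 2) "reversible"
  else "irreversible"
  structure(list(kind = kind, thresholds = sort(th)), class = "emt_switch")
}

#' @export
print.emt_switch <- function(x, ...) {
  cat("switch:", x$kind)
  if (length(x$thresholds)) {
    cat(" (thresholds:", paste(signif(x$thresholds, 6), collapse = ", "),
        ")")
  }
  cat("\n")
  invisible(x)
}

#' Plot a bifurcation diagram
#'
#' Stable branches solid, saddles dashed, folds marked.
#'
#' @param object `emt_bifurcation` object.
#' @param output `"E"` or `"S"`: which state to plot against the control.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emt_bifurcation <- function(object, output = c("E", "S"), ...) {
  output <- match.arg(output)
  pts <- object$points
  pts$y <- pts[[output]]
  folds <- object$folds
  folds$y <- folds[[output]]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$control, y = .data$y,
                                    group = .data$branch_id,
                                    linetype = .data$stability)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = folds, inherit.aes = FALSE,
                        ggplot2::aes(x = .data$control, y = .data$y),
                        shape = 21, size = 2, fill = "white") +
    ggplot2::scale_linetype_manual(
      values = c(stable = "solid", saddle = "dashed")) +
    ggplot2::labs(x = object$control, y = output,
                  title = sprintf("%s sweep (%s frame)", object$control,
                                  object$frame)) +
    ggplot2::theme_minimal()
}
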