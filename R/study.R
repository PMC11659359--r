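# Full-study orchestration: for each model frame (dimensional, Sets 1-7),
# one LHS design is drawn and evaluated under all eight treatment groups;
# PRCC of both outputs yields a per-frame significance grid, and the frames
# are compared.  With the shared-design default every frame rescales the
# same unit-hypercube draw (column RNG streams depend only on seed and
# column index), so frame-to-frame comparisons are not confounded by
# sampling noise.

#' Study configuration
#'
#' Defaults reproduce the published protocol: N = 10000 samples, all eight
#' frames, eight treatment groups per frame, significance cutoff 0.5,
#' readout at t = 10000 with grains 1e-4 (dimensional) and 1e-2
#' (nondimensional).
#'
#' @param n LHS sample count per frame.
#' @param seed Integer RNG seed.
#' @param frames Character subset of `"dimensional"`, `"set1"` ... `"set7"`.
#' @param threshold Significance cutoff on |rho|.
#' @param t_end Readout time.
#' @param shared_design Reuse one unit-hypercube draw across frames (TRUE,
#'   default) or draw independently per frame.
#' @return List of class `emt_study_config`.
#' @export
study_config <- function(n = 10000, seed = 1,
                         frames = c("dimensional", paste0("set", 1:7)),
                         threshold = 0.5, t_end = 10000,
                         shared_design = TRUE) {
  frames <- match.arg(frames, c("dimensional", paste0("set", 1:7)),
                      several.ok = TRUE)
  structure(list(n = n, seed = seed, frames = frames, threshold = threshold,
                 t_end = t_end, shared_design = shared_design),
            class = "emt_study_config")
}

frame_baseline <- function(frame) {
  if (frame == "dimensional") emt_parameters("dimensional")
  else emt_parameters("nondimensional",
                      set = as.integer(sub("set", "", frame)))
}

frame_kind <- function(frame) {
  if (frame == "dimensional") "dimensional" else "nondimensional"
}

#' Steady-state readouts for a batch of parameter sets
#'
#' Integrates every row of a parameter-set table under one treatment
#' condition and records the rounded state at `t_end`.
#'
#' @param param_sets Tibble from [assemble_parameter_sets()] (one column per
#'   model parameter).
#' @param contact,tgfb Treatment condition.
#' @param init Length-2 initial state; defaults to the tabulated initial
#'   condition for this contact level.
#' @param frame `"dimensional"` or `"nondimensional"`.
#' @param t_end Readout time.
#' @return Tibble with `E_ss`, `S_ss`, `rounded_E`, `rounded_S`, `converged`,
#'   one row per parameter set, in input order.
#' @export
steady_states <- function(param_sets, contact, tgfb, init = NULL,
                          frame = c("dimensional", "nondimensional"),
                          t_end = 10000) {
  frame <- match.arg(frame)
  if (contact < 0 || tgfb < 0) stop("contact and tgfb must be nonnegative")
  if (is.null(init)) {
    ic <- initial_conditions(frame)
    j <- match(contact, ic$contact)
    if (is.na(j)) stop("no tabulated initial condition for contact = ",
                       contact, "; supply `init`")
    init <- c(ic$E0[j], ic$S0[j])
  }
  M <- as.matrix(param_sets)
  n <- nrow(M)
  if (n == 0) {
    return(tibble::tibble(E_ss = numeric(), S_ss = numeric(),
                          rounded_E = numeric(), rounded_S = numeric(),
                          converged = logical()))
  }
  # grouped-form parameter matrix, vectorized across rows
  if (frame == "dimensional") {
    P <- cbind(
      a1 = M[, "alpha1"], icS = M[, "IC_S"], n1 = M[, "n1"],
      hc = M[, "k0"] * hill(contact / M[, "IC_C"], M[, "n2"][1]),
      b1 = M[, "beta1"], a2 = M[, "alpha2"], k1 = M[, "k1"],
      icE = M[, "IC_E"], n3 = M[, "n3"],
      ht = M[, "k2"] * hill(tgfb / M[, "IC_T"], M[, "n4"][1]),
      b2 = M[, "beta2"]
    )
  } else {
    hc_mu <- hill(contact, M[, "n2"][1])
    ht_th <- hill(tgfb, M[, "n4"][1])
    P <- cbind(
      a1 = M[, "A1"], icS = 1, n1 = M[, "n1"],
      hc = M[, "K0"] * hc_mu, b1 = M[, "B1"],
      a2 = M[, "A2"], k1 = M[, "K1"], icE = 1, n3 = M[, "n3"],
      ht = M[, "K2"] * ht_th, b2 = M[, "B2"]
    )
  }
  y0 <- c(E = init[[1]], S = init[[2]])
  times <- c(0, t_end)
  fin <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    out <- deSolve::ode(
      y = y0, times = times, func = "emt_derivs", parms = P[i, ],
      dllname = "emtsens", initfunc = "emt_init",
      jacfunc = "emt_jac", jactype = "fullusr",
      rtol = .rtol, atol = .atol, maxsteps = 50000
    )
    if (attr(out, "istate")[1] < 0 || any(!is.finite(out[2, 2:3]))) {
      stop("integration failed at parameter-set row ", i)
    }
    fin[i, ] <- out[2, 2:3]
  }
  # convergence screen, vectorized (clamp sub-atol undershoot)
  hs <- (pmax(fin[, 2], 0) / P[, "icS"])^P[, "n1"]
  he <- (pmax(fin[, 1], 0) / P[, "icE"])^P[, "n3"]
  dE <- P[, "a1"] / (1 + hs) + P[, "hc"] - P[, "b1"] * fin[, 1]
  dS <- P[, "a2"] - P[, "k1"] * he / (1 + he) + P[, "ht"] -
    P[, "b2"] * fin[, 2]
  tibble::tibble(
    E_ss = fin[, 1], S_ss = fin[, 2],
    rounded_E = round_output(fin[, 1], frame),
    rounded_S = round_output(fin[, 2], frame),
    converged = pmax(abs(dE), abs(dS)) < .converge_tol
  )
}

#' Run the LHS + PRCC study over the configured frames
#'
#' For each frame: builds the sampling ranges (published shifted ranges for
#' alpha2/k1 and A2/K1 applied), draws the LHS design, integrates all eight
#' treatment groups to their rounded steady-state readouts, computes PRCC of
#' both outputs against every sampled parameter, and applies the
#' significance cutoff.  The result is the per-frame significance grid plus
#' the dimensional-versus-nondimensional comparison.
#'
#' @param config `emt_study_config` from [study_config()].
#' @return Object of class `emt_study`: list with `grid` (tibble `frame`,
#'   `contact`, `tgfb`, `output`, `parameter`, `rho`, `significant`),
#'   `diagnostics` (per frame/group convergence fractions), `comparison`
#'   ([report_discrepancies()] output when the frame set allows it), and
#'   `config`.
#' @examples
#' \donttest{
#' st <- run_study(study_config(n = 200, seed = 1, frames = "dimensional"))
#' tidy(st)
#' }
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "emt_study_config"))
  rows <- list(); diags <- list()
  for (f in config$frames) {
    kind <- frame_kind(f)
    baseline <- frame_baseline(f)
    ranges <- build_ranges(baseline)
    seed_f <- if (config$shared_design) config$seed else
      (config$seed + 7907L * match(f, c("dimensional", paste0("set", 1:7))))
    design <- latin_hypercube(ranges, n = config$n, seed = seed_f)
    sets <- assemble_parameter_sets(design, baseline)
    groups <- treatment_groups(kind)
    outs <- if (kind == "dimensional") c("E", "S") else c("e", "s")
    for (gi in seq_len(nrow(groups))) {
      grp <- groups[gi, ]
      ss <- steady_states(sets, grp$contact, grp$tgfb,
                          init = c(grp$E0, grp$S0), frame = kind,
                          t_end = config$t_end)
      for (o in c(1, 2)) {
        y <- if (o == 1) ss$rounded_E else ss$rounded_S
        pr <- prcc(design, y, threshold = config$threshold)
        rows[[length(rows) + 1]] <- tibble::tibble(
          frame = f, contact = grp$contact, tgfb = grp$tgfb,
          output = outs[o], parameter = pr$parameter, rho = pr$rho,
          significant = pr$significant
        )
      }
      diags[[length(diags) + 1]] <- tibble::tibble(
        frame = f, contact = grp$contact, tgfb = grp$tgfb,
        prop_converged = mean(ss$converged)
      )
    }
  }
  grid <- dplyr::bind_rows(rows)
  res <- structure(
    list(grid = grid, diagnostics = dplyr::bind_rows(diags),
         comparison = NULL, config = config),
    class = "emt_study"
  )
  nondim <- setdiff(config$frames, "dimensional")
  if (length(nondim) >= 2 || ("dimensional" %in% config$frames &&
                              length(nondim) >= 1)) {
    res$comparison <- report_discrepancies(grid)
  }
  res
}

significant_sets <- function(grid) {
  grid |>
    dplyr::filter(.data$significant) |>
    dplyr::group_by(.data$frame, .data$contact, .data$tgfb, .data$output) |>
    dplyr::summarise(set = list(sort(.data$parameter)), .groups = "drop")
}

#' Compare significance grids across model formulations
#'
#' Two comparisons drive the study's conclusions: (1) for each treatment
#' group and output, whether the seven nondimensionalizations agree on the
#' significant-parameter set; (2) which dimensional parameters flagged
#' significant appear in no nondimensional grouping at all (the grouping
#' membership is derived symbolically via [grouping_composition()]; IC_C and
#' IC_T rescale the inputs and are invisible to every nondimensionalization).
#'
#' @param grid Significance-grid tibble (from an [run_study()] result).
#' @return List of class `emt_comparison` with `disagreements` (one row per
#'   (contact level, TGF-beta level, output) where nondimensional sets
#'   disagree, with the per-set significant sets) and `lost_parameters`
#'   (dimensional significances with no nondimensional counterpart
#'   grouping).
#' @export
report_discrepancies <- function(grid) {
  if (inherits(grid, "emt_study")) grid <- grid$grid
  nd <- dplyr::filter(grid, .data$frame != "dimensional")
  disagreements <- tibble::tibble()
  if (nrow(nd) > 0) {
    per_set <- nd |>
      dplyr::group_by(.data$frame, .data$contact, .data$tgfb,
                      .data$output) |>
      dplyr::summarise(
        set = list(sort(.data$parameter[.data$significant])),
        .groups = "drop")
    disagreements <- per_set |>
      dplyr::group_by(.data$contact, .data$tgfb, .data$output) |>
      dplyr::summarise(
        n_distinct = length(unique(purrr::map_chr(
          .data$set, paste, collapse = "+"))),
        frames = list(.data$frame),
        sets = list(.data$set),
        .groups = "drop") |>
      dplyr::filter(.data$n_distinct > 1)
  }
  lost <- tibble::tibble()
  dim_grid <- dplyr::filter(grid, .data$frame == "dimensional",
                            .data$significant)
  if (nrow(dim_grid) > 0) {
    visible <- unique(grouping_composition()$symbol)
    lost <- dim_grid |>
      dplyr::filter(!.data$parameter %in% visible) |>
      dplyr::select("contact", "tgfb", "output", "parameter", "rho")
  }
  structure(list(disagreements = disagreements, lost_parameters = lost),
            class = "emt_comparison")
}

#' @export
print.emt_comparison <- function(x, ...) {
  cat("Nondimensionalization-dependent cells:",
      nrow(x$disagreements), "\n")
  if (nrow(x$disagreements)) {
    print(dplyr::select(x$disagreements, "contact", "tgfb", "output",
                        "n_distinct"))
  }
  cat("Dimensional significances invisible to every grouping:",
      nrow(x$lost_parameters), "\n")
  if (nrow(x$lost_parameters)) print(x$lost_parameters)
  invisible(x)
}

#' @export
print.emt_study <- function(x, ...) {
  cat("EMT sensitivity study: n =", x$config$n, ", frames:",
      paste(x$config$frames, collapse = ", "), "\n")
  cat(nrow(x$grid), "grid cells;",
      sum(x$grid$significant), "significant (|rho| >=",
      x$config$threshold, ")\n")
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' @rdname run_study
#' @param x `emt_study` object.
#' @param ... Unused.
#' @export
tidy.emt_study <- function(x, ...) x$grid

#' @rdname run_study
#' @export
glance.emt_study <- function(x, ...) {
  tibble::tibble(
    n = x$config$n, seed = x$config$seed,
    n_frames = length(x$config$frames),
    n_cells = nrow(x$grid),
    n_significant = sum(x$grid$significant),
    threshold = x$config$threshold,
    n_disagreements = if (is.null(x$comparison)) NA_integer_ else
      nrow(x$comparison$disagreements)
  )
}

#' Significance-grid plot
#'
#' Tile plot of the significance grid in the style of the study's summary
#' figures: gold tiles where the parameter is significant for the
#' E-cadherin output, blue for Slug, black where the parameter is not varied
#' in that frame.
#'
#' @param object `emt_study` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emt_study <- function(object, ...) {
  grid <- object$grid |>
    dplyr::mutate(
      group = sprintf("contact=%g\ntgfb=%g", .data$contact, .data$tgfb),
      state = dplyr::case_when(
        .data$significant & .data$output %in% c("E", "e") ~ "E-cadherin",
        .data$significant & .data$output %in% c("S", "s") ~ "Slug",
        TRUE ~ "not significant"
      )
    ) |>
    dplyr::filter(.data$state != "not significant" |
                    !duplicated(paste(.data$frame, .data$group,
                                      .data$parameter)))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$group, y = .data$parameter,
                                     fill = .data$state)) +
    ggplot2::geom_tile(color = "grey40") +
    ggplot2::facet_wrap(~ .data$frame) +
    ggplot2::scale_fill_manual(values = c(
      "E-cadherin" = "goldenrod", "Slug" = "steelblue",
      "not significant" = "white")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}
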