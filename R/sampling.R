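# Latin hypercube sampling: the study's synthetic-input generator.  Each
# varied parameter's [lo, hi] interval is split into N equal-width strata and
# exactly one draw is placed in each stratum; strata orders are permuted
# independently per column.  Each column consumes its own RNG substream
# derived from the global seed and the column index, so adding a column never
# perturbs the draws of the others.

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

column_seed <- function(seed, j) {
  (as.integer(seed) %% 1000003L) * 2053L + 7919L * as.integer(j)
}

#' Latin hypercube sample over tabulated parameter ranges
#'
#' Draws an N x K design with uniform marginals over each varied parameter's
#' `[lo, hi]` interval and exactly one point per equal-width stratum per
#' column (the LHS property).  The sample-size rule N > (4/3) K is enforced:
#' for the 11-parameter dimensional design N = 15 is admissible and N = 14 is
#' not.
#'
#' @param ranges Range tibble from [build_ranges()] (rows with
#'   `varied = FALSE` are ignored).
#' @param n Number of samples N (>= 2 and > 4K/3).
#' @param seed Integer RNG seed; the design is a pure function of
#'   `(ranges, n, seed, method)`.
#' @param method `"jitter"` draws a uniform point within each stratum
#'   (default); `"midpoint"` uses stratum midpoints, a deterministic design
#'   useful in tests.
#' @return Tibble of class `emt_lhs` with one column per varied parameter,
#'   carrying `seed`, `ranges`, and `method` attributes.
#' @examples
#' latin_hypercube(build_ranges(emt_parameters()), n = 20, seed = 1)
#' @export
latin_hypercube <- function(ranges, n, seed,
                            method = c("jitter", "midpoint")) {
  method <- match.arg(method)
  stopifnot(all(c("name", "lo", "hi", "varied") %in% names(ranges)))
  ranges <- dplyr::filter(ranges, .data$varied)
  k <- nrow(ranges)
  if (k == 0) stop("no varied parameters in `ranges`")
  if (n < 2) stop("need at least n = 2 samples")
  if (n <= 4 * k / 3) {
    stop(sprintf("LHS requires n > 4K/3; got n = %d for K = %d (need n > %.2f)",
                 n, k, 4 * k / 3))
  }
  if (any(ranges$lo >= ranges$hi)) {
    stop("degenerate range (lo >= hi) for: ",
         paste(ranges$name[ranges$lo >= ranges$hi], collapse = ", "))
  }
  cols <- purrr::map(seq_len(k), function(j) {
    with_local_seed(column_seed(seed, j), {
      perm <- sample.int(n)
      u <- if (method == "jitter") (perm - runif(n)) / n else (perm - 0.5) / n
      ranges$lo[j] + u * (ranges$hi[j] - ranges$lo[j])
    })
  })
  out <- tibble::as_tibble(stats::setNames(cols, ranges$name))
  attr(out, "seed") <- seed
  attr(out, "ranges") <- ranges
  attr(out, "method") <- method
  class(out) <- c("emt_lhs", class(out))
  out
}

#' Expand an LHS design into complete parameter sets
#'
#' Each design row is combined with the baseline table: sampled parameters
#' take the row's values, unvaried parameters (Hill coefficients; the
#' gamma-defining grouping held at 1.00) keep their baseline values.  Row
#' order is preserved so PRCC can align inputs and outputs.
#'
#' @param samples LHS design ([latin_hypercube()]) or any tibble whose
#'   columns name varied parameters.
#' @param baseline Parameter tibble supplying fixed values and column order.
#' @return Tibble with `nrow(samples)` rows and one column per baseline
#'   parameter, with `frame`/`set_id` attributes.
#' @export
assemble_parameter_sets <- function(samples, baseline) {
  stopifnot(is.data.frame(samples))
  unknown <- setdiff(names(samples), baseline$name)
  if (length(unknown)) {
    stop("sample columns not in baseline: ", paste(unknown, collapse = ", "))
  }
  not_varied <- intersect(names(samples),
                          baseline$name[!baseline$varied])
  if (length(not_varied)) {
    stop("sample columns map onto unvaried parameters: ",
         paste(not_varied, collapse = ", "))
  }
  n <- nrow(samples)
  cols <- purrr::map(baseline$name, function(p) {
    if (p %in% names(samples)) samples[[p]]
    else rep(baseline$value[match(p, baseline$name)], n)
  })
  out <- tibble::as_tibble(stats::setNames(cols, baseline$name))
  attr(out, "frame") <- baseline$frame[1]
  attr(out, "set_id") <- baseline$set_id[1]
  out
}

#' Export an LHS design with its seed sidecar
#'
#' Writes the design matrix as CSV (header row of parameter names) and, when
#' jsonlite is available, a `<path>.json` sidecar recording the seed and
#' method.
#'
#' @param design `emt_lhs` tibble.
#' @param path CSV output path.
#' @return `design`, invisibly.
#' @export
export_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(seed = attr(design, "seed"), method = attr(design, "method"),
           n = nrow(design)),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(design)
}
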