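#' Range of a Betti curve
#'
#' The (min, max) of `beta_k` over the threshold sweep. For the minimum to
#' be the 0 that tissue-contrast ranges are quoted against, the threshold
#' grid must start below the first filtration value (as
#' [default_thresholds()] does).
#'
#' @param curve A `betti_curve`.
#' @return Named numeric vector `c(min = , max = )`.
#' @export
betti_range <- function(curve) {
  if (NROW(curve) == 0) {
    abort("empty Betti curve.", class = "fathom_input_error")
  }
  c(min = min(curve$betti), max = max(curve$betti))
}

#' Diagram-versus-diagonal statistics
#'
#' Summarises how far the finite dim-`k` points of a persistence diagram sit
#' from the diagonal: persistence is `death - birth` and the L-infinity
#' distance of a point to the diagonal is half its persistence. Small values
#' mean "many short-lived features", the signature the fat group shows.
#' Essential (infinite) intervals are excluded.
#'
#' @param diagram A `persistence_diagram`.
#' @param k Homology dimension.
#' @return One-row tibble with `mean_persistence`,
#'   `median_diagonal_distance` and `n_intervals`; all-`NA` statistics (with
#'   `n_intervals = 0`) when no finite dim-`k` interval exists.
#' @export
diagonal_stats <- function(diagram, k = 1) {
  d <- diagram[diagram$dim == k & is.finite(diagram$death), , drop = FALSE]
  if (nrow(d) == 0) {
    return(tibble::tibble(mean_persistence = NA_real_,
                          median_diagonal_distance = NA_real_,
                          n_intervals = 0L))
  }
  pers <- d$death - d$birth
  tibble::tibble(mean_persistence = mean(pers),
                 median_diagonal_distance = median(pers / 2),
                 n_intervals = nrow(d))
}

#' Per-group topological summary
#'
#' Combines the Betti-curve range and the diagram-diagonal statistics of
#' one tissue group into a single summary row. When a group contributes
#' several diagrams/curves (one per subject), pass them as lists: the Betti
#' range is aggregated as the min of minima and max of maxima over subjects,
#' and the diagonal statistics are computed on the pooled intervals.
#'
#' @param label Group label.
#' @param curves A `betti_curve` or list of them.
#' @param diagrams A `persistence_diagram` or list of them.
#' @param diag_dim Dimension for the diagonal statistics (default 1, loops).
#' @return One-row tibble (a `GroupSummary`).
#' @export
group_summary <- function(label, curves, diagrams, diag_dim = 1) {
  if (inherits(curves, "betti_curve")) curves <- list(curves)
  if (inherits(diagrams, "persistence_diagram")) diagrams <- list(diagrams)
  ranges <- vapply(curves, betti_range, numeric(2))
  pooled <- dplyr::bind_rows(lapply(diagrams, tibble::as_tibble))
  stats <- diagonal_stats(pooled, k = diag_dim)
  tibble::tibble(group = label,
                 betti_min = as.integer(min(ranges["min", ])),
                 betti_max = as.integer(max(ranges["max", ])),
                 mean_persistence = stats$mean_persistence,
                 median_diagonal_distance = stats$median_diagonal_distance,
                 n_intervals = stats$n_intervals)
}

#' Contrast the topological summaries of two tissue groups
#'
#' Builds the descriptive comparison the analysis reports: each group's
#' Betti range, which group's range is wider, the difference in maximum
#' Betti number, and the ordering of the diagram-diagonal statistics. No
#' hypothesis test is performed; the contrast is descriptive.
#'
#' @param summaries A tibble with exactly two rows as produced by
#'   [group_summary()] (or a list of two one-row tibbles).
#' @return A `topo_comparison` object; see [tidy.topo_comparison()].
#' @examples
#' a <- tibble::tibble(group = "fat", betti_min = 0L, betti_max = 30L,
#'                     mean_persistence = 1, median_diagonal_distance = 0.5,
#'                     n_intervals = 10L)
#' b <- tibble::tibble(group = "nonfat", betti_min = 0L, betti_max = 100L,
#'                     mean_persistence = 2, median_diagonal_distance = 1,
#'                     n_intervals = 20L)
#' compare_groups(dplyr::bind_rows(a, b))
#' @export
compare_groups <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- dplyr::bind_rows(summaries)
  }
  if (nrow(summaries) != 2) {
    abort("compare_groups needs exactly two group summaries.",
          class = "fathom_usage_error")
  }
  ordering <- function(metric) {
    v <- summaries[[metric]]
    if (any(is.na(v))) return(NA_character_)
    if (v[1] == v[2]) return("equal")
    smaller <- which.min(v)
    paste(summaries$group[smaller], "<", summaries$group[3 - smaller])
  }
  contrasts <- tibble::tibble(
    metric = c("betti_max", "median_diagonal_distance"),
    ordering = c(ordering("betti_max"), ordering("median_diagonal_distance")),
    difference = c(abs(diff(summaries$betti_max)),
                   abs(diff(summaries$median_diagonal_distance)))
  )
  structure(list(groups = summaries, contrasts = contrasts),
            class = "topo_comparison")
}

#' @export
print.topo_comparison <- function(x, ...) {
  cat("<topo_comparison>\n\nPer-group summaries:\n")
  print(x$groups)
  cat("\nContrasts:\n")
  print(x$contrasts)
  invisible(x)
}

#' Tidy methods for group comparisons
#'
#' `tidy()` returns the contrast table (one row per compared metric);
#' `glance()` returns a one-row overview with the Betti ranges and
#' orderings.
#'
#' @param x A `topo_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.topo_comparison <- function(x, ...) {
  x$contrasts
}

#' @rdname tidy.topo_comparison
#' @export
#' @exportS3Method generics::glance
glance.topo_comparison <- function(x, ...) {
  g <- x$groups
  tibble::tibble(
    group_1 = g$group[1], group_2 = g$group[2],
    betti_range_1 = sprintf("%d-%d", g$betti_min[1], g$betti_max[1]),
    betti_range_2 = sprintf("%d-%d", g$betti_min[2], g$betti_max[2]),
    betti_max_difference = abs(diff(g$betti_max)),
    betti_ordering = x$contrasts$ordering[x$contrasts$metric == "betti_max"],
    diagonal_ordering =
      x$contrasts$ordering[x$contrasts$metric == "median_diagonal_distance"]
  )
}

#' Serialise a comparison report
#'
#' @param x A `topo_comparison`.
#' @param path Output path for the JSON report.
#' @export
write_comparison_json <- function(x, path) {
  jsonlite::write_json(list(groups = x$groups, contrasts = x$contrasts),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-group Betti curves as CSV
#'
#' Columns `threshold`, `beta0`, `beta1` (either may be absent if only one
#' dimension was computed).
#'
#' @param curves Named list of `betti_curve` objects keyed by `beta0`,
#'   `beta1`.
#' @param path Output path.
#' @export
write_betti_csv <- function(curves, path) {
  stopifnot(length(curves) >= 1)
  out <- tibble::tibble(threshold = curves[[1]]$threshold)
  for (nm in names(curves)) out[[nm]] <- curves[[nm]]$betti
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
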