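#' Persistent homology of a filtered complex
#'
#' Computes the persistence pairing of the complex by the standard
#' boundary-matrix column reduction over the two-element field GF(2): cells
#' are processed in filtration order, each column is reduced by earlier
#' columns sharing its lowest nonzero row, and a column whose reduced low is
#' row `i` pairs cell `i` (birth) with the current cell (death). Unpaired
#' birth cells yield essential intervals with death `+Inf`. Intervals are
#' reported for dimensions 0 (components) and 1 (loops), with births and
#' deaths in the original input units (any cubical value shift is undone).
#'
#' Zero-length intervals (birth equal to death) carry no topological
#' information and clutter diagrams, so they are dropped by default.
#'
#' @param fc A [filtered_complex].
#' @param keep_zero Keep zero-persistence intervals?
#' @param source_label Optional label stored on the diagram.
#' @param validate Run [validate_filtered_complex()] first (default TRUE).
#' @return A `persistence_diagram`: a tibble with columns `dim`, `birth`,
#'   `death`.
#' @examples
#' fc <- vietoris_rips(make_fixture("grid"), eps_max = 2)
#' persistence(fc)  # one loop born at 1, filled at sqrt(2)
#' @export
persistence <- function(fc, keep_zero = FALSE, source_label = NULL,
                        validate = TRUE) {
  if (validate) validate_filtered_complex(fc)
  cells <- fc$cells
  n <- nrow(cells)
  pos_of_id <- integer(max(cells$id))
  pos_of_id[cells$id] <- seq_len(n)
  entries <- pos_of_id[fc$boundary$ids] - 1L
  offsets <- c(0L, cumsum(fc$boundary$lengths))
  pair <- reduce_boundary_cpp(as.integer(offsets), as.integer(entries),
                              as.integer(cells$dim))

  negative <- pair >= 0L
  killer_of <- integer(n)                      # 0 = essential
  killer_of[pair[negative] + 1L] <- which(negative)
  positive <- which(!negative)

  shift <- attr(fc, "value_shift")
  dims <- cells$dim[positive]
  birth <- cells$value[positive] - shift
  death <- ifelse(killer_of[positive] > 0L,
                  cells$value[pmax(killer_of[positive], 1L)] - shift, Inf)
  keep <- dims <= 1L
  if (!keep_zero) keep <- keep & (death > birth)

  out <- tibble::tibble(dim = dims[keep], birth = birth[keep],
                        death = death[keep]) |>
    dplyr::arrange(.data$dim, .data$birth, .data$death)
  structure(out,
            class = c("persistence_diagram", class(tibble::tibble())),
            source_label = source_label,
            backend = attr(fc, "backend"))
}

#' @export
print.persistence_diagram <- function(x, ...) {
  lbl <- attr(x, "source_label")
  cat(sprintf("<persistence_diagram>%s %d interval(s): %d in dim 0, %d in dim 1\n",
              if (is.null(lbl)) "" else paste0(" [", lbl, "]"),
              nrow(x), sum(x$dim == 0), sum(x$dim == 1)))
  NextMethod()
}

# ---- brute-force oracles --------------------------------------------------

# GF(2) rank by Gaussian elimination on a logical matrix. Small inputs only:
# this is the independent oracle route, not the production path.
gf2_rank <- function(m) {
  if (length(m) == 0 || nrow(m) == 0 || ncol(m) == 0) return(0L)
  m <- m != 0
  rank <- 0L
  for (j in seq_len(ncol(m))) {
    pivots <- which(m[, j])
    pivots <- pivots[pivots > rank]
    if (!length(pivots)) next
    rank <- rank + 1L
    piv <- pivots[1]
    if (piv != rank) m[c(rank, piv), ] <- m[c(piv, rank), ]
    hit <- which(m[, j])
    hit <- hit[hit != rank]
    if (length(hit)) m[hit, ] <- xor(m[hit, , drop = FALSE],
                                     matrix(m[rank, ], length(hit),
                                            ncol(m), byrow = TRUE))
  }
  rank
}

uf_components <- function(n_vertices, edge_a, edge_b) {
  parent <- seq_len(n_vertices)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(edge_a)) {
    ra <- find(edge_a[e]); rb <- find(edge_b[e])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n_vertices), find, integer(1))))
}

#' Betti number of a sublevel complex, by direct computation
#'
#' An oracle independent of the reduction algorithm: it computes the k-th
#' Betti number of the subcomplex of cells with filtration value at most `t`
#' (in original input units) from first principles. Components (`k = 0`) are
#' counted by union-find over the vertices and edges present. Loops
#' (`k = 1`) are counted either through the planar Euler characteristic
#' (`beta1 = beta0 - V + E - F`, exact for the cubical V-construction) or by
#' GF(2) ranks of the boundary matrices
#' (`beta1 = E - rank d1 - rank d2`), which applies to any complex. The
#' rank route is quadratic and meant for small validation inputs.
#'
#' @param fc A [filtered_complex].
#' @param k Homology dimension, 0 or 1.
#' @param t Threshold in original input units.
#' @param method `"auto"` (Euler for cubical, rank for Rips), `"euler"` or
#'   `"rank"`.
#' @return A nonnegative integer.
#' @export
betti_at <- function(fc, k, t, method = c("auto", "euler", "rank")) {
  method <- match.arg(method)
  if (!k %in% c(0, 1)) {
    abort("betti_at supports k = 0 or 1.", class = "fathom_usage_error")
  }
  cells <- fc$cells
  tt <- t + attr(fc, "value_shift")
  sub <- cells$value <= tt

  pos_of_id <- integer(max(cells$id))
  pos_of_id[cells$id] <- seq_len(nrow(cells))
  bnd <- boundary_list(fc)

  vpos <- which(sub & cells$dim == 0L)
  epos <- which(sub & cells$dim == 1L)
  fpos <- which(sub & cells$dim == 2L)

  vindex <- integer(nrow(cells))
  vindex[vpos] <- seq_along(vpos)
  ea <- vapply(bnd[epos], function(b) vindex[pos_of_id[b[1]]], integer(1))
  eb <- vapply(bnd[epos], function(b) vindex[pos_of_id[b[2]]], integer(1))
  b0 <- if (length(vpos)) uf_components(length(vpos), ea, eb) else 0L
  if (k == 0) return(b0)

  if (method == "auto") {
    method <- if (attr(fc, "backend") == "cubical") "euler" else "rank"
  }
  if (method == "euler") {
    chi <- length(vpos) - length(epos) + length(fpos)
    return(b0 - chi)
  }
  eindex <- integer(nrow(cells))
  eindex[epos] <- seq_along(epos)
  d2 <- matrix(FALSE, length(epos), length(fpos))
  for (fi in seq_along(fpos)) {
    d2[eindex[pos_of_id[bnd[[fpos[fi]]]]], fi] <- TRUE
  }
  d1 <- matrix(FALSE, length(vpos), length(epos))
  if (length(epos)) d1[cbind(c(ea, eb), c(seq_along(epos), seq_along(epos)))] <- TRUE
  length(epos) - gf2_rank(t(d1)) - gf2_rank(t(d2))
}

#' Betti curve from a persistence diagram
#'
#' Evaluates `beta_k(t)`, the number of dim-`k` intervals alive at `t` under
#' the half-open convention `birth <= t < death`, on a grid of thresholds.
#'
#' @param diagram A `persistence_diagram`.
#' @param k Homology dimension.
#' @param thresholds Strictly increasing numeric vector (see
#'   [default_thresholds()]).
#' @return A `betti_curve`: a tibble with columns `threshold` and `betti`.
#' @export
betti_curve <- function(diagram, k, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("thresholds must be strictly increasing.",
          class = "fathom_input_error")
  }
  d <- diagram[diagram$dim == k, , drop = FALSE]
  # alive at t (birth <= t < death) = births up to t minus deaths up to t
  births <- sort(d$birth)
  deaths <- sort(d$death[is.finite(d$death)])
  betti <- findInterval(thresholds, births) - findInterval(thresholds, deaths)
  structure(tibble::tibble(threshold = thresholds, betti = as.integer(betti)),
            class = c("betti_curve", class(tibble::tibble())),
            k = k)
}

#' Exact bottleneck distance between two persistence diagrams
#'
#' The bottleneck distance is the min-max matching cost between the two
#' multisets of dim-`k` points, where a point may be matched to another
#' point at L-infinity cost or to its diagonal projection at cost
#' `(death - birth) / 2`. The exact optimum is found by binary search over
#' the sorted candidate costs with an augmenting-path perfect-matching
#' feasibility test; by the stability theorem it is bounded by the sup-norm
#' difference of the underlying filtrations.
#'
#' @param d1,d2 `persistence_diagram` objects.
#' @param k Homology dimension to compare.
#' @param cap Finite value replacing `+Inf` deaths; both diagrams must use
#'   the same cap. Defaults to the largest finite birth/death across both.
#' @return A nonnegative number.
#' @export
bottleneck_distance <- function(d1, d2, k = 0, cap = NULL) {
  get_pts <- function(d) {
    p <- d[d$dim == k, c("birth", "death"), drop = FALSE]
    as.matrix(p)
  }
  p1 <- get_pts(d1); p2 <- get_pts(d2)
  if (is.null(cap)) {
    finite <- c(p1[is.finite(p1)], p2[is.finite(p2)])
    cap <- if (length(finite)) max(finite) else 0
  }
  p1[!is.finite(p1)] <- cap
  p2[!is.finite(p2)] <- cap
  p1 <- p1[p1[, 2] > p1[, 1], , drop = FALSE]
  p2 <- p2[p2[, 2] > p2[, 1], , drop = FALSE]
  n1 <- nrow(p1); n2 <- nrow(p2)
  if (n1 > 500 || n2 > 500) {
    abort("bottleneck_distance is limited to 500 off-diagonal points per diagram; use a dedicated TDA tool for larger diagrams.",
          class = "fathom_size_error")
  }
  m <- n1 + n2
  if (m == 0) return(0)
  diag1 <- (p1[, 2] - p1[, 1]) / 2
  diag2 <- (p2[, 2] - p2[, 1]) / 2
  cost <- matrix(0, m, m)
  if (n1 && n2) {
    cost[seq_len(n1), seq_len(n2)] <-
      outer(seq_len(n1), seq_len(n2), function(i, j) {
        pmax(abs(p1[i, 1] - p2[j, 1]), abs(p1[i, 2] - p2[j, 2]))
      })
  }
  if (n1) cost[seq_len(n1), n2 + seq_len(n1)] <-
      matrix(diag1, n1, n1)         # d1 points to diagonal
  if (n2) cost[n1 + seq_len(n2), seq_len(n2)] <-
      matrix(diag2, n2, n2, byrow = TRUE)  # diagonal to d2 points
  bottleneck_cpp(cost)
}

# ---- diagram I/O ----------------------------------------------------------

#' Read / write persistence diagrams as TSV
#'
#' Columns `dim`, `birth`, `death`; essential deaths are written as `"inf"`.
#'
#' @param diagram A `persistence_diagram`.
#' @param path File path.
#' @return `read_diagram_tsv()` returns a `persistence_diagram`.
#' @export
write_diagram_tsv <- function(diagram, path) {
  lines <- c("dim\tbirth\tdeath",
             sprintf("%d\t%.12g\t%s", diagram$dim, diagram$birth,
                     ifelse(is.finite(diagram$death),
                            sprintf("%.12g", diagram$death), "inf")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_diagram_tsv
#' @export
read_diagram_tsv <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  death <- ifelse(raw$death == "inf", Inf, suppressWarnings(as.numeric(raw$death)))
  structure(tibble::tibble(dim = as.integer(raw$dim),
                           birth = as.numeric(raw$birth),
                           death = death),
            class = c("persistence_diagram", class(tibble::tibble())))
}
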