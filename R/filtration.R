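#' @title Filtered complexes
#' @description
#' A `filtered_complex` holds the cells of a filtration: a tibble `cells`
#' with columns `id` (stable integer), `dim` (0, 1 or 2) and `value` (the
#' filtration value at which the cell enters), sorted by
#' `(value, dim, id)` so that no cell precedes any of its boundary cells,
#' plus a flat boundary structure (`boundary$lengths`, `boundary$ids`)
#' giving, per cell in sorted order, the ids of its codimension-1 faces.
#'
#' Filtration values are stored nonnegative: when a cubical complex is built
#' from a patch with negative HU values the whole patch is shifted so its
#' minimum maps to 0, and the shift is recorded in the `value_shift`
#' attribute. All user-facing threshold arguments ([betti_at()],
#' [critical_values()], Betti curves) are expressed in the original input
#' units; the shift is handled internally.
#' @name filtered_complex
NULL

new_filtered_complex <- function(id, dim, value, boundary_lengths,
                                 boundary_ids, backend,
                                 eps_max = Inf, value_shift = 0) {
  ord <- order(value, dim, id)
  starts <- cumsum(boundary_lengths) - boundary_lengths + 1L
  flat <- if (length(boundary_ids)) {
    boundary_ids[sequence(boundary_lengths[ord], from = starts[ord])]
  } else {
    integer(0)
  }
  structure(
    list(
      cells = tibble::tibble(id = id[ord], dim = dim[ord], value = value[ord]),
      boundary = list(lengths = boundary_lengths[ord], ids = flat)
    ),
    backend = backend, eps_max = eps_max, value_shift = value_shift,
    class = "filtered_complex"
  )
}

#' Materialise the boundary of each cell as a list of id vectors
#' @param fc A `filtered_complex`.
#' @return A list, aligned with `fc$cells`, of integer id vectors.
#' @export
boundary_list <- function(fc) {
  f <- rep.int(seq_along(fc$boundary$lengths), fc$boundary$lengths)
  out <- vector("list", nrow(fc$cells))
  if (length(fc$boundary$ids)) {
    grp <- split(fc$boundary$ids, f)
    out[as.integer(names(grp))] <- grp
  }
  out
}

#' Validate a filtered complex
#'
#' Checks boundary closure (every face id present), the face counts per
#' dimension (vertices none, edges two vertices, 2-cells three or four
#' edges), and filtration monotonicity (no cell enters before a face).
#'
#' @param fc A `filtered_complex`.
#' @return `fc`, invisibly; errors with class `fathom_invariant_error` on
#'   violation.
#' @export
validate_filtered_complex <- function(fc) {
  cells <- fc$cells
  pos_of_id <- integer(max(cells$id))
  pos_of_id[cells$id] <- seq_len(nrow(cells))
  ids <- fc$boundary$ids
  if (length(ids) && (any(ids < 1L) || any(ids > length(pos_of_id)) ||
                      any(pos_of_id[ids] == 0L))) {
    abort("complex not closed under boundary: unknown face id.",
          class = "fathom_invariant_error")
  }
  expected <- c(`0` = 0L, `1` = 2L)
  lens <- fc$boundary$lengths
  if (any(lens[cells$dim == 0L] != 0L) || any(lens[cells$dim == 1L] != 2L) ||
      any(!lens[cells$dim == 2L] %in% c(3L, 4L))) {
    abort("boundary cardinality does not match cell dimension.",
          class = "fathom_invariant_error")
  }
  if (length(ids)) {
    owner <- rep.int(seq_len(nrow(cells)), lens)
    if (any(cells$value[pos_of_id[ids]] > cells$value[owner])) {
      abort("filtration not monotone: a cell enters before one of its faces.",
            class = "fathom_invariant_error")
    }
    if (any(cells$dim[pos_of_id[ids]] != cells$dim[owner] - 1L)) {
      abort("boundary cells must have dimension one less than their coface.",
            class = "fathom_invariant_error")
    }
  }
  invisible(fc)
}

#' @export
print.filtered_complex <- function(x, ...) {
  tab <- table(factor(x$cells$dim, levels = 0:2))
  cat(sprintf(
    "<filtered_complex> backend=%s  %d cells (%d vertices, %d edges, %d 2-cells)\n",
    attr(x, "backend"), nrow(x$cells), tab[1], tab[2], tab[3]))
  cat(sprintf("  filtration range [%g, %g], value shift %g, eps_max %g\n",
              min(x$cells$value), max(x$cells$value),
              attr(x, "value_shift"), attr(x, "eps_max")))
  invisible(x)
}

#' Vietoris-Rips filtration of a planar point cloud
#'
#' Every point is a vertex at scale 0; an edge appears at the Euclidean
#' distance between its endpoints (pairs further apart than `eps_max` are
#' never connected); a triangle appears at the maximum of its three edge
#' scales (flag/clique convention). The filtration is indexed by
#' **diameter**: growing a ball of radius eps around each point connects two
#' points once their distance is `2 * eps`, so one unit of this filtration
#' axis equals one unit of inter-point distance (half-scale users should
#' divide by two).
#'
#' @param cloud A point-cloud data frame with columns `x`, `y`.
#' @param eps_max Truncation diameter; pairs beyond it are never joined.
#'   Defaults to 10 px, which bounds the quadratic edge set for clouds
#'   derived from masked image patches.
#' @param max_dim Highest cell dimension (2 = triangles, needed for H1).
#' @return A [filtered_complex].
#' @export
vietoris_rips <- function(cloud, eps_max = 10, max_dim = 2L) {
  if (!is.finite(eps_max) && !identical(eps_max, Inf)) {
    abort("eps_max must be positive.", class = "fathom_config_error")
  }
  if (eps_max <= 0) {
    abort("eps_max must be positive.", class = "fathom_config_error")
  }
  pts <- as_point_cloud(cloud)
  n <- nrow(pts)
  if (n == 0) {
    abort("cannot build a Rips complex from an empty cloud.",
          class = "fathom_input_error")
  }
  if (n > 5000) {
    abort(paste0("Rips construction is limited to 5000 points (got ", n,
                 "); use the cubical backend for dense image data."),
          class = "fathom_size_error")
  }
  D <- as.matrix(dist(cbind(pts$x, pts$y)))

  id <- seq_len(n)
  dim <- rep(0L, n)
  value <- rep(0, n)
  lens <- rep(0L, n)
  flat <- integer(0)

  ut <- which(upper.tri(D) & D <= eps_max, arr.ind = TRUE)
  if (nrow(ut)) {
    ei <- pmin(ut[, 1], ut[, 2])
    ej <- pmax(ut[, 1], ut[, 2])
    ev <- D[ut]
    eid <- n + seq_along(ei)
    id <- c(id, eid)
    dim <- c(dim, rep(1L, length(ei)))
    value <- c(value, ev)
    lens <- c(lens, rep(2L, length(ei)))
    flat <- c(flat, as.integer(rbind(ei, ej)))

    if (max_dim >= 2L) {
      ekey <- (ei - 1) * n + ej
      nb <- lapply(seq_len(n), function(v) {
        w <- which(D[v, ] <= eps_max)
        w[w > v]
      })
      ti <- tj <- tk <- integer(0)
      for (e in seq_along(ei)) {
        ks <- intersect(nb[[ei[e]]], nb[[ej[e]]])
        ks <- ks[ks > ej[e]]
        if (length(ks)) {
          ti <- c(ti, rep(ei[e], length(ks)))
          tj <- c(tj, rep(ej[e], length(ks)))
          tk <- c(tk, ks)
        }
      }
      if (length(ti)) {
        tv <- pmax(D[cbind(ti, tj)], D[cbind(ti, tk)], D[cbind(tj, tk)])
        e1 <- eid[match((ti - 1) * n + tj, ekey)]
        e2 <- eid[match((ti - 1) * n + tk, ekey)]
        e3 <- eid[match((tj - 1) * n + tk, ekey)]
        tid <- n + length(ei) + seq_along(ti)
        id <- c(id, tid)
        dim <- c(dim, rep(2L, length(ti)))
        value <- c(value, tv)
        lens <- c(lens, rep(3L, length(ti)))
        flat <- c(flat, as.integer(rbind(e1, e2, e3)))
      }
    }
  }
  new_filtered_complex(id, dim, value, lens, flat,
                       backend = "rips", eps_max = eps_max)
}

#' Lower-star cubical sublevel-set filtration of a grayscale patch
#'
#' Vertex-based (V-construction) cubical complex with 4-adjacency: one
#' vertex per pixel at its HU value, one edge per 4-adjacent pixel pair at
#' the maximum of its endpoints, one square per 2x2 pixel block at the
#' maximum of its four corners. Sweeping the threshold upward then
#' reproduces, as sublevel sets, the image thresholding sweep. When the
#' patch contains negative values the stored filtration values are shifted
#' so the minimum maps to 0; the shift is recorded and undone in all
#' user-facing thresholds.
#'
#' @param patch A numeric matrix (HU values).
#' @return A [filtered_complex].
#' @export
lower_star_cubical <- function(patch) {
  validate_patch(patch)
  r <- nrow(patch)
  c <- ncol(patch)
  shift <- max(0, -min(patch))
  v <- as.vector(patch) + shift  # column-major: pixel (i,j) -> (j-1)*r + i

  n_v <- r * c
  n_ev <- (r - 1L) * c        # vertical edges
  n_eh <- r * (c - 1L)        # horizontal edges
  n_sq <- (r - 1L) * (c - 1L)

  vid <- function(i, j) (j - 1L) * r + i
  ev_id <- function(i, j) n_v + (j - 1L) * (r - 1L) + i
  eh_id <- function(i, j) n_v + n_ev + (j - 1L) * r + i

  # vertical edges (i,j)-(i+1,j)
  iv <- rep(seq_len(r - 1L), times = c)
  jv <- rep(seq_len(c), each = r - 1L)
  av <- vid(iv, jv); bv <- av + 1L

  # horizontal edges (i,j)-(i,j+1)
  ih <- rep(seq_len(r), times = c - 1L)
  jh <- rep(seq_len(c - 1L), each = r)
  ah <- vid(ih, jh); bh <- ah + r

  # squares with top-left pixel (i,j)
  is <- rep(seq_len(r - 1L), times = c - 1L)
  js <- rep(seq_len(c - 1L), each = r - 1L)
  sa <- vid(is, js)
  sq_val <- pmax(v[sa], v[sa + 1L], v[sa + r], v[sa + r + 1L])
  s1 <- ev_id(is, js)        # left vertical
  s2 <- ev_id(is, js + 1L)   # right vertical
  s3 <- eh_id(is, js)        # top horizontal
  s4 <- eh_id(is + 1L, js)   # bottom horizontal

  id <- c(seq_len(n_v),
          n_v + seq_len(n_ev + n_eh),
          n_v + n_ev + n_eh + seq_len(n_sq))
  dim <- c(rep(0L, n_v), rep(1L, n_ev + n_eh), rep(2L, n_sq))
  value <- c(v, pmax(v[av], v[bv]), pmax(v[ah], v[bh]), sq_val)
  lens <- c(rep(0L, n_v), rep(2L, n_ev + n_eh), rep(4L, n_sq))
  flat <- c(as.integer(rbind(av, bv)), as.integer(rbind(ah, bh)),
            as.integer(rbind(s1, s2, s3, s4)))

  new_filtered_complex(id, dim, value, lens, flat,
                       backend = "cubical", eps_max = Inf, value_shift = shift)
}

#' Critical filtration values of a complex, in original input units
#'
#' @param fc A [filtered_complex].
#' @return Sorted distinct filtration values (HU for cubical complexes,
#'   distances for Rips complexes).
#' @export
critical_values <- function(fc) {
  sort(unique(fc$cells$value)) - attr(fc, "value_shift")
}

#' Default threshold grid for Betti curves
#'
#' All critical values of the complex plus one value below the minimum, so
#' the curve attains 0 before the first cell is born.
#'
#' @param fc A [filtered_complex].
#' @return A strictly increasing numeric vector.
#' @export
default_thresholds <- function(fc) {
  crit <- critical_values(fc)
  c(crit[1] - 1, crit)
}

#' Serialise a filtered complex to TSV
#'
#' Columns `id`, `dim`, `filtration_value` (stored, i.e. shifted, units) and
#' `boundary_ids` (semicolon-joined face ids).
#'
#' @param fc A [filtered_complex].
#' @param path Output file path.
#' @export
write_complex_tsv <- function(fc, path) {
  bnd <- boundary_list(fc)
  out <- fc$cells |>
    dplyr::mutate(
      filtration_value = .data$value,
      boundary_ids = vapply(bnd, paste, character(1), collapse = ";")
    ) |>
    dplyr::select("id", "dim", "filtration_value", "boundary_ids")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
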