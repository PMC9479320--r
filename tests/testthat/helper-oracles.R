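# Shared helpers: hand-built complexes, random inputs, ad-hoc diagrams.

# Build a filtered complex directly from vertex/edge/triangle specs.
# vertices: numeric vector of filtration values (ids 1..n).
# edges: list of list(c(a, b), value); cells get consecutive ids.
make_path_complex <- function(vertex_values, edges = list()) {
  n <- length(vertex_values)
  id <- seq_len(n)
  dim <- rep(0L, n)
  value <- vertex_values
  lens <- rep(0L, n)
  flat <- integer(0)
  for (e in edges) {
    id <- c(id, length(id) + 1L)
    dim <- c(dim, 1L)
    value <- c(value, e$value)
    lens <- c(lens, 2L)
    flat <- c(flat, e$ends)
  }
  fathom:::new_filtered_complex(id, dim, value, lens, flat,
                                backend = "rips", eps_max = Inf)
}

make_diagram <- function(dim, birth, death) {
  structure(tibble::tibble(dim = as.integer(dim), birth = birth, death = death),
            class = c("persistence_diagram", class(tibble::tibble())))
}

random_cloud <- function(n, scale = 1) {
  tibble::tibble(x = stats::runif(n, 0, scale), y = stats::runif(n, 0, scale))
}

random_patch <- function(r, c, mean = 0, sd = 1) {
  matrix(stats::rnorm(r * c, mean, sd), r, c)
}

# Thresholds probing a complex: every critical value plus midpoints between
# consecutive critical values, plus one value below the minimum.
probe_thresholds <- function(fc) {
  cv <- critical_values(fc)
  mids <- if (length(cv) > 1) (head(cv, -1) + tail(cv, -1)) / 2 else numeric(0)
  sort(unique(c(cv[1] - 1, cv, mids)))
}

# Number of connected components of the completed complex (all cells in).
final_components <- function(fc) {
  betti_at(fc, 0, max(critical_values(fc)))
}
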