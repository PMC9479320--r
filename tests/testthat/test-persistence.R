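test_that("a single merge produces the textbook two-interval diagram", {
  fc <- make_path_complex(c(0, 5), edges = list(list(ends = c(1L, 2L),
                                                     value = 7)))
  dg <- persistence(fc)
  expect_equal(dg$dim, c(0L, 0L))
  expect_equal(dg$birth, c(0, 5))
  expect_equal(dg$death, c(Inf, 7))
  expect_equal(betti_at(fc, 0, 6), 2)
  expect_equal(betti_curve(dg, 0, c(6, 7))$betti, c(2L, 1L))
})

test_that("the unit-square Rips diagram is exact to machine precision", {
  fc <- vietoris_rips(make_fixture("grid"), eps_max = 2)
  dg <- persistence(fc)
  d1 <- dg[dg$dim == 1, ]
  expect_equal(nrow(d1), 1)
  expect_identical(d1$birth, 1)
  expect_identical(d1$death, sqrt(2))
  d0 <- dg[dg$dim == 0, ]
  expect_equal(sum(is.infinite(d0$death)), 1)
  expect_equal(d0$death[is.finite(d0$death)], rep(1, 3))
  # independent rank oracle at a point inside the loop's lifetime
  expect_equal(betti_at(fc, 0, 1.2, method = "rank"), 1)
  expect_equal(betti_at(fc, 1, 1.2, method = "rank"), 1)
})

test_that("the 20-point circle has exactly one prominent loop", {
  fc <- vietoris_rips(make_fixture("circle"), eps_max = 2.1)
  dg <- persistence(fc)
  loops <- dg[dg$dim == 1, ]
  prominent <- loops[loops$death - loops$birth > 1, ]
  expect_equal(nrow(prominent), 1)
  expect_equal(prominent$birth, 2 * sin(pi / 20), tolerance = 1e-12)
  # rank oracle brackets the loop's lifetime
  expect_equal(betti_at(fc, 1, 0.5, method = "rank"), 1)
  expect_equal(betti_at(fc, 1, 2.05, method = "rank"), 0)
})

test_that("reduction agrees with the brute-force oracles on random inputs", {
  set.seed(5)
  for (i in 1:6) {
    fc <- vietoris_rips(random_cloud(8), eps_max = 2)
    dg <- persistence(fc)
    for (t in probe_thresholds(fc)) {
      expect_equal(betti_curve(dg, 0, t)$betti, betti_at(fc, 0, t))
      expect_equal(betti_curve(dg, 1, t)$betti,
                   betti_at(fc, 1, t, method = "rank"))
    }
  }
  for (i in 1:6) {
    fc <- lower_star_cubical(random_patch(5, 5))
    dg <- persistence(fc)
    for (t in probe_thresholds(fc)) {
      expect_equal(betti_curve(dg, 0, t)$betti, betti_at(fc, 0, t))
      expect_equal(betti_curve(dg, 1, t)$betti, betti_at(fc, 1, t))
    }
  }
})

test_that("interval counts are conserved and essentials match components", {
  set.seed(6)
  cases <- list(vietoris_rips(random_cloud(9), eps_max = 0.7),
                lower_star_cubical(random_patch(6, 6)))
  for (fc in cases) {
    dg <- persistence(fc, keep_zero = TRUE)
    nv <- sum(fc$cells$dim == 0)
    ne <- sum(fc$cells$dim == 1)
    ess0 <- sum(dg$dim == 0 & is.infinite(dg$death))
    # every vertex births a component
    expect_equal(sum(dg$dim == 0), nv)
    # edges split into component-killers and loop-births
    expect_equal(sum(dg$dim == 1), ne - (nv - ess0))
    # one essential dim-0 interval per final component, by union-find
    expect_equal(ess0, final_components(fc))
  }
  # planar cubical sublevel complexes never carry essential loops
  dg_cub <- persistence(cases[[2]])
  expect_equal(sum(dg_cub$dim == 1 & is.infinite(dg_cub$death)), 0)
})

test_that("zero-persistence intervals are excluded unless requested", {
  # two vertices joined at the same value they are born: pure zero interval
  fc <- make_path_complex(c(0, 1), edges = list(list(ends = c(1L, 2L),
                                                     value = 1)))
  expect_equal(nrow(persistence(fc)), 1)  # essential only
  dg_all <- persistence(fc, keep_zero = TRUE)
  expect_equal(nrow(dg_all), 2)
  expect_true(any(dg_all$birth == dg_all$death))
})

test_that("dim-0 Rips Betti curves never increase after all vertices appear", {
  set.seed(7)
  fc <- vietoris_rips(random_cloud(12), eps_max = 2)
  dg <- persistence(fc)
  curve <- betti_curve(dg, 0, probe_thresholds(fc))
  after <- curve$betti[curve$threshold >= 0]
  expect_true(all(diff(after) <= 0))
})

test_that("betti inputs are validated", {
  fc <- lower_star_cubical(matrix(1:4, 2, 2))
  expect_error(betti_at(fc, 2, 1), class = "fathom_usage_error")
  dg <- persistence(fc)
  expect_error(betti_curve(dg, 0, c(2, 1)), class = "fathom_input_error")
})

test_that("bottleneck distances match hand-enumerated matchings", {
  d13 <- make_diagram(1, 1, 3)
  empty <- make_diagram(integer(0), numeric(0), numeric(0))
  expect_equal(bottleneck_distance(d13, d13, k = 1), 0)
  # single point vs empty: forced diagonal match at persistence/2
  expect_equal(bottleneck_distance(d13, empty, k = 1), 1)
  expect_equal(bottleneck_distance(make_diagram(0, 0, 2),
                                   make_diagram(0, 0, 2.5), k = 0), 0.5)
  # matching beats the diagonal when points are close
  expect_equal(bottleneck_distance(make_diagram(c(0, 0), c(0, 5), c(4, 9)),
                                   make_diagram(0, 0, 4), k = 0), 2)
})

test_that("cubical diagrams are stable under sup-norm perturbations", {
  set.seed(8)
  patch <- random_patch(8, 8, sd = 10)
  d0 <- persistence(lower_star_cubical(patch))
  for (delta in c(0.5, 2)) {
    noisy <- patch + matrix(stats::runif(64, -delta, delta), 8, 8)
    d1 <- persistence(lower_star_cubical(noisy))
    cap <- max(patch, noisy)
    expect_lte(bottleneck_distance(d0, d1, k = 0, cap = cap), delta + 1e-12)
    expect_lte(bottleneck_distance(d0, d1, k = 1, cap = cap), delta + 1e-12)
  }
})

test_that("diagrams round-trip through TSV including essential intervals", {
  dir <- withr::local_tempdir()
  fc <- vietoris_rips(make_fixture("two_clusters"), eps_max = 12)
  dg <- persistence(fc)
  path <- file.path(dir, "diagram.tsv")
  write_diagram_tsv(dg, path)
  back <- read_diagram_tsv(path)
  expect_equal(back$dim, dg$dim)
  expect_equal(back$birth, dg$birth, tolerance = 1e-10)
  expect_equal(back$death, dg$death, tolerance = 1e-10)
  expect_true(any(grepl("\tinf$", readLines(path))))
})
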