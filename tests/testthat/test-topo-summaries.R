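test_that("betti_range reports the curve's extremes", {
  curve <- structure(tibble::tibble(threshold = 1:5,
                                    betti = c(0L, 1L, 2L, 2L, 1L)),
                     class = c("betti_curve", class(tibble::tibble())))
  expect_equal(betti_range(curve), c(min = 0, max = 2))
  const <- structure(tibble::tibble(threshold = 1:2, betti = c(3L, 3L)),
                     class = c("betti_curve", class(tibble::tibble())))
  expect_equal(betti_range(const), c(min = 3, max = 3))
  expect_error(betti_range(const[0, ]), class = "fathom_input_error")
})

test_that("betti_range is invariant under threshold-grid refinement", {
  set.seed(9)
  fc <- lower_star_cubical(random_patch(6, 6))
  dg <- persistence(fc)
  base <- default_thresholds(fc)
  refined <- sort(unique(c(base, base - 1e-9 + 2e-9, probe_thresholds(fc))))
  expect_equal(betti_range(betti_curve(dg, 0, base)),
               betti_range(betti_curve(dg, 0, refined)))
})

test_that("diagonal statistics follow the persistence arithmetic", {
  dg <- make_diagram(c(1, 1), c(1, 2), c(3, 2.5))
  s <- diagonal_stats(dg, k = 1)
  expect_equal(s$mean_persistence, 1.25)
  expect_equal(s$median_diagonal_distance, 0.625)

  single <- diagonal_stats(make_diagram(1, 0, 4), k = 1)
  expect_equal(single$mean_persistence, 4)
  expect_equal(single$median_diagonal_distance, 2)

  # essential intervals are excluded; none finite -> not-available signal
  ess <- diagonal_stats(make_diagram(1, 0, Inf), k = 1)
  expect_true(is.na(ess$mean_persistence))
  expect_equal(ess$n_intervals, 0L)
})

test_that("diagonal statistics scale linearly with the filtration", {
  set.seed(10)
  dg <- persistence(lower_star_cubical(random_patch(7, 7)))
  for (cc in c(2, 0.5)) {
    scaled <- make_diagram(dg$dim, cc * dg$birth, cc * dg$death)
    s1 <- diagonal_stats(dg, 1)
    s2 <- diagonal_stats(scaled, 1)
    expect_equal(s2$mean_persistence, cc * s1$mean_persistence)
    expect_equal(s2$median_diagonal_distance,
                 cc * s1$median_diagonal_distance)
  }
})

test_that("group comparison formats the fat-vs-nonfat contrast", {
  mk <- function(g, bmax, mdd) {
    tibble::tibble(group = g, betti_min = 0L, betti_max = as.integer(bmax),
                   mean_persistence = 1, median_diagonal_distance = mdd,
                   n_intervals = 5L)
  }
  cmp <- compare_groups(dplyr::bind_rows(mk("fat", 30, 0.5),
                                         mk("nonfat", 100, 1)))
  expect_s3_class(cmp, "topo_comparison")
  contrasts <- tidy(cmp)
  expect_equal(contrasts$ordering[contrasts$metric == "betti_max"],
               "fat < nonfat")
  expect_equal(contrasts$difference[contrasts$metric == "betti_max"], 70)
  g <- glance(cmp)
  expect_equal(g$betti_range_1, "0-30")
  expect_equal(g$betti_range_2, "0-100")

  same <- compare_groups(dplyr::bind_rows(mk("a", 10, 1), mk("b", 10, 1)))
  expect_equal(tidy(same)$ordering, c("equal", "equal"))
  expect_equal(tidy(same)$difference, c(0, 0))

  swapped <- compare_groups(dplyr::bind_rows(mk("nonfat", 100, 1),
                                             mk("fat", 30, 0.5)))
  expect_equal(tidy(swapped)$ordering, tidy(cmp)$ordering)
  expect_equal(tidy(swapped)$difference, tidy(cmp)$difference)

  expect_error(compare_groups(mk("solo", 1, 1)), class = "fathom_usage_error")
})

test_that("group summaries aggregate per-subject curves and pool diagrams", {
  set.seed(11)
  fcs <- list(lower_star_cubical(random_patch(6, 6)),
              lower_star_cubical(random_patch(6, 6)))
  dgs <- lapply(fcs, persistence)
  curves <- purrr::map2(dgs, fcs, ~ betti_curve(.x, 0, default_thresholds(.y)))
  s <- group_summary("g", curves, dgs)
  expect_equal(s$betti_max, max(vapply(curves, function(cv) max(cv$betti),
                                       numeric(1))))
  expect_equal(s$betti_min, 0L)
  pooled <- dplyr::bind_rows(lapply(dgs, tibble::as_tibble))
  expect_equal(s$n_intervals, diagonal_stats(pooled, 1)$n_intervals)
})

test_that("plot constructors return ggplot objects", {
  fc <- vietoris_rips(make_fixture("circle"), eps_max = 2.1)
  dg <- persistence(fc)
  expect_s3_class(autoplot(dg), "ggplot")
  expect_s3_class(plot_barcode(dg), "ggplot")
  expect_s3_class(autoplot(betti_curve(dg, 1, probe_thresholds(fc))), "ggplot")
})
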