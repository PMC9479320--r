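test_that("Rips complexes realise the diameter convention", {
  two <- tibble::tibble(x = c(0, 2), y = c(0, 0))
  fc <- vietoris_rips(two, eps_max = 5)
  expect_equal(fc$cells$dim, c(0L, 0L, 1L))
  expect_equal(fc$cells$value, c(0, 0, 2))

  sq <- vietoris_rips(make_fixture("grid"), eps_max = 2)
  vals <- sq$cells$value
  expect_equal(sum(sq$cells$dim == 1 & abs(vals - 1) < 1e-12), 4)
  expect_equal(sum(sq$cells$dim == 1 & abs(vals - sqrt(2)) < 1e-12), 2)
  expect_equal(sum(sq$cells$dim == 2), 4)
  expect_true(all(abs(vals[sq$cells$dim == 2] - sqrt(2)) < 1e-12))

  collinear <- tibble::tibble(x = c(0, 1, 2), y = 0)
  trunc <- vietoris_rips(collinear, eps_max = 0.5)
  expect_equal(nrow(trunc$cells), 3)
  expect_true(all(trunc$cells$dim == 0))

  expect_error(vietoris_rips(tibble::tibble(x = numeric(0), y = numeric(0)),
                             eps_max = 1), class = "fathom_input_error")
  expect_error(vietoris_rips(two, eps_max = -1), class = "fathom_config_error")
})

test_that("untruncated Rips complexes have all n(n-1)/2 edges", {
  set.seed(2)
  for (n in c(2, 5, 9)) {
    fc <- vietoris_rips(random_cloud(n), eps_max = 10, max_dim = 1)
    expect_equal(sum(fc$cells$dim == 1), n * (n - 1) / 2)
  }
})

test_that("cubical complexes follow the max-of-vertices lower-star rule", {
  fc <- lower_star_cubical(matrix(c(0, 1, 1, 2), 2, 2))
  expect_equal(sort(fc$cells$value[fc$cells$dim == 0]), c(0, 1, 1, 2))
  expect_equal(sort(fc$cells$value[fc$cells$dim == 1]), c(1, 1, 2, 2))
  expect_equal(fc$cells$value[fc$cells$dim == 2], 2)

  const <- lower_star_cubical(matrix(7, 3, 4))
  expect_equal(unique(const$cells$value), 7)
})

test_that("cubical cell counts and Euler characteristic match the formulas", {
  set.seed(3)
  for (sz in list(c(1, 1), c(1, 5), c(4, 7), c(8, 8))) {
    r <- sz[1]; c <- sz[2]
    fc <- lower_star_cubical(random_patch(r, c))
    nv <- sum(fc$cells$dim == 0)
    ne <- sum(fc$cells$dim == 1)
    nf <- sum(fc$cells$dim == 2)
    expect_equal(nv, r * c)
    expect_equal(ne, r * (c - 1) + c * (r - 1))
    expect_equal(nf, (r - 1) * (c - 1))
    expect_equal(nv - ne + nf, 1)
  }
})

test_that("negative patches are shifted with the shift recorded and undone", {
  patch <- matrix(c(-50, -10, 20, 60), 2, 2)
  fc <- lower_star_cubical(patch)
  expect_equal(attr(fc, "value_shift"), 50)
  expect_gte(min(fc$cells$value), 0)
  expect_equal(critical_values(fc), sort(unique(as.vector(patch))))
})

test_that("every constructed complex is boundary-closed and monotone", {
  set.seed(4)
  complexes <- list(
    vietoris_rips(random_cloud(10), eps_max = 0.8),
    lower_star_cubical(random_patch(6, 5)),
    lower_star_cubical(make_fixture("annulus_image"))
  )
  for (fc in complexes) {
    expect_silent(validate_filtered_complex(fc))
    # sort order respects boundaries: every face sits earlier in the order
    pos <- integer(max(fc$cells$id))
    pos[fc$cells$id] <- seq_len(nrow(fc$cells))
    owner <- rep.int(seq_len(nrow(fc$cells)), fc$boundary$lengths)
    expect_true(all(pos[fc$boundary$ids] < owner))
  }
})

test_that("non-monotone complexes are rejected", {
  bad <- make_path_complex(c(0, 5), edges = list(list(ends = c(1L, 2L),
                                                      value = 3)))
  expect_error(validate_filtered_complex(bad),
               class = "fathom_invariant_error")
})

test_that("the annulus sublevel set is the ring between its two plateaus", {
  fc <- lower_star_cubical(make_fixture("annulus_image"))
  for (t in c(-100, 0, 99.9)) {
    expect_equal(betti_at(fc, 0, t), 1)
    expect_equal(betti_at(fc, 1, t), 1)
  }
  expect_equal(betti_at(fc, 0, 100), 1)
  expect_equal(betti_at(fc, 1, 100), 0)
})

test_that("complexes serialise to the documented TSV layout", {
  dir <- withr::local_tempdir()
  fc <- vietoris_rips(make_fixture("grid"), eps_max = 2)
  path <- file.path(dir, "complex.tsv")
  write_complex_tsv(fc, path)
  tab <- utils::read.delim(path)
  expect_named(tab, c("id", "dim", "filtration_value", "boundary_ids"))
  expect_equal(nrow(tab), nrow(fc$cells))
  expect_true(all(grepl("^\\d+(;\\d+)*$",
                        tab$boundary_ids[tab$dim > 0])))
})
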