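#' Generator configuration for one synthetic tissue group
#'
#' Describes how to simulate HU patches for one group of subjects. The two
#' groups the analysis contrasts are `"fat"` (epicardial adipose tissue:
#' nearly all pixels fall in the fat HU window and form smooth connected
#' blobs) and `"nonfat"` (myocardium/blood-pool texture: in-window pixels are
#' sparse and fragmented). Each patch is an i.i.d. Gaussian random field,
#' optionally convolved with a Gaussian kernel of width `smoothing_sigma`
#' (the marginal standard deviation is renormalised after smoothing, so
#' `sd_hu` is the pixelwise sd either way), then clipped to the valid CT
#' range \[-1024, 3071\] HU.
#'
#' Group defaults: fat has `mean_hu = -110`, `sd_hu = 25`,
#' `smoothing_sigma = 2` (a normal(-110, 25) marginal places essentially all
#' mass inside the -190..-30 HU fat window, and the 2-pixel correlation
#' length makes the in-window region one smooth blob); nonfat has
#' `mean_hu = -10`, `sd_hu = 45`, `smoothing_sigma = 0` (only the lower tail
#' dips into the window, as scattered independent pixels).
#'
#' @param group `"fat"` or `"nonfat"`; picks the default intensity model.
#' @param n_subjects Number of simulated subjects (default 8 per group).
#' @param patches_per_subject Patches extracted per subject (default 36).
#' @param patch_size Side length of each square patch in pixels (default 32,
#'   minimum 4).
#' @param mean_hu,sd_hu Marginal mean and sd of pixel attenuation, in HU.
#' @param smoothing_sigma Gaussian smoothing width in pixels; 0 disables
#'   smoothing.
#' @param seed Base seed; per-patch seeds are derived deterministically from
#'   (seed, group, subject, patch), so the same configuration always yields
#'   bit-identical patches.
#' @return A `generator_config` object (a named list).
#' @export
generator_config <- function(group = c("fat", "nonfat"),
                             n_subjects = 8,
                             patches_per_subject = 36,
                             patch_size = 32,
                             mean_hu = NULL,
                             sd_hu = NULL,
                             smoothing_sigma = NULL,
                             seed = 0L) {
  group <- match.arg(group)
  defaults <- switch(group,
    fat    = list(mean_hu = -110, sd_hu = 25, smoothing_sigma = 2),
    nonfat = list(mean_hu = -10,  sd_hu = 45, smoothing_sigma = 0)
  )
  cfg <- list(
    group = group,
    n_subjects = as.integer(n_subjects),
    patches_per_subject = as.integer(patches_per_subject),
    patch_size = as.integer(patch_size),
    mean_hu = mean_hu %||% defaults$mean_hu,
    sd_hu = sd_hu %||% defaults$sd_hu,
    smoothing_sigma = smoothing_sigma %||% defaults$smoothing_sigma,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  num <- c(cfg$mean_hu, cfg$sd_hu, cfg$smoothing_sigma)
  if (!all(is.finite(num))) {
    abort("generator_config parameters must be finite.", class = "fathom_config_error")
  }
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 1L ||
      is.na(cfg$patches_per_subject) || cfg$patches_per_subject < 1L) {
    abort("n_subjects and patches_per_subject must be positive integers.",
          class = "fathom_config_error")
  }
  if (is.na(cfg$patch_size) || cfg$patch_size < 4L) {
    abort("patch_size must be an integer >= 4.", class = "fathom_config_error")
  }
  if (cfg$sd_hu < 0 || cfg$smoothing_sigma < 0) {
    abort("sd_hu and smoothing_sigma must be nonnegative.",
          class = "fathom_config_error")
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> group=%s  subjects=%d x %d patches of %dx%d\n",
    x$group, x$n_subjects, x$patches_per_subject, x$patch_size, x$patch_size
  ))
  cat(sprintf("  HU ~ N(%g, %g), smoothing sigma = %g px, base seed = %d\n",
              x$mean_hu, x$sd_hu, x$smoothing_sigma, x$seed))
  invisible(x)
}

# Deterministic 31-bit seed from (base seed, group, subject, patch).
# Polynomial rolling hash mod the Mersenne prime 2^31 - 1; all arithmetic
# stays below 2^53 so it is exact in doubles.
patch_seed <- function(base_seed, group, subject_id, patch_index) {
  tokens <- c(base_seed %% 2147483647,
              utf8ToInt(as.character(group)),
              subject_id, patch_index)
  h <- 17
  for (tok in tokens) {
    h <- (h * 31 + (tok %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- dnorm(seq(-r, r), sd = sigma)
  w / sum(w)
}

# Separable convolution with reflection padding. Returns the smoothed matrix
# divided by sum(kernel^2)^(1/2) per axis so that the marginal variance of
# smoothed white noise matches the input variance.
smooth_field <- function(m, sigma) {
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  conv_cols <- function(a) {
    n <- nrow(a)
    pad <- rbind(a[r:1, , drop = FALSE], a, a[n:(n - r + 1L), , drop = FALSE])
    out <- matrix(0, n, ncol(a))
    for (s in seq_along(k)) {
      out <- out + k[s] * pad[(s - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  sm <- t(conv_cols(t(conv_cols(m))))
  sm / sum(k^2)  # two axes, each shrinks sd by sqrt(sum(k^2))
}

#' Generate one synthetic HU patch
#'
#' Draws the patch for `(subject_id, patch_index)` under `config`. The
#' per-patch seed is a deterministic hash of (base seed, group, subject,
#' patch), so patches are mutually independent yet individually reproducible.
#'
#' @param config A [generator_config()].
#' @param subject_id,patch_index Positive integers identifying the patch.
#' @return A `patch_size` x `patch_size` numeric matrix of HU values.
#' @examples
#' p <- generate_patch(generator_config("fat", seed = 1), 1, 1)
#' mean(p >= -190 & p <= -30)  # essentially all pixels in the fat window
#' @export
generate_patch <- function(config, subject_id, patch_index) {
  validate_generator_config(config)
  n <- config$patch_size
  seed <- patch_seed(config$seed, config$group, subject_id, patch_index)
  noise <- withr::with_seed(seed, {
    matrix(rnorm(n * n, mean = 0, sd = config$sd_hu), n, n)
  }, .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion")
  if (config$smoothing_sigma > 0 && config$sd_hu > 0) {
    noise <- smooth_field(noise, config$smoothing_sigma)
  }
  pmin(pmax(noise + config$mean_hu, HU_RANGE[1]), HU_RANGE[2])
}

#' Generate a two-group synthetic cohort
#'
#' Generates all patches for a fat and a nonfat group with disjoint subject
#' ids (by default fat subjects are `1..n_fat` and nonfat subjects continue
#' from `n_fat + 1`).
#'
#' @param config_fat,config_nonfat [generator_config()] objects for the two
#'   groups.
#' @param subject_ids_fat,subject_ids_nonfat Optional explicit subject id
#'   vectors; they must not overlap.
#' @return A tibble with one row per patch and columns `group`, `subject`,
#'   `patch`, `seed`, and `values` (a list-column of HU matrices).
#' @export
generate_cohort <- function(config_fat = generator_config("fat"),
                            config_nonfat = generator_config("nonfat"),
                            subject_ids_fat = seq_len(config_fat$n_subjects),
                            subject_ids_nonfat = config_fat$n_subjects +
                              seq_len(config_nonfat$n_subjects)) {
  validate_generator_config(config_fat)
  validate_generator_config(config_nonfat)
  if (length(intersect(subject_ids_fat, subject_ids_nonfat)) > 0) {
    abort("fat and nonfat subject id spaces must be disjoint.",
          class = "fathom_config_error")
  }
  one_group <- function(cfg, subjects) {
    grid <- tidyr::expand_grid(subject = subjects,
                               patch = seq_len(cfg$patches_per_subject))
    grid |>
      dplyr::mutate(
        group = cfg$group,
        seed = purrr::map2_int(.data$subject, .data$patch,
                               ~ patch_seed(cfg$seed, cfg$group, .x, .y)),
        values = purrr::map2(.data$subject, .data$patch,
                             ~ generate_patch(cfg, .x, .y))
      )
  }
  dplyr::bind_rows(one_group(config_fat, subject_ids_fat),
                   one_group(config_nonfat, subject_ids_nonfat)) |>
    dplyr::select("group", "subject", "patch", "seed", "values")
}

#' Analytic fixtures with known topology
#'
#' Small inputs whose homology is known exactly, used to validate the
#' filtration and reduction machinery:
#' * `"circle"` — 20 points evenly spaced on the unit circle (one prominent
#'   loop under Vietoris-Rips).
#' * `"annulus_image"` — a 32x32 image whose pixels at radius 6..9 from the
#'   centre have value -100 HU and all others +100 HU; masked at the fat
#'   window the ring has Betti numbers (1, 1).
#' * `"two_clusters"` — two tight 5-point clusters 10 px apart (two
#'   components at small scale).
#' * `"grid"` — the four unit-square corners (one Rips loop on \[1, sqrt(2))).
#'
#' @param name Fixture name.
#' @return A point-cloud tibble with columns `x`, `y`, or a numeric matrix
#'   for `"annulus_image"`.
#' @export
make_fixture <- function(name = c("circle", "annulus_image", "two_clusters", "grid")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort(
                     paste0("unknown fixture: ", name[1]),
                     class = "fathom_usage_error"))
  switch(name,
    circle = {
      theta <- 2 * pi * (0:19) / 20
      tibble::tibble(x = cos(theta), y = sin(theta))
    },
    annulus_image = {
      centre <- (32 + 1) / 2
      idx <- expand.grid(row = 1:32, col = 1:32)
      r <- sqrt((idx$row - centre)^2 + (idx$col - centre)^2)
      matrix(ifelse(r >= 6 & r <= 9, -100, 100), 32, 32)
    },
    two_clusters = {
      base <- tibble::tibble(x = c(0, 0.3, -0.3, 0, 0),
                             y = c(0, 0, 0, 0.3, -0.3))
      dplyr::bind_rows(base, dplyr::mutate(base, x = .data$x + 10))
    },
    grid = tibble::tibble(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  )
}

#' Write a cohort to disk as CSV grids plus a manifest
#'
#' One numeric CSV grid per patch (row-major, no header), named
#' `{group}_{subject:02d}_{patch:02d}.csv`, plus a `manifest.tsv` tying every
#' patch to its group, subject, patch index, path and seed.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort |>
    dplyr::mutate(path = sprintf("%s_%02d_%02d.csv",
                                 .data$group, .data$subject, .data$patch))
  purrr::walk2(manifest$values, manifest$path,
               ~ write_patch_csv(.x, file.path(dir, .y)))
  out <- dplyr::select(manifest, "group", "subject", "patch", "path", "seed")
  readr::write_tsv(out, file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(out)
}
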