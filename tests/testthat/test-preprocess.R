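test_that("centroiding recovers a symmetric peak position", {
  prof <- gaussian_profile(895.040, sigma = 0.02, spacing = 0.01,
                           width = 0.05)  # 11 profile points
  expect_identical(nrow(prof), 11L)
  cent <- smooth_and_centroid(prof, window = 5, polyorder = 2)
  expect_identical(nrow(cent), 1L)
  expect_lt(abs(cent$mz - 895.040), 0.005)
  # unbiased: error well under a tenth of the profile spacing
  expect_lt(abs(cent$mz - 895.040), 0.001)
})

test_that("centroiding resolves two peaks 0.5 Th apart", {
  p1 <- gaussian_profile(886.03, sigma = 0.03, spacing = 0.01)
  p2 <- gaussian_profile(886.53, sigma = 0.03, spacing = 0.01, height = 700)
  grid <- seq(885.5, 887.0, by = 0.01)
  prof <- tibble::tibble(
    mz = grid,
    intensity = 1000 * exp(-(grid - 886.03)^2 / (2 * 0.03^2)) +
      700 * exp(-(grid - 886.53)^2 / (2 * 0.03^2)))
  cent <- smooth_and_centroid(prof, min_intensity = 0.01)
  expect_identical(nrow(cent), 2L)
  expect_lt(abs(cent$mz[1] - 886.03), 0.01)
  expect_lt(abs(cent$mz[2] - 886.53), 0.01)
})

test_that("centroiding edge cases: flat input and short profiles", {
  flat <- tibble::tibble(mz = seq(100, 101, by = 0.01), intensity = 0)
  expect_identical(nrow(smooth_and_centroid(flat)), 0L)
  short <- tibble::tibble(mz = c(1, 2, 3), intensity = c(0, 1, 0))
  expect_error(smooth_and_centroid(short, window = 5), "fewer points")
})

test_that("TIC normalisation scales to unit sum and keeps ratios", {
  s <- spectrum_tbl(c(100, 200), c(2, 8), "pep", 30)
  n1 <- tic_normalize(s)
  expect_equal(n1$intensity, c(0.2, 0.8), tolerance = 1e-12)
  # idempotent
  n2 <- tic_normalize(n1)
  expect_equal(n2$intensity, n1$intensity, tolerance = 1e-12)
  # ratios preserved
  expect_equal(n1$intensity[2] / n1$intensity[1],
               s$intensity[2] / s$intensity[1], tolerance = 1e-12)
  one <- tic_normalize(spectrum_tbl(500, 42, "pep", 30))
  expect_identical(one$intensity, 1)
  expect_error(tic_normalize(spectrum_tbl(c(1, 2), c(0, 0), "p", 1)),
               "all-zero")
})

test_that("alignment merges peaks by single linkage within tolerance", {
  s1 <- spectrum_tbl(886.52, 10, "a", 36, 1)
  s2 <- spectrum_tbl(886.53, 20, "b", 36, 1)
  both <- bind_spectra(list(s1, s2))
  al <- align_spectra(both, tol = 0.02)
  expect_length(al$mz, 1L)
  # consensus m/z is the intensity-weighted mean
  expect_equal(al$mz, (886.52 * 10 + 886.53 * 20) / 30, tolerance = 1e-9)
  al2 <- align_spectra(both, tol = 0.005)
  expect_length(al2$mz, 2L)
  # out-of-range peaks are discarded
  al3 <- align_spectra(both, mz_range = c(600, 800), tol = 0.02)
  expect_length(al3$mz, 0L)
})

test_that("alignment conserves each spectrum's in-range intensity", {
  set.seed(5)
  specs <- lapply(1:4, function(i) {
    spectrum_tbl(sort(runif(30, 600, 900)), runif(30, 0, 100),
                 paste0("p", i %% 2), 30 + i %/% 2, i %% 2 + 1)
  })
  all <- bind_spectra(specs)
  al <- align_spectra(all, mz_range = c(650, 850), tol = 0.5)
  for (i in seq_len(nrow(al$meta))) {
    m <- al$meta[i, ]
    sub <- all[all$peptide_id == m$peptide_id & all$voltage == m$voltage &
                 all$replicate == m$replicate &
                 all$mz >= 650 & all$mz <= 850, ]
    expect_equal(sum(al$x[i, ]), sum(sub$intensity), tolerance = 1e-9)
  }
})

test_that("range restriction subsets variables without renormalising", {
  s <- bind_spectra(list(spectrum_tbl(c(550.1, 700.2, 850.3), c(1, 2, 3), "a", 30, 1),
                         spectrum_tbl(c(550.1, 700.2, 850.3), c(3, 2, 1), "a", 32, 1)))
  al <- align_spectra(s, tol = 0.02)
  r <- restrict_range(al, 600, 800)
  expect_equal(r$mz, 700.2, tolerance = 1e-9)
  expect_equal(unname(r$x[, 1]), c(2, 2))
  # full range is the identity
  full <- restrict_range(al, 0, 1000)
  expect_identical(full$mz, al$mz)
  expect_identical(full$x, al$x)
  expect_error(restrict_range(al, 900, 950), "no variables")
})

test_that("long-format view matches the matrix", {
  s <- bind_spectra(list(spectrum_tbl(c(100, 200), c(1, 2), "a", 30, 1),
                         spectrum_tbl(c(100, 200), c(3, 4), "a", 32, 1)))
  al <- align_spectra(s, tol = 0.02)
  long <- tibble::as_tibble(al)
  expect_identical(nrow(long), 4L)
  expect_setequal(long$intensity, c(1, 2, 3, 4))
})
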