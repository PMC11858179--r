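noiseless <- list(sigma = 0, baseline = 0, mz_jitter = 0)

test_that("identical seeds give identical spectra; different seeds differ", {
  cfg <- isomer_scenario()
  a <- simulate_spectra(cfg, seed = 7)
  b <- simulate_spectra(cfg, seed = 7)
  expect_identical(a$spectra, b$spectra)
  c <- simulate_spectra(cfg, seed = 8)
  expect_false(identical(a$spectra$intensity, c$spectra$intensity))
})

test_that("single-channel depletion follows the closed-form logistic", {
  analytes <- tibble::tibble(analyte = "x", precursor_mz = 500,
                             v50 = 30, width = 3)
  channels <- tibble::tibble(analyte = "x", channel = "f", mz = 400,
                             parent = NA_character_, weight = 1,
                             onset = 25, steepness = 2, specific = FALSE)
  cfg <- sim_config(analytes, channels, noise = noiseless, replicates = 1)
  tr <- sim_truth(cfg)
  sy <- tr$fraction[tr$channel == "precursor"]
  expect_equal(sy, 1 / (1 + exp((cfg$voltages - 30) / 3)), tolerance = 1e-12)
  expect_equal(tr$fraction[tr$channel == "f"], 1 - sy, tolerance = 1e-12)
})

test_that("noiseless truth conserves intensity exactly", {
  cfg <- isomer_scenario(noise = noiseless)
  tr <- sim_truth(cfg)
  sums <- tapply(tr$fraction, paste(tr$analyte, tr$voltage), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("invalid channel graphs are rejected", {
  analytes <- tibble::tibble(analyte = "x", precursor_mz = 500,
                             v50 = 30, width = 3)
  cyc <- tibble::tibble(analyte = "x", channel = c("a", "b"), mz = c(1, 2),
                        parent = c("b", "a"), weight = c(0.5, 0.5),
                        onset = 25, steepness = 2, specific = FALSE)
  expect_error(sim_config(analytes, cyc), "cycle")
  orphan <- tibble::tibble(analyte = "x", channel = "a", mz = 1,
                           parent = "ghost", weight = 0.5, onset = 25,
                           steepness = 2, specific = FALSE)
  expect_error(sim_config(analytes, orphan), "not defined")
  drained <- tibble::tibble(analyte = "x", channel = c("p", "c1", "c2"),
                            mz = 1:3, parent = c(NA, "p", "p"),
                            weight = c(1, 0.6, 0.6), onset = 25,
                            steepness = 2, specific = FALSE)
  expect_error(sim_config(analytes, drained), "drain")
})

test_that("the default scenario encodes the three-isomer structure", {
  cfg <- isomer_scenario()
  expect_setequal(cfg$analytes$analyte,
                  c("Car-TAT1", "T-Car-T", "TAT1-Car"))
  # one shared precursor m/z (isomers)
  expect_length(unique(cfg$analytes$precursor_mz), 1L)
  # dominant channels identical across analytes
  shared <- lapply(split(cfg$channels, cfg$channels$analyte), function(ch) {
    sort(round(ch$mz[!ch$specific], 4))
  })
  expect_identical(shared[[1]], shared[[2]])
  expect_identical(shared[[1]], shared[[3]])
  # dominant channels live in m/z 800-900, diagnostics in 600-800
  expect_true(all(cfg$channels$mz[!cfg$channels$specific] > 800 &
                    cfg$channels$mz[!cfg$channels$specific] < 900))
  for (a in cfg$analytes$analyte) {
    spec_mz <- cfg$channels$mz[cfg$channels$analyte == a &
                                 cfg$channels$specific]
    expect_gte(sum(spec_mz > 600 & spec_mz < 800), 2L)
  }
})

test_that("scenario SY at 36 V is near 0.2 and diagnostics are low-level", {
  cfg <- isomer_scenario(noise = noiseless)
  tr <- sim_truth(cfg)
  sy36 <- tr$fraction[tr$channel == "precursor" & tr$voltage == 36]
  expect_true(all(sy36 > 0.1 & sy36 < 0.3))
  spec36 <- tr[tr$specific & tr$voltage == 36, ]
  expect_true(all(spec36$fraction < 0.05))
  expect_true(all(spec36$fraction > 0.001))
})

test_that("scenario channel m/z values come from the fragment model", {
  cfg <- isomer_scenario()
  ch <- cfg$channels
  get_mz <- function(a, id) ch$mz[ch$analyte == a & ch$channel == id]
  prec <- ion_spec("precursor", isomer_sequences()[["TAT1-Car"]], charge = 2)
  expect_equal(get_mz("Car-TAT1", "prec-NH3"),
               ion_mz(ion_spec("precursor",
                               isomer_sequences()[["TAT1-Car"]], 2,
                               losses = "ammonia"))$mz,
               tolerance = 1e-12)
  y12 <- ion_spec("y", "GRKKRRQRRRPS", 2, losses = c("ammonia", "water"))
  expect_equal(get_mz("Car-TAT1", "y12-H2O-NH3"), ion_mz(y12)$mz,
               tolerance = 1e-12)
  bb <- ion_spec("internal_b", "RRRPSGRKKRRQ", 2, losses = "water")
  expect_equal(get_mz("T-Car-T", "bb-H2O"), ion_mz(bb)$mz,
               tolerance = 1e-12)
})

test_that("simulations round-trip through MGF on disk", {
  cfg <- isomer_scenario(replicates = 1)
  sim <- simulate_spectra(cfg, seed = 11)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_mgf(file.path(dir, "spectra.mgf"))
  expect_identical(nrow(back), nrow(sim$spectra))
  expect_setequal(unique(back$peptide_id), cfg$analytes$analyte)
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE)
  expect_identical(nrow(truth), nrow(sim$truth))
})
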