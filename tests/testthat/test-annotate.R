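test_that("precursor-loss peaks get the least-exotic assignment", {
  cat <- cached_catalogue("Car-TAT1")
  s <- spectrum_tbl(886.53, 100, "Car-TAT1", 36)
  ann <- annotate_spectrum(s, cat, tol = 0.02)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$label, "[M+2H-NH3]2+")
  expect_identical(ann$charge, 2L)
})

test_that("the half-Th spacing separates water from ammonia losses", {
  cat <- cached_catalogue("Car-TAT1")
  prec <- ion_mz(ion_spec("precursor", isomer_sequences()[["Car-TAT1"]],
                          charge = 2))$mz
  s <- spectrum_tbl(c(prec - 8.51, prec - 9.01), c(10, 10), "x", 36)
  ann <- annotate_spectrum(s, cat, tol = 0.02)
  lab_nh3 <- ann$label[which.min(abs(ann$observed_mz - (prec - 8.51)))]
  lab_h2o <- ann$label[which.min(abs(ann$observed_mz - (prec - 9.01)))]
  expect_identical(lab_nh3, "[M+2H-NH3]2+")
  # the -9.01 peak is a water loss at z = 2; the full-length b ion is
  # mass-identical to [M+2H-H2O]2+ (b14 = M - H2O) and, carrying no
  # explicit loss, wins the least-exotic tie-break
  expect_true(lab_h2o %in% c("[M+2H-H2O]2+", "[b14]2+"))
  expect_false(lab_nh3 == lab_h2o)
})

test_that("peaks without candidates stay unannotated", {
  cat <- cached_catalogue("Car-TAT1")
  s <- spectrum_tbl(400.00, 5, "x", 36)
  ann <- annotate_spectrum(s, cat, tol = 0.001)
  expect_identical(nrow(ann), 0L)
})

test_that("annotation is order-independent and self-consistent", {
  cat <- cached_catalogue("T-Car-T")
  set.seed(41)
  mzs <- sample(cat$mz, 40)
  s <- spectrum_tbl(mzs, rep(1, 40), "x", 36)
  a1 <- annotate_spectrum(s, cat, tol = 0.02)
  shuffled <- cat[sample(nrow(cat)), ]
  class(shuffled) <- class(cat)
  s_rev <- s[rev(seq_len(nrow(s))), ]
  a2 <- annotate_spectrum(s_rev, shuffled, tol = 0.02)
  a2 <- a2[order(a2$observed_mz), ]
  a1 <- a1[order(a1$observed_mz), ]
  expect_identical(a1$label, a2$label)
  expect_true(all(abs(a1$error_mth) <= 20))
})

test_that("catalogue-generated peaks round-trip with exact labels", {
  cat <- cached_catalogue("TAT1-Car")
  # bijective setting: ions whose m/z is unique in the catalogue
  iso <- which(vapply(seq_len(nrow(cat)), function(i) {
    d <- abs(cat$mz[-i] - cat$mz[i])
    min(d) > 1e-3
  }, logical(1)))
  set.seed(43)
  pick <- sample(iso, min(150, length(iso)))
  s <- spectrum_tbl(cat$mz[pick], rep(1, length(pick)), "x", 36)
  ann <- annotate_spectrum(s, cat, tol = 5e-4)
  expect_identical(nrow(ann), length(pick))      # 100% recall
  expect_identical(ann$label[order(ann$observed_mz)],
                   cat$label[pick][order(cat$mz[pick])])
  expect_true(all(ann$error_mth == 0))
})

test_that("ppm tolerance mode matches proportionally", {
  cat <- cached_catalogue("TAT1-Car")
  target <- cat$mz[which.min(abs(cat$mz - 857))]
  s <- spectrum_tbl(target + target * 5e-6, 1, "x", 36)
  expect_identical(nrow(annotate_spectrum(s, cat, tol = 10,
                                          tol_mode = "ppm")), 1L)
  expect_identical(nrow(annotate_spectrum(s, cat, tol = 1,
                                          tol_mode = "ppm")), 0L)
})

test_that("exhaustive mode returns every candidate within tolerance", {
  cat <- cached_catalogue("TAT1-Car")
  s <- spectrum_tbl(857.0, 1, "x", 36)
  all_m <- annotate_spectrum(s, cat, tol = 0.02, all_matches = TRUE)
  best <- annotate_spectrum(s, cat, tol = 0.02)
  expect_gte(nrow(all_m), nrow(best))
  expect_true(best$label %in% all_m$label)
})

test_that("ion labels parse back to kind, charge and losses", {
  cases <- list(
    ion_spec("y", "GRKKRRQRRRPS", 2, losses = c("ammonia", "water")),
    ion_spec("precursor", "GRK", 2, losses = c("ammonia", "ammonia")),
    ion_spec("b", c("bA", "H"), 1),
    ion_spec("internal_b", "RRRP", 1, losses = "guanidine"),
    ion_spec("scrambled_b", "GRKGR", 2, losses = "carbodiimide"))
  for (ion in cases) {
    parsed <- parse_ion_label(ion_label(ion))
    expect_identical(parsed$kind, ion$kind)
    expect_identical(parsed$charge, ion$charge)
    expect_identical(parsed$losses, sort(ion$losses[[1]]))
  }
})

test_that("annotations export with flattened loss multisets", {
  cat <- cached_catalogue("Car-TAT1")
  s <- spectrum_tbl(886.53, 100, "x", 36)
  ann <- annotate_spectrum(s, cat, tol = 0.02)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_identical(back$losses, "ammonia")
})
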