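seqs <- isomer_sequences()

test_that("conventional b/y enumeration covers the expected ladder", {
  conv <- enumerate_conventional(seqs[["TAT1-Car"]], max_charge = 2)
  b10 <- conv[conv$base == "b10" & conv$charge == 2L, ]
  expect_equal(nrow(b10), 1L)
  expect_lt(abs(b10$mz - 689.95), 0.01)
  # full-length b ion is included
  expect_true("b14" %in% conv$base)

  cv <- enumerate_conventional(seqs[["Car-TAT1"]], max_charge = 2)
  b2 <- cv[cv$base == "b2" & cv$charge == 1L, ]
  y12 <- cv[cv$base == "y12" & cv$charge == 2L, ]
  expect_lt(abs(b2$mz - 209.10), 0.01)
  expect_lt(abs(y12$mz - 790.99), 0.01)
  # charge-separation pair: b2 and y12 are complementary (2 + 12 = 14)
  expect_identical(length(b2$residues[[1]]) + length(y12$residues[[1]]), 14L)

  single <- enumerate_conventional("G", max_charge = 1)
  expect_identical(single$base, "b1")
})

test_that("b/y mass closure: complementary pairs sum to the peptide mass", {
  codes <- parse_peptide(seqs[["Car-TAT1"]])
  n <- length(codes)
  conv <- enumerate_conventional(codes, max_charge = 1)
  M <- peptide_mass(codes)
  for (i in seq_len(n - 1)) {
    b <- conv[conv$base == paste0("b", i), ]
    y <- conv[conv$base == paste0("y", n - i), ]
    # neutral masses: strip the proton back off
    expect_lt(abs((b$mz - PROTON_MASS) + (y$mz - PROTON_MASS) - M), 1e-6)
  }
})

test_that("neutral-loss series reproduces precursor-loss assignments", {
  prec <- ion_spec("precursor", seqs[["TAT1-Car"]], charge = 2)
  ser <- enumerate_loss_series(prec, max_total = 2)
  key <- vapply(ser$losses, paste, character(1), collapse = "+")
  expect_lt(abs(ser$mz[key == "ammonia"] - 886.53), 0.011)
  expect_lt(abs(ser$mz[key == "ammonia+guanidine"] - 857.00), 0.01)
  # every loss-series m/z equals base plus the exact shifts
  base_mz <- ion_mz(prec)$mz
  for (i in seq_len(nrow(ser))) {
    expect_equal(ser$mz[i],
                 base_mz + sum(delta_mz(ser$losses[[i]], 2)),
                 tolerance = 1e-12)
  }
  expect_true(all(ser$mz < base_mz))
})

test_that("y12 loss series contains the diagnostic 773.47 ion", {
  conv <- enumerate_conventional(seqs[["Car-TAT1"]], max_charge = 2)
  y12 <- conv[conv$base == "y12" & conv$charge == 2L, ]
  ser <- enumerate_loss_series(y12, max_total = 2)
  key <- vapply(ser$losses, paste, character(1), collapse = "+")
  expect_lt(abs(ser$mz[key == "ammonia+water"] - 773.47), 0.01)
})

test_that("loss caps and degenerate inputs behave", {
  prec <- ion_spec("precursor", seqs[["TAT1-Car"]], charge = 2)
  expect_identical(nrow(enumerate_loss_series(prec, max_total = 0)), 0L)
  # arginine-free ion cannot lose carbodiimide or guanidine
  noR <- ion_spec("b", c("G", "S", "P"), charge = 1)
  ser <- enumerate_loss_series(noR, max_total = 3)
  all_losses <- unlist(ser$losses)
  expect_false(any(all_losses %in% c("carbodiimide", "guanidine")))
  # explicit caps override the defaults
  capped <- enumerate_loss_series(prec, max_total = 4,
                                  caps = c(ammonia = 1, water = 0,
                                           carbodiimide = 0, guanidine = 0))
  expect_identical(nrow(capped), 1L)
  expect_identical(capped$losses[[1]], "ammonia")
})

test_that("scrambled enumeration models macrocycle reopening", {
  sc <- enumerate_scrambled(seqs[["T-Car-T"]], max_charge = 2,
                            min_length = 1)
  # every contiguous substring of the cyclic 14-mer: 14 starts x 13 partial
  # lengths + 14 full rotations = 196 spans per charge
  expect_identical(nrow(sc), 196L * 2L)
  bs12 <- sc[sc$base == "int(RRRPSGRKKRRQ)" & sc$charge == 2L, ]
  expect_lt(abs(bs12$mz[1] - 781.99), 0.01)
  rrrp <- sc[sc$base == "int(RRRP)" & sc$charge == 1L, ]
  expect_lt(abs(rrrp$mz[1] - 566.36), 0.01)
  # all full-length rotations have identical m/z (composition-invariant)
  full <- sc[sc$kind == "scrambled_b" & sc$charge == 2L, ]
  expect_identical(nrow(full), 14L)
  expect_true(all(abs(full$mz - full$mz[1]) < 1e-12))
  expect_error(enumerate_scrambled("GR"), "length >= 3")
})

test_that("scrambled enumeration matches the brute-force cyclic oracle", {
  set.seed(3)
  alphabet <- c("G", "R", "K", "P")
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    codes <- sample(alphabet, n, replace = TRUE)
    sc <- enumerate_scrambled(codes, max_charge = 1, min_length = 1)
    got <- sort(vapply(sc$residues,
                       function(r) paste(sort(r), collapse = ""),
                       character(1)))
    expect_identical(got, brute_force_cyclic_substrings(codes))
  }
})

test_that("full catalogue contains the assigned diagnostic ions", {
  ctt <- cached_catalogue("T-Car-T")
  # water loss from the scrambled 12-residue b ion
  hit <- ctt[ctt$base == "int(RRRPSGRKKRRQ)" &
               vapply(ctt$losses, identical, logical(1), "water") &
               ctt$charge == 2L, ]
  expect_identical(nrow(hit), 1L)
  expect_lt(abs(hit$mz - 772.98), 0.01)

  tac <- cached_catalogue("TAT1-Car")
  b10c <- tac[tac$base == "b10" & tac$charge == 2L &
                vapply(tac$losses, identical, logical(1), "carbodiimide"), ]
  expect_lt(abs(b10c$mz - 668.93), 0.01)
})

test_that("catalogue respects its structural invariants", {
  ctt <- cached_catalogue("T-Car-T")
  expect_false(is.unsorted(ctt$mz))
  expect_true(all(ctt$mz > 0))
  prec2 <- ion_mz(ion_spec("precursor", seqs[["T-Car-T"]], charge = 2))$mz
  expect_true(all(ctt$mz[ctt$charge == 2L] <= prec2 + 1))
  # deduplication leaves no repeated (kind, composition, charge, losses)
  key <- paste(ctt$kind,
               vapply(ctt$residues, function(r) paste(sort(r), collapse = ""),
                      character(1)),
               ctt$charge,
               vapply(ctt$losses, paste, character(1), collapse = "+"))
  expect_identical(anyDuplicated(key), 0L)
})

test_that("scrambling can be disabled", {
  plain <- build_catalogue(seqs[["T-Car-T"]], scrambling = FALSE,
                           max_total = 1)
  expect_false(any(plain$kind %in% c("scrambled_b", "internal_b")))
  expect_false(any(abs(plain$mz - 781.99) < 0.01 &
                     lengths(plain$losses) == 0))
})

test_that("catalogue export writes a readable inclusion list", {
  path <- withr::local_tempfile(fileext = ".tsv")
  small <- build_catalogue("GRK", max_total = 1)
  write_catalogue(small, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_identical(nrow(back), nrow(small))
  expect_true(all(c("label", "kind", "charge", "losses", "mz") %in%
                    names(back)))
})
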