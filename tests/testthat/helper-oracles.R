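# Independent oracles and fixture builders. These never call the code paths
# they are used to check.

# brute-force enumeration of scrambled/internal b ions: rotate the string,
# take every substring, return the multiset of (sorted composition, length)
brute_force_cyclic_substrings <- function(codes, min_length = 1L) {
  n <- length(codes)
  out <- character(0)
  for (start in seq_len(n)) {
    rot <- c(codes[start:n], codes[seq_len(start - 1L)][start > 1])
    rot <- rot[!is.na(rot)]
    for (len in min_length:n) {
      out <- c(out, paste(sort(rot[seq_len(len)]), collapse = ""))
    }
  }
  sort(out)
}

# dense eigendecomposition PCA oracle on a centred matrix
eigen_pca_oracle <- function(X, k) {
  e <- eigen(crossprod(X), symmetric = TRUE)
  loadings <- e$vectors[, seq_len(k), drop = FALSE]
  scores <- X %*% loadings
  list(scores = scores, loadings = loadings,
       evpct = 100 * e$values[seq_len(k)] / sum(X^2))
}

# align oracle signs to a reference before comparing component matrices
match_signs <- function(target, reference) {
  for (k in seq_len(ncol(target))) {
    if (sum(target[, k] * reference[, k]) < 0) target[, k] <- -target[, k]
  }
  target
}

# gaussian profile-mode peak on a regular grid
gaussian_profile <- function(center, sigma = 0.02, height = 1000,
                             spacing = 0.01, width = 0.3) {
  mz <- seq(center - width, center + width, by = spacing)
  tibble::tibble(mz = mz,
                 intensity = height * exp(-(mz - center)^2 / (2 * sigma^2)))
}

# shared fragment catalogues (expensive to build; reused across tests)
.catalogue_cache <- new.env(parent = emptyenv())
cached_catalogue <- function(id) {
  if (is.null(.catalogue_cache[[id]])) {
    .catalogue_cache[[id]] <- build_catalogue(isomer_sequences()[[id]],
                                              peptide_id = id)
  }
  .catalogue_cache[[id]]
}

# minimal mzML writer fixture via mzR (built at test time, never stored)
write_test_mzml <- function(path, collision_energy = 36) {
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 2L, polarity = 1L,
    peaksCount = 3L, totIonCurrent = 1030, retentionTime = 1,
    basePeakMZ = 895.04, basePeakIntensity = 1000,
    collisionEnergy = collision_energy, ionisationEnergy = 0,
    lowMZ = 100, highMZ = 895.04, precursorScanNum = 0L,
    precursorMZ = 895.04, precursorCharge = 2L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = 895.04, isolationWindowLowerOffset = 1,
    isolationWindowUpperOffset = 1, scanWindowLowerLimit = 50,
    scanWindowUpperLimit = 2000)
  mzR::writeMSData(list(cbind(mz = c(100, 200, 895.04),
                              intensity = c(10, 20, 1000))),
                   file = path, header = hdr)
  path
}
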