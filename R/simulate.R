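## Seeded generator of energy-resolved MS/MS spectrum series with known
## ground truth. The kinetics are phenomenological: logistic precursor
## depletion SY(V) = 1/(1 + exp((V - v50)/width)); the depleted fraction is
## split over primary fragmentation channels by branching weights gated by
## their own logistic onsets; each consecutive channel drains a fraction of
## its parent with a later onset, which guarantees lower maxima and
## right-shifted breakdown curves. Intensity is conserved exactly at every
## voltage in the noiseless truth.

.default_noise <- function() {
  list(sigma = 0.05, baseline = 0.001, mz_jitter = 0.003)
}

#' Build a simulation configuration
#'
#' @param analytes Tibble with one row per analyte: `analyte`,
#'   `precursor_mz`, `v50` (half-depletion voltage, V) and `width`
#'   (depletion steepness, V).
#' @param channels Tibble with one row per fragmentation channel: `analyte`,
#'   `channel` (id), `mz`, `parent` (`NA` for a primary channel, otherwise a
#'   channel id of the same analyte), `weight` (branching weight for
#'   primaries; drained fraction of the parent, summing to < 1 per parent,
#'   for consecutive channels), `onset` and `steepness` (logistic gate, V),
#'   `specific` (logical: analyte-diagnostic channel).
#' @param voltages Strictly increasing acceleration-voltage grid (V).
#' @param replicates Replicate spectra per voltage.
#' @param noise List with `sigma` (multiplicative log-normal sd),
#'   `baseline` (additive uniform noise as a fraction of the base peak) and
#'   `mz_jitter` (peak position sd, Th).
#' @param tic_scale Nominal total ion current of a synthetic spectrum.
#' @param ref_voltage Voltage at which diagnostic abundances are reported.
#' @param seed Default seed used by [simulate_spectra()].
#' @return A `sim_config` object.
#' @export
sim_config <- function(analytes, channels, voltages = seq(20, 42, by = 2),
                       replicates = 3L, noise = .default_noise(),
                       tic_scale = 1e5, ref_voltage = 36, seed = 1L) {
  analytes <- tibble::as_tibble(analytes)
  channels <- tibble::as_tibble(channels)
  stopifnot(all(diff(voltages) > 0), replicates >= 1L,
            all(channels$weight >= 0))
  noise <- utils::modifyList(.default_noise(), noise)
  for (a in analytes$analyte) {
    ch <- channels[channels$analyte == a, ]
    unknown <- setdiff(stats::na.omit(ch$parent), ch$channel)
    if (length(unknown) > 0) {
      stop("channel parent(s) not defined for analyte ", a, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    ## cycle check by repeated leaf stripping
    rem <- stats::setNames(ch$parent, ch$channel)
    repeat {
      leaves <- names(rem)[!names(rem) %in% rem]
      if (length(leaves) == 0L) break
      rem <- rem[!names(rem) %in% leaves]
    }
    if (length(rem) > 0) {
      stop("channel graph for analyte ", a, " contains a cycle: ",
           paste(names(rem), collapse = ", "), call. = FALSE)
    }
    for (p in unique(stats::na.omit(ch$parent))) {
      if (sum(ch$weight[!is.na(ch$parent) & ch$parent == p]) >= 1) {
        stop("children of channel ", p, " (analyte ", a,
             ") drain >= 100% of it", call. = FALSE)
      }
    }
  }
  structure(list(analytes = analytes, channels = channels,
                 voltages = voltages, replicates = as.integer(replicates),
                 noise = noise, tic_scale = tic_scale,
                 ref_voltage = ref_voltage, seed = as.integer(seed)),
            class = "sim_config")
}

.logistic_gate <- function(v, onset, steepness) {
  1 / (1 + exp(-(v - onset) / steepness))
}

#' Noiseless ground-truth fractions of a simulation
#'
#' At each voltage: SY from the logistic depletion; the depleted intensity
#' split over primary channels in proportion to weight x gate; each
#' consecutive channel takes weight x gate of its parent's allocation.
#' SY plus all channel fractions sum to 1 exactly.
#'
#' @param config A `sim_config`.
#' @return Tibble: `analyte`, `voltage`, `channel` (`"precursor"` included),
#'   `mz`, `parent`, `specific`, `fraction`.
#' @export
sim_truth <- function(config) {
  out <- list()
  for (a in config$analytes$analyte) {
    arow <- config$analytes[config$analytes$analyte == a, ]
    ch <- config$channels[config$channels$analyte == a, ]
    prim <- ch[is.na(ch$parent), ]
    for (v in config$voltages) {
      sy <- 1 / (1 + exp((v - arow$v50) / arow$width))
      depleted <- 1 - sy
      gates <- .logistic_gate(v, prim$onset, prim$steepness)
      s <- prim$weight * gates
      alloc <- stats::setNames(
        if (sum(s) > 0) depleted * s / sum(s) else rep(0, nrow(prim)),
        prim$channel)
      ## consecutive channels drain their parent's allocation, depth first
      remaining <- ch$channel[!ch$channel %in% names(alloc)]
      while (length(remaining) > 0) {
        ready <- remaining[ch$parent[match(remaining, ch$channel)] %in%
                             names(alloc)]
        for (cc in ready) {
          i <- match(cc, ch$channel)
          take <- alloc[[ch$parent[i]]] * ch$weight[i] *
            .logistic_gate(v, ch$onset[i], ch$steepness[i])
          alloc[[cc]] <- take
        }
        ## subtract drained amounts after all siblings computed
        for (p in unique(ch$parent[match(ready, ch$channel)])) {
          kids <- ready[ch$parent[match(ready, ch$channel)] == p]
          alloc[[p]] <- alloc[[p]] - sum(unlist(alloc[kids]))
        }
        remaining <- setdiff(remaining, ready)
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        analyte = a, voltage = v,
        channel = c("precursor", names(alloc)),
        mz = c(arow$precursor_mz, ch$mz[match(names(alloc), ch$channel)]),
        parent = c(NA_character_, ch$parent[match(names(alloc), ch$channel)]),
        specific = c(FALSE, ch$specific[match(names(alloc), ch$channel)]),
        fraction = unname(c(sy, unlist(alloc))))
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate an energy-resolved spectrum series
#'
#' Generates centroided spectra for every analyte, voltage and replicate.
#' Peak intensities are the noiseless fractions scaled to `tic_scale`, with
#' multiplicative log-normal noise, additive uniform baseline noise and
#' Gaussian m/z jitter per replicate. Identical seeds give identical output.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (default from the config).
#' @return List with `spectra` (long spectrum tibble), `truth` (see
#'   [sim_truth()]) and `diagnostics` (per analyte: specific channel m/z and
#'   its noiseless fraction at the reference voltage).
#' @export
simulate_spectra <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  truth <- sim_truth(config)
  nz <- config$noise
  specs <- list()
  for (a in config$analytes$analyte) {
    arow <- config$analytes[config$analytes$analyte == a, ]
    for (v in config$voltages) {
      tr <- truth[truth$analyte == a & truth$voltage == v, ]
      for (r in seq_len(config$replicates)) {
        base_int <- tr$fraction * config$tic_scale
        keep <- base_int > 0
        intensity <- base_int[keep] *
          exp(stats::rnorm(sum(keep), 0, nz$sigma))
        intensity <- intensity +
          stats::runif(sum(keep), 0, nz$baseline * max(intensity))
        mzs <- tr$mz[keep] + stats::rnorm(sum(keep), 0, nz$mz_jitter)
        specs[[length(specs) + 1L]] <- spectrum_tbl(
          mzs, intensity, a, v, r, arow$precursor_mz, 2L)
      }
    }
  }
  diag_tbl <- truth[truth$specific & truth$voltage == config$ref_voltage, ]
  diagnostics <- tibble::tibble(analyte = diag_tbl$analyte,
                                channel = diag_tbl$channel,
                                mz = diag_tbl$mz,
                                abundance = diag_tbl$fraction)
  list(spectra = bind_spectra(specs), truth = truth,
       diagnostics = diagnostics)
}

#' Default three-isomer simulation scenario
#'
#' Emulates the energy-resolved CID behaviour of the three isomeric
#' carnosine-TAT1 peptides: one shared precursor m/z; dominant non-specific
#' precursor neutral-loss channels in m/z 800-900 common to all three
#' analytes; and low-abundance analyte-specific channels in m/z 600-800 —
#' the consecutive y12 loss series for Car-TAT1, the water-loss scrambled
#' b-ion series for T-Car-T, and the b10 ladder for TAT1-Car. Every channel
#' m/z is computed from the fragment model at call time, never typed in.
#' Depletion is tuned so the noiseless SY at 36 V is about 0.2.
#'
#' @param replicates Replicates per voltage.
#' @param noise Noise parameters, see [sim_config()].
#' @param seed Default seed.
#' @return A `sim_config` for the three isomers.
#' @export
isomer_scenario <- function(replicates = 3L, noise = .default_noise(),
                            seed = 1L) {
  seqs <- isomer_sequences()
  tab <- residue_table()
  nl <- neutral_losses()
  prec_mz <- ion_mz(ion_spec("precursor", seqs[["TAT1-Car"]], charge = 2))$mz

  ## shared precursor-loss channels, from the loss-series enumeration
  prec <- ion_spec("precursor", seqs[["TAT1-Car"]], charge = 2)
  ser <- enumerate_loss_series(prec, nl, max_total = 2)
  lkey <- vapply(ser$losses, paste, character(1), collapse = "+")
  mz_of <- function(key) ser$mz[match(key, lkey)]
  shared <- tibble::tibble(
    channel = c("prec-NH3", "prec-CH2N2", "prec-CH5N3", "prec-CH5N3-NH3"),
    mz = c(mz_of("ammonia"), mz_of("carbodiimide"), mz_of("guanidine"),
           mz_of("ammonia+guanidine")),
    parent = c(NA, NA, NA, "prec-CH5N3"),
    weight = c(0.38, 0.25, 0.22, 0.45),
    onset = c(27, 28, 28.5, 33),
    steepness = c(2.5, 2.5, 2.5, 2.5),
    specific = FALSE)

  ## Car-TAT1: consecutive losses from the doubly charged y12 ion
  conv <- enumerate_conventional(seqs[["Car-TAT1"]], max_charge = 2)
  y12 <- conv[conv$base == "y12" & conv$charge == 2L, ]
  y12ser <- enumerate_loss_series(y12, nl, max_total = 4)
  ykey <- vapply(y12ser$losses, paste, character(1), collapse = "+")
  ymz <- function(key) y12ser$mz[match(key, ykey)]
  car_tat1 <- tibble::tibble(
    channel = c("y12-H2O-NH3", "y12-H2O-2NH3", "y12-H2O-NH3-CH2N2",
                "y12-H2O-2NH3-CH2N2"),
    mz = c(ymz("ammonia+water"), ymz("ammonia+ammonia+water"),
           ymz("ammonia+carbodiimide+water"),
           ymz("ammonia+ammonia+carbodiimide+water")),
    parent = c(NA, "y12-H2O-NH3", "y12-H2O-NH3", "y12-H2O-NH3-CH2N2"),
    weight = c(0.055, 0.30, 0.22, 0.35),
    onset = c(30, 33.5, 34, 36.5),
    steepness = c(2.5, 2.2, 2.2, 2.2),
    specific = TRUE)

  ## T-Car-T: water loss from the scrambled 12-residue b ion, then its
  ## consecutive losses
  sc <- enumerate_scrambled(seqs[["T-Car-T"]], max_charge = 2)
  bs <- sc[sc$base == "int(RRRPSGRKKRRQ)" & sc$charge == 2L, ][1, ]
  bser <- enumerate_loss_series(bs, nl, max_total = 4)
  bkey <- vapply(bser$losses, paste, character(1), collapse = "+")
  bmz <- function(key) bser$mz[match(key, bkey)]
  t_car_t <- tibble::tibble(
    channel = c("bb-H2O", "bb-H2O-NH3", "bb-H2O-CH2N2", "bb-H2O-NH3-CH2N2"),
    mz = c(bmz("water"), bmz("ammonia+water"), bmz("carbodiimide+water"),
           bmz("ammonia+carbodiimide+water")),
    parent = c(NA, "bb-H2O", "bb-H2O", "bb-H2O-CH2N2"),
    weight = c(0.055, 0.30, 0.22, 0.35),
    onset = c(30, 33.5, 34, 36.5),
    steepness = c(2.5, 2.2, 2.2, 2.2),
    specific = TRUE)

  ## TAT1-Car: conventional b10 (doubly charged) and its carbodiimide loss
  convT <- enumerate_conventional(seqs[["TAT1-Car"]], max_charge = 2)
  b10 <- convT[convT$base == "b10" & convT$charge == 2L, ]
  b10ser <- enumerate_loss_series(b10, nl, max_total = 1)
  ckey <- vapply(b10ser$losses, paste, character(1), collapse = "+")
  tat1_car <- tibble::tibble(
    channel = c("b10", "b10-CH2N2"),
    mz = c(b10$mz, b10ser$mz[match("carbodiimide", ckey)]),
    parent = c(NA, "b10"),
    weight = c(0.05, 0.40),
    onset = c(30, 33.5),
    steepness = c(2.5, 2.2),
    specific = TRUE)

  channels <- dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(shared, car_tat1), analyte = "Car-TAT1"),
    dplyr::mutate(dplyr::bind_rows(shared, t_car_t), analyte = "T-Car-T"),
    dplyr::mutate(dplyr::bind_rows(shared, tat1_car), analyte = "TAT1-Car"))

  analytes <- tibble::tibble(
    analyte = c("Car-TAT1", "T-Car-T", "TAT1-Car"),
    precursor_mz = prec_mz,
    v50 = c(31.2, 32.0, 31.6),   # Car-TAT1 depletes slightly earlier
    width = 3.2)

  sim_config(analytes, channels, replicates = replicates, noise = noise,
             seed = seed)
}

#' Write a simulation to disk
#'
#' MGF spectra plus tab-separated truth and diagnostics tables.
#'
#' @param sim Result of [simulate_spectra()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mgf(sim$spectra, file.path(dir, "spectra.mgf"))
  utils::write.table(as.data.frame(sim$truth), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$diagnostics),
                     file.path(dir, "diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
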