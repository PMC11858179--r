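## Survival-Yield and breakdown curves. SY is the precursor's share of the
## total ion current of an MS/MS spectrum,
##   SY = I_precursor / (I_precursor + sum(I_fragment)),
## and a breakdown curve is a fragment variable's TIC share as a function of
## the acceleration voltage. Both are ratios, so they are invariant to any
## rescaling (e.g. TIC normalisation) of the spectrum.

.one_fraction <- function(spectrum, target_mz, tol) {
  tic <- sum(spectrum$intensity)
  if (nrow(spectrum) == 0L || tic <= 0) {
    stop("empty spectrum: cannot compute an intensity fraction", call. = FALSE)
  }
  sum(spectrum$intensity[abs(spectrum$mz - target_mz) <= tol]) / tic
}

#' Survival Yield of one spectrum
#'
#' Fraction of the total ion current carried by peaks within `tol` of the
#' precursor m/z. All centroids within the window count as precursor; isotope
#' peaks beyond it count as fragments (explicit, configurable policy).
#'
#' @param spectrum Peak tibble of a single spectrum.
#' @param precursor_mz Precursor m/z; defaults to the spectrum's
#'   `precursor_mz` column.
#' @param tol Matching half-window in Th.
#' @return Fraction in [0, 1].
#' @examples
#' s <- spectrum_tbl(c(895.04, 400), c(2000, 8000), "pep", 30,
#'                   precursor_mz = 895.04)
#' survival_yield(s)
#' @export
survival_yield <- function(spectrum, precursor_mz = NULL, tol = 0.05) {
  stopifnot(tol > 0)
  if (is.null(precursor_mz)) precursor_mz <- spectrum$precursor_mz[1]
  if (is.null(precursor_mz) || is.na(precursor_mz)) {
    stop("no precursor m/z available", call. = FALSE)
  }
  .one_fraction(spectrum, precursor_mz, tol)
}

.per_spectrum_fraction <- function(spectra, target, tol, value_name) {
  keys <- intersect(.SPECTRUM_KEYS, names(spectra))
  grouped <- dplyr::group_by(spectra, dplyr::across(dplyr::all_of(keys)))
  per <- dplyr::summarise(
    grouped,
    .value = {
      tic <- sum(intensity)
      if (tic <= 0) stop("empty spectrum in series", call. = FALSE)
      sum(intensity[abs(mz - target) <= tol]) / tic
    },
    .groups = "drop")
  avg <- dplyr::summarise(
    dplyr::group_by(per, dplyr::across(dplyr::all_of(
      setdiff(keys, "replicate")))),
    "{value_name}" := mean(.value), n_replicates = dplyr::n(),
    .groups = "drop")
  avg
}

#' Survival-Yield curve across voltages
#'
#' One SY value per voltage (replicates averaged), per peptide, sorted by
#' voltage. Duplicated (peptide, voltage, replicate) spectra are refused when
#' spectra are supplied as a list (see [bind_spectra()]).
#'
#' @param spectra Long spectrum tibble, or a list of spectrum tibbles.
#' @param precursor_mz Precursor m/z; defaults to the per-spectrum column.
#' @param tol Matching half-window in Th.
#' @return `sy_curve` tibble: `peptide_id`, `voltage`, `sy`, `n_replicates`.
#' @export
sy_curve <- function(spectra, precursor_mz = NULL, tol = 0.05) {
  stopifnot(tol > 0)
  if (is.list(spectra) && !is.data.frame(spectra)) {
    spectra <- bind_spectra(spectra)
  }
  if (nrow(spectra) == 0L) stop("empty spectrum series", call. = FALSE)
  if (is.null(precursor_mz)) {
    out <- dplyr::group_split(dplyr::group_by(spectra, peptide_id))
    res <- dplyr::bind_rows(lapply(out, function(s) {
      pm <- s$precursor_mz[1]
      if (is.na(pm)) stop("no precursor m/z for peptide ", s$peptide_id[1],
                          call. = FALSE)
      .per_spectrum_fraction(s, pm, tol, "sy")
    }))
  } else {
    res <- .per_spectrum_fraction(spectra, precursor_mz, tol, "sy")
  }
  res <- dplyr::arrange(res, peptide_id, voltage)
  class(res) <- c("sy_curve", class(res))
  res
}

#' Breakdown curve of a fragment variable
#'
#' Per voltage (replicates averaged), the fraction of TIC within `tol` of
#' `target_mz`. A voltage where the target is absent contributes 0 — absence
#' is evidence, not missing data. With the precursor m/z as target this is
#' exactly the SY curve.
#'
#' @param spectra Long spectrum tibble or list of spectrum tibbles.
#' @param target_mz Target m/z value(s); vectorised.
#' @param tol Matching half-window in Th.
#' @return `breakdown_curve` tibble: `peptide_id`, `target_mz`, `voltage`,
#'   `fraction`, `n_replicates`.
#' @export
breakdown_curve <- function(spectra, target_mz, tol = 0.05) {
  stopifnot(tol > 0, length(target_mz) >= 1L)
  if (is.list(spectra) && !is.data.frame(spectra)) {
    spectra <- bind_spectra(spectra)
  }
  if (nrow(spectra) == 0L) stop("empty spectrum series", call. = FALSE)
  res <- dplyr::bind_rows(lapply(target_mz, function(tm) {
    out <- .per_spectrum_fraction(spectra, tm, tol, "fraction")
    out$target_mz <- tm
    out
  }))
  res <- dplyr::arrange(res[, c("peptide_id", "target_mz", "voltage",
                                "fraction", "n_replicates")],
                        peptide_id, target_mz, voltage)
  class(res) <- c("breakdown_curve", class(res))
  res
}

#' Fit a logistic depletion model to a Survival-Yield curve
#'
#' Convenience utility fitting SY(V) = 1 / (1 + exp((V - v50) / width)) per
#' peptide by nonlinear least squares. The curves themselves, not the fit,
#' are the primary result; the fit summarises curve position (v50, the
#' voltage of half depletion) and steepness.
#'
#' @param curve An `sy_curve` tibble.
#' @return Tibble with `peptide_id`, `v50`, `width`.
#' @export
fit_depletion <- function(curve) {
  dplyr::bind_rows(lapply(split(curve, curve$peptide_id), function(d) {
    fit <- try(stats::nls(sy ~ 1 / (1 + exp((voltage - v50) / w)),
                          data = d,
                          start = list(v50 = stats::median(d$voltage), w = 3)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      return(tibble::tibble(peptide_id = d$peptide_id[1], v50 = NA_real_,
                            width = NA_real_))
    }
    co <- stats::coef(fit)
    tibble::tibble(peptide_id = d$peptide_id[1], v50 = unname(co["v50"]),
                   width = unname(co["w"]))
  }))
}

#' Export a curve as delimited text
#'
#' @param curve An `sy_curve` or `breakdown_curve` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
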