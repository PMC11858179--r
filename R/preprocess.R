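## Preprocessing: Savitzky-Golay smoothing + centroiding of profile spectra,
## TIC normalisation, and single-linkage alignment of centroided peaks into
## a sample x variable matrix for chemometrics.

#' Smooth a profile spectrum and centroid its peaks
#'
#' Savitzky-Golay smoothing (default 5-channel window, order-2 polynomial)
#' followed by local-maximum centroiding: contiguous regions above an
#' intensity threshold are split at interior local minima, and each segment
#' yields one peak at the intensity-weighted m/z centroid with the segment's
#' summed intensity.
#'
#' @param profile Data frame with `mz` and `intensity` columns (one profile
#'   spectrum); any spectrum-identity columns are carried through.
#' @param window Odd smoothing window length, at least `polyorder + 2`.
#' @param polyorder Polynomial order of the filter.
#' @param min_intensity Threshold as a fraction of the smoothed base peak.
#' @return Centroided spectrum tibble.
#' @export
smooth_and_centroid <- function(profile, window = 5L, polyorder = 2L,
                                min_intensity = 0.01) {
  stopifnot(window %% 2L == 1L, window >= polyorder + 2L)
  if (nrow(profile) < window) {
    stop("profile has fewer points (", nrow(profile), ") than the smoothing window",
         call. = FALSE)
  }
  o <- order(profile$mz)
  mz <- profile$mz[o]
  y <- signal::sgolayfilt(profile$intensity[o], p = polyorder, n = window)
  y[y < 0] <- 0
  thr <- min_intensity * max(y)
  meta <- profile[1, setdiff(intersect(names(profile), .SPECTRUM_META),
                             character(0)), drop = FALSE]
  if (max(y) <= 0) {
    return(dplyr::bind_cols(tibble::as_tibble(meta)[0, ],
                            tibble::tibble(mz = numeric(0),
                                           intensity = numeric(0))))
  }
  above <- y > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cent_mz <- numeric(0); cent_int <- numeric(0)
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    if (length(idx) >= 3L) {
      yi <- y[idx]
      interior <- 2:(length(idx) - 1L)
      is_min <- yi[interior] < yi[interior - 1L] & yi[interior] <= yi[interior + 1L]
      cuts <- interior[is_min]
    } else {
      cuts <- integer(0)
    }
    seg_id <- cumsum(seq_along(idx) %in% cuts)
    for (g in split(idx, seg_id)) {
      cent_mz <- c(cent_mz, stats::weighted.mean(mz[g], y[g]))
      cent_int <- c(cent_int, sum(y[g]))
    }
  }
  ord <- order(cent_mz)
  peaks <- tibble::tibble(mz = cent_mz[ord], intensity = cent_int[ord])
  if (nrow(meta) == 1L && ncol(meta) > 0) {
    peaks <- dplyr::bind_cols(
      tibble::as_tibble(meta)[rep(1L, nrow(peaks)), , drop = FALSE], peaks)
  }
  peaks
}

#' Normalise spectra to total ion current
#'
#' Divides each spectrum's intensities by their sum, so every spectrum's
#' relative abundances lie in [0, 1] and sum to 1. Relative intensities
#' (peak ratios) are unchanged. An all-zero spectrum is an error.
#'
#' @param spectra Long spectrum tibble (grouping by the spectrum-identity
#'   columns present), or a plain `mz`/`intensity` data frame treated as one
#'   spectrum.
#' @return The tibble with normalised intensities.
#' @export
tic_normalize <- function(spectra) {
  keys <- intersect(.SPECTRUM_KEYS, names(spectra))
  grouped <- dplyr::group_by(spectra, dplyr::across(dplyr::all_of(keys)))
  tots <- dplyr::summarise(grouped, .tic = sum(intensity), .groups = "drop")
  if (any(tots$.tic <= 0)) {
    stop("cannot TIC-normalise an all-zero spectrum", call. = FALSE)
  }
  out <- dplyr::ungroup(dplyr::mutate(grouped,
                                      intensity = intensity / sum(intensity)))
  attr(out, "tic_normalised") <- TRUE
  out
}

#' Align spectra into a sample-by-variable matrix
#'
#' Pools all peaks within `mz_range` and clusters them into consensus m/z
#' variables by single linkage: sorted peaks are split wherever the gap to
#' the next peak exceeds `tol`. Each variable's m/z is the intensity-weighted
#' mean of its member peaks; each spectrum contributes its summed intensity
#' per variable. Total in-range intensity per spectrum is conserved.
#'
#' @param spectra Long spectrum tibble.
#' @param mz_range Length-2 numeric: variables outside are discarded.
#' @param tol Single-linkage gap tolerance in Th.
#' @return An `aligned_spectra` object: list with `mz` (variable m/z), `x`
#'   (samples x variables intensity matrix), `meta` (per-sample identity
#'   tibble) and `normalised` flag.
#' @export
align_spectra <- function(spectra, mz_range = c(-Inf, Inf), tol = 0.02) {
  stopifnot(tol > 0, length(mz_range) == 2L, mz_range[1] < mz_range[2])
  meta_cols <- intersect(.SPECTRUM_META, names(spectra))
  meta <- dplyr::distinct(spectra[, meta_cols, drop = FALSE])
  meta <- dplyr::arrange(meta, dplyr::across(dplyr::all_of(
    intersect(.SPECTRUM_KEYS, meta_cols))))
  pk <- spectra[spectra$mz >= mz_range[1] & spectra$mz <= mz_range[2], ]
  if (nrow(pk) == 0L) {
    return(structure(list(mz = numeric(0),
                          x = matrix(0, nrow(meta), 0),
                          meta = meta,
                          normalised = isTRUE(attr(spectra, "tic_normalised"))),
                     class = "aligned_spectra"))
  }
  o <- order(pk$mz)
  pk <- pk[o, ]
  newgrp <- c(TRUE, diff(pk$mz) > tol)
  cl <- cumsum(newgrp)
  var_mz <- vapply(split(seq_len(nrow(pk)), cl), function(i) {
    stats::weighted.mean(pk$mz[i], pmax(pk$intensity[i], .Machine$double.eps))
  }, numeric(1))
  key_cols <- intersect(.SPECTRUM_KEYS, meta_cols)
  sample_key <- function(df) {
    do.call(paste, c(df[key_cols], sep = "\r"))
  }
  row_id <- match(sample_key(pk), sample_key(meta))
  x <- matrix(0, nrow = nrow(meta), ncol = length(var_mz))
  ind <- cbind(row_id, cl)
  agg <- tapply(pk$intensity, list(row_id, cl), sum)
  x[cbind(rep(as.integer(rownames(agg)), ncol(agg)),
          rep(as.integer(colnames(agg)), each = nrow(agg)))] <-
    ifelse(is.na(as.vector(agg)), 0, as.vector(agg))
  structure(list(mz = unname(var_mz), x = x, meta = meta,
                 normalised = isTRUE(attr(spectra, "tic_normalised"))),
            class = "aligned_spectra")
}

#' Restrict an aligned matrix to an m/z window
#'
#' Keeps variables with `lo <= mz <= hi`. Rows are deliberately *not*
#' re-normalised: TIC normalisation refers to the full spectrum, and the
#' loading-magnitude/abundance relationship depends on keeping that scale.
#'
#' @param aligned An `aligned_spectra` object.
#' @param lo,hi Window bounds in Th.
#' @return An `aligned_spectra` object.
#' @export
restrict_range <- function(aligned, lo, hi) {
  stopifnot(inherits(aligned, "aligned_spectra"), lo < hi)
  keep <- aligned$mz >= lo & aligned$mz <= hi
  if (!any(keep)) stop("no variables within [", lo, ", ", hi, "]", call. = FALSE)
  aligned$mz <- aligned$mz[keep]
  aligned$x <- aligned$x[, keep, drop = FALSE]
  aligned
}

#' @export
print.aligned_spectra <- function(x, ...) {
  cat("aligned_spectra: ", nrow(x$x), " spectra x ", length(x$mz),
      " m/z variables", if (x$normalised) " (TIC-normalised)", "\n", sep = "")
  invisible(x)
}

#' Long-format view of an aligned matrix
#'
#' @param x An `aligned_spectra` object.
#' @param ... Unused.
#' @return Tibble with sample identity columns, `mz` and `intensity`.
#' @importFrom tibble as_tibble
#' @method as_tibble aligned_spectra
#' @export
as_tibble.aligned_spectra <- function(x, ...) {
  long <- tidyr::crossing(dplyr::mutate(x$meta, .row = dplyr::row_number()),
                          tibble::tibble(.col = seq_along(x$mz),
                                         mz = x$mz))
  long$intensity <- x$x[cbind(long$.row, long$.col)]
  dplyr::select(long, -".row", -".col")
}
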