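## Spectra live in one long tibble: one row per centroided peak, with the
## spectrum identity carried in columns (peptide_id, voltage, replicate,
## precursor_mz, precursor_charge). A "spectrum" is the subset of rows
## sharing those keys; series and whole experiments are just bigger tibbles.

.SPECTRUM_KEYS <- c("peptide_id", "voltage", "replicate")
.SPECTRUM_META <- c(.SPECTRUM_KEYS, "precursor_mz", "precursor_charge")

#' Assemble a spectrum tibble from peak vectors
#'
#' @param mz,intensity Numeric peak vectors (equal length); peaks are sorted
#'   ascending by m/z and intensities must be non-negative.
#' @param peptide_id Analyte label.
#' @param voltage Collision (acceleration) voltage in V.
#' @param replicate Replicate index.
#' @param precursor_mz,precursor_charge Precursor definition.
#' @return Long spectrum tibble.
#' @export
spectrum_tbl <- function(mz, intensity, peptide_id, voltage, replicate = 1L,
                         precursor_mz = NA_real_,
                         precursor_charge = NA_integer_) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative peak intensity", call. = FALSE)
  o <- order(mz)
  tibble::tibble(peptide_id = peptide_id, voltage = as.numeric(voltage),
                 replicate = as.integer(replicate),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge),
                 mz = mz[o], intensity = intensity[o])
}

#' Bind spectra, refusing duplicated scan identities
#'
#' @param spectra List of spectrum tibbles.
#' @return One long tibble.
#' @export
bind_spectra <- function(spectra) {
  keys <- lapply(spectra, function(s) unique(s[, .SPECTRUM_KEYS]))
  keys <- dplyr::bind_rows(keys)
  if (anyDuplicated(keys)) {
    d <- keys[duplicated(keys), ][1, ]
    stop("duplicate spectrum for peptide '", d$peptide_id, "', voltage ",
         d$voltage, " V, replicate ", d$replicate, call. = FALSE)
  }
  dplyr::bind_rows(spectra)
}

## ---- MGF -------------------------------------------------------------

.parse_title_tokens <- function(title) {
  toks <- regmatches(title, gregexpr("[A-Za-z_]+=[^ ,;]+", title))[[1]]
  if (length(toks) == 0L) return(list())
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(lapply(kv, `[`, 2L), tolower(vapply(kv, `[`, "", 1L)))
}

#' Read an MGF peak-list file
#'
#' One scan per voltage. Spectrum identity is taken from TITLE `key=value`
#' tokens (`peptide=`, `voltage=`, `replicate=`); voltage may instead come
#' from a `COLLISION_ENERGY=` line. A scan without a resolvable voltage or
#' peptide label is an error — metadata is never silently defaulted.
#'
#' @param path MGF file path.
#' @return Long spectrum tibble.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF (unbalanced BEGIN/END IONS): ", path, call. = FALSE)
  }
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    blk <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    hdr <- grep("^[A-Z_]+=", blk, value = TRUE)
    fields <- stats::setNames(
      sub("^[A-Z_]+=", "", hdr),
      tolower(sub("=.*$", "", hdr)))
    fget <- function(k) if (k %in% names(fields)) fields[[k]] else NULL
    toks <- .parse_title_tokens(fget("title") %||% "")
    pep <- toks$peptide
    volt <- toks$voltage %||% fget("collision_energy")
    if (is.null(pep)) {
      stop("MGF scan ", k, " (line ", starts[k],
           "): no peptide=... token in TITLE", call. = FALSE)
    }
    if (is.null(volt)) {
      stop("MGF scan ", k, " (line ", starts[k],
           "): no voltage metadata (voltage= token or COLLISION_ENERGY)",
           call. = FALSE)
    }
    rep_ <- as.integer(toks$replicate %||% 1L)
    pm <- fget("pepmass")
    pmz <- if (is.null(pm)) NA_real_
           else as.numeric(strsplit(pm, "\\s+")[[1]][1])
    ch <- fget("charge")
    z <- if (is.null(ch)) NA_integer_ else as.integer(sub("\\+$", "", ch))
    pk <- blk[grepl("^[0-9]", blk)]
    vals <- strsplit(trimws(pk), "[ \t]+")
    bad <- which(lengths(vals) < 2L)
    if (length(bad) > 0) {
      stop("MGF scan ", k, ": malformed peak line '", pk[bad[1]], "'",
           call. = FALSE)
    }
    mz <- suppressWarnings(as.numeric(vapply(vals, `[`, "", 1L)))
    it <- suppressWarnings(as.numeric(vapply(vals, `[`, "", 2L)))
    if (anyNA(mz) || anyNA(it)) {
      stop("MGF scan ", k, ": non-numeric peak values", call. = FALSE)
    }
    out[[k]] <- spectrum_tbl(mz, it, pep, as.numeric(volt), rep_, pmz, z)
  }
  bind_spectra(out)
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: one scan per spectrum, identity encoded as TITLE
#' `key=value` tokens.
#'
#' @param spectra Long spectrum tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  grp <- dplyr::group_split(dplyr::group_by(
    spectra, dplyr::across(dplyr::all_of(.SPECTRUM_KEYS))))
  for (s in grp) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=peptide=%s voltage=%s replicate=%d",
                       s$peptide_id[1], format(s$voltage[1]),
                       s$replicate[1]), con)
    if (!is.na(s$precursor_mz[1])) {
      writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz[1]), con)
    }
    if (!is.na(s$precursor_charge[1])) {
      writeLines(sprintf("CHARGE=%d+", s$precursor_charge[1]), con)
    }
    writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

## ---- delimited peak lists -------------------------------------------

#' Read a delimited peak list with a metadata sidecar
#'
#' The peak list is a two-column delimited file with a header naming `mz` and
#' `intensity`. Metadata comes from `meta`: either a named list / one-row
#' data frame, or the path of a sidecar delimited file with columns
#' `peptide_id`, `voltage` and optionally `replicate`, `precursor_mz`,
#' `precursor_charge`. Missing peptide or voltage metadata is an error.
#'
#' @param path Peak-list file.
#' @param meta Metadata (see above).
#' @param sep Field separator (default `","`).
#' @return Long spectrum tibble (one spectrum).
#' @export
read_peaklist <- function(path, meta, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df))) {
    stop("peak list ", path, " must have a header with columns mz,intensity",
         call. = FALSE)
  }
  if (is.character(meta) && length(meta) == 1L) {
    meta <- utils::read.table(meta, sep = sep, header = TRUE,
                              stringsAsFactors = FALSE)
  }
  meta <- as.list(tibble::as_tibble(meta)[1, ])
  if (is.null(meta$peptide_id) || is.null(meta$voltage)) {
    stop("metadata must provide peptide_id and voltage", call. = FALSE)
  }
  spectrum_tbl(df$mz, df$intensity, meta$peptide_id, meta$voltage,
               meta$replicate %||% 1L, meta$precursor_mz %||% NA_real_,
               meta$precursor_charge %||% NA_integer_)
}

## ---- mzML (via mzR) --------------------------------------------------

#' Read MS/MS spectra from an mzML file
#'
#' Uses the Bioconductor `mzR` backend. Voltage is taken from the standard
#' collision-energy annotation; MS2 scans without one are an error.
#'
#' @param path mzML file.
#' @param peptide_id Analyte label (default: file name without extension).
#' @param replicate Replicate index applied to all scans.
#' @return Long spectrum tibble.
#' @export
read_mzml <- function(path, peptide_id = NULL, replicate = 1L) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(peptide_id)) {
    peptide_id <- sub("\\.[^.]+$", "", basename(path))
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  h <- mzR::header(fh)
  h <- h[h$msLevel == 2L, , drop = FALSE]
  if (nrow(h) == 0L) stop("no MS2 scans in ", path, call. = FALSE)
  ce <- h$collisionEnergy
  if (is.null(ce) || anyNA(ce)) {
    stop("mzML ", path, ": MS2 scan without collision-energy annotation",
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(h)), function(i) {
    pk <- mzR::peaks(fh, h$seqNum[i])
    spectrum_tbl(pk[, 1], pk[, 2], peptide_id, ce[i], replicate,
                 h$precursorMZ[i], h$precursorCharge[i])
  })
  bind_spectra(out)
}

#' Read spectra, dispatching on format
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"mgf"`, `"mzml"` or `"csv"`.
#' @param ... Passed to the format-specific reader.
#' @return Long spectrum tibble.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml", "csv"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub("^.*\\.", "", path))
    format <- switch(ext, mgf = "mgf", mzml = "mzml", csv = "csv",
                     stop("cannot infer format from extension '.", ext, "'",
                          call. = FALSE))
  }
  switch(format,
         mgf = read_mgf(path),
         mzml = read_mzml(path, ...),
         csv = read_peaklist(path, ...))
}
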