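## Peak annotation: match observed centroids against a theoretical fragment
## catalogue and render human-readable assignments.

#' Annotate a spectrum against a fragment catalogue
#'
#' Each observed peak is matched to the catalogue entry minimising |delta
#' m/z| within the tolerance. When two candidates are equidistant the least
#' exotic explanation wins: fewer total neutral losses first, then kind
#' priority (precursor/conventional b,y over internal over scrambled), then
#' the lower charge. Unmatched peaks are omitted. Annotation is
#' deterministic and independent of peak or catalogue order.
#'
#' @param spectrum Peak tibble (`mz`, `intensity`, identity columns kept).
#' @param catalogue A `fragment_catalogue`.
#' @param tol Tolerance value.
#' @param tol_mode `"absolute"` (Th, default) or `"ppm"`.
#' @param all_matches If `TRUE`, return every candidate within tolerance per
#'   peak, not just the best.
#' @return Annotation tibble: `observed_mz`, `intensity`, theoretical `mz`,
#'   `error_mth` (mTh), `error_ppm`, `kind`, `charge`, `label`, `losses`.
#' @export
annotate_spectrum <- function(spectrum, catalogue, tol = 0.02,
                              tol_mode = c("absolute", "ppm"),
                              all_matches = FALSE) {
  tol_mode <- match.arg(tol_mode)
  stopifnot(tol > 0)
  kind_priority <- c(precursor = 1L, b = 1L, y = 1L, internal_b = 2L,
                     scrambled_b = 3L)
  cat_ord <- order(catalogue$mz)
  cmz <- catalogue$mz[cat_ord]
  n_loss <- lengths(catalogue$losses)[cat_ord]
  prio <- kind_priority[catalogue$kind][cat_ord]
  chg <- catalogue$charge[cat_ord]

  rows <- lapply(seq_len(nrow(spectrum)), function(i) {
    m <- spectrum$mz[i]
    lim <- if (tol_mode == "absolute") tol else m * tol * 1e-6
    d <- abs(cmz - m)
    hit <- which(d <= lim)
    if (length(hit) == 0L) return(NULL)
    if (!all_matches) {
      o <- hit[order(d[hit], n_loss[hit], prio[hit], chg[hit])]
      hit <- o[1]
    }
    ci <- cat_ord[hit]
    tibble::tibble(observed_mz = m, intensity = spectrum$intensity[i],
                   mz = catalogue$mz[ci],
                   error_mth = (m - catalogue$mz[ci]) * 1e3,
                   error_ppm = (m - catalogue$mz[ci]) / catalogue$mz[ci] * 1e6,
                   kind = catalogue$kind[ci], charge = catalogue$charge[ci],
                   label = catalogue$label[ci],
                   losses = catalogue$losses[ci])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(observed_mz = numeric(0), intensity = numeric(0),
                          mz = numeric(0), error_mth = numeric(0),
                          error_ppm = numeric(0), kind = character(0),
                          charge = integer(0), label = character(0),
                          losses = list())
  }
  out
}

#' Export annotations as delimited text
#'
#' @param annotations Annotation tibble from [annotate_spectrum()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  out <- as.data.frame(annotations[, setdiff(names(annotations), "losses")])
  out$losses <- vapply(annotations$losses, paste, character(1), collapse = "+")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
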