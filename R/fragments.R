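## Enumeration of theoretical fragment ions: conventional b/y ladders,
## combinatorial neutral-loss series, and scrambled/internal b ions from
## head-to-tail macrocyclisation of the b_n ion followed by reopening at any
## amide bond. Indexing is 1-based: b_i holds the first i residues, y_j the
## last j.

#' Enumerate conventional b and y ions
#'
#' Emits b_i for i = 1..n (b_n, the water-deficient full-length ion, is a
#' genuine CID product of arginine-rich peptides) and y_j for j = 1..n-1, at
#' every charge from 1 to `max_charge`.
#'
#' @param seq Peptide sequence (string or residue-code vector).
#' @param max_charge Highest charge state to emit.
#' @param table Residue table.
#' @return Ion tibble with an `mz` column.
#' @examples
#' enumerate_conventional("bA-HGRKKRRQRRRPS", max_charge = 2)
#' @export
enumerate_conventional <- function(seq, max_charge = 2L,
                                   table = residue_table()) {
  stopifnot(max_charge >= 1L)
  codes <- parse_peptide(seq, table)
  n <- length(codes)
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <-
      tibble::tibble(kind = "b", residues = list(codes[seq_len(i)]),
                     base = paste0("b", i),
                     provenance = NA_character_)
  }
  for (j in seq_len(max(n - 1L, 0L))) {
    rows[[length(rows) + 1L]] <-
      tibble::tibble(kind = "y", residues = list(codes[(n - j + 1L):n]),
                     base = paste0("y", j),
                     provenance = NA_character_)
  }
  ions <- dplyr::bind_rows(rows)
  ions <- tidyr::crossing(ions, charge = seq_len(max_charge))
  ions$losses <- rep(list(character(0)), nrow(ions))
  ion_mz(ions[, c("kind", "residues", "charge", "losses", "base", "provenance")],
         table)
}

#' Enumerate scrambled and internal b ions from macrocycle reopening
#'
#' Models the scrambling pathway: the full-length b ion cyclises head-to-tail
#' and the macrocycle reopens at any amide bond, so every contiguous substring
#' of the *cyclic* sequence becomes a b-type ion. Full-length rotations are
#' `kind = "scrambled_b"`; shorter spans are `kind = "internal_b"`. Provenance
#' records the (start, length) span on the cyclic sequence. The model is
#' purely combinatorial — it contains every reopening, with no energetic
#' weighting.
#'
#' @inheritParams enumerate_conventional
#' @param min_length Shortest span emitted (default 2; single-residue acylium
#'   ions are excluded).
#' @return Ion tibble with an `mz` column.
#' @examples
#' sc <- enumerate_scrambled("GRKKRRQ-bA-H-RRRPS", max_charge = 2)
#' sc[sc$base == "bs(RRRPSGRKKRRQ)", ]
#' @export
enumerate_scrambled <- function(seq, max_charge = 2L, min_length = 2L,
                                table = residue_table()) {
  codes <- parse_peptide(seq, table)
  n <- length(codes)
  if (n < 3L) stop("scrambling needs a sequence of length >= 3", call. = FALSE)
  stopifnot(max_charge >= 1L, min_length >= 1L, min_length <= n)
  cyc <- c(codes, codes)
  spans <- expand.grid(start = seq_len(n), len = min_length:n)
  res <- lapply(seq_len(nrow(spans)), function(k) {
    cyc[spans$start[k]:(spans$start[k] + spans$len[k] - 1L)]
  })
  full <- spans$len == n
  ions <- tibble::tibble(
    kind = ifelse(full, "scrambled_b", "internal_b"),
    residues = res,
    base = ifelse(full,
                  paste0("bs(", vapply(res, codes_to_string, character(1)), ")"),
                  paste0("int(", vapply(res, codes_to_string, character(1)), ")")),
    provenance = sprintf("cyclic span start=%d len=%d", spans$start, spans$len)
  )
  ions <- tidyr::crossing(ions, charge = seq_len(max_charge))
  ions$losses <- rep(list(character(0)), nrow(ions))
  ion_mz(ions[, c("kind", "residues", "charge", "losses", "base", "provenance")],
         table)
}

#' Default per-loss caps for a neutral-loss series
#'
#' Ammonia up to 4 and water up to 2 per ion; carbodiimide and guanidine are
#' shed from arginine side-chain termini, so each is capped by the number of
#' arginines the ion contains.
#'
#' @param residues Residue codes of the base ion.
#' @return Named integer vector of caps for the default loss catalogue.
#' @export
default_loss_caps <- function(residues) {
  n_arg <- sum(residues == "R")
  c(ammonia = 4L, water = 2L, carbodiimide = n_arg, guanidine = n_arg)
}

## all loss-count multisets (as a data frame of counts) respecting caps and
## 1 <= total <= max_total, for the given catalogue names
.loss_multisets <- function(names, caps, max_total) {
  grids <- lapply(names, function(nm) {
    0:min(caps[[nm]] %||% max_total, max_total)
  })
  names(grids) <- names
  g <- expand.grid(grids)
  tot <- rowSums(g)
  g <- g[tot >= 1L & tot <= max_total, , drop = FALSE]
  g
}

`%||%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
}

#' Expand ions by consecutive neutral losses
#'
#' CID of arginine-rich peptides proceeds by consecutive neutral losses — the
#' same small molecule can leave several times. For each base ion this emits
#' every multiset of losses of total size 1..`max_total` respecting per-loss
#' caps; combinations exceeding a cap (or the fragment's own mass) are
#' silently excluded. m/z strictly decreases with every added loss.
#'
#' @param base Ion tibble of base ions (with or without prior losses).
#' @param loss_catalogue Neutral-loss catalogue to draw from.
#' @param max_total Maximum total number of losses added per ion.
#' @param caps Named integer vector of per-loss maxima; `NULL` uses
#'   [default_loss_caps()] per ion.
#' @param table Residue table.
#' @return Ion tibble of the loss-bearing ions (the bases are not repeated).
#' @examples
#' prec <- ion_spec("precursor", "GRKKRRQRRRPS-bA-H", charge = 2)
#' ser <- enumerate_loss_series(prec, max_total = 2)
#' ser[vapply(ser$losses, length, 1L) == 1, c("base", "losses", "mz")]
#' @export
enumerate_loss_series <- function(base, loss_catalogue = neutral_losses(),
                                  max_total = 4L, caps = NULL,
                                  table = residue_table()) {
  stopifnot(max_total >= 0L)
  if (max_total == 0L || nrow(base) == 0L) return(base[0, ])
  base <- ion_mz(base, table, loss_catalogue)
  nms <- loss_catalogue$name
  neutral <- .ion_neutral_mass(base, table)
  prior <- .loss_mass_sum(base$losses, loss_catalogue)

  ## effective per-loss cap matrix (bases x losses); capped at max_total
  eff <- vapply(seq_len(nrow(base)), function(i) {
    ci <- if (is.null(caps)) default_loss_caps(base$residues[[i]]) else caps
    ci <- as.list(ci)
    vapply(nms, function(nm) min(ci[[nm]] %||% max_total, max_total), numeric(1))
  }, numeric(length(nms)))
  eff <- matrix(eff, ncol = length(nms), byrow = TRUE,
                dimnames = list(NULL, nms))
  sig <- apply(eff, 1L, paste, collapse = ",")

  pieces <- list()
  for (s in unique(sig)) {
    grp <- which(sig == s)
    ci <- as.list(eff[grp[1], ])
    ms <- .loss_multisets(nms, ci, max_total)
    if (nrow(ms) == 0L) next
    lost <- as.numeric(as.matrix(ms) %*%
                         loss_catalogue$mass[match(names(ms), loss_catalogue$name)])
    ms_losses <- lapply(seq_len(nrow(ms)), function(k) {
      sort(rep(names(ms), times = as.integer(ms[k, ])))
    })
    bi <- rep(grp, each = nrow(ms))
    mi <- rep(seq_len(nrow(ms)), times = length(grp))
    keep <- (prior[bi] + lost[mi]) < neutral[bi]
    bi <- bi[keep]; mi <- mi[keep]
    if (length(bi) == 0L) next
    has_prior <- lengths(base$losses[bi]) > 0L
    loss_col <- ms_losses[mi]
    if (any(has_prior)) {
      loss_col[has_prior] <- mapply(function(a, b) sort(c(a, b)),
                                    base$losses[bi][has_prior],
                                    loss_col[has_prior], SIMPLIFY = FALSE)
    }
    stem <- base$base[bi]; prov <- base$provenance[bi]
    z <- base$charge[bi]
    mz_new <- (neutral[bi] - prior[bi] - lost[mi] + z * PROTON_MASS) / z
    pieces[[length(pieces) + 1L]] <- tibble::tibble(
      kind = base$kind[bi], residues = base$residues[bi],
      charge = z, losses = loss_col, base = stem, provenance = prov,
      mz = mz_new)
  }
  res <- dplyr::bind_rows(pieces)
  if (nrow(res) == 0L) return(base[0, ])
  res
}

.composition_key <- function(residues) {
  vapply(residues, function(r) {
    paste(sort.int(r, method = "radix"), collapse = "")
  }, character(1))
}

.loss_key <- function(losses) {
  vapply(losses, paste, character(1), collapse = "+")
}

#' Build the full theoretical fragment catalogue for a peptide
#'
#' Union of the precursor, conventional b/y ions, scrambled/internal b ions
#' (optional) and the neutral-loss expansion of every base ion. Entries are
#' deduplicated by (kind, residue composition, charge, losses), so
#' mass-identical cyclic rotations collapse to one m/z row whose provenance
#' concatenates the merged spans. Sorted by m/z.
#'
#' @inheritParams enumerate_conventional
#' @param loss_catalogue Neutral-loss catalogue.
#' @param max_total Maximum total losses per ion (see
#'   [enumerate_loss_series()]).
#' @param caps Per-loss caps, `NULL` for content-dependent defaults.
#' @param scrambling Include scrambled/internal ions from macrocycle
#'   reopening.
#' @param internal Keep internal (shorter-than-full) spans of the macrocycle;
#'   ignored when `scrambling = FALSE`.
#' @param min_length Shortest internal span.
#' @param peptide_id Label stored on the catalogue.
#' @return A `fragment_catalogue`: an ion tibble (with `mz` and `label`
#'   columns) carrying the peptide and generation settings as attributes.
#' @examples
#' cat <- build_catalogue("GRKKRRQRRRPS-bA-H", max_total = 2)
#' head(cat)
#' @export
build_catalogue <- function(seq, max_charge = 2L,
                            loss_catalogue = neutral_losses(),
                            max_total = 4L, caps = NULL, scrambling = TRUE,
                            internal = TRUE, min_length = 2L,
                            table = residue_table(), peptide_id = NULL) {
  codes <- parse_peptide(seq, table)
  prec <- dplyr::bind_rows(lapply(seq_len(max_charge), function(z) {
    ion_spec("precursor", codes, charge = z)
  }))
  bases <- dplyr::bind_rows(
    ion_mz(prec, table, loss_catalogue),
    enumerate_conventional(codes, max_charge, table)
  )
  if (scrambling) {
    sc <- enumerate_scrambled(codes, max_charge, min_length, table)
    if (!internal) sc <- sc[sc$kind == "scrambled_b", ]
    bases <- dplyr::bind_rows(bases, sc)
  }
  ions <- dplyr::bind_rows(
    bases,
    enumerate_loss_series(bases, loss_catalogue, max_total, caps, table)
  )
  key <- paste(ions$kind, .composition_key(ions$residues), ions$charge,
               .loss_key(ions$losses), sep = "|")
  first <- !duplicated(key)
  prov_split <- split(ions$provenance, factor(key, levels = key[first]))
  merged_prov <- vapply(prov_split, function(p) {
    p <- unique(p[!is.na(p)])
    if (length(p) == 0L) NA_character_ else paste(p, collapse = "; ")
  }, character(1))
  ions <- ions[first, ]
  ions$provenance <- unname(merged_prov)
  ions <- ions[order(ions$mz), ]
  ions$label <- ion_label(ions, loss_catalogue)
  structure(ions,
            class = c("fragment_catalogue", "tbl_df", "tbl", "data.frame"),
            peptide = codes,
            peptide_id = peptide_id %||% codes_to_string(codes),
            config = list(max_charge = max_charge, max_total = max_total,
                          scrambling = scrambling, internal = internal,
                          min_length = min_length))
}

#' Export a fragment catalogue as delimited text
#'
#' Writes label, kind, charge, losses and m/z as a tab-separated table usable
#' as an inclusion or annotation list.
#'
#' @param cat A `fragment_catalogue`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(cat, path) {
  out <- data.frame(label = cat$label, kind = cat$kind,
                    sequence = vapply(cat$residues, codes_to_string, character(1)),
                    charge = cat$charge,
                    losses = .loss_key(cat$losses),
                    mz = cat$mz)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
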