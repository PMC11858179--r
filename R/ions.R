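## Theoretical ions are rows of a tibble: kind, residues (list-column of
## residue codes), charge, losses (list-column: multiset of loss names),
## base (display stem, e.g. "b2", "y12", "M"), provenance (free text).

.ION_KINDS <- c("precursor", "b", "y", "internal_b", "scrambled_b")

#' Construct a theoretical ion
#'
#' @param kind One of `"precursor"`, `"b"`, `"y"`, `"internal_b"`,
#'   `"scrambled_b"`. b-type ions (including internal and scrambled) weigh the
#'   sum of their residue masses; y ions and the precursor add one water.
#' @param residues Residue codes composing the ion (character vector or
#'   sequence string parsed with [parse_peptide()]).
#' @param charge Positive integer charge.
#' @param losses Character vector naming neutral losses, with repeats for
#'   multiple losses of the same molecule (a multiset).
#' @param base Display stem used in labels; derived from `kind` if omitted.
#' @param provenance Free-text origin (e.g. the cyclic span that produced a
#'   scrambled ion).
#' @return One-row ion tibble.
#' @examples
#' ion_spec("b", c("bA", "H"), charge = 1)
#' @export
ion_spec <- function(kind, residues, charge = 1L, losses = character(),
                     base = NULL, provenance = NA_character_) {
  kind <- match.arg(kind, .ION_KINDS)
  if (is.character(residues) && length(residues) == 1L) {
    residues <- parse_peptide(residues)
  }
  stopifnot(length(residues) >= 1L, charge >= 1L)
  if (is.null(base)) {
    base <- switch(kind,
      precursor = "M",
      b = paste0("b", length(residues)),
      y = paste0("y", length(residues)),
      internal_b = paste0("int(", codes_to_string(residues), ")"),
      scrambled_b = paste0("bs(", codes_to_string(residues), ")"))
  }
  tibble::tibble(kind = kind, residues = list(residues),
                 charge = as.integer(charge), losses = list(sort(losses)),
                 base = base, provenance = provenance)
}

#' Render residue codes as a compact sequence string
#'
#' Multi-character codes are bracketed, so the string re-parses unambiguously
#' with [parse_peptide()].
#' @param codes Character vector of residue codes.
#' @return Single string.
#' @export
codes_to_string <- function(codes) {
  paste(ifelse(nchar(codes) > 1L, paste0("[", codes, "]"), codes),
        collapse = "")
}

## neutral fragment mass before losses, vectorised over an ion tibble
.ion_neutral_mass <- function(ions, table = residue_table()) {
  lut <- stats::setNames(table$mass, table$code)
  base <- vapply(ions$residues, function(r) sum(lut[r]), numeric(1))
  water <- ifelse(ions$kind %in% c("y", "precursor"), formula_mass("H2O"), 0)
  base + water
}

.loss_mass_sum <- function(losses, catalogue = neutral_losses()) {
  lut <- stats::setNames(catalogue$mass, catalogue$name)
  vapply(losses, function(l) {
    if (length(l) == 0L) return(0)
    unknown <- setdiff(l, names(lut))
    if (length(unknown) > 0) {
      stop("unknown neutral loss: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    sum(lut[l])
  }, numeric(1))
}

#' Compute m/z for theoretical ions
#'
#' m/z = (neutral fragment mass - sum of neutral-loss masses +
#' z * proton mass) / z, with the proton at 1.007276 Da.
#'
#' @param ions Ion tibble (from [ion_spec()] or the enumeration functions).
#' @param table Residue table.
#' @param loss_catalogue Neutral-loss catalogue resolving loss names.
#' @return The input tibble with an `mz` column added (replaced if present).
#' @examples
#' ion_mz(ion_spec("precursor", "GRKKRRQRRRPS-bA-H", charge = 2))$mz
#' @export
ion_mz <- function(ions, table = residue_table(),
                   loss_catalogue = neutral_losses()) {
  stopifnot(all(ions$charge >= 1L))
  neutral <- .ion_neutral_mass(ions, table)
  lost <- .loss_mass_sum(ions$losses, loss_catalogue)
  if (any(lost >= neutral)) {
    bad <- which(lost >= neutral)[1]
    stop("non-physical ion: losses (", round(lost[bad], 4),
         " Da) exceed fragment mass (", round(neutral[bad], 4), " Da) for ",
         ions$base[bad], call. = FALSE)
  }
  ions$mz <- (neutral - lost + ions$charge * PROTON_MASS) / ions$charge
  ions
}

#' m/z shift caused by a neutral loss on a charged ion
#'
#' On a z-charged ion the loss of a neutral of mass m shifts m/z by -m/z; on
#' doubly charged ions loss masses are effectively halved (ammonia at z = 2
#' shifts by -17.0265/2 = -8.51).
#'
#' @param loss Loss name (resolved in `loss_catalogue`) or a numeric neutral
#'   mass in Da.
#' @param charge Positive integer charge.
#' @param loss_catalogue Neutral-loss catalogue.
#' @return Signed (negative) m/z shift in Th; vectorised over `loss`.
#' @examples
#' delta_mz("ammonia", 2)
#' delta_mz("guanidine", 2)
#' @export
delta_mz <- function(loss, charge, loss_catalogue = neutral_losses()) {
  stopifnot(all(charge >= 1L))
  if (is.character(loss)) {
    i <- match(loss, loss_catalogue$name)
    if (anyNA(i)) {
      stop("unknown neutral loss: ", paste(loss[is.na(i)], collapse = ", "),
           call. = FALSE)
    }
    loss <- loss_catalogue$mass[i]
  }
  -loss / charge
}

#' Render ion labels
#'
#' Labels follow the conventional bracket notation, e.g. `"[y12-H2O-NH3]2+"`
#' or `"[bs(RRRPSGRKKRRQ)-H2O]2+"`; repeated losses collapse to a count
#' (`"-2NH3"`). Losses are shown by formula when the catalogue provides one.
#'
#' @param ions Ion tibble.
#' @param loss_catalogue Neutral-loss catalogue (for name -> formula display).
#' @return Character vector of labels.
#' @export
ion_label <- function(ions, loss_catalogue = neutral_losses()) {
  fml <- stats::setNames(loss_catalogue$formula, loss_catalogue$name)
  base <- ifelse(ions$kind == "precursor",
                 paste0("M+", ions$charge, "H"), ions$base)
  losspart <- vapply(ions$losses, function(l) {
    if (length(l) == 0L) return("")
    disp <- ifelse(!is.na(fml[l]) & nzchar(fml[l]), fml[l], unname(l))
    r <- rle(sort.int(disp, method = "radix"))
    paste0("-", ifelse(r$lengths > 1L, paste0(r$lengths, r$values), r$values),
           collapse = "")
  }, character(1))
  paste0("[", base, losspart, "]", ions$charge, "+")
}

#' Parse an ion label back to kind, charge and losses
#'
#' Inverse of [ion_label()] for the fields a label encodes: the ion kind, the
#' charge state and the neutral-loss multiset. Residue content is recovered
#' from the base stem where it is explicit (internal/scrambled ions).
#'
#' @param label Single label string.
#' @param loss_catalogue Neutral-loss catalogue (formula -> name).
#' @return List with elements `kind`, `base`, `charge`, `losses`.
#' @export
parse_ion_label <- function(label, loss_catalogue = neutral_losses()) {
  m <- regmatches(label, regexec("^\\[([^]]+)\\](\\d+)\\+$", label))[[1]]
  if (length(m) != 3L) stop("cannot parse ion label: ", label, call. = FALSE)
  charge <- as.integer(m[3])
  parts <- strsplit(m[2], "-", fixed = TRUE)[[1]]
  base <- parts[1]
  kind <- if (grepl("^M\\+", base)) "precursor"
          else if (grepl("^bs\\(", base)) "scrambled_b"
          else if (grepl("^int\\(", base)) "internal_b"
          else if (grepl("^b\\d+$", base)) "b"
          else if (grepl("^y\\d+$", base)) "y"
          else stop("unrecognised ion stem: ", base, call. = FALSE)
  name_of <- stats::setNames(loss_catalogue$name, loss_catalogue$formula)
  losses <- character(0)
  for (p in parts[-1]) {
    mm <- regmatches(p, regexec("^(\\d*)(.+)$", p))[[1]]
    k <- if (nzchar(mm[2])) as.integer(mm[2]) else 1L
    nm <- if (mm[3] %in% names(name_of)) name_of[[mm[3]]] else mm[3]
    losses <- c(losses, rep(nm, k))
  }
  list(kind = kind, base = if (kind == "precursor") "M" else base,
       charge = charge, losses = sort(losses))
}
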