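## Monoisotopic atomic masses (IUPAC/CODATA-derived, 7 dp). Only the elements
## occurring in peptides and their common neutral losses are tabulated; an
## unknown symbol is an error, never a silent zero.
.element_masses <- c(
  H = 1.0078250,
  C = 12.0000000,
  N = 14.0030740,
  O = 15.9949146,
  S = 31.9720707,
  P = 30.9737615,
  Se = 79.9165218
)

#' Mass of a proton in Da, used for all charge-state arithmetic.
#' @export
PROTON_MASS <- 1.007276

#' Parse a molecular formula string
#'
#' Converts a Hill-style formula such as `"C72H133N37O17"` into a named
#' integer vector of element counts. An empty string is the empty formula.
#'
#' @param x A single formula string, or an already-parsed named numeric vector
#'   (returned unchanged after validation).
#' @return Named integer vector of non-negative element counts.
#' @examples
#' parse_formula("H2O")
#' parse_formula("CH2N2")
#' @export
parse_formula <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x)) && length(x) > 0) {
      stop("numeric formula must be a named element -> count vector", call. = FALSE)
    }
    if (any(x < 0)) stop("element counts must be non-negative", call. = FALSE)
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub("\\s", "", x)
  if (!nzchar(x)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  tokens <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula: '", x, "'", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", tokens)
  ct <- as.numeric(ifelse(grepl("[0-9]+$", tokens),
                          sub("^[A-Za-z]+", "", tokens), "1"))
  out <- tapply(ct, el, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Formula string or named element-count vector
#'   (see [parse_formula()]).
#' @return Monoisotopic mass in Da. The empty formula has mass 0.
#' @examples
#' formula_mass("H2O")
#' formula_mass("C72H133N37O17")
#' @export
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (length(counts) == 0L) return(0)
  unknown <- setdiff(names(counts), names(.element_masses))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(counts * .element_masses[names(counts)])
}

## residue formulas: the 20 standard residues plus beta-alanine ("bA"),
## a non-proteinogenic residue mass-identical to alanine.
.residue_formulas <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O",
  bA = "C3H5NO"
)

#' Residue mass table
#'
#' Monoisotopic residue masses and elemental compositions for the 20 standard
#' amino acids plus beta-alanine (code `"bA"`, composition C3H5NO — the
#' residue found in carnosine, mass-identical to alanine). Masses are computed
#' from the compositions, so the two representations cannot drift apart.
#'
#' @param extra Optional tibble/data frame of additional residues with columns
#'   `code` and `formula` (masses are derived) or `code` and `mass`.
#' @return A tibble with columns `code`, `formula`, `mass` (Da).
#' @examples
#' residue_table()
#' @export
residue_table <- function(extra = NULL) {
  tab <- tibble::tibble(
    code = names(.residue_formulas),
    formula = unname(.residue_formulas),
    mass = vapply(.residue_formulas, formula_mass, numeric(1), USE.NAMES = FALSE)
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    if (!"code" %in% names(extra)) stop("extra residues need a 'code' column", call. = FALSE)
    if (!"mass" %in% names(extra)) {
      if (!"formula" %in% names(extra)) {
        stop("extra residues need a 'formula' or 'mass' column", call. = FALSE)
      }
      extra$mass <- vapply(extra$formula, formula_mass, numeric(1))
    }
    if (!"formula" %in% names(extra)) extra$formula <- NA_character_
    tab <- dplyr::bind_rows(tab[!tab$code %in% extra$code, ],
                            extra[, c("code", "formula", "mass")])
  }
  tab
}

## default neutral-loss catalogue. Masses are the 4-dp literature values;
## each agrees with its formula-derived mass within 1e-4 Da (tested).
.loss_defaults <- tibble::tibble(
  name = c("ammonia", "water", "carbodiimide", "guanidine"),
  formula = c("NH3", "H2O", "CH2N2", "CH5N3"),
  mass = c(17.0265, 18.0105, 42.0218, 59.0483)
)

#' Neutral-loss catalogue
#'
#' The small neutral molecules lost during CID of arginine-rich peptides:
#' ammonia and water, plus carbodiimide (CH2N2) and guanidine (CH5N3), both
#' shed from arginine side-chain termini. On a z-charged ion each loss shifts
#' m/z by -mass/z, so on doubly charged ions the shifts are halved.
#'
#' @param extra Optional tibble of additional losses with columns `name` and
#'   `formula` (mass derived) or `name` and `mass`.
#' @return Tibble with columns `name`, `formula`, `mass` (Da).
#' @examples
#' neutral_losses()
#' @export
neutral_losses <- function(extra = NULL) {
  tab <- .loss_defaults
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    if (!"name" %in% names(extra)) stop("extra losses need a 'name' column", call. = FALSE)
    if (!"mass" %in% names(extra)) {
      extra$mass <- vapply(extra$formula, formula_mass, numeric(1))
    }
    if (!"formula" %in% names(extra)) extra$formula <- NA_character_
    tab <- dplyr::bind_rows(tab[!tab$name %in% extra$name, ],
                            extra[, c("name", "formula", "mass")])
  }
  tab
}

#' Parse a peptide sequence with multi-character residue codes
#'
#' Single-letter runs are split into individual residues; hyphen- or
#' bracket-delimited tokens name multi-character codes, so
#' `"GRKKRRQRRRPS-bA-H"` and `"GRKKRRQ[bA]HRRRPS"` both parse. The aliases
#' `"betaAla"` and `"bAla"` map to `"bA"`.
#'
#' @param seq Sequence string, or a character vector already split into codes
#'   (validated and returned as-is).
#' @param table Residue table, see [residue_table()].
#' @return Character vector of residue codes.
#' @examples
#' parse_peptide("GRKKRRQRRRPS-bA-H")
#' parse_peptide("bA-HGRKKRRQRRRPS")
#' @export
parse_peptide <- function(seq, table = residue_table()) {
  if (length(seq) > 1L) {
    codes <- seq
  } else {
    stopifnot(is.character(seq), nzchar(seq))
    s <- gsub("\\[([^]]+)\\]", "-\\1-", seq)    # bracket tokens -> hyphen tokens
    segs <- strsplit(s, "-", fixed = TRUE)[[1]]
    segs <- segs[nzchar(segs)]
    segs[segs %in% c("betaAla", "bAla")] <- "bA"
    codes <- unlist(lapply(segs, function(seg) {
      if (seg %in% table$code) return(seg)
      strsplit(seg, "")[[1]]
    }))
  }
  codes[codes %in% c("betaAla", "bAla")] <- "bA"
  bad <- which(!codes %in% table$code)
  if (length(bad) > 0) {
    stop("unresolvable residue code '", codes[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  }
  if (length(codes) == 0L) stop("empty peptide sequence", call. = FALSE)
  codes
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water (the intact, non-fragment molecule).
#' Because mass is determined by residue composition alone, sequence isomers
#' (such as the three carnosine-TAT1 conjugates) share one mass.
#'
#' @inheritParams parse_peptide
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mass("GRKKRRQRRRPS-bA-H")
#' peptide_mass("G")
#' @export
peptide_mass <- function(seq, table = residue_table()) {
  codes <- parse_peptide(seq, table)
  masses <- table$mass[match(codes, table$code)]
  sum(masses) + formula_mass("H2O")
}

#' Write / read a residue or neutral-loss table as delimited text
#'
#' Tab-separated with a header, so users can extend the residue alphabet or
#' the loss catalogue outside R and read it back with the `extra` argument of
#' [residue_table()] / [neutral_losses()].
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `write_mass_table()` returns `path` invisibly; `read_mass_table()`
#'   returns a tibble.
#' @export
write_mass_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mass_table
#' @export
read_mass_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' Built-in sequences of the three isomeric carnosine-TAT1 peptides
#'
#' TAT1 is the arginine-rich cell-penetrating peptide GRKKRRQRRRPS; carnosine
#' (beta-alanyl-histidine) is grafted at the C-terminus (TAT1-Car), the
#' N-terminus (Car-TAT1) or mid-sequence (T-Car-T). The three are sequence
#' isomers with identical monoisotopic mass.
#'
#' @return Named character vector of sequence strings.
#' @examples
#' isomer_sequences()
#' @export
isomer_sequences <- function() {
  c("TAT1-Car" = "GRKKRRQRRRPS-bA-H",
    "Car-TAT1" = "bA-HGRKKRRQRRRPS",
    "T-Car-T"  = "GRKKRRQ-bA-H-RRRPS")
}
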