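## Element assignment and radii tables.
## vdW radii: Bondi (1964) with common extensions; covalent radii:
## Cordero et al. single-bond values. Both in Angstrom.

.vdwTable <- c(
  "H" = 1.20, "C" = 1.70, "N" = 1.55, "O" = 1.52, "S" = 1.80, "P" = 1.80,
  "F" = 1.47, "CL" = 1.75, "BR" = 1.85, "I" = 1.98, "SE" = 1.90, "B" = 1.92,
  "ZN" = 1.39, "FE" = 1.94, "MG" = 1.73, "CA" = 2.31, "NA" = 2.27,
  "K" = 2.75, "MN" = 1.97, "CU" = 1.40, "NI" = 1.63, "CO" = 1.95,
  "CD" = 1.58, "HG" = 1.55)

.covTable <- c(
  "H" = 0.31, "C" = 0.76, "N" = 0.71, "O" = 0.66, "S" = 1.05, "P" = 1.07,
  "F" = 0.57, "CL" = 1.02, "BR" = 1.20, "I" = 1.39, "SE" = 1.20, "B" = 0.84,
  "ZN" = 1.22, "FE" = 1.32, "MG" = 1.41, "CA" = 1.76, "NA" = 1.66,
  "K" = 2.03, "MN" = 1.39, "CU" = 1.32, "NI" = 1.24, "CO" = 1.26,
  "CD" = 1.44, "HG" = 1.32)

.vdwDefault <- 1.70
.covDefault <- 0.76

## residue names treated as water or monatomic ions: never auto-selected
## as the mobile ligand, always static
.waterNames <- c("HOH", "WAT", "DOD", "H2O", "SOL", "TIP", "TIP3", "TIP4")
.ionNames <- c("ZN", "MG", "CA", "NA", "K", "CL", "MN", "FE", "CU", "NI",
               "CO", "CD", "HG", "IOD", "BR", "SO4", "PO4", "LI", "CS")

#' Infer the chemical element of a PDB atom
#'
#' Uses the element column when present; otherwise infers from the atom
#' name: leading digits are stripped, then a two-letter symbol is accepted
#' if it is a known element and the record is HETATM or the name is
#' unambiguous, else the first alphabetic character is used.
#'
#' @param name atom name (PDB columns 13-16), character vector.
#' @param element element column (77-78), may be `NA` or empty.
#' @param hetero logical, HETATM record.
#' @return upper-case element symbols.
#' @export
inferElement <- function(name, element = NA_character_,
                         hetero = FALSE) {
  n <- max(length(name), length(element), length(hetero))
  name <- rep_len(name, n); element <- rep_len(element, n)
  hetero <- rep_len(hetero, n)
  out <- toupper(trimws(ifelse(is.na(element), "", element)))
  known2 <- names(.vdwTable)[nchar(names(.vdwTable)) == 2L]
  need <- !(out %in% names(.vdwTable)) | out == ""
  for (i in which(need)) {
    nm <- toupper(gsub("[^A-Za-z].*$|^[0-9']+", "", gsub("[0-9']", "",
                                                         name[i])))
    nm0 <- toupper(gsub("[0-9' ]", "", name[i]))
    if (hetero[i] && nchar(nm0) >= 2L && substr(nm0, 1L, 2L) %in% known2) {
      out[i] <- substr(nm0, 1L, 2L)
    } else if (nchar(nm0) >= 1L) {
      out[i] <- substr(nm0, 1L, 1L)
    } else {
      out[i] <- "C"
    }
  }
  out
}

#' Look up van der Waals / covalent radii
#'
#' Unknown elements fall back to 1.70 / 0.76 Angstrom (carbon-like) with a
#' warning.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii (Angstrom).
#' @export
vdwRadius <- function(element) {
  el <- toupper(element)
  r <- unname(.vdwTable[el])
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ", "),
            "; using default vdW radius ", .vdwDefault, " A")
    r[is.na(r)] <- .vdwDefault
  }
  r
}

#' @rdname vdwRadius
#' @export
covalentRadius <- function(element) {
  el <- toupper(element)
  r <- unname(.covTable[el])
  if (anyNA(r)) r[is.na(r)] <- .covDefault
  r
}

isWaterName <- function(resname) toupper(trimws(resname)) %in% .waterNames
isIonName <- function(resname) toupper(trimws(resname)) %in% .ionNames
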