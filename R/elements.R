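#' Element parameter table
#'
#' Fixed internal table of atomic masses (amu) and van der Waals radii
#' (Angstrom) used to annotate atoms read from coordinate files. Masses are
#' IUPAC 2021 standard atomic weights; radii are the Bondi set. The table is
#' shipped with the package so that entropy and contact-area results are
#' reproducible without any external parameter source.
#'
#' @return A data.frame with columns `element`, `mass` (amu) and `vdw`
#'   (Angstrom).
#' @examples
#' elementTable()
#' @export
elementTable <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I", "SE"),
    mass = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974,
             18.998, 35.45, 79.904, 126.904, 78.971),
    vdw = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80,
            1.47, 1.75, 1.85, 1.98, 1.90),
    stringsAsFactors = FALSE
  )
}

# Look up masses / radii for a vector of element symbols; errors list the
# offending atoms so bad inputs fail loudly rather than propagating NAs.
.elementParams <- function(elements, atomNames = NULL) {
  tab <- elementTable()
  idx <- match(toupper(elements), tab$element)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    lab <- if (is.null(atomNames)) elements[bad] else
      paste0(atomNames[bad], " (element '", elements[bad], "')")
    stop("unknown element for atom(s): ", paste(unique(lab), collapse = ", "))
  }
  list(mass = tab$mass[idx], vdw = tab$vdw[idx])
}
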