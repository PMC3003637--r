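#' Average amino-acid mass table
#'
#' Returns the residue-mass table used for peptide mass and m/z arithmetic:
#' average (isotope-abundance weighted) residue masses in Da for the 20
#' standard amino acids, the mass of water (added once per peptide for the
#' termini) and the proton mass.  Average rather than monoisotopic masses are
#' the package default because the bundled tables' printed m/z values (read
#' manually from ion-trap spectra) agree with average masses.  Cysteine is
#' unmodified (no carbamidomethylation).
#'
#' @param path Optional path to a custom key-value mass table (tab-separated:
#'   residue code or `water`/`proton`, then mass in Da); defaults to the
#'   bundled table.
#' @return An object of class `aa_mass_table`: a list with `residue` (named
#'   numeric vector over the 20 codes), `water` and `proton`.
#' @examples
#' m <- amino_acid_masses()
#' m$residue[["G"]]
#' @export
amino_acid_masses <- function(path = NULL) {
  if (is.null(path)) path <- qsrrpep_extdata("average_masses.tsv")
  raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("key", "mass"),
                           colClasses = c("character", "numeric"))
  residue <- stats::setNames(raw$mass[!raw$key %in% c("water", "proton")],
                             raw$key[!raw$key %in% c("water", "proton")])
  missing <- setdiff(AA_CODES, names(residue))
  if (length(missing) > 0L) {
    stop("mass table lacks residues: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(residue <= 0) || !all(c("water", "proton") %in% raw$key)) {
    stop("mass table must list positive masses plus 'water' and 'proton'",
         call. = FALSE)
  }
  structure(
    list(residue = residue,
         water = raw$mass[raw$key == "water"],
         proton = raw$mass[raw$key == "proton"]),
    class = "aa_mass_table"
  )
}

#' Neutral average mass of a peptide
#'
#' Sum of residue masses plus one water (the N- and C-terminal H and OH).
#'
#' @param p Peptide sequence.
#' @param masses An `aa_mass_table`, by default [amino_acid_masses()].
#' @return Neutral mass in Da.
#' @examples
#' average_mass("G")  # glycine: 75.07 Da
#' @export
average_mass <- function(p, masses = amino_acid_masses()) {
  seq <- parse_peptide(p)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(masses$residue[chars]) + masses$water
}

#' Mass-to-charge ratio of a protonated peptide
#'
#' `(M + z * m_proton) / z` with M the neutral average mass.
#'
#' @param p Peptide sequence.
#' @param charge Positive integer charge state.
#' @param masses An `aa_mass_table`.
#' @return m/z in Thomson.
#' @examples
#' mz("LVNEVTEFAK", 2)  # ~575.66
#' @export
mz <- function(p, charge, masses = amino_acid_masses()) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (average_mass(p, masses) + charge * masses$proton) / charge
}
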