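#' @title QSRR structural descriptors
#' @name descriptors
#' @description Two descriptors drive the retention model: the base-10
#'   logarithm of the sum over a peptide's residues of (retention factor +
#'   1), and an externally calculated octanol-water logP (clogP) that the
#'   package consumes as an input column, never computes.
NULL

#' Sum of (k + 1) over a peptide's residues
#'
#' Equals `length + sum of k over retained residues`; the "+1" per residue
#' keeps the logarithm defined for peptides with no retained residue.
#'
#' @param p Peptide sequence.
#' @param kt A `retention_factors` table (default the solved package table,
#'   [default_retention_factors()]).
#' @return Dimensionless sum, always >= peptide length.
#' @examples
#' sum_k_plus_1("QQNQSAEQNK")  # no retained residues: 10
#' @export
sum_k_plus_1 <- function(p, kt = default_retention_factors()) {
  seq <- parse_peptide(p)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  nchar(seq) + sum(unclass(kt)[chars])
}

#' Composite hydrophobicity descriptor log10 Sum(k+1)
#'
#' @inheritParams sum_k_plus_1
#' @return Base-10 logarithm of [sum_k_plus_1()].
#' @examples
#' log_sum_descriptor("QQNQSAEQNK")      # exactly 1
#' log_sum_descriptor("QQNQSAEQNKQQNS")  # log10(14) = 1.1461
#' @export
log_sum_descriptor <- function(p, kt = default_retention_factors()) {
  log10(sum_k_plus_1(p, kt))
}

#' Compute descriptors for a peptide table
#'
#' Adds (or overwrites) the `log_sum_k1` column from the sequences.  clogP
#' is never computed in-package (the source values come from an external
#' logP predictor); if a `clogp` column is present, rows with missing clogP
#' are flagged in the `clogp_missing` column and a warning names them --
#' such rows carry no complete descriptor pair and should be excluded from
#' model fitting.
#'
#' @param tab A peptide table (data frame with `peptide_sequence`).
#' @param kt A `retention_factors` table.
#' @return The table with `log_sum_k1` (and `clogp_missing` when `clogp`
#'   exists), stage marked `"descriptors"`.
#' @export
add_descriptors <- function(tab, kt = default_retention_factors()) {
  stopifnot(is.data.frame(tab), "peptide_sequence" %in% names(tab))
  tab$log_sum_k1 <- vapply(tab$peptide_sequence, log_sum_descriptor,
                           numeric(1), kt = kt, USE.NAMES = FALSE)
  if ("clogp" %in% names(tab)) {
    tab$clogp_missing <- !is.finite(tab$clogp)
    if (any(tab$clogp_missing)) {
      warning("missing clogP for row(s) ",
              paste(which(tab$clogp_missing), collapse = ", "),
              "; flagged via clogp_missing (excluded from modelling)",
              call. = FALSE)
    }
  }
  table_stage(tab) <- "descriptors"
  tab
}

#' Attach externally computed clogP values
#'
#' @param tab A peptide table.
#' @param clogp Numeric vector, one value per row (NA allowed; flagged).
#' @return The table with a `clogp` column (stored verbatim) and a
#'   `clogp_missing` flag.
#' @export
attach_clogp <- function(tab, clogp) {
  stopifnot(is.data.frame(tab))
  if (length(clogp) != nrow(tab)) {
    stop("need one clogP value per record (", nrow(tab), " rows, ",
         length(clogp), " values)", call. = FALSE)
  }
  tab$clogp <- as.numeric(clogp)
  tab$clogp_missing <- !is.finite(tab$clogp)
  if (any(tab$clogp_missing)) {
    warning("missing clogP for row(s) ",
            paste(which(tab$clogp_missing), collapse = ", "),
            "; flagged via clogp_missing (excluded from modelling)",
            call. = FALSE)
  }
  tab
}
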