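#' @title Peptide sequence handling
#' @name peptide
#' @description Validation, in-silico tryptic digestion and missed-cleavage
#'   counting for peptides over the 20 standard one-letter amino-acid codes.
NULL

AA_CODES <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Validate a peptide sequence
#'
#' Trims whitespace, folds to upper case and checks that every character is
#' one of the 20 standard one-letter amino-acid codes.
#'
#' @param text Character scalar, the sequence (case-insensitive).
#' @return The validated upper-case sequence as a character scalar.
#' @examples
#' parse_peptide("LVNEVTEFAK")
#' parse_peptide("g")  # "G"
#' @export
parse_peptide <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("peptide must be a single character string", call. = FALSE)
  }
  seq <- toupper(trimws(text))
  if (!nzchar(seq)) {
    stop("peptide sequence is empty", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_CODES)
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid residue '%s' at position %d (not a standard amino-acid code)",
      chars[bad[1]], bad[1]), call. = FALSE)
  }
  seq
}

#' Count missed tryptic cleavage sites in a peptide
#'
#' A missed cleavage is a lysine (K) or arginine (R) at any position except
#' the C-terminus.  No proline exception is applied: a K/R followed by P
#' still counts as a cleavage site, matching the bookkeeping of the bundled
#' calibration table (its 29-mer with an internal K-P site is listed with 5
#' missed cleavages, which only the no-exception rule yields).
#'
#' @param p Peptide sequence (validated via [parse_peptide()]).
#' @return Integer count of internal K/R residues.
#' @examples
#' count_missed_cleavages("KIKVYLPR")  # 2
#' count_missed_cleavages("AAAA")      # 0
#' @export
count_missed_cleavages <- function(p) {
  seq <- parse_peptide(p)
  if (nchar(seq) == 1L) return(0L)
  internal <- substring(seq, 1L, nchar(seq) - 1L)
  chars <- strsplit(internal, "", fixed = TRUE)[[1]]
  sum(chars %in% c("K", "R"))
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every K or R (no proline exception) and
#' returns all fragments spanning up to `max_missed` internal cleavage
#' sites.  Fully cleaved fragments (0 missed cleavages) partition the parent
#' sequence; fragments with missed cleavages are concatenations of adjacent
#' fully cleaved fragments.
#'
#' @param protein Protein sequence (any length >= 1; case-insensitive).
#' @param max_missed Maximum number of missed cleavage sites per fragment
#'   (non-negative integer; default 0).
#' @return A data frame with columns `peptide_sequence`, `start`, `end`
#'   (1-based positions in the parent) and `missed_cleavages`, ordered by
#'   start position then by missed-cleavage count.
#' @examples
#' tryptic_digest("GAKRLM")             # GAK, R, LM
#' tryptic_digest("GAKRLM", max_missed = 1)
#' @export
tryptic_digest <- function(protein, max_missed = 0L) {
  seq <- parse_peptide(protein)
  max_missed <- as.integer(max_missed)
  if (is.na(max_missed) || max_missed < 0L) {
    stop("max_missed must be a non-negative integer", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  # cut points: after each internal K/R
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts < n]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  n_frag <- length(starts)

  rows <- vector("list", n_frag)
  for (i in seq_len(n_frag)) {
    upper <- min(n_frag, i + max_missed)
    js <- i:upper
    rows[[i]] <- data.frame(
      peptide_sequence = vapply(js, function(j)
        substring(seq, starts[i], ends[j]), character(1)),
      start = starts[i],
      end = ends[js],
      missed_cleavages = js - i,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Digest proteins from a FASTA file
#'
#' Reads a multi-record protein FASTA file and applies [tryptic_digest()] to
#' each record, keeping the description line as the protein label.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @param max_missed Maximum missed cleavages per fragment.
#' @return A data frame with columns `protein`, `peptide_sequence`, `start`,
#'   `end` and `missed_cleavages`.
#' @export
digest_fasta <- function(path, max_missed = 0L) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             whole.header = TRUE)
  out <- lapply(seq_along(recs), function(i) {
    frag <- tryptic_digest(as.character(recs[[i]]), max_missed = max_missed)
    cbind(protein = attr(recs[[i]], "Annot"), frag,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$protein <- sub("^>", "", out$protein)
  rownames(out) <- NULL
  out
}
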