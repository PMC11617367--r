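#' Tryptic-status flag
#'
#' A peptide is counted as tryptic when its C-terminal residue is arginine
#' or lysine, consistent with trypsin cleavage.
#'
#' @param seqs character vector of peptide sequences.
#' @return logical vector.
#' @examples
#' is_tryptic(c("GLYGGPSYGYGAPTSQR", "YGEEMADHCPS"))
#' @export
is_tryptic <- function(seqs) {
  if (any(!nzchar(seqs))) dp_input_error("is_tryptic: empty sequence")
  substring(seqs, nchar(seqs), nchar(seqs)) %in% c("R", "K")
}

#' Average molecular mass in kDa
#'
#' Sum of standard average residue masses plus one water, over 1000.
#' Monoisotopic masses are deliberately not used: the reported contig masses
#' follow the average-mass convention.
#'
#' @param seqs character vector of canonical-residue sequences.
#' @return numeric vector (kDa, unrounded).
#' @examples
#' average_mass_kda("G")  # 0.0750672
#' @export
average_mass_kda <- function(seqs) {
  vapply(seqs, function(s) {
    ch <- seq_chars(s)
    bad <- which(!(ch %in% AA20))
    if (length(bad))
      dp_input_error("non-canonical residue '%s' at position %d of '%s'",
                     ch[bad[1]], bad[1], s)
    (sum(AA_AVG_MASS[ch]) + WATER_AVG_MASS) / 1000
  }, 0.0, USE.NAMES = FALSE)
}

#' Aliphatic index
#'
#' Ikai's relative-volume measure of aliphatic side chains:
#' `AI = X_Ala + 2.9 * X_Val + 3.9 * (X_Ile + X_Leu)` with `X_r` the mole
#' percent of residue r. Values of 70 or more conventionally flag a
#' thermostable sequence.
#'
#' @param seqs character vector of sequences.
#' @param rounded round half-up to integer for reporting (default FALSE).
#' @return numeric vector.
#' @examples
#' aliphatic_index("GLYGGPSYGYGAPTSQR")                  # 28.82...
#' aliphatic_index("GLYGGPSYGYGAPTSQR", rounded = TRUE)  # 29
#' @export
aliphatic_index <- function(seqs, rounded = FALSE) {
  ai <- vapply(seqs, function(s) {
    if (!nzchar(s)) dp_input_error("aliphatic_index: empty sequence")
    ch <- seq_chars(s)
    n <- length(ch)
    xa <- 100 * sum(ch == "A") / n
    xv <- 100 * sum(ch == "V") / n
    xil <- 100 * sum(ch == "I" | ch == "L") / n
    xa + 2.9 * xv + 3.9 * xil
  }, 0.0, USE.NAMES = FALSE)
  if (rounded) round_half_up(ai) else ai
}

#' Physicochemical property table for peptides or contigs
#'
#' @param seqs character vector of sequences.
#' @return data.frame with `sequence`, `length_aa`, `mw_kda` (rounded to one
#'   decimal below 10 kDa, to integer above), `aliphatic_index` (rounded
#'   half-up to integer), `tryptic`, `thermostable` (AI >= 70).
#' @export
peptide_properties <- function(seqs) {
  mw <- average_mass_kda(seqs)
  ai <- aliphatic_index(seqs, rounded = TRUE)
  data.frame(
    sequence = seqs,
    length_aa = nchar(seqs),
    mw_kda = ifelse(mw < 10, round_half_up(mw, 1L), round_half_up(mw)),
    aliphatic_index = ai,
    tryptic = is_tryptic(seqs),
    thermostable = ai >= 70,
    stringsAsFactors = FALSE)
}
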