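#' Read a reference proteome from FASTA
#'
#' Headers are parsed as UniProt-style `db|ACCESSION|NAME` when possible,
#' otherwise the first whitespace-delimited token becomes the accession.
#' Sequences are uppercased and validated against the 20-letter amino-acid
#' alphabet; ambiguity codes (B, Z, X) and the rare residues U/O are rejected
#' because the downstream mass and aliphatic-index formulas are defined only
#' for canonical residues.
#'
#' @param path FASTA file.
#' @return a data.frame with columns `accession`, `name`, `sequence`,
#'   `length_aa` (one row per record).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) dp_input_error("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) dp_input_error("FASTA format error in %s: %s",
                                                     path, conditionMessage(e)))
  if (length(set) == 0L) dp_input_error("FASTA file %s contains no records", path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  acc <- character(length(seqs)); nm <- character(length(seqs))
  for (i in seq_along(headers)) {
    tok <- strsplit(headers[i], "[ \t]")[[1]][1]
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) {
      acc[i] <- parts[2]
      nm[i] <- if (length(parts) >= 3L) parts[3] else ""
    } else {
      acc[i] <- tok
      nm[i] <- ""
    }
  }
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L)
      dp_input_error("record '%s' has an empty sequence", acc[i])
    bad <- which(!(seq_chars(seqs[i]) %in% AA20))
    if (length(bad))
      dp_input_error("record '%s': illegal residue '%s' at position %d",
                     acc[i], substr(seqs[i], bad[1], bad[1]), bad[1])
  }
  if (anyDuplicated(acc))
    dp_input_error("duplicate accession(s): %s",
                   paste(unique(acc[duplicated(acc)]), collapse = ", "))
  data.frame(accession = acc, name = nm, sequence = seqs,
             length_aa = nchar(seqs), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a reference proteome to FASTA
#'
#' Inverse of [read_fasta()]; headers are written as `sp|ACC|NAME` (or the
#' bare accession when no name is present), 60 residues per line.
#'
#' @param db data.frame with `accession`, `sequence` and optionally `name`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  stopifnot(all(c("accession", "sequence") %in% names(db)))
  nm <- if ("name" %in% names(db)) db$name else rep("", nrow(db))
  hdr <- ifelse(nzchar(nm), paste0("sp|", db$accession, "|", nm), db$accession)
  set <- Biostrings::AAStringSet(db$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
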