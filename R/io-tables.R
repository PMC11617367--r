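## TSV readers/writers for identification tables, plus the bracket PTM
## notation used throughout: the bracketed three-letter code REPLACES the
## modified residue letter, so "A[SEP]QPQALLVIAR" is the peptide
## "ASQPQALLVIAR" with a phosphoserine at position 2 (SEP stands for the
## phosphorylated serine itself; likewise TPO for Thr and PTR for Tyr).
## A bracketed tag that is not a phospho code attaches to the preceding
## residue instead (it annotates rather than replaces).

#' Parse bracket-annotated peptide notation
#'
#' @param x character vector of sequences possibly carrying `[SEP]`, `[TPO]`,
#'   `[PTR]` (each replacing its phosphorylated residue's letter) or other
#'   bracketed tags (attached to the preceding residue).
#' @return a list with one element per input: `sequence` (plain) and
#'   `modifications`, a data.frame of `position` (1-based) and `mod_type`.
#' @examples
#' parse_mod_sequence("A[SEP]QPQALLVIAR")[[1]]
#' @export
parse_mod_sequence <- function(x) {
  lapply(x, function(s) {
    plain <- character(0)
    mods_pos <- integer(0); mods_type <- character(0)
    i <- 1L; n <- nchar(s); pos <- 0L
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch == "[") {
        j <- regexpr("]", substr(s, i, n), fixed = TRUE)
        if (j < 0L) dp_input_error("unterminated '[' in sequence '%s'", s)
        tag <- substr(s, i + 1L, i + j - 2L)
        if (tag %in% names(PHOSPHO_MODS)) {
          ## the code stands in for the modified residue itself
          pos <- pos + 1L
          plain <- c(plain, PHOSPHO_MODS[[tag]])
        } else if (pos == 0L) {
          dp_input_error("modification tag '[%s]' precedes any residue in '%s'",
                         tag, s)
        }
        mods_pos <- c(mods_pos, pos)
        mods_type <- c(mods_type, tag)
        i <- i + j
      } else {
        pos <- pos + 1L
        plain <- c(plain, ch)
        i <- i + 1L
      }
    }
    seqn <- paste(plain, collapse = "")
    validate_mods(seqn, mods_pos, mods_type)
    list(sequence = seqn,
         modifications = data.frame(position = mods_pos, mod_type = mods_type,
                                    stringsAsFactors = FALSE))
  })
}

## A phospho tag must sit on its cognate residue (S<->SEP, T<->TPO, Y<->PTR).
validate_mods <- function(seqn, pos, type) {
  if (length(pos) == 0L) return(invisible(TRUE))
  if (any(pos < 1L | pos > nchar(seqn)))
    dp_input_error("modification position out of range in '%s'", seqn)
  for (k in seq_along(pos)) {
    if (type[k] %in% names(PHOSPHO_MODS)) {
      expected <- PHOSPHO_MODS[[type[k]]]
      got <- substr(seqn, pos[k], pos[k])
      if (got != expected)
        dp_input_error("%s annotated on '%s' at position %d of '%s' (expected %s)",
                       type[k], got, pos[k], seqn, expected)
    }
  }
  invisible(TRUE)
}

## Render a plain sequence + modification table back to bracket notation
## (phospho codes replace their residue letter; other tags follow it).
format_mod_sequence <- function(sequence, modifications) {
  if (is.null(modifications) || nrow(modifications) == 0L) return(sequence)
  m <- modifications[order(modifications$position), , drop = FALSE]
  out <- ""
  last <- 0L
  for (k in seq_len(nrow(m))) {
    phospho <- m$mod_type[k] %in% names(PHOSPHO_MODS)
    upto <- if (phospho) m$position[k] - 1L else m$position[k]
    out <- paste0(out, substr(sequence, last + 1L, upto),
                  "[", m$mod_type[k], "]")
    last <- m$position[k]
  }
  paste0(out, substr(sequence, last + 1L, nchar(sequence)))
}

#' Read library-search peptide identifications
#'
#' Expects a TSV with header `sample_id, group, peptide, proteins, mods`;
#' `proteins` is `;`-separated accessions, `mods` is `pos:type`
#' pairs separated by `;` (may be empty — bracket notation inside `peptide`
#' is also accepted and merged).
#'
#' @param path TSV file.
#' @param groups allowed group labels, first = case. Default
#'   `c("case", "control")`.
#' @return data.frame with columns `sample_id`, `group`, `sequence`,
#'   `proteins` (list column), `modifications` (list column of data.frames),
#'   `strategy` (`"library"`).
#' @export
read_library_hits <- function(path, groups = c("case", "control")) {
  tab <- read_tsv_checked(path, c("sample_id", "group", "peptide",
                                  "proteins", "mods"))
  if (nrow(tab) == 0L) {
    warning("empty identification table: ", path)
    return(empty_library_hits())
  }
  bad <- which(!(tab$group %in% groups))
  if (length(bad))
    dp_input_error("row %d: unknown group label '%s' (allowed: %s)",
                   bad[1], tab$group[bad[1]], paste(groups, collapse = ", "))
  parsed <- parse_mod_sequence(tab$peptide)
  seqs <- vapply(parsed, `[[`, "", "sequence")
  mods <- lapply(seq_len(nrow(tab)), function(i) {
    m <- parsed[[i]]$modifications
    extra <- tab$mods[i]
    if (!is.na(extra) && nzchar(extra)) {
      for (pair in strsplit(extra, ";", fixed = TRUE)[[1]]) {
        kv <- strsplit(trimws(pair), ":", fixed = TRUE)[[1]]
        if (length(kv) != 2L)
          dp_input_error("row %d: malformed mods entry '%s'", i, pair)
        p <- suppressWarnings(as.integer(kv[1]))
        if (is.na(p)) dp_input_error("row %d: non-integer mod position '%s'", i, kv[1])
        validate_mods(seqs[i], p, kv[2])
        m <- rbind(m, data.frame(position = p, mod_type = kv[2],
                                 stringsAsFactors = FALSE))
      }
    }
    m
  })
  check_sequences(seqs, path)
  data.frame(sample_id = tab$sample_id, group = tab$group, sequence = seqs,
             proteins = I(strsplit(tab$proteins, ";", fixed = TRUE)),
             modifications = I(mods),
             strategy = "library", stringsAsFactors = FALSE)
}

empty_library_hits <- function() {
  data.frame(sample_id = character(0), group = character(0),
             sequence = character(0), proteins = I(list()),
             modifications = I(list()), strategy = character(0),
             stringsAsFactors = FALSE)
}

#' Read de novo peptide reads
#'
#' Expects a TSV with header `sample_id, peptide, confidence`; `confidence`
#' is a comma-separated list of per-residue reals in \[0, 1\], one per
#' residue.
#'
#' @param path TSV file.
#' @return data.frame with `sample_id`, `sequence`, `confidence`
#'   (list column of numeric vectors).
#' @export
read_denovo_reads <- function(path) {
  tab <- read_tsv_checked(path, c("sample_id", "peptide", "confidence"))
  if (nrow(tab) == 0L) {
    warning("empty de novo read table: ", path)
    return(data.frame(sample_id = character(0), sequence = character(0),
                      confidence = I(list()), stringsAsFactors = FALSE))
  }
  check_sequences(tab$peptide, path)
  conf <- lapply(strsplit(tab$confidence, ",", fixed = TRUE), as.numeric)
  for (i in seq_along(conf)) {
    if (anyNA(conf[[i]]) || any(conf[[i]] < 0) || any(conf[[i]] > 1))
      dp_input_error("row %d: confidence values must be reals in [0,1]", i)
    if (length(conf[[i]]) != nchar(tab$peptide[i]))
      dp_input_error("row %d: %d confidence values for a %d-residue read",
                     i, length(conf[[i]]), nchar(tab$peptide[i]))
  }
  data.frame(sample_id = tab$sample_id, sequence = tab$peptide,
             confidence = I(conf), stringsAsFactors = FALSE)
}

#' Read a plasma reference-concentration table
#'
#' @param path TSV with header `accession, concentration_g_per_L`.
#' @return named numeric vector of concentrations in g/L.
#' @export
read_abundance <- function(path) {
  tab <- read_tsv_checked(path, c("accession", "concentration_g_per_L"))
  conc <- as.numeric(tab$concentration_g_per_L)
  if (anyNA(conc) || any(conc <= 0))
    dp_input_error("concentrations must be positive reals (file %s)", path)
  setNames(conc, tab$accession)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) dp_input_error("file not found: %s", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", comment.char = "#",
                           check.names = FALSE)
  unknown <- setdiff(names(tab), required)
  if (length(unknown))
    dp_input_error("%s: unknown column(s): %s", path,
                   paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(tab))
  if (length(missing))
    dp_input_error("%s: missing column(s): %s", path,
                   paste(missing, collapse = ", "))
  tab
}

check_sequences <- function(seqs, path) {
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) dp_input_error("%s row %d: empty sequence", path, i)
    bad <- which(!(seq_chars(seqs[i]) %in% AA20))
    if (length(bad))
      dp_input_error("%s row %d: illegal residue '%s' at position %d",
                     path, i, substr(seqs[i], bad[1], bad[1]), bad[1])
  }
  invisible(TRUE)
}

#' Write library hits / de novo reads back to their TSV dialects
#'
#' @param hits data.frame as returned by [read_library_hits()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_library_hits <- function(hits, path) {
  mods <- vapply(seq_len(nrow(hits)), function(i) {
    m <- hits$modifications[[i]]
    if (is.null(m) || nrow(m) == 0L) return("")
    paste(sprintf("%d:%s", m$position, m$mod_type), collapse = ";")
  }, "")
  out <- data.frame(sample_id = hits$sample_id, group = hits$group,
                    peptide = hits$sequence,
                    proteins = vapply(hits$proteins, paste, "", collapse = ";"),
                    mods = mods, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_hits
#' @param reads data.frame as returned by [read_denovo_reads()].
#' @export
write_denovo_reads <- function(reads, path) {
  out <- data.frame(
    sample_id = reads$sample_id, peptide = reads$sequence,
    confidence = vapply(reads$confidence,
                        function(v) paste(format(v, trim = TRUE, digits = 6),
                                          collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
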