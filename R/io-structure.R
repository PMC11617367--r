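#' Read a protein structure (PDB or mmCIF)
#'
#' Thin wrapper over bio3d that normalizes either encoding into a single
#' atom table. Only polymer (`ATOM`) records are kept; the first model is
#' used when several are present. The B-factor column is carried through as
#' the per-residue confidence channel (AlphaFold models store pLDDT there).
#'
#' @param path a `.pdb` or `.cif` file (format chosen by extension; anything
#'   not ending in `.cif` is parsed as PDB).
#' @return an object of class `dualprot_structure`: a list with `atoms`
#'   (data.frame: `atom_name`, `element`, `x`, `y`, `z`, `occupancy`,
#'   `b_factor`, `residue_index`, `residue_name`, `chain`) and `path`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) dp_input_error("structure file not found: %s", path)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) dp_input_error("cannot parse structure %s: %s",
                                       path, conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) dp_input_error("no polymer atoms in %s", path)
  elem <- toupper(trimws(as.character(a$elesy)))
  miss <- is.na(elem) | !nzchar(elem)
  if (any(miss)) {
    warning(sum(miss), " atom(s) lack an element symbol; inferred from atom name")
    elem[miss] <- substr(gsub("[^A-Za-z].*", "", trimws(a$elety[miss])), 1, 1)
    elem[miss] <- toupper(elem[miss])
  }
  atoms <- data.frame(
    atom_name = trimws(a$elety),
    element = elem,
    x = a$x, y = a$y, z = a$z,
    occupancy = a$o,
    b_factor = a$b,
    residue_index = a$resno,
    residue_name = trimws(a$resid),
    chain = as.character(a$chain),
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    dp_input_error("non-finite coordinates in %s", path)
  new_structure(atoms, path)
}

new_structure <- function(atoms, path = NA_character_) {
  structure(list(atoms = atoms, path = path), class = "dualprot_structure")
}

#' @export
print.dualprot_structure <- function(x, ...) {
  res <- unique(paste(x$atoms$chain, x$atoms$residue_index))
  cat(sprintf("dualprot structure: %d atoms, %d residues, chain(s) %s\n",
              nrow(x$atoms), length(res),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' One-letter sequence of a structure chain
#'
#' @param model a `dualprot_structure`.
#' @param chain chain id (default: first chain present).
#' @return character scalar; unknown residue names become `X`.
#' @export
structure_sequence <- function(model, chain = NULL) {
  a <- model$atoms
  chain <- chain %||% a$chain[1]
  a <- a[a$chain == chain, , drop = FALSE]
  per_res <- a[!duplicated(a$residue_index), , drop = FALSE]
  per_res <- per_res[order(per_res$residue_index), , drop = FALSE]
  three <- per_res$residue_name
  one <- bio3d::aa321(three)
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

## Per-residue B-factor summary for one chain (mean over heavy atoms).
residue_bfactors <- function(model, chain = NULL) {
  a <- model$atoms
  chain <- chain %||% a$chain[1]
  a <- a[a$chain == chain, , drop = FALSE]
  vapply(split(a$b_factor, a$residue_index), mean, 0.0)
}

#' Write a structure model as PDB
#'
#' @param model a `dualprot_structure`.
#' @param path output `.pdb` file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, format_atom_name(a$atom_name[i]), a$residue_name[i], a$chain[i],
            a$residue_index[i], a$x[i], a$y[i], a$z[i],
            a$occupancy[i], a$b_factor[i], a$element[i])
  }, "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## PDB columns 13-16: names of 1-3 characters start in column 14
format_atom_name <- function(x) {
  ifelse(nchar(x) >= 4L, substr(x, 1, 4), paste0(" ", formatC(x, width = -3)))
}
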