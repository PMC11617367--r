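#' Map a contig onto a reference database
#'
#' Aligns the contig against every database protein, keeps the best hit
#' (maximal identity; ties broken by longer alignment, then database order)
#' and classifies the contig: `canonical` at 100% identity,
#' `noncanonical_variant` in \[`min_identity`, 100), `unmatched` below the
#' gate or with no hit. An alignment must cover at least half of the contig
#' to count as a hit at all.
#'
#' @param sequence contig (or peptide) sequence.
#' @param db reference data.frame from [read_fasta()].
#' @param min_identity identity gate in percent (default 75).
#' @param il_equivalent treat I/L as identical (default TRUE).
#' @param min_coverage_frac minimum aligned fraction of the contig
#'   (default 0.5).
#' @param ... passed to [align_local()] (scoring scheme).
#' @return list with `alignment` (a `dualprot_alignment` or `NULL`) and
#'   `class` (one of `"canonical"`, `"noncanonical_variant"`, `"unmatched"`).
#' @export
map_contig <- function(sequence, db, min_identity = 75, il_equivalent = TRUE,
                       min_coverage_frac = 0.5, ...) {
  if (nrow(db) == 0L) dp_input_error("map_contig: empty reference database")
  best <- NULL
  for (i in seq_len(nrow(db))) {
    al <- align_local(sequence, db$sequence[i], il_equivalent = il_equivalent,
                      target_accession = db$accession[i], ...)
    if (is.null(al)) next
    if ((al$query_end - al$query_start) < min_coverage_frac * nchar(sequence))
      next
    if (is.null(best) ||
        al$identity_pct > best$identity_pct ||
        (al$identity_pct == best$identity_pct &&
         al$aligned_columns > best$aligned_columns))
      best <- al
  }
  if (is.null(best) || best$identity_pct < min_identity)
    return(list(alignment = best, class = "unmatched"))
  cls <- if (best$identity_pct == 100) "canonical" else "noncanonical_variant"
  list(alignment = best, class = cls)
}

#' Greedy centroid clustering of peptides and contigs
#'
#' Usearch-style single-pass clustering: sequences are sorted by length
#' (descending, ties lexicographic), the first unassigned sequence founds a
#' cluster, and each subsequent sequence joins the first existing centroid to
#' which its identity — `100 * matches / min(length)` from the local
#' alignment — reaches `min_identity`. The min-length denominator lets a
#' tryptic peptide cluster with the longer contig that contains it and with
#' its missed-cleavage extensions.
#'
#' @param ids character vector of sequence identifiers.
#' @param seqs character vector of sequences (same length as `ids`).
#' @param min_identity percent threshold (default 95).
#' @param il_equivalent treat I/L as identical (default TRUE).
#' @param ... scoring scheme, passed to [align_local()].
#' @return data.frame with columns `id`, `sequence`, `cluster` (integer),
#'   `centroid` (the centroid sequence of the cluster).
#' @export
cluster_greedy <- function(ids, seqs, min_identity = 95, il_equivalent = TRUE,
                           ...) {
  if (length(ids) != length(seqs))
    dp_input_error("cluster_greedy: ids and seqs differ in length")
  if (length(ids) == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      cluster = integer(0), centroid = character(0),
                      stringsAsFactors = FALSE))
  ord <- order(-nchar(seqs), seqs, ids)
  centroids <- character(0)
  assign <- integer(length(ids))
  for (k in ord) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      idp <- identity_minlen(seqs[k], centroids[ci],
                             il_equivalent = il_equivalent, ...)
      if (idp >= min_identity) {
        assign[k] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, seqs[k])
      assign[k] <- length(centroids)
    }
  }
  data.frame(id = ids, sequence = seqs, cluster = assign,
             centroid = centroids[assign], stringsAsFactors = FALSE)
}

#' Count proteotypic peptides per protein
#'
#' A peptide is proteotypic when it occurs as a substring of exactly one
#' database protein (I/L-equivalent by default); only such peptides identify
#' their protein unambiguously. Returns, for every accession, the number of
#' distinct detected proteotypic peptides.
#'
#' @param peptides character vector of detected peptide sequences (duplicates
#'   are collapsed).
#' @param db reference data.frame from [read_fasta()].
#' @param il_equivalent treat I/L as identical (default TRUE).
#' @return named integer vector over `db$accession`.
#' @export
count_proteotypic <- function(peptides, db, il_equivalent = TRUE) {
  peptides <- unique(peptides)
  targets <- if (il_equivalent) collapse_il(db$sequence) else db$sequence
  counts <- setNames(integer(nrow(db)), db$accession)
  for (p in peptides) {
    pp <- if (il_equivalent) collapse_il(p) else p
    in_prot <- which(vapply(targets, function(s) grepl(pp, s, fixed = TRUE),
                            FALSE, USE.NAMES = FALSE))
    if (length(in_prot) == 1L)
      counts[in_prot] <- counts[in_prot] + 1L
  }
  counts
}
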