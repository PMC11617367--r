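#' Local pairwise alignment of peptide sequences
#'
#' Optimal Smith-Waterman alignment with affine gaps (full dynamic
#' programming — the reference databases handled here are small enough that
#' BLAST-style seeding is unnecessary). Among co-optimal alignments the one
#' with the smallest target start, then the fewest gap columns, is returned.
#'
#' @param query,target non-empty amino-acid strings.
#' @param match,mismatch,gap_open,gap_extend scoring scheme; a gap of length
#'   L costs `gap_open + (L-1) * gap_extend`. Defaults +2/-1/-3/-1.
#' @param il_equivalent treat I and L as identical (isobaric residues are
#'   indistinguishable to de novo sequencing). Default FALSE here; mapping
#'   functions pass the configured value.
#' @param target_accession optional label carried into the result.
#' @return `NULL` when the best local score is not positive (no hit);
#'   otherwise a list of class `dualprot_alignment`: `score`,
#'   `query_start/query_end` and `target_start/target_end` (0-based
#'   half-open), `aligned_columns`, `matches`, `identity_pct`, `n_gaps`,
#'   `aligned_query`/`aligned_target` (gapped strings), `mismatch_positions`
#'   (data.frame of `query_pos`, `target_pos` 0-based, `query_res`,
#'   `target_res`), and `target_accession`.
#' @examples
#' align_local("PEPTIDE", "XXPEPTIDEXX")$identity_pct  # 100
#' @export
align_local <- function(query, target, match = 2, mismatch = -1,
                        gap_open = -3, gap_extend = -1,
                        il_equivalent = FALSE, target_accession = NA_character_) {
  if (!nzchar(query) || !nzchar(target))
    dp_input_error("align_local requires non-empty sequences")
  q <- if (il_equivalent) collapse_il(query) else query
  t <- if (il_equivalent) collapse_il(target) else target
  raw <- sw_align_cpp(q, t, match, mismatch, gap_open, gap_extend)
  if (!isTRUE(raw$hit)) return(NULL)
  aq <- seq_chars(raw$aligned_query)
  at <- seq_chars(raw$aligned_target)
  is_col <- aq != "-" & at != "-"
  matches <- sum(is_col & aq == at)
  cols <- length(aq)
  ## report mismatches in original residue letters
  qpos <- cumsum(aq != "-") - 1L + raw$query_start
  tpos <- cumsum(at != "-") - 1L + raw$target_start
  mm <- which(is_col & aq != at)
  mismatch_positions <- if (length(mm)) {
    data.frame(
      query_pos = qpos[mm], target_pos = tpos[mm],
      query_res = substring(query, qpos[mm] + 1L, qpos[mm] + 1L),
      target_res = substring(target, tpos[mm] + 1L, tpos[mm] + 1L),
      stringsAsFactors = FALSE)
  } else {
    data.frame(query_pos = integer(0), target_pos = integer(0),
               query_res = character(0), target_res = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(
    score = raw$score,
    query_start = raw$query_start, query_end = raw$query_end,
    target_start = raw$target_start, target_end = raw$target_end,
    aligned_columns = cols, matches = matches,
    identity_pct = 100 * matches / cols,
    n_gaps = raw$n_gaps,
    aligned_query = raw$aligned_query, aligned_target = raw$aligned_target,
    mismatch_positions = mismatch_positions,
    target_accession = target_accession), class = "dualprot_alignment")
}

#' @export
print.dualprot_alignment <- function(x, ...) {
  cat(sprintf("local alignment: score %.1f, identity %.1f%% (%d/%d), target %s [%d,%d)\n",
              x$score, x$identity_pct, x$matches, x$aligned_columns,
              x$target_accession, x$target_start, x$target_end))
  cat(" ", x$aligned_query, "\n ", x$aligned_target, "\n", sep = "")
  invisible(x)
}

#' Percent identity over the shorter sequence
#'
#' The clustering identity: `100 * matches / min(nchar(a), nchar(b))` from
#' the best local alignment, so that a peptide nested in a longer contig (or
#' a missed-cleavage extension) scores 100.
#'
#' @param a,b sequences.
#' @inheritParams align_local
#' @return identity percent in \[0, 100\]; 0 when there is no local hit.
#' @export
identity_minlen <- function(a, b, il_equivalent = FALSE, ...) {
  al <- align_local(a, b, il_equivalent = il_equivalent, ...)
  if (is.null(al)) return(0)
  100 * al$matches / min(nchar(a), nchar(b))
}
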